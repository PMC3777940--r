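#' Regulator activity profiles from expression and connectivity
#'
#' The activity of regulator l in sample m is the median expression, in that
#' sample, of the genes the connectivity matrix marks as bound by l. Rows of
#' the result are the activity profiles of the L regulators across samples.
#' For an even number of bound genes the median is the mean of the two middle
#' order statistics ([stats::median()]).
#'
#' Because coefficient magnitudes are scale-coupled to the activity rows,
#' an optional per-row standardization (`(z - mean(z)) / sd(z)`) is offered:
#' it puts observed and permutation-null activities on a common scale, which
#' sharpens the permutation test. It is off by default so activities remain
#' in expression units.
#'
#' @param expr Expression matrix, genes x samples, gene IDs in rownames.
#' @param conn Binary connectivity matrix, genes x regulators, from
#'   [build_connectivity()]; rownames must equal `rownames(expr)` in the same
#'   order.
#' @param standardize Standardize each activity row to mean 0, sd 1.
#' @return Numeric matrix, regulators x samples, dimnames set.
#' @export
build_activity <- function(expr, conn, standardize = FALSE) {
  if (!identical(rownames(expr), rownames(conn)))
    stop("gene IDs of `expr` and `conn` differ or are ordered differently",
         call. = FALSE)
  if (!all(conn %in% c(0, 1)))
    stop("`conn` must be binary", call. = FALSE)
  sizes <- colSums(conn)
  if (any(sizes == 0))
    stop("regulator(s) with empty target set: ",
         paste(colnames(conn)[sizes == 0], collapse = ", "), call. = FALSE)

  Z <- matrix(NA_real_, nrow = ncol(conn), ncol = ncol(expr),
              dimnames = list(colnames(conn), colnames(expr)))
  for (l in seq_len(ncol(conn))) {
    rows <- conn[, l] == 1
    Z[l, ] <- apply(expr[rows, , drop = FALSE], 2, stats::median)
  }
  if (standardize) {
    sds <- apply(Z, 1, stats::sd)
    if (any(sds == 0))
      stop("cannot standardize constant activity profile(s): ",
           paste(rownames(Z)[sds == 0], collapse = ", "), call. = FALSE)
    Z <- (Z - rowMeans(Z)) / sds
  }
  Z
}
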