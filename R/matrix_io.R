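#' Read a gene-expression matrix from delimited text
#'
#' Expects a header row of sample IDs (the first header cell is ignored) and
#' one row per gene, the first column holding the gene ID. Values are kept in
#' file order; typically they are log-scale expression measurements.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @return Numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs).
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("expression file must contain a header and at least one gene row: ",
         path, call. = FALSE)
  header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L)
    stop("expression file header names no samples: ", path, call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)

  body <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  m <- length(sample_ids)
  vals <- matrix(NA_real_, nrow = length(body), ncol = m,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != m + 1L)
      stop(sprintf("row %d (gene %s) has %d fields, expected %d",
                   i + 1L, gene_ids[i], length(row), m + 1L), call. = FALSE)
    x <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop(sprintf("non-numeric expression value '%s' at gene %s, sample %s",
                   row[bad[1L] + 1L], gene_ids[i], sample_ids[bad[1L]]),
           call. = FALSE)
    vals[i, ] <- x
  }
  vals
}

#' Read regulator-target binding evidence
#'
#' Two layouts are supported. `"pairs"`: two tab-separated columns, regulator
#' then gene, one pair per line. `"sets"`: one regulator per line followed by
#' its target gene IDs (GMT-like; a second description column, marked by
#' a leading `#`, is tolerated and skipped). Duplicate pairs are collapsed
#' with a message; blank lines are skipped with a warning.
#'
#' @param path Path to the file.
#' @param format `"pairs"` or `"sets"`.
#' @return A tibble with columns `regulator` and `gene`, deduplicated, in
#'   first-appearance order.
#' @export
read_binding <- function(path, format = c("pairs", "sets")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("skipped %d blank line(s) in %s", sum(blank), path),
            call. = FALSE)
    lines <- lines[!blank]
  }
  if (!length(lines)) stop("binding file is empty: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  pairs <- if (format == "pairs") {
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop(sprintf("line %d of %s has fewer than 2 fields", bad[1L], path),
           call. = FALSE)
    tibble::tibble(
      regulator = vapply(fields, `[[`, "", 1L),
      gene      = vapply(fields, `[[`, "", 2L)
    )
  } else {
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop(sprintf("line %d of %s names a regulator with no targets",
                   bad[1L], path), call. = FALSE)
    purrr::map_dfr(fields, function(f) {
      genes <- f[-1L]
      # optional description column, GMT style
      if (length(genes) > 1L && startsWith(genes[1L], "#")) genes <- genes[-1L]
      tibble::tibble(regulator = f[[1L]], gene = genes)
    })
  }
  if (any(pairs$regulator == "" | pairs$gene == ""))
    stop("empty regulator or gene ID in ", path, call. = FALSE)
  n0 <- nrow(pairs)
  pairs <- dplyr::distinct(pairs)
  if (nrow(pairs) < n0)
    message(sprintf("collapsed %d duplicate binding pair(s)", n0 - nrow(pairs)))
  pairs
}

#' Build the binary regulator-gene connectivity matrix
#'
#' Entry (i, l) is 1 when regulator l has binding evidence for gene i, 0
#' otherwise. Binding pairs whose gene is absent from the expression matrix
#' are dropped (a message reports the count). Matching is exact,
#' case-sensitive string equality.
#'
#' @param binding Tibble/data frame with columns `regulator`, `gene`
#'   (see [read_binding()]).
#' @param expr Expression matrix from [read_expression()] (gene IDs in
#'   rownames).
#' @param regulator_ids Regulators to include, in column order; defaults to
#'   first-appearance order in `binding`.
#' @param on_empty What to do with a regulator that retains zero targets
#'   after intersection with the expression genes: `"error"` (default) or
#'   `"drop"` (remove its column with a warning).
#' @return Binary matrix, genes x regulators, dimnames set.
#' @export
build_connectivity <- function(binding, expr,
                               regulator_ids = NULL,
                               on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  stopifnot(is.data.frame(binding), all(c("regulator", "gene") %in% names(binding)))
  if (nrow(binding) == 0L)
    stop("binding table is empty; connectivity would have no 1s", call. = FALSE)
  gene_ids <- rownames(expr)
  if (is.null(gene_ids))
    stop("`expr` must carry gene IDs as rownames", call. = FALSE)
  if (is.null(regulator_ids)) regulator_ids <- unique(binding$regulator)
  if (!length(regulator_ids)) stop("no regulators given", call. = FALSE)

  keep <- binding$gene %in% gene_ids & binding$regulator %in% regulator_ids
  dropped <- sum(binding$gene %in% gene_ids == FALSE &
                   binding$regulator %in% regulator_ids)
  if (dropped > 0L)
    message(sprintf("dropped %d binding pair(s) whose gene is absent from the expression matrix",
                    dropped))
  b <- binding[keep, , drop = FALSE]

  C <- matrix(0, nrow = length(gene_ids), ncol = length(regulator_ids),
              dimnames = list(gene_ids, regulator_ids))
  if (nrow(b))
    C[cbind(match(b$gene, gene_ids), match(b$regulator, regulator_ids))] <- 1

  empty <- colSums(C) == 0
  if (any(empty)) {
    who <- paste(regulator_ids[empty], collapse = ", ")
    if (on_empty == "error")
      stop("regulator(s) with no targets in the expression matrix: ", who,
           call. = FALSE)
    warning("dropping regulator(s) with no targets in the expression matrix: ",
            who, call. = FALSE)
    C <- C[, !empty, drop = FALSE]
  }
  C
}

# TSV dialect used for all outputs: UTF-8, tab, '.' decimal, no quoting,
# 12 significant digits.
format_num <- function(x) formatC(x, digits = 12, format = "g")

write_matrix_tsv <- function(m, path, corner = "id") {
  df <- data.frame(rownames(m), apply(m, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(corner, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a numeric matrix written by the package's TSV writer
#'
#' @param path Path to the TSV (first column row IDs, header of column IDs).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write the standard result files of a fit + significance run
#'
#' Writes, under `out_dir`: `Y.tsv` (gene x regulator coefficients),
#' `pvalues.tsv` (matching empirical p-values), `modules.tsv` (long-format
#' module membership: regulator, gene, score, p, direction), and
#' `network.sif` (Cytoscape SIF edge list, `regulator regulates gene`).
#'
#' @param Y Coefficient matrix (genes x regulators).
#' @param pvals P-value matrix with the same dimnames, or `NULL` to skip.
#' @param modules Module table from [extract_modules()], or `NULL` to write
#'   header-only files.
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_rca_outputs <- function(Y, pvals = NULL, modules = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  paths <- c(Y = file.path(out_dir, "Y.tsv"),
             pvalues = file.path(out_dir, "pvalues.tsv"),
             modules = file.path(out_dir, "modules.tsv"),
             network = file.path(out_dir, "network.sif"))

  write_matrix_tsv(Y, paths[["Y"]], corner = "gene")
  if (!is.null(pvals)) {
    stopifnot(identical(dim(pvals), dim(Y)))
    write_matrix_tsv(pvals, paths[["pvalues"]], corner = "gene")
  }

  mod <- if (is.null(modules) || nrow(modules) == 0L) {
    tibble::tibble(regulator = character(), gene = character(),
                   score = double(), p = double(), direction = character())
  } else {
    modules[, intersect(c("regulator", "gene", "score", "p", "direction"),
                        names(modules))]
  }
  out <- as.data.frame(mod)
  if ("score" %in% names(out)) out$score <- format_num(out$score)
  if ("p" %in% names(out)) out$p <- format_num(out$p)
  utils::write.table(out, paths[["modules"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  sif <- data.frame(source = mod$regulator,
                    interaction = rep("regulates", nrow(mod)),
                    target = mod$gene)
  utils::write.table(sif, paths[["network"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
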