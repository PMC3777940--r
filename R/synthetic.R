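#' Simulate a ground-truth regulatory dataset
#'
#' Generates an expression matrix with low-rank sparse structure plus
#' Gaussian noise, together with the binding evidence a study would supply:
#' `X = Y_true Z_true + N(0, noise_sd^2)`, where each column of `Y_true` is
#' non-negative with Hoyer sparseness exactly `sparseness_true` and support
#' sampled uniformly, and `C` is the support pattern of `Y_true` corrupted
#' with the requested false-negative rate (true targets missing from the
#' binding evidence) and false-positive rate (spurious binding calls).
#'
#' Activity models for the rows of `Z_true`:
#' \describe{
#'   \item{`"blocks"`}{piecewise-constant profiles over contiguous sample
#'     blocks, mimicking tumour-subgroup structure (default);}
#'   \item{`"sinusoid"`}{phase-shifted sine waves;}
#'   \item{`"gaussian"`}{i.i.d. standard normals.}
#' }
#' Rows are redrawn (up to 100 times) until every pair has |correlation|
#' below 0.7, so regulator activities are distinguishable.
#'
#' @param n_genes,n_samples,n_regulators Dimensions N, M, L;
#'   `n_regulators <= n_genes`.
#' @param sparseness_true Hoyer sparseness of each true coefficient column.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param conn_fnr,conn_fpr Per-entry corruption rates of the connectivity
#'   matrix relative to the true support, in \[0, 1\].
#' @param activity_model `"blocks"`, `"sinusoid"` or `"gaussian"`.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @return Object of class `rca_sim`: list with `X`, `C`, `Y_true`, `Z_true`,
#'   `params`.
#' @export
simulate_regulatory_data <- function(n_genes, n_samples, n_regulators,
                                     sparseness_true = 0.8, noise_sd = 0.1,
                                     conn_fnr = 0, conn_fpr = 0,
                                     activity_model = c("blocks", "sinusoid",
                                                        "gaussian"),
                                     seed = 1L) {
  activity_model <- match.arg(activity_model)
  stopifnot(n_regulators <= n_genes, n_genes >= 2, n_samples >= 2,
            sparseness_true >= 0, sparseness_true <= 1,
            noise_sd >= 0, conn_fnr >= 0, conn_fnr <= 1,
            conn_fpr >= 0, conn_fpr <= 1)
  set.seed(as.integer(seed))

  gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  sample_ids <- sprintf("s%d", seq_len(n_samples))
  reg_ids <- sprintf("r%d", seq_len(n_regulators))

  Z <- draw_activities(n_regulators, n_samples, activity_model)
  dimnames(Z) <- list(reg_ids, sample_ids)

  # Support size from the sparseness target: a vector with L1/L2 ratio
  # rho = sqrt(n) - s (sqrt(n) - 1) needs at least ceiling(rho^2) non-zeros.
  # Uniform(0.5, 1.5) magnitudes have E[L1/L2] ~= sqrt(k / (13/12)), so
  # k = round(rho^2 * 13/12) makes the projection a small correction and
  # keeps every support magnitude well away from zero.
  rho <- sqrt(n_genes) - sparseness_true * (sqrt(n_genes) - 1)
  k <- min(n_genes, max(2L, ceiling(rho^2), round(rho^2 * 13 / 12)))
  # sparseness the support subvector must carry so the full column hits s
  s_k <- min(1, max(0, (sqrt(k) - rho) / (sqrt(k) - 1)))

  Y <- matrix(0, n_genes, n_regulators, dimnames = list(gene_ids, reg_ids))
  for (l in seq_len(n_regulators)) {
    supp <- sample.int(n_genes, k)
    w <- stats::runif(k, 0.5, 1.5)
    Y[supp, l] <- project_sparse(w, s_k, nonneg = TRUE)
  }

  X <- Y %*% Z
  if (noise_sd > 0)
    X <- X + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                    n_genes, n_samples)
  dimnames(X) <- list(gene_ids, sample_ids)

  supp_mat <- Y > 0
  C <- matrix(0, n_genes, n_regulators, dimnames = dimnames(Y))
  C[supp_mat] <- 1
  if (conn_fnr > 0)
    C[supp_mat][stats::runif(sum(supp_mat)) < conn_fnr] <- 0
  if (conn_fpr > 0)
    C[!supp_mat][stats::runif(sum(!supp_mat)) < conn_fpr] <- 1
  # keep every regulator estimable: restore its strongest true target
  for (l in which(colSums(C) == 0)) C[which.max(Y[, l]), l] <- 1

  structure(list(X = X, C = C, Y_true = Y, Z_true = Z,
                 params = list(n_genes = n_genes, n_samples = n_samples,
                               n_regulators = n_regulators,
                               sparseness_true = sparseness_true,
                               noise_sd = noise_sd, conn_fnr = conn_fnr,
                               conn_fpr = conn_fpr,
                               activity_model = activity_model,
                               seed = as.integer(seed))),
            class = "rca_sim")
}

draw_activities <- function(L, M, model) {
  draw_one <- function() {
    switch(model,
      blocks = {
        n_blocks <- sample(2:min(4, M), 1)
        cuts <- sort(sample(seq_len(M - 1), n_blocks - 1))
        sizes <- diff(c(0, cuts, M))
        rep(stats::rnorm(n_blocks, sd = 1.5), times = sizes)
      },
      sinusoid = sin(2 * pi * (seq_len(M) / M) * stats::runif(1, 0.5, 2) +
                       stats::runif(1, 0, 2 * pi)),
      gaussian = stats::rnorm(M)
    )
  }
  Z <- matrix(0, L, M)
  for (l in seq_len(L)) {
    for (attempt in seq_len(100L)) {
      cand <- draw_one()
      if (stats::sd(cand) == 0) next
      ok <- l == 1 || all(abs(apply(Z[seq_len(l - 1), , drop = FALSE], 1,
                                    stats::cor, y = cand)) < 0.7)
      if (ok) { Z[l, ] <- cand; break }
      if (attempt == 100L)
        stop("could not draw sufficiently uncorrelated activity profiles",
             call. = FALSE)
    }
    if (all(Z[l, ] == 0))
      stop("degenerate activity profile drawn for regulator ", l, call. = FALSE)
  }
  Z
}

#' Score recovery of the true support by a fitted decomposition
#'
#' Per regulator: AUROC of |Y| ranking true-support genes above the rest,
#' and precision/recall of the top-k coefficients at matched sparsity
#' (k = true support size). `rel_residual` is the overall relative
#' reconstruction error `||X - Y Z||_F / ||X||_F`.
#'
#' @param fit An [rca_fit()] result (column order matches the simulated
#'   regulators, since Z is fixed by the connectivity input).
#' @param truth An `rca_sim` object from [simulate_regulatory_data()].
#' @return Tibble with one row per regulator: `regulator`, `auroc`,
#'   `precision`, `recall`, `support_size`, `rel_residual`.
#' @export
score_recovery <- function(fit, truth) {
  Y <- fit$Y
  Yt <- truth$Y_true
  if (!identical(dim(Y), dim(Yt)))
    stop("fit and truth have different dimensions", call. = FALSE)
  res <- purrr::map_dfr(seq_len(ncol(Y)), function(l) {
    pos <- Yt[, l] > 0
    k <- sum(pos)
    top <- rank(-abs(Y[, l]), ties.method = "first") <= k
    tibble::tibble(
      regulator = colnames(Yt)[l],
      auroc = auroc(abs(Y[, l]), pos),
      precision = sum(top & pos) / k,
      recall = sum(top & pos) / k,
      support_size = k
    )
  })
  res$rel_residual <- sqrt(sum((truth$X - Y %*% fit$Z)^2) / sum(truth$X^2))
  res
}

# Rank-based AUROC (Mann-Whitney): probability a random positive scores
# above a random negative, ties counted half.
auroc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
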