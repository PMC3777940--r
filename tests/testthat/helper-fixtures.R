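# Fixture builders shared across the suite. Everything is generated in code;
# no data files are shipped.

write_expr_fixture <- function(values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                                               byrow = TRUE),
                               gene_ids = paste0("g", seq_len(nrow(values))),
                               sample_ids = paste0("s", seq_len(ncol(values))),
                               path = tempfile(fileext = ".tsv")) {
  lines <- c(paste(c("gene", sample_ids), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i)
               paste(c(gene_ids[i], values[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

write_pairs_fixture <- function(pairs, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(pairs, paste, "", collapse = "\t"), path)
  path
}

# A tiny well-specified dataset: disjoint supports and block activities, so
# the median-estimated activity matrix is an exact rescaling of the truth and
# the noiseless decomposition is exactly recoverable.
make_disjoint_sim <- function(n_genes = 60, n_regulators = 3, n_samples = 8,
                              support_size = 10, sparseness = NULL,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  if (is.null(sparseness)) {
    rho <- sqrt(support_size / (13 / 12))
    sparseness <- (sqrt(n_genes) - rho) / (sqrt(n_genes) - 1)
  }
  rho <- sqrt(n_genes) - sparseness * (sqrt(n_genes) - 1)
  s_k <- (sqrt(support_size) - rho) / (sqrt(support_size) - 1)
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  reg_ids <- paste0("r", seq_len(n_regulators))
  Z <- matrix(0, n_regulators, n_samples,
              dimnames = list(reg_ids, paste0("s", seq_len(n_samples))))
  for (l in seq_len(n_regulators)) {
    half <- sample(n_samples - 1, 1)
    Z[l, ] <- rep(rnorm(2, sd = 2), times = c(half, n_samples - half))
  }
  Y <- matrix(0, n_genes, n_regulators, dimnames = list(gene_ids, reg_ids))
  supports <- split(sample(n_genes, support_size * n_regulators),
                    rep(seq_len(n_regulators), each = support_size))
  for (l in seq_len(n_regulators))
    Y[supports[[l]], l] <- project_sparse(runif(support_size, 0.5, 1.5), s_k)
  X <- Y %*% Z
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), sd = noise_sd),
                                    nrow = nrow(X))
  C <- (Y > 0) * 1
  list(X = X, C = C, Y_true = Y, Z_true = Z, sparseness = sparseness)
}

# Exhaustive-geometry oracle for the sparseness projection on n <= 4:
# enumerates points on the exact constraint set
#   {w : sum(w) = k1, ||w||_2 = l2, w >= 0}
# (a sphere slice) and returns the minimal distance to v among them.
grid_oracle_min_dist <- function(v, s, n_points = 4000) {
  n <- length(v)
  stopifnot(n >= 2, n <= 4)
  l2 <- sqrt(sum(v^2))
  k1 <- target_l1(l2, n, s)
  center <- rep(k1 / n, n)
  r2 <- l2^2 - k1^2 / n
  if (r2 < 0) r2 <- 0
  rad <- sqrt(r2)
  # orthonormal basis of the zero-sum hyperplane
  Q <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  U <- switch(as.character(n),
    "2" = matrix(c(1, -1), nrow = 1),
    "3" = {
      th <- seq(0, 2 * pi, length.out = n_points)
      rbind(cos(th), sin(th))
    },
    "4" = {
      # Fibonacci sphere on S^2
      i <- seq_len(n_points) - 0.5
      phi <- acos(1 - 2 * i / n_points)
      th <- pi * (1 + sqrt(5)) * i
      rbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    })
  pts <- center + rad * (Q %*% U)      # n x n_points, exact constraints
  feas <- colSums(pts < -1e-9) == 0    # keep the non-negative arc
  if (!any(feas)) return(Inf)
  sqrt(min(colSums((pts[, feas, drop = FALSE] - v)^2)))
}

# Random connectivity with given per-regulator target counts.
random_connectivity <- function(n_genes, sizes, gene_ids, reg_ids) {
  C <- matrix(0, n_genes, length(sizes), dimnames = list(gene_ids, reg_ids))
  for (l in seq_along(sizes)) C[sample.int(n_genes, sizes[l]), l] <- 1
  C
}
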