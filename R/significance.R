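#' Randomized-binding permutation null for the coefficient matrix
#'
#' For each of `B` runs, every regulator's target set is replaced by a
#' uniformly random gene subset of the same size (drawn without replacement
#' from all genes in `X`, all regulators re-randomized jointly per run), the
#' activity matrix is rebuilt from the random binding, and Y is refit with
#' the same configuration. Null coefficient values are pooled per regulator
#' column across genes and runs (default), or kept per gene with
#' `pool = "per_gene"`.
#'
#' All randomness derives from `seed`: run b uses a sub-seed for both its
#' target-set draw and its Y initialisation, so any single run (and the whole
#' null) is reproducible.
#'
#' @param X Expression matrix, genes x samples.
#' @param C Observed binary connectivity matrix (only its column sizes are
#'   used to size the random target sets).
#' @param config An [rca_config()] shared by all runs.
#' @param B Number of permutation runs (the study default is 1000).
#' @param seed Root seed for the permutation ensemble.
#' @param pool `"column"` (pool null values per regulator across genes and
#'   runs) or `"per_gene"` (retain the N x L x B null array).
#' @return Object of class `rca_null`: list with `per_regulator_null` (named
#'   list of numeric vectors), `per_gene_null` (N x L x B array or `NULL`),
#'   `B`, `seeds`, `pool`.
#' @export
permutation_null <- function(X, C, config = rca_config(), B = 1000L,
                             seed = 1L, pool = c("column", "per_gene")) {
  pool <- match.arg(pool)
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be at least 1", call. = FALSE)
  n <- nrow(X)
  sizes <- colSums(C)
  reg_ids <- colnames(C)

  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, B)

  pooled <- stats::setNames(vector("list", length(reg_ids)), reg_ids)
  for (l in seq_along(pooled)) pooled[[l]] <- vector("list", B)
  per_gene <- if (pool == "per_gene")
    array(NA_real_, dim = c(n, length(reg_ids), B),
          dimnames = list(rownames(X), reg_ids, NULL))
  else NULL

  for (b in seq_len(B)) {
    set.seed(run_seeds[b])
    Cb <- matrix(0, n, length(reg_ids), dimnames = dimnames(C))
    for (l in seq_along(reg_ids))
      Cb[sample.int(n, sizes[l]), l] <- 1
    cfg <- config
    cfg$seed <- run_seeds[b]
    fit_b <- tryCatch(rca_fit(X, Cb, cfg), error = function(e)
      stop(sprintf("permutation run %d failed: %s", b, conditionMessage(e)),
           call. = FALSE))
    for (l in seq_along(reg_ids)) pooled[[l]][[b]] <- fit_b$Y[, l]
    if (!is.null(per_gene)) per_gene[, , b] <- fit_b$Y
  }
  structure(list(
    per_regulator_null = purrr::map(pooled, ~ unname(do.call(c, .x))),
    per_gene_null = per_gene,
    B = B, seeds = run_seeds, pool = pool
  ), class = "rca_null")
}

#' Empirical p-values of observed coefficients against the permutation null
#'
#' Right-tail add-one estimator: `p = (1 + #{null >= observed}) / (1 + K)`
#' where K is the size of the null pool, so p is never zero and its minimum
#' attainable value is `1/(K+1)`. The comparison is on coefficient magnitude
#' (identical to the raw value in non-negative mode). In column mode the pool
#' is the regulator's full null column ensemble; in per-gene mode each gene
#' is compared with its own B null values.
#'
#' @param Y Observed coefficient matrix (genes x regulators).
#' @param null An `rca_null` from [permutation_null()].
#' @return Numeric matrix of p-values in (0, 1\] with the dimnames of `Y`.
#' @export
empirical_pvalues <- function(Y, null) {
  stopifnot(inherits(null, "rca_null"))
  reg_ids <- colnames(Y)
  missing_reg <- setdiff(reg_ids, names(null$per_regulator_null))
  if (length(missing_reg))
    stop("regulator(s) absent from the null: ",
         paste(missing_reg, collapse = ", "), call. = FALSE)

  P <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  if (null$pool == "per_gene") {
    for (l in seq_along(reg_ids)) {
      nv <- abs(null$per_gene_null[, reg_ids[l], , drop = FALSE])
      for (i in seq_len(nrow(Y)))
        P[i, l] <- (1 + sum(nv[i, 1, ] >= abs(Y[i, l]))) / (1 + dim(nv)[3])
    }
  } else {
    for (l in seq_along(reg_ids)) {
      nv <- sort(abs(null$per_regulator_null[[reg_ids[l]]]))
      K <- length(nv)
      # exceedances via binary search on the sorted pool
      idx <- findInterval(abs(Y[, l]), nv, left.open = TRUE)
      P[, l] <- (1 + (K - idx)) / (1 + K)
    }
  }
  P
}

#' Call regulatory modules from coefficients and p-values
#'
#' A gene joins regulator l's module when its empirical p-value is below
#' `p_cutoff` and |coefficient| exceeds `min_score`; if `top_k` is given the
#' module is truncated to the k largest |coefficients|. Within each module,
#' genes are ordered by decreasing |coefficient|, ties broken by gene ID.
#' Benjamini-Hochberg adjusted p-values are added per regulator.
#'
#' @param Y Coefficient matrix (genes x regulators).
#' @param pvals Matching p-value matrix from [empirical_pvalues()].
#' @param p_cutoff Raw p-value threshold (default 0.05).
#' @param top_k Optional cap on module size.
#' @param min_score Minimum |coefficient| (default 0, i.e. any non-zero).
#' @return Tibble with columns `regulator`, `gene`, `score`, `p`, `p_adj`,
#'   `direction` (`"over"`/`"under"` by coefficient sign in signed mode,
#'   `"unspecified"` in non-negative mode).
#' @export
extract_modules <- function(Y, pvals, p_cutoff = 0.05, top_k = NULL,
                            min_score = 0) {
  stopifnot(identical(dim(Y), dim(pvals)))
  if (p_cutoff <= 0 || p_cutoff > 1)
    stop("`p_cutoff` must lie in (0, 1]", call. = FALSE)
  signed <- any(Y < 0)

  purrr::map_dfr(seq_len(ncol(Y)), function(l) {
    score <- Y[, l]
    p <- pvals[, l]
    p_adj <- stats::p.adjust(p, method = "BH")
    keep <- p < p_cutoff & abs(score) > min_score
    out <- tibble::tibble(
      regulator = colnames(Y)[l],
      gene = rownames(Y)[keep],
      score = unname(score[keep]), p = unname(p[keep]),
      p_adj = unname(p_adj[keep]),
      direction = if (!signed) "unspecified"
                  else ifelse(score[keep] >= 0, "over", "under")
    )
    out <- out[order(-abs(out$score), out$gene), ]
    if (!is.null(top_k) && nrow(out) > top_k) out <- out[seq_len(top_k), ]
    out
  })
}

#' Significance and enrichment ratio of a gene-set overlap
#'
#' Tests whether two target sets share more genes than expected by chance in
#' a universe of `universe_size` genes: hypergeometric upper-tail p-value
#' (equivalently a one-sided Fisher test) and the ratio
#' `R = observed * universe / (|A| * |B|)` of observed to expected overlap.
#'
#' @param set_a,set_b Character vectors of gene IDs (deduplicated
#'   internally).
#' @param universe_size Number of genes in the universe both sets were drawn
#'   from; must be at least `|A union B|`.
#' @return One-row tibble: `overlap`, `size_a`, `size_b`, `universe`,
#'   `expected`, `ratio`, `p`.
#' @export
overlap_significance <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  if (universe_size < length(union(a, b)))
    stop("`universe_size` is smaller than |A union B|", call. = FALSE)
  ov <- length(intersect(a, b))
  expected <- length(a) * length(b) / universe_size
  p <- stats::phyper(ov - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  tibble::tibble(overlap = ov, size_a = length(a), size_b = length(b),
                 universe = universe_size, expected = expected,
                 ratio = if (expected > 0) ov / expected else NA_real_,
                 p = p)
}

#' Co-target table across regulators and regulator groups
#'
#' For every gene called in at least one module, lists the regulators whose
#' modules contain it. Optional `groups` (named list of regulator-ID vectors)
#' add one logical column per group with union semantics: the gene is
#' attributed to a group if any member regulator calls it (e.g. an NF-kB
#' group spanning RelA/NFKB1/cRel subunits).
#'
#' @param modules Module table from [extract_modules()].
#' @param groups Optional named list of character vectors of regulator IDs.
#' @return Tibble with `gene`, `regulators` (comma-separated, sorted),
#'   `n_regulators`, then one logical column per group.
#' @export
intersect_regulator_targets <- function(modules, groups = NULL) {
  stopifnot(is.data.frame(modules),
            all(c("regulator", "gene") %in% names(modules)))
  if (nrow(modules) == 0L)
    stop("`modules` is empty; nothing to intersect", call. = FALSE)
  known <- unique(modules$regulator)
  if (!is.null(groups)) {
    unknown <- setdiff(unlist(groups), known)
    if (length(unknown))
      stop("unknown regulator(s) in groups: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  tab <- modules |>
    dplyr::distinct(.data$gene, .data$regulator) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      regulators = paste(sort(.data$regulator), collapse = ","),
      n_regulators = dplyr::n_distinct(.data$regulator),
      reg_list = list(unique(.data$regulator)),
      .groups = "drop"
    )
  if (!is.null(groups)) {
    for (g in names(groups)) {
      members <- groups[[g]]
      tab[[g]] <- purrr::map_lgl(tab$reg_list,
                                 ~ length(intersect(.x, members)) > 0)
    }
  }
  tab$reg_list <- NULL
  tab
}

#' Density plot of the permutation null per regulator
#'
#' @param object An `rca_null` from [permutation_null()].
#' @param ... Unused.
#' @return A ggplot of the pooled null coefficient densities, one facet per
#'   regulator.
#' @method autoplot rca_null
#' @export
autoplot.rca_null <- function(object, ...) {
  df <- purrr::imap_dfr(object$per_regulator_null,
                        ~ tibble::tibble(regulator = .y, value = .x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::facet_wrap(~regulator, scales = "free") +
    ggplot2::labs(x = "null coefficient value", y = "count",
                  title = sprintf("Permutation null (B = %d runs)", object$B)) +
    ggplot2::theme_minimal()
}
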