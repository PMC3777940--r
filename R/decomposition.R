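#' Configuration for the sparse decomposition
#'
#' Bundles every tunable of the projected-gradient fit of X = Y Z.
#'
#' @param sparseness Target Hoyer sparseness for each column of Y, in
#'   \[0, 1\], or `NULL` to disable the sparseness projection entirely
#'   (plain gradient descent, useful to check the least-squares limit).
#' @param nonneg Constrain Y to be non-negative (default). With
#'   `nonneg = FALSE` the projection acts on magnitudes and signs are kept.
#' @param step_size Initial gradient step. `NULL` (default) picks
#'   `1 / (2 * ||Z Z^T||_2)`, the inverse Lipschitz constant of the gradient,
#'   at fit time.
#' @param tol Relative-change convergence criterion on the objective.
#' @param max_iters Maximum outer iterations.
#' @param seed Seed for the random initialisation of Y.
#' @param init_scale Upper bound of the uniform initial Y entries.
#' @param fixed_step Use the literal fixed-step iteration with no
#'   backtracking line search. The objective trace is then not guaranteed to
#'   be monotone.
#' @param mask Zero entries of Y wherever the connectivity matrix is 0 at
#'   every iterate (ablation mode; off by default because non-zero Y outside
#'   C is how novel targets are predicted).
#' @param standardize_z Standardize each activity row to mean 0, sd 1 before
#'   fitting (see [build_activity()]); recommended when the fit feeds the
#'   permutation test, so observed and null coefficients share a scale.
#' @return A list of class `rca_config`.
#' @export
rca_config <- function(sparseness = 0.7, nonneg = TRUE, step_size = NULL,
                       tol = 1e-6, max_iters = 2000L, seed = 1L,
                       init_scale = 1, fixed_step = FALSE, mask = FALSE,
                       standardize_z = FALSE) {
  if (!is.null(sparseness) && (sparseness < 0 || sparseness > 1))
    stop("`sparseness` must lie in [0, 1] or be NULL", call. = FALSE)
  if (!is.null(step_size) && step_size <= 0)
    stop("`step_size` must be positive", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (max_iters < 1) stop("`max_iters` must be at least 1", call. = FALSE)
  if (init_scale <= 0) stop("`init_scale` must be positive", call. = FALSE)
  structure(list(sparseness = sparseness, nonneg = isTRUE(nonneg),
                 step_size = step_size, tol = tol,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 init_scale = init_scale, fixed_step = isTRUE(fixed_step),
                 mask = isTRUE(mask), standardize_z = isTRUE(standardize_z)),
            class = "rca_config")
}

#' Squared-error objective of the decomposition
#'
#' The squared Frobenius residual `sum((X - Y Z)^2)`, the quantity minimised
#' under the per-column sparseness constraint on Y.
#'
#' @param X Expression matrix, genes x samples.
#' @param Y Coefficient matrix, genes x regulators.
#' @param Z Activity matrix, regulators x samples.
#' @return Non-negative scalar; zero iff X = Y Z exactly.
#' @export
rca_objective <- function(X, Y, Z) {
  if (ncol(Y) != nrow(Z) || nrow(Y) != nrow(X) || ncol(Z) != ncol(X))
    stop(sprintf("non-conformable dimensions: X %dx%d, Y %dx%d, Z %dx%d",
                 nrow(X), ncol(X), nrow(Y), ncol(Y), nrow(Z), ncol(Z)),
         call. = FALSE)
  sum((X - Y %*% Z)^2)
}

#' Random initial coefficient matrix
#'
#' Entries are i.i.d. uniform on (0, `init_scale`], then each column is
#' projected to the configured sparseness so the constraint holds from the
#' first iterate.
#'
#' @param n Number of genes (rows).
#' @param l Number of regulators (columns).
#' @param config An [rca_config()]; `config$seed` makes the draw
#'   reproducible.
#' @return Numeric n x l matrix.
#' @export
init_Y <- function(n, l, config = rca_config()) {
  set.seed(config$seed)
  Y <- matrix(config$init_scale * (1 - stats::runif(n * l)), nrow = n, ncol = l)
  project_columns(Y, config)
}

# Column-wise sparseness projection honouring the config; columns of length
# 1 cannot carry a sparseness constraint and are only sign-handled.
project_columns <- function(Y, config) {
  if (is.null(config$sparseness)) {
    if (config$nonneg) Y[Y < 0] <- 0
    return(Y)
  }
  if (nrow(Y) < 2L) {
    if (config$nonneg) Y[Y < 0] <- 0
    return(Y)
  }
  for (j in seq_len(ncol(Y))) {
    cj <- Y[, j]
    if (all(cj == 0)) cj[1L] <- .Machine$double.eps  # revive a dead column
    Y[, j] <- project_sparse(cj, config$sparseness, nonneg = config$nonneg)
  }
  Y
}

#' One projected-gradient update of Y
#'
#' Computes the gradient step `Y - step * (Y Z - X) Z^T`, projects each
#' column back to the target sparseness (L2 norm unchanged), and — unless
#' `config$fixed_step` — halves the step until the objective decreases
#' (floor 1e-12). If the floor is reached without a decrease the update
#' signals stagnation and returns Y unchanged.
#'
#' @param Y Current coefficient matrix.
#' @param X Expression matrix.
#' @param Z Activity matrix.
#' @param config An [rca_config()].
#' @param step Step size to try first; defaults to `config$step_size` or the
#'   Lipschitz default.
#' @param C Optional connectivity matrix, used only when `config$mask` is
#'   set.
#' @return List with elements `Y` (updated matrix), `objective`, `step`
#'   (the accepted step), and `stagnated` (logical).
#' @export
update_step <- function(Y, X, Z, config = rca_config(), step = NULL, C = NULL) {
  if (is.null(step)) step <- config$step_size
  if (is.null(step)) step <- default_step(Z)
  G <- (Y %*% Z - X) %*% t(Z)
  f0 <- rca_objective(X, Y, Z)

  propose <- function(eta) {
    cand <- Y - eta * G
    if (config$mask && !is.null(C)) cand[C == 0] <- 0
    project_columns(cand, config)
  }

  if (config$fixed_step) {
    Y1 <- propose(step)
    return(list(Y = Y1, objective = rca_objective(X, Y1, Z),
                step = step, stagnated = FALSE))
  }

  eta <- step
  while (eta >= 1e-12) {
    Y1 <- propose(eta)
    f1 <- rca_objective(X, Y1, Z)
    if (f1 < f0) return(list(Y = Y1, objective = f1, step = eta,
                             stagnated = FALSE))
    eta <- eta / 2
  }
  list(Y = Y, objective = f0, step = step, stagnated = TRUE)
}

default_step <- function(Z) {
  # inverse Lipschitz constant of the gradient 2 (YZ - X) Z^T
  1 / (2 * norm(Z %*% t(Z), type = "2"))
}

#' Fit the sparse regulatory decomposition
#'
#' Runs the full learning procedure: build the activity matrix Z from the
#' expression matrix and connectivity (median of bound-gene expression),
#' initialise Y at random, project its columns to the target sparseness, and
#' iterate projected-gradient updates until the relative change of the
#' squared-error objective falls below `config$tol` (or `max_iters` is hit).
#' Z is computed once and held fixed throughout.
#'
#' @param X Expression matrix, genes x samples (rownames = gene IDs).
#' @param C Binary connectivity matrix, genes x regulators, aligned to `X`.
#' @param config An [rca_config()].
#' @return Object of class `rca_fit`: list with `Y` (genes x regulators
#'   coefficients), `Z`, `objective_trace`, `converged`, `iterations`,
#'   `config`. [tidy()], [glance()] and [ggplot2::autoplot()] methods are
#'   provided.
#' @examples
#' sim <- simulate_regulatory_data(n_genes = 60, n_samples = 8,
#'                                 n_regulators = 3, seed = 1)
#' fit <- rca_fit(sim$X, sim$C, rca_config(sparseness = 0.8, seed = 1))
#' glance(fit)
#' @export
rca_fit <- function(X, C, config = rca_config()) {
  if (!identical(rownames(X), rownames(C)))
    stop("gene IDs of `X` and `C` differ or are ordered differently",
         call. = FALSE)
  Z <- build_activity(X, C, standardize = isTRUE(config$standardize_z))
  step <- config$step_size
  if (is.null(step)) step <- default_step(Z)

  step0 <- step
  Y <- init_Y(nrow(X), ncol(C), config)
  dimnames(Y) <- list(rownames(X), colnames(C))
  trace <- rca_objective(X, Y, Z)
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(config$max_iters)) {
    res <- update_step(Y, X, Z, config, step = step, C = C)
    iters <- it
    f_prev <- trace[length(trace)]
    Y <- res$Y
    trace <- c(trace, res$objective)
    if (res$stagnated) { converged <- TRUE; break }
    if (!config$fixed_step) step <- min(res$step * 2, step0)
    if (abs(res$objective - f_prev) < config$tol * max(1, f_prev)) {
      converged <- TRUE
      break
    }
  }
  if (any(!is.finite(Y)))
    stop("fit produced non-finite coefficients; reduce the step size",
         call. = FALSE)

  structure(list(Y = Y, Z = Z, objective_trace = trace,
                 converged = converged, iterations = iters, config = config),
            class = "rca_fit")
}

#' @export
print.rca_fit <- function(x, ...) {
  cat(sprintf("Sparse regulatory decomposition: %d genes x %d regulators, %d samples\n",
              nrow(x$Y), ncol(x$Y), ncol(x$Z)))
  cat(sprintf("  objective %.6g after %d iteration(s); %s\n",
              x$objective_trace[length(x$objective_trace)], x$iterations,
              if (x$converged) "converged" else "max_iters reached"))
  invisible(x)
}

#' Tidy a fitted decomposition into a long coefficient table
#'
#' @param x An `rca_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `regulator`, `coefficient`, one row
#'   per gene-regulator pair.
#' @method tidy rca_fit
#' @export
tidy.rca_fit <- function(x, ...) {
  tibble::as_tibble(x$Y, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "regulator",
                        values_to = "coefficient")
}

#' One-row summary of a fitted decomposition
#'
#' @param x An `rca_fit` object.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_regulators`, `n_samples`, `objective`
#'   (final squared-error), `iterations`, `converged`, and `mean_sparseness`
#'   (mean realised column sparseness of Y).
#' @method glance rca_fit
#' @export
glance.rca_fit <- function(x, ...) {
  sp <- if (nrow(x$Y) >= 2)
    mean(apply(x$Y, 2, function(cj)
      if (all(cj == 0)) NA_real_ else hoyer_sparseness(cj)))
  else NA_real_
  tibble::tibble(
    n_genes = nrow(x$Y), n_regulators = ncol(x$Y), n_samples = ncol(x$Z),
    objective = x$objective_trace[length(x$objective_trace)],
    iterations = x$iterations, converged = x$converged,
    mean_sparseness = sp
  )
}

#' Objective-trace plot for a fitted decomposition
#'
#' @param object An `rca_fit` object.
#' @param ... Unused.
#' @return A ggplot of the squared-error objective against iteration.
#' @method autoplot rca_fit
#' @export
autoplot.rca_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "squared-error objective",
                  title = "Projected-gradient descent trace") +
    ggplot2::theme_minimal()
}
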