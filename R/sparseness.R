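#' Hoyer L1/L2 sparseness of a vector
#'
#' The sparseness of a vector \eqn{v} of length \eqn{n \ge 2} is
#' \deqn{s(v) = \frac{\sqrt{n} - \|v\|_1 / \|v\|_2}{\sqrt{n} - 1},}
#' computed on the absolute values of the entries so it is well defined for
#' signed data. It equals 1 if and only if \eqn{v} has a single non-zero
#' entry, 0 if and only if all entries have equal magnitude, and is invariant
#' under non-zero scaling.
#'
#' @param v Numeric vector, length at least 2, with at least one non-zero
#'   entry.
#' @return A number in \[0, 1\].
#' @seealso [project_sparse()] to move a vector to a chosen sparseness,
#'   [target_l1()] for the L1 norm that achieves it.
#' @examples
#' hoyer_sparseness(c(5, 0, 0, 0)) # 1
#' hoyer_sparseness(c(2, 2, 2))    # 0
#' @export
hoyer_sparseness <- function(v) {
  if (!is.numeric(v)) stop("`v` must be numeric", call. = FALSE)
  n <- length(v)
  if (n < 2) stop("sparseness is undefined for vectors of length < 2", call. = FALSE)
  if (any(!is.finite(v))) stop("`v` contains non-finite entries", call. = FALSE)
  a <- abs(v)
  l2 <- sqrt(sum(a^2))
  if (l2 == 0) stop("sparseness is undefined for the all-zero vector", call. = FALSE)
  l1 <- sum(a)
  (sqrt(n) - l1 / l2) / (sqrt(n) - 1)
}

#' L1 norm achieving a desired sparseness at a fixed L2 norm
#'
#' Inverts the sparseness measure: a vector of length `n` with L2 norm `l2`
#' has Hoyer sparseness `s` exactly when its L1 norm equals
#' `l2 * (sqrt(n) - s * (sqrt(n) - 1))`.
#'
#' @param l2 Positive L2 norm.
#' @param n Vector length, at least 2.
#' @param s Desired sparseness in \[0, 1\].
#' @return The required L1 norm (positive scalar).
#' @export
target_l1 <- function(l2, n, s) {
  if (!is.numeric(l2) || length(l2) != 1L || l2 <= 0)
    stop("`l2` must be a single positive number", call. = FALSE)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (s < 0 || s > 1) stop("`s` must lie in [0, 1]", call. = FALSE)
  l2 * (sqrt(n) - s * (sqrt(n) - 1))
}

#' Project a vector to a target sparseness with unchanged L2 norm
#'
#' Maps `v` to the closest point (Euclidean distance) having the same L2 norm
#' and the L1 norm that achieves sparseness `s`, by the alternating
#' hyperplane-shift / zero-clamp / L2-rescale scheme used in sparse
#' non-negative matrix factorisation. With `nonneg = TRUE` all returned
#' entries are non-negative. With `nonneg = FALSE` the projection is applied
#' to the entry magnitudes and the original signs are restored, so the
#' measure (which is sign-blind) still hits the target.
#'
#' Ties between equidistant solutions (e.g. projecting an all-equal vector to
#' sparseness 1) are broken deterministically toward the lowest index.
#'
#' @param v Non-zero numeric vector of length at least 2.
#' @param s Target sparseness in \[0, 1\].
#' @param nonneg Enforce non-negative output (default `TRUE`).
#' @param max_iter Maximum clamp iterations before a convergence error.
#' @param tol Constraint residual tolerance for declaring convergence.
#' @return Numeric vector `w` with `||w||_2 = ||v||_2` and
#'   `hoyer_sparseness(w) = s` (to within `tol`-driven accuracy).
#' @examples
#' project_sparse(c(1, 0), s = 0)          # c(1, 1)/sqrt(2)
#' project_sparse(c(1, 1), s = 1)          # c(sqrt(2), 0)
#' @export
project_sparse <- function(v, s, nonneg = TRUE, max_iter = 200L, tol = 1e-9) {
  if (!is.numeric(v)) stop("`v` must be numeric", call. = FALSE)
  n <- length(v)
  if (n < 2) stop("projection is undefined for vectors of length < 2", call. = FALSE)
  if (any(!is.finite(v))) stop("`v` contains non-finite entries", call. = FALSE)
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stop("cannot project the all-zero vector", call. = FALSE)
  if (s < 0 || s > 1) stop("`s` must lie in [0, 1]", call. = FALSE)

  if (!nonneg) {
    sgn <- sign(v)
    sgn[sgn == 0] <- 1
    return(sgn * project_sparse(abs(v), s, nonneg = TRUE,
                                max_iter = max_iter, tol = tol))
  }

  k1 <- target_l1(l2, n, s)
  w <- hoyer_project(v, k1, l2, max_iter = max_iter, tol = tol)
  w
}

# Alternating projection onto {w >= 0, sum(w) = k1, ||w||_2 = l2}.
# Starts from the orthogonal projection of x onto the L1 hyperplane, then
# repeatedly solves for the sphere intersection along the ray from the
# hyperplane centroid and clamps negative coordinates to zero.
hoyer_project <- function(x, k1, l2, max_iter = 200L, tol = 1e-9) {
  n <- length(x)
  w <- x + (k1 - sum(x)) / n
  zeroed <- rep(FALSE, n)

  for (iter in seq_len(max_iter)) {
    n_free <- sum(!zeroed)
    if (n_free == 0L)
      stop("sparseness projection zeroed every coordinate", call. = FALSE)
    mid <- ifelse(zeroed, 0, k1 / n_free)
    d <- w - mid
    # ||mid + alpha * d||^2 = l2^2, alpha >= 0
    a <- sum(d^2)
    b <- 2 * sum(mid * d)
    cc <- sum(mid^2) - l2^2
    if (a < 1e-20 * l2^2) {
      # Degenerate direction (w sits at the centroid): deterministic
      # tie-break pushing mass toward the lowest free index.
      d <- ifelse(zeroed, 0, -1 / n_free)
      d[which(!zeroed)[1L]] <- d[which(!zeroed)[1L]] + 1
      a <- sum(d^2)
      b <- 2 * sum(mid * d)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0) disc <- 0
    alpha <- (-b + sqrt(disc)) / (2 * a)
    w <- mid + alpha * d

    if (all(w >= -tol)) {
      w[w < 0] <- 0
      # residual check: both constraints must hold
      r1 <- abs(sum(w) - k1) / k1
      r2 <- abs(sqrt(sum(w^2)) - l2) / l2
      if (r1 < tol && r2 < tol) return(w / sqrt(sum(w^2)) * l2)
    }
    neg <- w < 0
    zeroed <- zeroed | neg
    w[zeroed] <- 0
    n_free <- sum(!zeroed)
    if (n_free == 0L)
      stop("sparseness projection zeroed every coordinate", call. = FALSE)
    # redistribute the L1 residual over the free coordinates
    shift <- (sum(w) - k1) / n_free
    w[!zeroed] <- w[!zeroed] - shift
  }
  stop(sprintf("sparseness projection failed to converge in %d iterations",
               max_iter), call. = FALSE)
}
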