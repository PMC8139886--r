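#' Construct a degree distribution
#'
#' A degree distribution assigns to each distinct node degree `k` the
#' probability `p` that a randomly chosen node has that degree. It is the
#' only piece of network structure the super compact pairwise (SCPW) model
#' consumes: everything downstream depends on the distribution solely
#' through its first three raw moments.
#'
#' @param k Integer vector of distinct, nonnegative degrees (the support).
#'   Degree-0 nodes are allowed; they contribute to the moments.
#' @param p Numeric vector of probabilities matching `k`. Must be
#'   nonnegative and sum to 1 within `tol`.
#' @param tol Tolerance on the total probability mass.
#'
#' @return A tibble of class `degree_distribution` with columns `k` and
#'   `p`, ordered by `k`.
#'
#' @examples
#' degree_distribution(k = c(3, 5), p = c(0.5, 0.5))
#'
#' @seealso [dist_bimodal()], [dist_poisson()], [dist_regular()],
#'   [network_moments()]
#' @export
degree_distribution <- function(k, p, tol = 1e-12) {
  if (length(k) == 0L || length(k) != length(p)) {
    stop("`k` and `p` must be nonempty vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k < 0) || any(abs(k - round(k)) > 0)) {
    stop("degrees must be finite nonnegative integers", call. = FALSE)
  }
  k <- as.numeric(round(k))
  if (anyDuplicated(k)) {
    stop("degrees in the support must be distinct", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("probabilities must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(
      sprintf(
        "probabilities are unnormalized: sum(p) = %.15g differs from 1 by more than %g",
        sum(p), tol
      ),
      call. = FALSE
    )
  }
  ord <- order(k)
  out <- tibble::tibble(k = k[ord], p = p[ord])
  class(out) <- c("degree_distribution", class(out))
  out
}

#' Bimodal degree distribution
#'
#' Two-point degree distribution placing mass `frac` on degree `k_lo` and
#' `1 - frac` on `k_hi`. The defaults reproduce the toolkit's reference
#' bimodal network (half the nodes with degree 3, half with degree 5),
#' whose moments are exactly (4, 17, 76).
#'
#' @param k_lo,k_hi The two degrees, `k_lo < k_hi`, both positive.
#' @param frac Probability mass on `k_lo`.
#' @return A [degree_distribution()].
#' @export
dist_bimodal <- function(k_lo = 3, k_hi = 5, frac = 0.5) {
  if (k_lo <= 0 || k_hi <= 0 || k_lo >= k_hi) {
    stop("need positive degrees with k_lo < k_hi", call. = FALSE)
  }
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)", call. = FALSE)
  degree_distribution(c(k_lo, k_hi), c(frac, 1 - frac))
}

#' Truncated Poisson degree distribution
#'
#' Poisson probability mass function truncated at the smallest degree `K`
#' whose upper tail mass falls below `tail_mass`, then renormalized so the
#' retained mass sums to 1 exactly. With the default truncation the first
#' three moments of the mean-`m` family agree with the analytic values
#' `m`, `m^2 + m`, `m^3 + 3 m^2 + m` to well below 1e-8.
#'
#' @param mean Positive mean degree.
#' @param tail_mass Upper-tail mass at which to truncate; must lie in
#'   (0, 1e-6).
#' @return A [degree_distribution()] on `0:K`.
#' @export
dist_poisson <- function(mean, tail_mass = 1e-12) {
  if (!is.finite(mean) || mean <= 0) {
    stop("`mean` must be a positive number", call. = FALSE)
  }
  if (!is.finite(tail_mass) || tail_mass <= 0 || tail_mass >= 1e-6) {
    stop("`tail_mass` must lie in (0, 1e-6)", call. = FALSE)
  }
  K <- stats::qpois(tail_mass, lambda = mean, lower.tail = FALSE)
  while (stats::ppois(K, lambda = mean, lower.tail = FALSE) >= tail_mass) {
    K <- K + 1L
  }
  k <- 0:K
  p <- stats::dpois(k, lambda = mean)
  degree_distribution(k, p / sum(p))
}

#' Regular (single-degree) distribution
#'
#' All nodes share degree `k`. Moments and the epidemic threshold are well
#' defined, but the closure constants are not: [model_constants()] refuses
#' zero-variance distributions.
#'
#' @param k Positive integer degree.
#' @return A [degree_distribution()].
#' @export
dist_regular <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k <= 0 || abs(k - round(k)) > 0) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  degree_distribution(k, 1)
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf(
    "# Degree distribution on %d degrees (range %g-%g)\n",
    nrow(x), min(x$k), max(x$k)
  ))
  NextMethod()
}
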