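#' Degree-distribution moments
#'
#' Computes the first three raw moments of a node-degree distribution,
#' the only network summary the SCPW model uses. The input may be an
#' empirical degree sequence (one degree per node) or a distribution
#' table; the two routes agree exactly when the sequence realizes the
#' distribution as a multiset.
#'
#' @param x A [degree_distribution()] (or any data frame with columns `k`
#'   and `p`), or a numeric vector of nonnegative integer degrees.
#' @param ... Passed to methods.
#'
#' @return A one-row tibble of class `network_moments` with columns `k1`,
#'   `k2`, `k3`: the raw moments \eqn{\langle k \rangle},
#'   \eqn{\langle k^2 \rangle}, \eqn{\langle k^3 \rangle}.
#'
#' @examples
#' network_moments(dist_bimodal())          # 4, 17, 76
#' network_moments(c(1, 2, 3))              # 2, 14/3, 12
#' @export
network_moments <- function(x, ...) UseMethod("network_moments")

#' @rdname network_moments
#' @export
network_moments.data.frame <- function(x, ...) {
  if (!all(c("k", "p") %in% names(x))) {
    stop("distribution input needs columns `k` and `p`", call. = FALSE)
  }
  if (!inherits(x, "degree_distribution")) {
    x <- degree_distribution(x$k, x$p) # revalidates, incl. normalization
  }
  new_network_moments(
    k1 = sum(x$k * x$p),
    k2 = sum(x$k^2 * x$p),
    k3 = sum(x$k^3 * x$p)
  )
}

#' @rdname network_moments
#' @export
network_moments.numeric <- function(x, ...) {
  if (length(x) == 0L) stop("degree sequence is empty", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 0)) {
    stop("degree sequence entries must be nonnegative integers", call. = FALSE)
  }
  if (all(x == 0)) {
    stop("degree sequence must contain at least one positive degree",
      call. = FALSE
    )
  }
  x <- as.numeric(x)
  # base sum() accumulates in extended precision; stable for N <= 1e7
  new_network_moments(
    k1 = sum(x) / length(x),
    k2 = sum(x^2) / length(x),
    k3 = sum(x^3) / length(x)
  )
}

#' @rdname network_moments
#' @export
network_moments.integer <- network_moments.numeric

#' Assemble a moment triple directly
#'
#' Wraps raw moment values \eqn{(\langle k \rangle, \langle k^2 \rangle,
#' \langle k^3 \rangle)} as a `network_moments` row, checking the Jensen
#' (\eqn{\langle k^2 \rangle \ge \langle k \rangle^2}) and Cauchy-Schwarz
#' (\eqn{\langle k^2 \rangle^2 \le \langle k^3 \rangle \langle k \rangle})
#' feasibility inequalities within a relative tolerance.
#'
#' @param k1,k2,k3 Raw moments; `k1` must be positive.
#' @param tol Relative tolerance on the feasibility inequalities.
#' @return A one-row `network_moments` tibble.
#' @export
as_network_moments <- function(k1, k2, k3, tol = 1e-12) {
  if (!is.finite(k1) || k1 <= 0) stop("`k1` must be positive", call. = FALSE)
  if (k2 < k1^2 * (1 - tol)) {
    stop("infeasible moments: Jensen requires k2 >= k1^2", call. = FALSE)
  }
  if (k2^2 > k3 * k1 * (1 + tol)) {
    stop("infeasible moments: Cauchy-Schwarz requires k2^2 <= k3*k1",
      call. = FALSE
    )
  }
  new_network_moments(k1, k2, k3)
}

new_network_moments <- function(k1, k2, k3) {
  out <- tibble::tibble(k1 = k1, k2 = k2, k3 = k3)
  class(out) <- c("network_moments", class(out))
  out
}

#' Epidemic threshold of the SCPW model
#'
#' The disease-free equilibrium of the SCPW system loses stability as the
#' transmission-recovery ratio \eqn{\delta = \tau/\gamma} increases
#' through
#' \deqn{\delta_c = \frac{\langle k \rangle}{\langle k^2 \rangle -
#'   \langle k \rangle},}
#' which requires only the first two moments and remains valid for
#' regular networks (degree-`k` regular: \eqn{\delta_c = 1/(k-1)}).
#'
#' @param m A `network_moments` row (or anything with `k1`, `k2`
#'   elements), or a degree input accepted by [network_moments()].
#' @return The threshold \eqn{\delta_c} as a number.
#' @examples
#' epidemic_threshold(network_moments(dist_bimodal())) # 4/13
#' @export
epidemic_threshold <- function(m) {
  m <- coerce_moments(m)
  if (m$k2 <= m$k1) {
    stop(
      "epidemic threshold undefined: requires k2 > k1 (got k2 <= k1)",
      call. = FALSE
    )
  }
  m$k1 / (m$k2 - m$k1)
}

#' Derived SCPW model constants
#'
#' Consolidates the three degree moments into the constants every
#' downstream formula uses. With variance
#' \eqn{V = \langle k^2 \rangle - \langle k \rangle^2}:
#' \deqn{\alpha = \frac{\langle k^2\rangle^2 - \langle k\rangle\langle
#'   k^3\rangle}{V}, \qquad
#'   \beta = \frac{\langle k^3\rangle - \langle k^2\rangle\langle
#'   k\rangle}{V} - 1,}
#' the mean excess degree \eqn{\bar k = (\langle k^2\rangle - \langle
#' k\rangle)/\langle k\rangle}, the threshold \eqn{\delta_c = 1/\bar k},
#' and the rescaled constants \eqn{\sigma = \langle k\rangle \delta_c},
#' \eqn{\lambda = \alpha\delta_c/\langle k\rangle},
#' \eqn{\mu = \beta\delta_c}. The identities \eqn{\alpha/\langle k\rangle
#' + \beta = \bar k} and \eqn{\lambda + \mu = 1} hold by construction and
#' are asserted.
#'
#' @param m Moments input as in [epidemic_threshold()].
#' @param variance_tol Relative degeneracy guard: the distribution is
#'   rejected when \eqn{V \le} `variance_tol` \eqn{\cdot \langle
#'   k\rangle^2}, since \eqn{\alpha} and \eqn{\beta} are 0/0 for a
#'   regular network.
#'
#' @return A one-row tibble of class `model_constants` with columns
#'   `k1`, `k2`, `k3`, `alpha`, `beta`, `kbar`, `delta_c`, `sigma`,
#'   `lambda`, `mu`.
#'
#' @examples
#' model_constants(network_moments(dist_bimodal()))
#' @export
model_constants <- function(m, variance_tol = 1e-10) {
  m <- coerce_moments(m)
  k1 <- m$k1
  k2 <- m$k2
  k3 <- m$k3
  v <- k2 - k1^2
  if (v <= variance_tol * k1^2) {
    stop(
      paste0(
        "degenerate distribution: the denominator <k^2> - <k>^2 of the ",
        "closure constants alpha and beta vanishes for a (near-)regular ",
        "network; the SCPW constants are undefined there"
      ),
      call. = FALSE
    )
  }
  if (k2 <= k1) {
    stop("epidemic threshold undefined: requires k2 > k1", call. = FALSE)
  }
  alpha <- (k2^2 - k1 * k3) / v
  beta <- (k3 - k2 * k1) / v - 1
  kbar <- (k2 - k1) / k1
  delta_c <- k1 / (k2 - k1)
  out <- tibble::tibble(
    k1 = k1, k2 = k2, k3 = k3,
    alpha = alpha, beta = beta, kbar = kbar, delta_c = delta_c,
    sigma = k1 * delta_c,
    lambda = alpha * delta_c / k1,
    mu = beta * delta_c
  )
  stopifnot(
    abs(alpha / k1 + beta - kbar) <= 1e-10 * max(1, abs(kbar)),
    abs(out$lambda + out$mu - 1) <= 1e-10
  )
  class(out) <- c("model_constants", class(out))
  out
}

# Accept moments rows, constants rows, distributions, or raw sequences.
coerce_moments <- function(m) {
  if (inherits(m, "network_moments") || inherits(m, "model_constants")) {
    return(m)
  }
  if (is.data.frame(m)) {
    if (all(c("k1", "k2") %in% names(m))) {
      if (nrow(m) != 1L) stop("expected a one-row moments table", call. = FALSE)
      return(m)
    }
    return(network_moments(m))
  }
  if (is.numeric(m) && !is.null(names(m)) && all(c("k1", "k2") %in% names(m))) {
    return(tibble::tibble(
      k1 = m[["k1"]], k2 = m[["k2"]],
      k3 = if ("k3" %in% names(m)) m[["k3"]] else NA_real_
    ))
  }
  if (is.numeric(m)) {
    return(network_moments(m))
  }
  stop("cannot interpret input as degree moments", call. = FALSE)
}

# Validated extraction of a constants row as a plain named list.
constants_row <- function(c) {
  need <- c(
    "k1", "alpha", "beta", "kbar", "delta_c", "sigma", "lambda", "mu"
  )
  if (!is.data.frame(c) || !all(need %in% names(c)) || nrow(c) != 1L) {
    stop(
      "`constants` must be a one-row model_constants table; see model_constants()",
      call. = FALSE
    )
  }
  as.list(c[1, ])
}

#' @export
print.model_constants <- function(x, ...) {
  cat(sprintf(
    "# SCPW model constants (delta_c = %.6g, kbar = %.6g)\n",
    x$delta_c, x$kbar
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.model_constants <- function(x, ...) {
  tibble::tibble(
    term = names(x),
    value = as.numeric(x[1, ])
  )
}

#' @export
glance.model_constants <- function(x, ...) {
  tibble::tibble(
    delta_c = x$delta_c, kbar = x$kbar, sigma = x$sigma,
    lambda = x$lambda, mu = x$mu
  )
}
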