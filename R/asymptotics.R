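#' Near-threshold approximation of the endemic equilibrium
#'
#' Just above the epidemic threshold the endemic state is a small
#' perturbation of the disease-free state `(x, y) = (0, 1)`. With the
#' small parameter \eqn{\eta = 1 - \delta_c/\delta}, the first-order
#' expansion of the equilibrium pair fraction and prevalence is
#' \deqn{x^* \approx \frac{\eta}{\lambda\sigma + \mu\delta_c + \mu -
#'   \delta_c}, \qquad
#'   w^* \approx \frac{\sigma\,\eta}{\lambda\sigma + \mu\delta_c + \mu -
#'   \delta_c},}
#' with remainder \eqn{O(\eta^2)}. The constant term of the expansion
#' cancels precisely because \eqn{\lambda + \mu = \delta_c \bar k = 1};
#' that identity is asserted before expanding. The linearization of the
#' steady-state polynomial `P` about the emergence point,
#' \eqn{y \approx 1 - (2 + \delta_c/(1-\eta))x}, is exposed via the
#' `y_slope` column (it seeds the exact Newton solve).
#'
#' @param delta Ratio(s) \eqn{\delta \ge \delta_c}; vectorized.
#' @param constants A [model_constants()] row.
#' @param eta_max Refuse to extrapolate beyond this \eqn{\eta}; the
#'   expansion is a small-\eqn{\eta} asymptotic, not a global formula.
#' @return A tibble with one row per `delta`: `delta`, `eta`, `x_star`,
#'   `w_star`, `slope` (the coefficient \eqn{dw^*/d\eta}), `y_slope`.
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' near_threshold_equilibrium(cs$delta_c / (1 - 0.1), cs) # w* = 26/23 * 0.1
#' @export
near_threshold_equilibrium <- function(delta, constants, eta_max = 0.5) {
  cc <- constants_row(constants)
  if (abs(cc$lambda + cc$mu - 1) > 1e-10) {
    stop("inconsistent constants: lambda + mu must equal 1", call. = FALSE)
  }
  eta <- 1 - cc$delta_c / delta
  if (any(eta < -1e-15)) {
    stop("near-threshold expansion requires delta >= delta_c", call. = FALSE)
  }
  if (any(eta > eta_max)) {
    stop(sprintf(
      "eta = %.3g exceeds eta_max = %g: outside the near-threshold regime",
      max(eta), eta_max
    ), call. = FALSE)
  }
  eta <- pmax(eta, 0)
  den <- cc$lambda * cc$sigma + cc$mu * cc$delta_c + cc$mu - cc$delta_c
  if (abs(den) < 1e-14) {
    stop("degenerate expansion: the eta-coefficient denominator vanishes",
      call. = FALSE
    )
  }
  tibble::tibble(
    delta = delta,
    eta = eta,
    x_star = eta / den,
    w_star = cc$sigma * eta / den,
    slope = cc$sigma / den,
    y_slope = -(2 + cc$delta_c / (1 - eta))
  )
}

#' Far-regime linearization of the steady-state polynomial
#'
#' Far above the threshold almost no susceptible-susceptible links
#' remain, so \eqn{y \approx 0}. The root of `P` on the `y = 0` slice is
#' \deqn{\phi(\epsilon) = \frac{\epsilon^2 - \lambda\epsilon}
#'   {2\epsilon^2 + (\delta_c + \mu)\epsilon - \lambda\sigma},}
#' and the implicit-function-theorem slope of the linearization
#' \eqn{y \approx \psi(\epsilon)(x - \phi(\epsilon))} is
#' \deqn{\psi(\epsilon) = -\frac{(\epsilon-\lambda)(2\epsilon^2 +
#'   (\delta_c+\mu)\epsilon - \lambda\sigma)}
#'   {\epsilon(\epsilon^2 - (\mu + 5\lambda)\epsilon -
#'   \lambda(2\delta_c + \mu - 2\sigma))},}
#' where \eqn{\epsilon = \delta_c/\delta}.
#'
#' @param eps Small parameter(s) \eqn{\epsilon = \delta_c/\delta > 0};
#'   vectorized.
#' @param constants A [model_constants()] row.
#' @return A tibble with columns `eps`, `phi`, `psi`.
#' @export
far_linearization <- function(eps, constants) {
  cc <- constants_row(constants)
  if (any(eps <= 0)) stop("`eps` must be positive", call. = FALSE)
  den_phi <- 2 * eps^2 + (cc$delta_c + cc$mu) * eps - cc$lambda * cc$sigma
  den_psi <- eps * (eps^2 - (cc$mu + 5 * cc$lambda) * eps -
    cc$lambda * (2 * cc$delta_c + cc$mu - 2 * cc$sigma))
  if (any(abs(den_phi) < 1e-14) || any(abs(den_psi) < 1e-14)) {
    stop("degenerate expansion: a linearization denominator vanishes",
      call. = FALSE
    )
  }
  phi <- (eps^2 - cc$lambda * eps) / den_phi
  psi <- -(eps - cc$lambda) * den_phi / den_psi
  tibble::tibble(eps = eps, phi = phi, psi = psi)
}

#' Series coefficients of the far-regime expansion
#'
#' Leading coefficients of the \eqn{\epsilon}-series of the
#' linearization point \eqn{\phi}, its slope \eqn{\psi}, and the
#' prevalence:
#' \deqn{\phi(\epsilon) = \frac{1}{\sigma}\epsilon +
#'   \frac{\delta_c + \mu - \sigma}{\lambda\sigma^2}\epsilon^2 + \dots,
#'   \qquad
#'   \psi(\epsilon) = \frac{\lambda\sigma}{2\delta_c + \mu -
#'   2\sigma}\epsilon^{-1} - \frac{2\delta_c^2 + 3\delta_c\mu +
#'   \sigma(5\lambda + 2\sigma) + \mu^2}{(2\delta_c + \mu -
#'   2\sigma)^2} + \dots}
#' The equilibrium pair fraction keeps the same two orders as
#' \eqn{\phi}, and `w_slope` is the \eqn{\epsilon}-coefficient
#' \eqn{(\delta_c + \mu - \sigma)/(\lambda\sigma)} of the prevalence
#' series.
#'
#' @param constants A [model_constants()] row.
#' @return One-row tibble: `phi1`, `phi2`, `psi_m1`, `psi_0`, `w_slope`.
#' @export
far_series_coefficients <- function(constants) {
  cc <- constants_row(constants)
  d2 <- 2 * cc$delta_c + cc$mu - 2 * cc$sigma
  tibble::tibble(
    phi1 = 1 / cc$sigma,
    phi2 = (cc$delta_c + cc$mu - cc$sigma) / (cc$lambda * cc$sigma^2),
    psi_m1 = cc$lambda * cc$sigma / d2,
    psi_0 = -(2 * cc$delta_c^2 + 3 * cc$delta_c * cc$mu +
      cc$sigma * (5 * cc$lambda + 2 * cc$sigma) + cc$mu^2) / d2^2,
    w_slope = (cc$delta_c + cc$mu - cc$sigma) / (cc$lambda * cc$sigma)
  )
}

#' Far-from-threshold approximation of the endemic equilibrium
#'
#' With \eqn{\epsilon = \delta_c/\delta} small, the equilibrium pair
#' fraction and prevalence are
#' \deqn{x^* \approx \frac{1}{\sigma}\epsilon + \frac{\delta_c + \mu -
#'   \sigma}{\lambda\sigma^2}\epsilon^2, \qquad
#'   w^* = \sigma\epsilon^{-1}x^* \approx 1 + \frac{\delta_c + \mu -
#'   \sigma}{\lambda\sigma}\epsilon,}
#' with remainders \eqn{O(\epsilon^3)} and \eqn{O(\epsilon^2)}.
#'
#' @param delta Ratio(s) \eqn{\delta > \delta_c}; vectorized.
#' @param constants A [model_constants()] row.
#' @param eps_max Refuse to extrapolate beyond this \eqn{\epsilon}.
#' @return A tibble with one row per `delta`: `delta`, `eps`, `x_star`,
#'   `w_star`.
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' far_equilibrium(cs$delta_c / 0.2, cs) # w* = 1 - (13/15) * 0.2
#' @export
far_equilibrium <- function(delta, constants, eps_max = 0.9) {
  cc <- constants_row(constants)
  if (any(delta <= cc$delta_c)) {
    stop("far expansion requires delta > delta_c", call. = FALSE)
  }
  eps <- cc$delta_c / delta
  if (any(eps > eps_max)) {
    stop(sprintf(
      "eps = %.3g exceeds eps_max = %g: outside the far regime",
      max(eps), eps_max
    ), call. = FALSE)
  }
  co <- far_series_coefficients(constants)
  x_star <- co$phi1 * eps + co$phi2 * eps^2
  tibble::tibble(
    delta = delta,
    eps = eps,
    x_star = x_star,
    w_star = cc$sigma * x_star / eps
  )
}

#' Implied epidemic threshold of the far approximation
#'
#' The far-regime prevalence line \eqn{w^* \approx 1 + G\epsilon} with
#' \eqn{G = (\delta_c + \mu - \sigma)/(\lambda\sigma)} crosses zero at
#' \eqn{\epsilon^* = -1/G} (requiring \eqn{G < 0}), implying a threshold
#' estimate \eqn{\delta^* = \delta_c/\epsilon^* = -G\,\delta_c}. The
#' estimate is classified against the true threshold; independently, the
#' moment rule says the estimate is an overestimate whenever
#' \eqn{\langle k^2\rangle \ge \langle k\rangle^2 + \langle k\rangle}
#' (otherwise the direction depends on the third moment as well).
#'
#' @param constants A [model_constants()] row (its stored moments supply
#'   the rule check).
#' @return One-row tibble: `delta_estimate`, `eps_star`,
#'   `classification` (`"overestimate"`, `"underestimate"`, `"equal"`),
#'   `moment_rule_overestimate`.
#' @examples
#' cs <- model_constants(as_network_moments(10, 110, 1310))
#' far_threshold_estimate(cs) # 0.11, overestimate
#' @export
far_threshold_estimate <- function(constants) {
  cc <- constants_row(constants)
  G <- (cc$delta_c + cc$mu - cc$sigma) / (cc$lambda * cc$sigma)
  if (G >= 0) {
    stop(
      "no crossing: the far-regime prevalence slope is nonnegative, so the",
      " approximation never reaches w* = 0 at positive eps",
      call. = FALSE
    )
  }
  eps_star <- -1 / G
  delta_est <- cc$delta_c / eps_star
  cls <- if (abs(delta_est - cc$delta_c) <= 1e-12 * cc$delta_c) {
    "equal"
  } else if (delta_est > cc$delta_c) {
    "overestimate"
  } else {
    "underestimate"
  }
  k2 <- if (!is.null(cc$k2)) cc$k2 else NA_real_
  tibble::tibble(
    delta_estimate = delta_est,
    eps_star = eps_star,
    classification = cls,
    moment_rule_overestimate = k2 >= cc$k1^2 + cc$k1
  )
}

#' Tabulate both approximations over a delta grid
#'
#' Evaluates the near- and far-regime prevalence approximations where
#' their domain guards allow, labelling each `delta` with the regime its
#' magnitude suggests (`delta/delta_c` below `seed_switch` is "near").
#'
#' @param constants A [model_constants()] row.
#' @param delta Vector of ratios above the threshold.
#' @param seed_switch Regime boundary on `delta/delta_c`.
#' @param eta_max,eps_max Domain guards; outside them the corresponding
#'   column is `NA`.
#' @return Tibble with columns `delta`, `eta_or_eps`, `w_near`, `w_far`,
#'   `regime`.
#' @export
approximation_table <- function(constants, delta, seed_switch = 2,
                                eta_max = 0.5, eps_max = 0.9) {
  cc <- constants_row(constants)
  purrr::map_dfr(delta, function(d) {
    ratio <- d / cc$delta_c
    near <- ratio >= 1 && ratio < seed_switch
    w_n <- tryCatch(
      near_threshold_equilibrium(d, constants, eta_max = eta_max)$w_star,
      error = function(e) NA_real_
    )
    w_f <- tryCatch(
      far_equilibrium(d, constants, eps_max = eps_max)$w_star,
      error = function(e) NA_real_
    )
    tibble::tibble(
      delta = d,
      eta_or_eps = if (near) 1 - cc$delta_c / d else cc$delta_c / d,
      w_near = w_n,
      w_far = w_f,
      regime = if (near) "near" else "far"
    )
  })
}
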