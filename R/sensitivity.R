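#' Feasibility of a degree-moment triple
#'
#' Raw moments of any degree distribution satisfy Jensen's inequality
#' \eqn{\langle k^2\rangle \ge \langle k\rangle^2} and the
#' Cauchy-Schwarz inequality \eqn{\langle k^2\rangle^2 \le \langle
#' k^3\rangle\langle k\rangle}. For fixed \eqn{\langle k^3\rangle} these
#' carve a wedge-shaped feasible region in the
#' \eqn{(\langle k\rangle, \langle k^2\rangle)} plane; sensitivity maps
#' are masked outside it.
#'
#' @param k1,k2,k3 Moment values (vectorized; treated as free reals).
#' @return Logical vector: both inequalities hold (non-strict).
#' @examples
#' feasible_moments(4, 17, 76) # TRUE
#' feasible_moments(4, 18, 76) # FALSE (Cauchy-Schwarz)
#' @export
feasible_moments <- function(k1, k2, k3) {
  k1 > 0 & k2 >= k1^2 & k2^2 <= k3 * k1
}

#' Sensitivity of endemic prevalence to degree moments, near regime
#'
#' Closed-form partial derivatives of the near-threshold prevalence
#' approximation with respect to the three raw moments, evaluated at the
#' epidemic threshold \eqn{\delta = \delta_c}. With
#' \eqn{D = \langle k\rangle - 2\langle k^2\rangle + \langle k^3\rangle}:
#' \deqn{\frac{\partial w^*}{\partial\langle k\rangle} =
#'   -\frac{\langle k^2\rangle}{D}, \qquad
#'   \frac{\partial w^*}{\partial\langle k^2\rangle} =
#'   \frac{\langle k\rangle}{D}, \qquad
#'   \frac{\partial w^*}{\partial\langle k^3\rangle} = 0.}
#' At the threshold the prevalence is insensitive to the third moment;
#' increasing \eqn{\langle k\rangle} (or decreasing
#' \eqn{\langle k^2\rangle}) lowers the endemic prevalence.
#'
#' By default the limit values at the threshold are returned. With
#' `at_threshold = FALSE` and a `delta` above the threshold, the full
#' \eqn{\delta}-dependent derivative of the near approximation is
#' evaluated by central differences through the moment-to-constants
#' chain (a numerical convenience, not a closed form).
#'
#' @param m Moments input accepted by [network_moments()]/[coerce]able
#'   one-row table with `k1`, `k2`, `k3`.
#' @param at_threshold Use the closed-form threshold values (default).
#' @param delta Evaluation ratio for the `at_threshold = FALSE` variant.
#' @param step Relative finite-difference step for that variant.
#' @return One-row tibble: `k1`, `k2`, `k3`, `regime`, `delta`, `d_k1`,
#'   `d_k2`, `d_k3`.
#' @examples
#' sens_near(as_network_moments(4, 17, 76)) # d_k2 = 2/23
#' @export
sens_near <- function(m, at_threshold = TRUE, delta = NULL, step = 1e-7) {
  m <- coerce_moments(m)
  k1 <- m$k1
  k2 <- m$k2
  k3 <- m$k3
  if (!feasible_moments(k1, k2, k3)) {
    stop("infeasible moments: violates Jensen or Cauchy-Schwarz",
      call. = FALSE
    )
  }
  if (at_threshold) {
    den <- k1 - 2 * k2 + k3
    if (abs(den) < 1e-14 * max(1, abs(k3))) {
      stop("degenerate sensitivity: denominator k1 - 2 k2 + k3 vanishes",
        call. = FALSE
      )
    }
    return(tibble::tibble(
      k1 = k1, k2 = k2, k3 = k3, regime = "near", delta = NA_real_,
      d_k1 = -k2 / den, d_k2 = k1 / den, d_k3 = 0
    ))
  }
  if (is.null(delta)) {
    stop("`delta` is required when at_threshold = FALSE", call. = FALSE)
  }
  w_of <- function(k1, k2, k3) {
    cs <- model_constants(new_network_moments(k1, k2, k3))
    near_threshold_equilibrium(delta, cs)$w_star
  }
  tibble::tibble(
    k1 = k1, k2 = k2, k3 = k3, regime = "near", delta = delta,
    d_k1 = central_diff(function(v) w_of(v, k2, k3), k1, step),
    d_k2 = central_diff(function(v) w_of(k1, v, k3), k2, step),
    d_k3 = central_diff(function(v) w_of(k1, k2, v), k3, step)
  )
}

central_diff <- function(f, at, rel_step) {
  h <- rel_step * max(abs(at), 1)
  (f(at + h) - f(at - h)) / (2 * h)
}

#' Sensitivity of endemic prevalence to degree moments, far regime
#'
#' Closed-form partial derivatives of the far-from-threshold prevalence
#' approximation at a fixed \eqn{\delta}. With
#' \eqn{E = (\langle k^2\rangle^2 - \langle k^3\rangle\langle
#' k\rangle)^2}:
#' \deqn{\frac{\partial w^*}{\partial\langle k\rangle} =
#'   \frac{\langle k^3\rangle^2 + 3\langle k\rangle^2\langle
#'   k^2\rangle^2 - 2(\langle k\rangle^3\langle k^3\rangle + \langle
#'   k^2\rangle^3)}{E}\cdot\frac{1}{\delta},}
#' \deqn{\frac{\partial w^*}{\partial\langle k^2\rangle} =
#'   -\frac{2(\langle k\rangle^2 - \langle k^2\rangle)(\langle
#'   k\rangle\langle k^2\rangle - \langle k^3\rangle)}{E}\cdot
#'   \frac{1}{\delta}, \qquad
#'   \frac{\partial w^*}{\partial\langle k^3\rangle} =
#'   \frac{(\langle k\rangle^2 - \langle k^2\rangle)^2}{E}\cdot
#'   \frac{1}{\delta}.}
#' All three share the factor \eqn{1/\delta}, so the choice of
#' \eqn{\delta} rescales but never reorders them. They blow up on the
#' Cauchy-Schwarz boundary \eqn{\langle k^2\rangle^2 = \langle
#' k^3\rangle\langle k\rangle}, where they are undefined.
#'
#' @param m Moments input (as in [sens_near()]).
#' @param delta Evaluation ratio, `> 0`.
#' @return One-row tibble: `k1`, `k2`, `k3`, `regime`, `delta`, `d_k1`,
#'   `d_k2`, `d_k3`.
#' @examples
#' sens_far(as_network_moments(4, 17, 76), delta = 1.5)
#' @export
sens_far <- function(m, delta = 1.5) {
  m <- coerce_moments(m)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  k1 <- m$k1
  k2 <- m$k2
  k3 <- m$k3
  gap <- k2^2 - k3 * k1
  if (abs(gap) < 1e-12 * max(1, k2^2)) {
    stop(
      "undefined sensitivity: moments lie on the Cauchy-Schwarz boundary",
      call. = FALSE
    )
  }
  E <- gap^2
  tibble::tibble(
    k1 = k1, k2 = k2, k3 = k3, regime = "far", delta = delta,
    d_k1 = (k3^2 + 3 * k1^2 * k2^2 - 2 * (k1^3 * k3 + k2^3)) / E / delta,
    d_k2 = -2 * (k1^2 - k2) * (k1 * k2 - k3) / E / delta,
    d_k3 = (k1^2 - k2)^2 / E / delta
  )
}

#' Sensitivity heat-map grid over the moment plane
#'
#' Evaluates the near- or far-regime moment sensitivities on a uniform
#' \eqn{(\langle k\rangle, \langle k^2\rangle)} grid at a fixed
#' \eqn{\langle k^3\rangle} slice. Cells outside the feasibility wedge
#' are masked (`feasible = FALSE`, `NA` values); feasible cells where
#' the regime's denominator degenerates (the Cauchy-Schwarz boundary in
#' the far regime, a vanishing \eqn{\langle k\rangle - 2\langle
#' k^2\rangle + \langle k^3\rangle} in the near regime) are kept in the
#' mask but flagged `defined = FALSE`.
#'
#' @param k3 Fixed third moment of the slice.
#' @param k1_range,k2_range Length-2 axis ranges (positive).
#' @param n Grid points per axis (`>= 2`).
#' @param regime `"near"` or `"far"`.
#' @param delta Evaluation ratio for the far regime.
#' @return A tibble of class `scpw_sensitivity_grid` in long format:
#'   `k1`, `k2`, `k3`, `regime`, `delta`, `feasible`, `defined`,
#'   `d_k1`, `d_k2`, `d_k3`.
#' @examples
#' g <- sensitivity_grid(76, c(1, 6), c(5, 20), n = 25, regime = "near")
#' @export
sensitivity_grid <- function(k3, k1_range, k2_range, n = 50L,
                             regime = c("near", "far"), delta = 1.5) {
  regime <- match.arg(regime)
  if (any(k1_range <= 0) || any(k2_range <= 0) || k3 <= 0) {
    stop("moment ranges must be positive", call. = FALSE)
  }
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  g <- tidyr::expand_grid(
    k1 = seq(k1_range[1], k1_range[2], length.out = n),
    k2 = seq(k2_range[1], k2_range[2], length.out = n)
  )
  g$k3 <- k3
  g$regime <- regime
  g$delta <- if (regime == "far") delta else NA_real_
  g$feasible <- feasible_moments(g$k1, g$k2, k3)

  if (regime == "near") {
    den <- g$k1 - 2 * g$k2 + k3
    g$defined <- g$feasible & abs(den) >= 1e-12 * max(1, abs(k3))
    ok <- g$defined
    g$d_k1 <- ifelse(ok, -g$k2 / den, NA_real_)
    g$d_k2 <- ifelse(ok, g$k1 / den, NA_real_)
    g$d_k3 <- ifelse(ok, 0, NA_real_)
  } else {
    gap <- g$k2^2 - k3 * g$k1
    g$defined <- g$feasible & abs(gap) >= 1e-12 * pmax(1, g$k2^2)
    ok <- g$defined
    E <- gap^2
    g$d_k1 <- ifelse(
      ok,
      (k3^2 + 3 * g$k1^2 * g$k2^2 - 2 * (g$k1^3 * k3 + g$k2^3)) / E / delta,
      NA_real_
    )
    g$d_k2 <- ifelse(
      ok, -2 * (g$k1^2 - g$k2) * (g$k1 * g$k2 - k3) / E / delta, NA_real_
    )
    g$d_k3 <- ifelse(ok, (g$k1^2 - g$k2)^2 / E / delta, NA_real_)
  }
  n_deg <- sum(g$feasible & !g$defined)
  if (n_deg > 0) {
    message(sprintf("%d feasible cell(s) masked as degenerate", n_deg))
  }
  out <- g[, c(
    "k1", "k2", "k3", "regime", "delta", "feasible", "defined",
    "d_k1", "d_k2", "d_k3"
  )]
  class(out) <- c("scpw_sensitivity_grid", class(out))
  out
}

#' @export
autoplot.scpw_sensitivity_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("d_k1", "d_k2", "d_k3"),
    names_to = "partial", values_to = "sensitivity"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$k1, y = .data$k2, fill = .data$sensitivity)
  ) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~partial) +
    ggplot2::scale_fill_gradient2(na.value = "white") +
    ggplot2::labs(
      x = expression("<k>"), y = expression("<k^2>"),
      title = sprintf(
        "Prevalence sensitivities (%s regime, <k^3> = %g)",
        object$regime[1], object$k3[1]
      )
    ) +
    ggplot2::theme_minimal()
}
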