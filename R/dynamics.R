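#' Pair-closure factor Q of the SCPW model
#'
#' The SCPW system closes the pair-level equations with a factor
#' \deqn{Q = \frac{\alpha [S]}{([SI]+[SS])^2} + \frac{\beta}{[SI]+[SS]},}
#' which approximates \eqn{(S_2 - S_1)/S_1^2}, the normalized excess of
#' the second moment of the susceptible-degree distribution. It is
#' singular when no susceptible-anchored pairs remain; the toolkit errors
#' there rather than regularizing.
#'
#' @param state Named numeric vector with at least `S`, `SI`, `SS`
#'   (expected susceptible nodes and pair counts).
#' @param constants A [model_constants()] row (only `alpha` and `beta`
#'   are used).
#' @param guard Positive lower bound on `[SI] + [SS]`.
#' @return The closure factor, a number (units 1/pairs).
#' @export
q_closure <- function(state, constants, guard = 1e-12) {
  cc <- constants_row(constants)
  den <- state[["SI"]] + state[["SS"]]
  if (!is.finite(den) || den <= guard) {
    stop("singular state: [SI] + [SS] is at or below the denominator guard",
      call. = FALSE
    )
  }
  cc$alpha * state[["S"]] / den^2 + cc$beta / den
}

#' Right-hand sides of the SCPW systems
#'
#' Four equivalent formulations of the SCPW vector field:
#'
#' * `rhs_dimensional()`: expected counts `(S, I, SI, SS, II)` with
#'   transmission rate `tau` and recovery rate `gamma` (rates per unit
#'   time). Node and pair totals are conserved:
#'   \eqn{\dot S + \dot I = 0} and
#'   \eqn{2\dot{[SI]} + \dot{[SS]} + \dot{[II]} = 0}.
#' * `rhs_nondim()`: proportions `(v, w, x, y, z)` in rescaled time
#'   `T = t*gamma`, depending only on \eqn{\delta = \tau/\gamma}; the
#'   conservation laws become \eqn{v + w = 1} and \eqn{2x + y + z = 1}.
#' * `rhs_wxz()`: the 3-variable reduction `(w, x, z)` used for the
#'   disease-free-equilibrium analysis (all coordinates vanish at the
#'   DFE), obtained by substituting `v = 1 - w`, `y = 1 - 2x - z`.
#' * `rhs_vxy()`: the 3-variable reduction `(v, x, y)` written with the
#'   rescaled constants \eqn{\sigma, \lambda, \mu} and the ratio
#'   \eqn{\delta/\delta_c}; this is the form whose steady states the
#'   endemic-equilibrium polynomials encode.
#'
#' @param state Named numeric state vector of the respective system.
#' @param tau,gamma Transmission and recovery rates (1/time).
#' @param delta Transmission-recovery ratio \eqn{\delta = \tau/\gamma}.
#' @param constants A [model_constants()] row.
#' @param guard Denominator guard for the closure terms.
#' @return Named numeric vector of time derivatives, same names as
#'   `state`.
#' @name scpw_rhs
NULL

#' @rdname scpw_rhs
#' @export
rhs_dimensional <- function(state, tau, gamma, constants, guard = 1e-12) {
  if (tau < 0 || gamma <= 0) {
    stop("need tau >= 0 and gamma > 0", call. = FALSE)
  }
  Q <- q_closure(state, constants, guard = guard)
  S <- state[["S"]]
  I <- state[["I"]]
  SI <- state[["SI"]]
  SS <- state[["SS"]]
  II <- state[["II"]]
  c(
    S = gamma * I - tau * SI,
    I = tau * SI - gamma * I,
    SI = gamma * (II - SI) - tau * SI + tau * SI * (SS - SI) * Q,
    SS = 2 * gamma * SI - 2 * tau * SI * SS * Q,
    II = -2 * gamma * II + 2 * tau * SI + 2 * tau * SI^2 * Q
  )
}

#' @rdname scpw_rhs
#' @export
rhs_nondim <- function(state, delta, constants, guard = 1e-12) {
  cc <- constants_row(constants)
  v <- state[["v"]]
  w <- state[["w"]]
  x <- state[["x"]]
  y <- state[["y"]]
  z <- state[["z"]]
  s <- x + y
  if (!is.finite(s) || s <= guard) {
    stop("singular state: x + y is at or below the denominator guard",
      call. = FALSE
    )
  }
  # closure terms share the factor a*v*x/s^2 + b*x/s
  cl <- cc$alpha * delta / cc$k1 * v * x / s^2 + cc$beta * delta * x / s
  c(
    v = w - cc$k1 * delta * x,
    w = cc$k1 * delta * x - w,
    x = z - (delta + 1) * x + cl * (y - x),
    y = 2 * x - 2 * cl * y,
    z = -2 * z + 2 * delta * x + 2 * cl * x
  )
}

#' @rdname scpw_rhs
#' @export
rhs_wxz <- function(state, delta, constants, guard = 1e-12) {
  cc <- constants_row(constants)
  w <- state[["w"]]
  x <- state[["x"]]
  z <- state[["z"]]
  s <- 1 - x - z # equals x + y under 2x + y + z = 1
  if (!is.finite(s) || s <= guard) {
    stop("singular state: 1 - x - z is at or below the denominator guard",
      call. = FALSE
    )
  }
  cl <- cc$alpha * delta / cc$k1 * (1 - w) * x / s^2 + cc$beta * delta * x / s
  c(
    w = cc$k1 * delta * x - w,
    x = z - (delta + 1) * x + cl * (1 - 3 * x - z),
    z = -2 * z + 2 * delta * x + 2 * cl * x
  )
}

#' @rdname scpw_rhs
#' @export
rhs_vxy <- function(state, delta, constants, guard = 1e-12) {
  cc <- constants_row(constants)
  v <- state[["v"]]
  x <- state[["x"]]
  y <- state[["y"]]
  s <- x + y
  if (!is.finite(s) || s <= guard) {
    stop("singular state: x + y is at or below the denominator guard",
      call. = FALSE
    )
  }
  r <- delta / cc$delta_c
  cl <- cc$lambda * r * v * x / s^2 + cc$mu * r * x / s
  c(
    v = 1 - v - cc$sigma * r * x,
    x = 1 - y - (3 + cc$delta_c * r) * x + cl * (y - x),
    y = 2 * x - 2 * cl * y
  )
}

#' Default epidemic initial condition
#'
#' Seeds a small outbreak at prevalence `init_w` with pair fractions set
#' by proportionate mixing (`x = v*w`, `y = v^2`, `z = w^2`), then
#' renormalized so `2x + y + z = 1` holds exactly.
#'
#' @param init_w Initial prevalence in (0, 1).
#' @return Named numeric `(v, w, x, y, z)`.
#' @export
scpw_init <- function(init_w = 1e-2) {
  if (init_w <= 0 || init_w >= 1) stop("`init_w` must be in (0,1)", call. = FALSE)
  v <- 1 - init_w
  w <- init_w
  x <- v * w
  y <- v^2
  z <- w^2
  s <- 2 * x + y + z
  c(v = v, w = w, x = x / s, y = y / s, z = z / s)
}

#' Integrate an SCPW system
#'
#' Adaptive stiff-capable integration (via [deSolve::ode()], `lsodar`)
#' of the nondimensional system or either 3-variable reduction, with an
#' event-based stop once the vector field norm falls below `conv_tol`
#' (the trajectory has converged to an equilibrium). Whatever system is
#' integrated, the returned trajectory is reported in the full
#' `(v, w, x, y, z)` coordinates, reconstructing the eliminated
#' variables from the conservation laws.
#'
#' Conservation is monitored, not enforced: for the 5-variable system a
#' drift in `v + w` or `2x + y + z` beyond `cons_tol` aborts loudly.
#' Trajectories leaving `[0, 1]` by more than `cons_tol` are flagged via
#' the `positivity_ok` attribute, never clipped.
#'
#' @param constants A [model_constants()] row.
#' @param delta Transmission-recovery ratio.
#' @param system `"nondim"`, `"wxz"`, or `"vxy"`.
#' @param init Optional named initial state in the full `(v,w,x,y,z)`
#'   coordinates; defaults to [scpw_init()] at `init_w`.
#' @param init_w Initial prevalence for the default seeding.
#' @param t_end Final nondimensional time `T = t*gamma`.
#' @param rtol,atol Relative/absolute local error tolerances.
#' @param conv_tol Stop early when `max(abs(rates))` drops below this.
#' @param n_out Number of output times (uniform on `[0, t_end]`).
#' @param cons_tol Conservation / positivity monitoring tolerance.
#'
#' @return A tibble of class `scpw_trajectory` with columns
#'   `T, v, w, x, y, z` and attributes `delta`, `system`, `converged`,
#'   `positivity_ok`.
#'
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' tr <- scpw_simulate(cs, delta = 0.6)
#' glance(tr)
#' @export
scpw_simulate <- function(constants, delta, system = c("nondim", "wxz", "vxy"),
                          init = NULL, init_w = 1e-2, t_end = 200,
                          rtol = 1e-8, atol = 1e-10, conv_tol = 1e-10,
                          n_out = 201L, cons_tol = 1e-6) {
  system <- match.arg(system)
  cc <- constants_row(constants)
  if (delta < 0) stop("`delta` must be nonnegative", call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (is.null(init)) init <- scpw_init(init_w)
  full <- c("v", "w", "x", "y", "z")
  if (!all(full %in% names(init))) {
    stop("`init` must name all of v, w, x, y, z", call. = FALSE)
  }
  if (abs(init[["v"]] + init[["w"]] - 1) > 1e-9 ||
    abs(2 * init[["x"]] + init[["y"]] + init[["z"]] - 1) > 1e-9) {
    stop("`init` violates the conservation laws", call. = FALSE)
  }

  y0 <- switch(system,
    nondim = init[full],
    wxz = init[c("w", "x", "z")],
    vxy = init[c("v", "x", "y")]
  )
  rhs <- switch(system,
    nondim = function(t, y, p) list(rhs_nondim(y, delta, constants)),
    wxz = function(t, y, p) list(rhs_wxz(y, delta, constants)),
    vxy = function(t, y, p) list(rhs_vxy(y, delta, constants))
  )
  rootfn <- function(t, y, p) max(abs(unlist(rhs(t, y, p)))) - conv_tol

  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = NULL,
    method = "lsodar", rtol = rtol, atol = atol, rootfunc = rootfn
  )
  sol <- as.data.frame(sol)
  if (nrow(sol) < 2L && t_end > 0) {
    stop("integration failed near the initial state", call. = FALSE)
  }

  out <- switch(system,
    nondim = tibble::tibble(
      T = sol$time, v = sol$v, w = sol$w, x = sol$x, y = sol$y, z = sol$z
    ),
    wxz = tibble::tibble(
      T = sol$time, v = 1 - sol$w, w = sol$w, x = sol$x,
      y = 1 - 2 * sol$x - sol$z, z = sol$z
    ),
    vxy = tibble::tibble(
      T = sol$time, v = sol$v, w = 1 - sol$v, x = sol$x, y = sol$y,
      z = 1 - 2 * sol$x - sol$y
    )
  )

  if (system == "nondim") {
    drift <- max(abs(out$v + out$w - 1), abs(2 * out$x + out$y + out$z - 1))
    if (drift > cons_tol) {
      stop(sprintf(
        "conservation drift %.3g exceeds %.3g during integration",
        drift, cons_tol
      ), call. = FALSE)
    }
  }
  pos_ok <- all(out[full] >= -cons_tol & out[full] <= 1 + cons_tol)
  if (!pos_ok) {
    warning("trajectory left [0,1]; flagged, not clipped", call. = FALSE)
  }

  final <- unlist(out[nrow(out), full])
  rate_norm <- max(abs(rhs_nondim(final, delta, constants,
    guard = .Machine$double.xmin
  )))
  attr(out, "delta") <- delta
  attr(out, "system") <- system
  attr(out, "converged") <- rate_norm < conv_tol * 10
  attr(out, "positivity_ok") <- pos_ok
  class(out) <- c("scpw_trajectory", class(out))
  out
}

#' @export
print.scpw_trajectory <- function(x, ...) {
  cat(sprintf(
    "# SCPW trajectory: delta = %g, system = %s, converged = %s\n",
    attr(x, "delta"), attr(x, "system"), attr(x, "converged")
  ))
  NextMethod()
}

#' @export
tidy.scpw_trajectory <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = c("v", "w", "x", "y", "z"),
    names_to = "compartment", values_to = "fraction"
  )
}

#' @export
glance.scpw_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    delta = attr(x, "delta"),
    system = attr(x, "system"),
    converged = attr(x, "converged"),
    positivity_ok = attr(x, "positivity_ok"),
    T_final = x$T[n],
    w_final = x$w[n]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.scpw_trajectory <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$T, y = .data$fraction, colour = .data$compartment)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "nondimensional time T",
      y = "fraction of nodes / pairs",
      title = sprintf("SCPW trajectory (delta = %g)", attr(object, "delta"))
    ) +
    ggplot2::theme_minimal()
}
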