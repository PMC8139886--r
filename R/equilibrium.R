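#' Disease-free equilibrium stability analysis
#'
#' Assembles the Jacobian of the `(w, x, z)` reduction at the
#' disease-free equilibrium,
#' \deqn{DF = \begin{pmatrix} -1 & \langle k\rangle\delta & 0 \\
#'   0 & \bar k\delta - (\delta+1) & 1 \\ 0 & 2\delta & -2
#'   \end{pmatrix},}
#' whose block-triangular structure yields the eigenvalue \eqn{-1}
#' together with the eigenvalues of the lower-right block `B`. Those are
#' always real (the discriminant is
#' \eqn{(\delta(\bar k - 1)+1)^2 + 8\delta > 0}), and
#' \eqn{\det B = 2(1 - \delta\bar k)}, so the DFE is stable exactly for
#' \eqn{\delta < 1/\bar k = \delta_c}.
#'
#' @param delta Transmission-recovery ratio(s); vectorized.
#' @param constants A [model_constants()] row.
#' @return A tibble with one row per `delta`: `delta`, `trace_B`,
#'   `det_B`, `eig1 <= eig2 <= eig3`, `stable`. For scalar `delta` the
#'   assembled Jacobian is attached as attribute `"jacobian"`.
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' dfe_analysis(0.2, cs) # det_B = 0.7, stable
#' @export
dfe_analysis <- function(delta, constants) {
  cc <- constants_row(constants)
  if (any(delta < 0)) stop("`delta` must be nonnegative", call. = FALSE)
  rows <- purrr::map(delta, function(d) {
    J <- matrix(
      c(
        -1, cc$k1 * d, 0,
        0, cc$kbar * d - (d + 1), 1,
        0, 2 * d, -2
      ),
      nrow = 3, byrow = TRUE
    )
    B <- J[2:3, 2:3]
    ev <- sort(Re(eigen(J, only.values = TRUE)$values))
    list(
      jacobian = J,
      row = tibble::tibble(
        delta = d,
        trace_B = sum(diag(B)),
        det_B = B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1],
        eig1 = ev[1], eig2 = ev[2], eig3 = ev[3],
        stable = (B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]) > 0 &
          sum(diag(B)) < 0
      )
    )
  })
  out <- dplyr::bind_rows(purrr::map(rows, "row"))
  if (length(delta) == 1L) attr(out, "jacobian") <- rows[[1]]$jacobian
  out
}

#' Endemic steady-state polynomials
#'
#' The endemic equilibria of the SCPW model are the feasible common
#' roots of two polynomials in the pair fractions `(x, y)`. With
#' \eqn{\epsilon = \delta_c/\delta} and \eqn{s = x + y}:
#' \deqn{P(x,y) = \epsilon^2 (1-y-2x) s^2 - \epsilon(\delta_c x s^2 +
#'   \lambda x^2 + \mu x^2 s) + \lambda\sigma x^3,}
#' \deqn{Q(x,y) = \epsilon^2 s^2 - \epsilon(\lambda y + \mu y s) +
#'   \lambda\sigma x y.}
#' A factor `x` corresponding to the disease-free equilibrium has been
#' removed from `Q`'s parent equation, so `x = 0` does not generally
#' solve `Q`. (The \eqn{\mu} term of `P` is \eqn{\mu x^2 s}, the form
#' consistent with the derivation from the `(v, x, y)` system and with
#' the perturbation expansions.)
#'
#' @param x,y Pair fractions (vectorized).
#' @param delta Transmission-recovery ratio, `> 0`.
#' @param constants A [model_constants()] row.
#' @return Numeric vector of polynomial values.
#' @export
steady_state_P <- function(x, y, delta, constants) {
  cc <- constants_row(constants)
  e <- cc$delta_c / delta
  s <- x + y
  e^2 * (1 - y - 2 * x) * s^2 -
    e * (cc$delta_c * x * s^2 + cc$lambda * x^2 + cc$mu * x^2 * s) +
    cc$lambda * cc$sigma * x^3
}

#' @rdname steady_state_P
#' @export
steady_state_Q <- function(x, y, delta, constants) {
  cc <- constants_row(constants)
  e <- cc$delta_c / delta
  s <- x + y
  e^2 * s^2 - e * (cc$lambda * y + cc$mu * y * s) +
    cc$lambda * cc$sigma * x * y
}

# Analytic Jacobian of (P, Q) in (x, y).
pq_jacobian <- function(x, y, delta, cc) {
  e <- cc$delta_c / delta
  s <- x + y
  u <- 1 - y - 2 * x
  Px <- e^2 * (-2 * s^2 + 2 * u * s) -
    e * (cc$delta_c * (s^2 + 2 * x * s) + 2 * cc$lambda * x +
      cc$mu * (2 * x * s + x^2)) + 3 * cc$lambda * cc$sigma * x^2
  Py <- e^2 * (-s^2 + 2 * u * s) -
    e * (2 * cc$delta_c * x * s + cc$mu * x^2)
  Qx <- 2 * e^2 * s - e * cc$mu * y + cc$lambda * cc$sigma * y
  Qy <- 2 * e^2 * s - e * (cc$lambda + cc$mu * (s + y)) +
    cc$lambda * cc$sigma * x
  matrix(c(Px, Py, Qx, Qy), nrow = 2, byrow = TRUE)
}

# Finite-difference Jacobian of the (v, x, y) vector field; used for the
# numerical stability assessment of endemic equilibria.
vxy_jacobian <- function(state, delta, constants, h = 1e-7) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- state
    dn <- state
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (rhs_vxy(up, delta, constants) -
      rhs_vxy(dn, delta, constants)) / (2 * h)
  }
  J
}

#' Solve for the endemic equilibrium
#'
#' Newton iteration on the steady-state polynomial system
#' ([steady_state_P()], [steady_state_Q()]) with analytic Jacobian and
#' residual-halving damping. Below the threshold
#' (\eqn{\delta \le \delta_c}) no endemic state exists and the solver
#' reports so. Above it the iteration starts from a regime-appropriate
#' asymptotic seed — the near-threshold expansion when
#' `delta/delta_c < seed_switch`, the far-regime expansion otherwise —
#' unless `seed_hint` overrides it; if the first seed fails, the other
#' seed and then a continuation walk from just above \eqn{\delta_c} are
#' tried. A converged root is accepted only inside the feasible open
#' region `x > 0`, `y >= 0`, `x + y < 1`, `2x + y < 1`.
#'
#' Prevalence is recovered from the pair fraction via
#' \eqn{w^* = (\delta_c/\delta)^{-1}\sigma x^*} and \eqn{v = 1 - w}.
#' Stability is assessed numerically from the eigenvalues of the
#' finite-difference Jacobian of the `(v, x, y)` vector field at the
#' solution.
#'
#' @param delta Transmission-recovery ratio, `> 0`.
#' @param constants A [model_constants()] row.
#' @param seed_hint Optional `c(x, y)` starting point.
#' @param seed_switch Regime boundary on `delta/delta_c` for seed choice.
#' @param max_iter Newton iteration cap.
#' @param tol Residual convergence tolerance.
#' @return A one-row tibble of class `endemic_equilibrium`: `delta`,
#'   `exists`, `x`, `y`, `v`, `w`, `resid_P`, `resid_Q`, `stable`.
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' solve_endemic(2 * cs$delta_c, cs)
#' @export
solve_endemic <- function(delta, constants, seed_hint = NULL,
                          seed_switch = 2, max_iter = 100L, tol = 1e-12) {
  cc <- constants_row(constants)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)

  empty <- tibble::tibble(
    delta = delta, exists = FALSE, x = NA_real_, y = NA_real_,
    v = NA_real_, w = NA_real_, resid_P = NA_real_, resid_Q = NA_real_,
    stable = NA
  )
  class(empty) <- c("endemic_equilibrium", class(empty))
  if (delta <= cc$delta_c) {
    return(empty)
  }

  seeds <- list()
  if (!is.null(seed_hint)) seeds <- c(seeds, list(as.numeric(seed_hint)))
  seeds <- c(seeds, endemic_seeds(delta, cc, seed_switch))

  root <- NULL
  for (s0 in seeds) {
    root <- newton_pq(s0, delta, constants, cc, max_iter, tol)
    if (!is.null(root)) break
  }
  if (is.null(root)) {
    # continuation fallback: walk delta up from just above the threshold
    dgrid <- exp(seq(log(cc$delta_c * 1.001), log(delta), length.out = 25L))
    cur <- NULL
    for (d in dgrid) {
      s0 <- if (is.null(cur)) endemic_seeds(d, cc, seed_switch)[[1]] else cur
      sol <- newton_pq(s0, d, constants, cc, max_iter, tol)
      if (!is.null(sol)) cur <- sol
    }
    if (!is.null(cur)) root <- newton_pq(cur, delta, constants, cc, max_iter, tol)
  }
  if (is.null(root)) {
    stop(sprintf(
      paste0(
        "endemic solve failed at delta = %g (delta/delta_c = %g): Newton did ",
        "not converge to a feasible root from asymptotic seeds or continuation"
      ),
      delta, delta / cc$delta_c
    ), call. = FALSE)
  }

  x <- root[1]
  y <- root[2]
  w <- cc$sigma * (delta / cc$delta_c) * x
  v <- 1 - w
  J <- vxy_jacobian(c(v = v, x = x, y = y), delta, constants)
  stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
  out <- tibble::tibble(
    delta = delta, exists = TRUE, x = x, y = y, v = v, w = w,
    resid_P = abs(steady_state_P(x, y, delta, constants)),
    resid_Q = abs(steady_state_Q(x, y, delta, constants)),
    stable = stable
  )
  class(out) <- c("endemic_equilibrium", class(out))
  out
}

# Asymptotic starting points for the Newton iteration.
endemic_seeds <- function(delta, cc, seed_switch) {
  near <- tryCatch(
    {
      eta <- 1 - cc$delta_c / delta
      den <- cc$lambda * cc$sigma + cc$mu * cc$delta_c + cc$mu - cc$delta_c
      x0 <- eta / den
      y0 <- 1 - (2 + cc$delta_c / (1 - eta)) * x0
      c(x0, y0)
    },
    error = function(e) NULL
  )
  far <- tryCatch(
    {
      e <- cc$delta_c / delta
      phi <- (e^2 - cc$lambda * e) /
        (2 * e^2 + (cc$delta_c + cc$mu) * e - cc$lambda * cc$sigma)
      x0 <- e / cc$sigma +
        (cc$delta_c + cc$mu - cc$sigma) / (cc$lambda * cc$sigma^2) * e^2
      psi <- -(e - cc$lambda) *
        (2 * e^2 + (cc$delta_c + cc$mu) * e - cc$lambda * cc$sigma) /
        (e * (e^2 - (cc$mu + 5 * cc$lambda) * e -
          cc$lambda * (2 * cc$delta_c + cc$mu - 2 * cc$sigma)))
      c(x0, max(psi * (x0 - phi), 0))
    },
    error = function(e) NULL
  )
  seeds <- if (delta / cc$delta_c < seed_switch) list(near, far) else list(far, near)
  purrr::compact(seeds)
}

# Damped Newton on (P, Q); returns c(x, y) or NULL.
newton_pq <- function(s0, delta, constants, cc, max_iter, tol) {
  xy <- s0
  f <- c(
    steady_state_P(xy[1], xy[2], delta, constants),
    steady_state_Q(xy[1], xy[2], delta, constants)
  )
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    J <- pq_jacobian(xy[1], xy[2], delta, cc)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(NULL)
    }
    lam <- 1
    repeat {
      cand <- xy + lam * step
      fc <- c(
        steady_state_P(cand[1], cand[2], delta, constants),
        steady_state_Q(cand[1], cand[2], delta, constants)
      )
      if (max(abs(fc)) < max(abs(f)) || lam < 1e-10) break
      lam <- lam / 2
    }
    if (max(abs(lam * step)) < 1e-14) {
      xy <- cand
      f <- fc
      break
    }
    xy <- cand
    f <- fc
  }
  x <- xy[1]
  y <- xy[2]
  feas <- is.finite(x) && is.finite(y) &&
    x > 0 && y >= -1e-12 && x + y < 1 && 2 * x + y < 1 &&
    max(abs(f)) < 1e-10
  if (!feas) {
    return(NULL)
  }
  c(x, max(y, 0))
}

#' Bifurcation diagram over a delta grid
#'
#' Sweeps the transmission-recovery ratio over a uniform grid (with
#' \eqn{\delta_c} always appended), recording DFE stability, the exact
#' endemic equilibrium (solved by continuation: each solution seeds the
#' next grid point), and both perturbation approximations of prevalence.
#' Solver failures at individual grid points are recorded per point, not
#' fatal.
#'
#' @param constants A [model_constants()] row.
#' @param delta_min,delta_max Grid range, `0 <= delta_min < delta_max`.
#' @param n_points Number of uniform grid points (`>= 2`).
#' @param approx_limits Named list with `eta_max` and `eps_max` domain
#'   guards forwarded to the approximation evaluators; outside those the
#'   approximation columns are `NA`.
#' @return A tibble of class `scpw_bifurcation`: `delta`, `dfe_stable`,
#'   `endemic_exists`, `w_exact`, `x`, `y`, `w_near`, `w_far`,
#'   `resid_P`, `resid_Q`, `endemic_stable`, `at_threshold`,
#'   `nearest_dc`, `solver_error`. The constants are attached as
#'   attribute `"constants"`.
#' @examples
#' cs <- model_constants(network_moments(dist_bimodal()))
#' bd <- bifurcation_diagram(cs, 0, 1, n_points = 21)
#' glance(bd)
#' @export
bifurcation_diagram <- function(constants, delta_min, delta_max,
                                n_points = 101L,
                                approx_limits = list(eta_max = 0.5, eps_max = 0.9)) {
  cc <- constants_row(constants)
  if (delta_min < 0 || delta_min >= delta_max) {
    stop("need 0 <= delta_min < delta_max", call. = FALSE)
  }
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  grid <- seq(delta_min, delta_max, length.out = n_points)
  if (cc$delta_c > delta_min && cc$delta_c < delta_max) {
    grid <- sort(unique(c(grid, cc$delta_c)))
  }

  prev <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    d <- grid[i]
    dfe_stable <- d < cc$delta_c
    eq <- NULL
    err <- NA_character_
    if (d > cc$delta_c) {
      eq <- tryCatch(
        solve_endemic(d, constants, seed_hint = prev),
        error = function(e) NULL
      )
      if (is.null(eq)) err <- "solver failure"
    }
    if (!is.null(eq) && isTRUE(eq$exists)) prev <- c(eq$x, eq$y)

    eta <- 1 - cc$delta_c / d
    eps <- cc$delta_c / d
    w_near <- if (d >= cc$delta_c && eta <= approx_limits$eta_max) {
      near_threshold_equilibrium(d, constants,
        eta_max = approx_limits$eta_max
      )$w_star
    } else {
      NA_real_
    }
    w_far <- if (d > cc$delta_c && eps <= approx_limits$eps_max) {
      far_equilibrium(d, constants, eps_max = approx_limits$eps_max)$w_star
    } else {
      NA_real_
    }

    rows[[i]] <- tibble::tibble(
      delta = d,
      dfe_stable = dfe_stable,
      endemic_exists = !is.null(eq) && isTRUE(eq$exists),
      w_exact = if (!is.null(eq) && isTRUE(eq$exists)) eq$w else NA_real_,
      x = if (!is.null(eq) && isTRUE(eq$exists)) eq$x else NA_real_,
      y = if (!is.null(eq) && isTRUE(eq$exists)) eq$y else NA_real_,
      w_near = w_near,
      w_far = w_far,
      resid_P = if (!is.null(eq)) eq$resid_P else NA_real_,
      resid_Q = if (!is.null(eq)) eq$resid_Q else NA_real_,
      endemic_stable = if (!is.null(eq)) eq$stable else NA,
      solver_error = err
    )
  }
  out <- dplyr::bind_rows(rows)
  out$at_threshold <- out$delta == cc$delta_c
  out$nearest_dc <- seq_len(nrow(out)) ==
    which.min(abs(out$delta - cc$delta_c))
  attr(out, "constants") <- constants
  class(out) <- c("scpw_bifurcation", class(out))
  out
}

#' @export
print.scpw_bifurcation <- function(x, ...) {
  cc <- constants_row(attr(x, "constants"))
  cat(sprintf(
    "# SCPW bifurcation diagram: %d grid points, delta_c = %.6g\n",
    nrow(x), cc$delta_c
  ))
  NextMethod()
}

#' @export
tidy.scpw_bifurcation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary of a bifurcation diagram
#'
#' One-row summary: the threshold, the extent of the endemic branch on
#' the grid, and the worst-case disagreement between the exact branch
#' and each perturbation approximation over its own sub-range (near:
#' `delta <= 1.2 delta_c`; far: `delta >= 2 delta_c`).
#'
#' @param x A [bifurcation_diagram()] result.
#' @param ... Unused.
#' @export
glance.scpw_bifurcation <- function(x, ...) {
  cc <- constants_row(attr(x, "constants"))
  on_branch <- x$endemic_exists
  near_rng <- on_branch & x$delta <= 1.2 * cc$delta_c & !is.na(x$w_near)
  far_rng <- on_branch & x$delta >= 2 * cc$delta_c & !is.na(x$w_far)
  tibble::tibble(
    delta_c = cc$delta_c,
    branch_delta_min = if (any(on_branch)) min(x$delta[on_branch]) else NA_real_,
    branch_delta_max = if (any(on_branch)) max(x$delta[on_branch]) else NA_real_,
    max_abs_err_near = if (any(near_rng)) {
      max(abs(x$w_exact[near_rng] - x$w_near[near_rng]))
    } else {
      NA_real_
    },
    max_abs_err_far = if (any(far_rng)) {
      max(abs(x$w_exact[far_rng] - x$w_far[far_rng]))
    } else {
      NA_real_
    },
    n_solver_failures = sum(!is.na(x$solver_error))
  )
}

#' @export
autoplot.scpw_bifurcation <- function(object, ...) {
  cc <- constants_row(attr(object, "constants"))
  d <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    d[, c("delta", "w_exact", "w_near", "w_far")],
    cols = c("w_exact", "w_near", "w_far"),
    names_to = "branch", values_to = "w"
  )
  dfe <- tibble::tibble(
    delta = d$delta, w = 0,
    stability = ifelse(d$dfe_stable, "stable", "unstable")
  )
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = dfe,
      ggplot2::aes(x = .data$delta, y = .data$w, linetype = .data$stability)
    ) +
    ggplot2::geom_line(
      data = dplyr::filter(long, !is.na(.data$w)),
      ggplot2::aes(x = .data$delta, y = .data$w, colour = .data$branch)
    ) +
    ggplot2::geom_vline(xintercept = cc$delta_c, linetype = "dotted") +
    ggplot2::labs(
      x = expression(delta), y = "equilibrium prevalence w*",
      title = "SCPW bifurcation diagram"
    ) +
    ggplot2::theme_minimal()
}
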