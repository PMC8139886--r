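# Independent oracles kept out of the production path.

# Closure factor in its susceptible-mean-degree (n_S) form: the
# expression the alpha/beta rewriting came from.
q_closure_ns_form <- function(state, m) {
  nS <- (state[["SI"]] + state[["SS"]]) / state[["S"]]
  k1 <- m$k1
  k2 <- m$k2
  k3 <- m$k3
  1 / (nS * state[["S"]]) *
    ((k2 * (k2 - k1 * nS) + k3 * (nS - k1)) / (nS * (k2 - k1^2)) - 1)
}

# Exhaustive root enumeration for the endemic steady-state polynomial
# system: Q is quadratic in y for fixed x, so each y-branch reduces P to
# a 1-D sign scan refined by uniroot. Returns feasible roots only.
enumerate_endemic_roots <- function(delta, constants, nx = 1200) {
  cc <- as.list(constants[1, ])
  e <- cc$delta_c / delta
  ybranch <- function(x, branch) {
    A <- e^2 - e * cc$mu
    B <- 2 * e^2 * x - e * cc$lambda - e * cc$mu * x +
      cc$lambda * cc$sigma * x
    C <- e^2 * x^2
    if (abs(A) < 1e-14) {
      if (abs(B) < 1e-14 || branch == 2) {
        return(NA_real_)
      }
      return(-C / B)
    }
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      return(NA_real_)
    }
    ((-B + c(1, -1)[branch] * sqrt(disc)) / (2 * A))
  }
  xs <- seq(1e-6, 0.999, length.out = nx)
  roots <- list()
  for (branch in 1:2) {
    f <- vapply(xs, function(x) {
      y <- ybranch(x, branch)
      if (is.na(y)) NA_real_ else steady_state_P(x, y, delta, constants)
    }, numeric(1))
    for (i in seq_len(nx - 1)) {
      if (is.na(f[i]) || is.na(f[i + 1]) || f[i] * f[i + 1] >= 0) next
      r <- stats::uniroot(
        function(x) {
          steady_state_P(x, ybranch(x, branch), delta, constants)
        },
        c(xs[i], xs[i + 1]),
        tol = 1e-13
      )$root
      y <- ybranch(r, branch)
      if (r > 1e-9 && y >= -1e-9 && r + y < 1 && 2 * r + y < 1) {
        roots <- c(roots, list(c(x = r, y = y)))
      }
    }
  }
  # de-duplicate roots found on both quadratic branches
  if (length(roots) > 1) {
    keep <- rep(TRUE, length(roots))
    for (i in seq_along(roots)) {
      if (!keep[i]) next
      for (j in seq_along(roots)) {
        if (j > i && keep[j] &&
          max(abs(roots[[i]] - roots[[j]])) < 1e-6) {
          keep[j] <- FALSE
        }
      }
    }
    roots <- roots[keep]
  }
  roots
}
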