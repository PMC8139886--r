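test_that("closure factor matches direct evaluation and its n_S form", {
  cs <- bimodal_cs()
  # direct: alpha*S/(SI+SS)^2 + beta/(SI+SS)
  st <- c(S = 10000, I = 0, SI = 0, SS = 40000, II = 0)
  expect_equal(
    q_closure(st, cs),
    -15 * 10000 / 40000^2 + 7 / 40000
  )
  expect_equal(q_closure(st, cs), 8.125e-5)

  # zero closure constants give zero for any valid state
  null_cs <- cs
  null_cs$alpha <- 0
  null_cs$beta <- 0
  expect_equal(q_closure(st, null_cs), 0)

  # equivalence with the susceptible-mean-degree form on random states
  set.seed(7)
  m <- network_moments(dist_bimodal())
  for (i in 1:100) {
    st <- dimensional_state(random_state5(), N = 10000, k1 = cs$k1)
    expect_equal(q_closure(st, cs), q_closure_ns_form(st, m),
      tolerance = 1e-10
    )
  }

  expect_error(
    q_closure(c(S = 1, SI = 0, SS = 0), cs),
    "singular state"
  )
})

test_that("dimensional rates vanish at the disease-free state and conserve totals", {
  cs <- bimodal_cs()
  N <- 10000
  dfe <- c(S = N, I = 0, SI = 0, SS = cs$k1 * N, II = 0)
  expect_equal(
    unname(rhs_dimensional(dfe, tau = 0.3, gamma = 1, cs)),
    rep(0, 5)
  )
  set.seed(11)
  for (i in 1:100) {
    st <- dimensional_state(random_state5(), N = N, k1 = cs$k1)
    r <- rhs_dimensional(st, tau = stats::runif(1, 0, 2), gamma = 1, cs)
    scale <- max(abs(r), 1)
    expect_lt(abs(r[["S"]] + r[["I"]]) / scale, 1e-9)
    expect_lt(abs(2 * r[["SI"]] + r[["SS"]] + r[["II"]]) / scale, 1e-9)
  }
})

test_that("nondimensional rates vanish at the DFE and respect structural identities", {
  cs <- bimodal_cs()
  dfe <- c(v = 1, w = 0, x = 0, y = 1, z = 0)
  expect_equal(unname(rhs_nondim(dfe, delta = 0.7, cs)), rep(0, 5))

  # every x-coupled closure term carries a factor x: at x = 0, ydot = 0
  # and xdot = z
  st <- c(v = 0.8, w = 0.2, x = 0, y = 0.6, z = 0.4)
  r <- rhs_nondim(st, delta = 1.3, cs)
  expect_equal(r[["y"]], 0)
  expect_equal(r[["x"]], 0.4)

  set.seed(12)
  for (i in 1:1000) {
    st <- random_state5()
    d <- stats::runif(1, 0, 3)
    r <- rhs_nondim(st, d, cs)
    expect_lt(abs(r[["v"]] + r[["w"]]), 1e-12)
    expect_lt(abs(2 * r[["x"]] + r[["y"]] + r[["z"]]) / max(abs(r), 1), 1e-12)
  }
})

test_that("both 3-variable reductions agree with the 5-variable field", {
  for (cs in list(bimodal_cs(), poisson_cs())) {
    set.seed(13)
    for (i in 1:500) {
      st <- random_state5()
      d <- stats::runif(1, 0.05, 3)
      r5 <- rhs_nondim(st, d, cs)
      r_wxz <- rhs_wxz(st[c("w", "x", "z")], d, cs)
      expect_lt(max(abs(r_wxz - r5[c("w", "x", "z")])), 1e-12)
      r_vxy <- rhs_vxy(st[c("v", "x", "y")], d, cs)
      expect_lt(max(abs(r_vxy - r5[c("v", "x", "y")])), 1e-12)
      # prevalence equation reads off directly: wdot = <k> delta x - w
      expect_equal(
        r_wxz[["w"]], cs$k1 * d * st[["x"]] - st[["w"]],
        tolerance = 1e-12
      )
    }
  }
})

test_that("sigma * delta/delta_c equals <k> * delta (reparameterization identity)", {
  cs <- bimodal_cs()
  for (d in c(0.01, 0.31, 1.7, 9)) {
    expect_equal(cs$sigma * d / cs$delta_c, cs$k1 * d, tolerance = 1e-12)
  }
})

test_that("dimensional and nondimensional fields agree under the model scaling", {
  cs <- poisson_cs()
  N <- 5000
  gamma <- 0.37
  set.seed(14)
  for (i in 1:100) {
    st5 <- random_state5()
    d <- stats::runif(1, 0.02, 2)
    dim_state <- dimensional_state(st5, N = N, k1 = cs$k1)
    r_dim <- rhs_dimensional(dim_state, tau = d * gamma, gamma = gamma, cs)
    # T = t * gamma; nodes scale by N, pairs by <k> N
    rescaled <- c(
      v = r_dim[["S"]] / (N * gamma),
      w = r_dim[["I"]] / (N * gamma),
      x = r_dim[["SI"]] / (cs$k1 * N * gamma),
      y = r_dim[["SS"]] / (cs$k1 * N * gamma),
      z = r_dim[["II"]] / (cs$k1 * N * gamma)
    )
    r_nd <- rhs_nondim(st5, d, cs)
    expect_lt(max(abs(rescaled - r_nd)) / max(abs(r_nd), 1), 1e-9)
  }
})

test_that("integration keeps the DFE fixed and kills subthreshold outbreaks", {
  cs <- bimodal_cs()
  dfe <- c(v = 1, w = 0, x = 0, y = 1, z = 0)
  tr <- scpw_simulate(cs, delta = 0.5, init = dfe, t_end = 50)
  expect_lt(max(abs(tr$w)), 1e-12)
  expect_lt(max(abs(1 - tr$y)), 1e-12)

  # delta = 0.1 < delta_c = 4/13: the outbreak dies out
  tr <- scpw_simulate(cs, delta = 0.1, t_end = 500)
  expect_true(attr(tr, "converged"))
  expect_lt(tr$w[nrow(tr)], 1e-6)
})

test_that("the three system forms produce the same trajectory", {
  cs <- poisson_cs()
  d <- 2 * cs$delta_c
  trs <- lapply(c("nondim", "wxz", "vxy"), function(sys) {
    scpw_simulate(cs, d,
      system = sys, t_end = 30, n_out = 61L,
      rtol = 1e-11, atol = 1e-13
    )
  })
  common_T <- min(vapply(trs, function(t) max(t$T), numeric(1)))
  for (col in c("v", "w", "x", "y", "z")) {
    a <- trs[[1]][trs[[1]]$T <= common_T, ][[col]]
    b <- trs[[2]][trs[[2]]$T <= common_T, ][[col]]
    c3 <- trs[[3]][trs[[3]]$T <= common_T, ][[col]]
    n <- min(length(a), length(b), length(c3))
    expect_lt(max(abs(a[1:n] - b[1:n])), 1e-8)
    expect_lt(max(abs(a[1:n] - c3[1:n])), 1e-8)
  }
})

test_that("supra-threshold trajectories converge to the endemic root", {
  cs <- bimodal_cs()
  d <- 2 * cs$delta_c
  tr <- scpw_simulate(cs, d, t_end = 2000)
  eq <- solve_endemic(d, cs)
  final <- tr[nrow(tr), ]
  expect_lt(abs(final$w - eq$w), 1e-6)
  expect_lt(abs(final$x - eq$x), 1e-6)
  expect_lt(abs(final$y - eq$y), 1e-6)
})

test_that("invalid initial conditions and parameters are rejected", {
  cs <- bimodal_cs()
  expect_error(scpw_simulate(cs, -0.1), "nonnegative")
  expect_error(
    scpw_simulate(cs, 0.5, init = c(v = 0.5, w = 0.1, x = 0.2, y = 0.3, z = 0.3)),
    "conservation"
  )
  expect_error(scpw_init(0), "in \\(0,1\\)")
})
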