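test_that("DFE Jacobian block quantities match their closed forms", {
  cs <- bimodal_cs()
  # det B = 2(1 - delta*kbar): at delta = 0.2, kbar = 3.25 -> 0.7, stable
  an <- dfe_analysis(0.2, cs)
  expect_equal(an$det_B, 0.7)
  expect_true(an$stable)
  # threshold exactly: det B = 0
  expect_equal(dfe_analysis(cs$delta_c, cs)$det_B, 0, tolerance = 1e-12)
  # eigenvalue -1 from the upper-left block is always present
  sweep <- dfe_analysis(seq(0.05, 1, by = 0.05), cs)
  expect_true(all(
    abs(sweep$eig1 + 1) < 1e-9 | abs(sweep$eig2 + 1) < 1e-9 |
      abs(sweep$eig3 + 1) < 1e-9
  ))
})

test_that("DFE stability flips exactly at delta_c, eigenvalues always real", {
  set.seed(21)
  for (i in 1:100) {
    m <- random_moments(1)
    cs <- model_constants(m)
    for (d in stats::runif(10, 0, 3 / cs$kbar)) {
      an <- dfe_analysis(d, cs)
      # closed-form discriminant is positive, so eigenvalues are real
      disc <- (d * (cs$kbar - 1) + 1)^2 + 8 * d
      expect_gt(disc, 0)
      expect_equal(an$trace_B^2 - 4 * an$det_B, disc, tolerance = 1e-9)
      # stability boolean agrees with the numerical eigensolver
      J <- attr(dfe_analysis(d, cs), "jacobian")
      lead <- max(Re(eigen(J)$values))
      expect_equal(an$stable, lead < 0)
      expect_equal(an$stable, d < cs$delta_c)
    }
  }
})

test_that("steady-state polynomials behave as derived on the x = 0 slice", {
  cs <- bimodal_cs()
  d <- 2 * cs$delta_c
  e <- cs$delta_c / d
  for (y in c(0.2, 0.5, 0.9)) {
    expect_equal(
      steady_state_P(0, y, d, cs),
      e^2 * (1 - y) * y^2
    )
    # the DFE factor was removed from Q: x = 0 does not solve it
    expect_equal(
      steady_state_Q(0, y, d, cs),
      e * y * (e * y - cs$lambda - cs$mu * y)
    )
  }
  expect_gt(abs(steady_state_Q(0, 1, d, cs)), 0)
})

test_that("no endemic state below threshold; Newton root above it", {
  cs <- bimodal_cs()
  below <- solve_endemic(cs$delta_c / 2, cs)
  expect_false(below$exists)

  eq <- solve_endemic(2 * cs$delta_c, cs)
  expect_true(eq$exists)
  expect_true(eq$stable)
  expect_lt(eq$resid_P, 1e-10)
  expect_lt(eq$resid_Q, 1e-10)
  # w*/x* relation and v = 1 - w
  expect_equal(eq$w, cs$sigma * (2 * cs$delta_c / cs$delta_c) * eq$x,
    tolerance = 1e-10
  )
  expect_equal(eq$v, 1 - eq$w, tolerance = 1e-12)
  expect_error(solve_endemic(-1, cs), "positive")
})

test_that("the exact root approaches the near-threshold prediction", {
  for (cs in list(bimodal_cs(), poisson_cs())) {
    d <- cs$delta_c / (1 - 1e-3) # eta = 1e-3
    eq <- solve_endemic(d, cs)
    w_near <- near_threshold_equilibrium(d, cs)$w_star
    expect_lt(abs(eq$w - w_near) / w_near, 0.02)
  }
})

test_that("predicted near-threshold point nearly solves the polynomials", {
  cs <- bimodal_cs()
  eta <- 1e-4
  d <- cs$delta_c / (1 - eta)
  nr <- near_threshold_equilibrium(d, cs)
  x <- nr$x_star
  y <- 1 + nr$y_slope * x # Eq-33-style linearization about (0, 1)
  expect_lt(abs(steady_state_P(x, y, d, cs)), 100 * eta^2)
  expect_lt(abs(steady_state_Q(x, y, d, cs)), 100 * eta^2)
})

test_that("bifurcation diagram: forward branch, monotone prevalence, threshold crossing", {
  cs <- bimodal_cs()
  bd <- bifurcation_diagram(cs, 0, 1, n_points = 41)
  expect_true(all(bd$dfe_stable == (bd$delta < cs$delta_c)))
  expect_true(all(bd$endemic_exists == (bd$delta > cs$delta_c)))
  w <- bd$w_exact[bd$endemic_exists]
  expect_true(all(diff(w) > 0)) # prevalence increases with delta
  expect_true(all(bd$endemic_stable[bd$endemic_exists]))
  expect_true(any(bd$at_threshold)) # delta_c is appended to the grid
  expect_equal(
    bd$w_exact[bd$endemic_exists],
    cs$sigma * (bd$delta[bd$endemic_exists] / cs$delta_c) *
      bd$x[bd$endemic_exists],
    tolerance = 1e-10
  )

  ps <- poisson_cs()
  bp <- bifurcation_diagram(ps, 0, 0.5, n_points = 26)
  expect_true(all(bp$endemic_exists == (bp$delta > 0.1)))

  g <- glance(bd)
  expect_equal(g$delta_c, 4 / 13)
  expect_equal(g$n_solver_failures, 0L)
})

test_that("prevalence saturates far above the threshold", {
  cs <- bimodal_cs()
  eq <- solve_endemic(50 * cs$delta_c, cs)
  expect_gt(eq$w, 0.95)
})

test_that("root enumeration confirms the forward transcritical bifurcation", {
  for (cs in list(bimodal_cs(), poisson_cs())) {
    # below threshold: no feasible endemic root anywhere in the region
    for (ratio in c(0.5, 0.9, 0.99)) {
      expect_length(enumerate_endemic_roots(ratio * cs$delta_c, cs), 0)
    }
    # just above: exactly one, small, agreeing with the Newton solve,
    # shrinking to zero as delta drops to delta_c
    w_prev <- Inf
    for (ratio in c(1.2, 1.1, 1.05, 1.02)) {
      d <- ratio * cs$delta_c
      roots <- enumerate_endemic_roots(d, cs)
      expect_length(roots, 1)
      eq <- solve_endemic(d, cs)
      expect_equal(roots[[1]][["x"]], eq$x, tolerance = 1e-6)
      expect_true(eq$stable)
      expect_lt(eq$w, w_prev)
      w_prev <- eq$w
    }
    expect_lt(w_prev, 0.1) # w* -> 0 as delta -> delta_c+
  }
})
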