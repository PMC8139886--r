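test_that("near-threshold expansion evaluates its closed-form coefficients", {
  cs <- bimodal_cs()
  # slope sigma/(lambda*sigma + mu*delta_c + mu - delta_c) = 26/23
  nr <- near_threshold_equilibrium(cs$delta_c / (1 - 0.1), cs)
  expect_equal(nr$slope, 26 / 23, tolerance = 1e-12)
  expect_equal(nr$w_star, 26 / 23 * 0.1, tolerance = 1e-12)
  expect_equal(nr$w_star, cs$sigma * nr$x_star, tolerance = 1e-12)
  # at the threshold itself the predicted prevalence is zero
  expect_equal(near_threshold_equilibrium(cs$delta_c, cs)$w_star, 0)
})

test_that("near expansion enforces its domain and consistency guards", {
  cs <- bimodal_cs()
  expect_error(
    near_threshold_equilibrium(0.9 * cs$delta_c, cs),
    "delta >= delta_c"
  )
  expect_error(
    near_threshold_equilibrium(cs$delta_c / (1 - 0.7), cs),
    "eta_max"
  )
  bad <- cs
  bad$mu <- bad$mu + 0.5 # breaks lambda + mu = 1
  expect_error(near_threshold_equilibrium(0.5, bad), "lambda \\+ mu")
})

test_that("near-threshold remainder shrinks quadratically in eta", {
  for (cs in list(bimodal_cs(), poisson_cs())) {
    etas <- c(1e-1, 1e-2, 1e-3)
    ratio <- vapply(etas, function(eta) {
      d <- cs$delta_c / (1 - eta)
      w_exact <- solve_endemic(d, cs)$w
      w_near <- near_threshold_equilibrium(d, cs)$w_star
      abs(w_exact - w_near) / eta^2
    }, numeric(1))
    # an O(eta^2) remainder keeps the scaled error bounded as eta -> 0
    expect_true(all(is.finite(ratio)))
    expect_true(all(ratio[-1] < 3 * ratio[-length(ratio)] + 1e-8))
  }
})

test_that("far linearization point solves P on the y = 0 slice", {
  set.seed(31)
  for (i in 1:100) {
    cs <- model_constants(random_moments(1))
    eps <- stats::runif(1, 0.02, 0.9)
    fl <- far_linearization(eps, cs)
    expect_lt(
      abs(steady_state_P(fl$phi, 0, cs$delta_c / eps, cs)),
      1e-10
    )
  }
})

test_that("far linearization series limits match their leading coefficients", {
  cs <- bimodal_cs()
  co <- far_series_coefficients(cs)
  # phi(eps) = eps/sigma + O(eps^2): scaled error stays bounded
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    abs(far_linearization(eps, cs)$phi - eps / cs$sigma) / eps^2
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(max(errs) / min(errs), 3)
  expect_equal(errs[3], abs(co$phi2), tolerance = 1e-2)
  # psi(eps) * eps -> lambda*sigma/(2 delta_c + mu - 2 sigma)
  lim <- vapply(c(1e-3, 1e-5), function(eps) {
    far_linearization(eps, cs)$psi * eps
  }, numeric(1))
  expect_equal(lim[2], co$psi_m1, tolerance = 1e-4)
})

test_that("far expansion evaluates its closed-form coefficients", {
  cs <- bimodal_cs()
  # prevalence slope (delta_c + mu - sigma)/(lambda*sigma) = -13/15
  fe <- far_equilibrium(cs$delta_c / 0.2, cs)
  expect_equal(fe$w_star, 1 - 13 / 15 * 0.2, tolerance = 1e-12)
  expect_equal(far_series_coefficients(cs)$w_slope, -13 / 15,
    tolerance = 1e-12
  )
  # Poisson(10): slope (0.1 + 2 - 1)/(-1) = -1.1
  expect_equal(far_series_coefficients(poisson_cs())$w_slope, -1.1,
    tolerance = 1e-12
  )
  # eps -> 0 limit: w* -> 1
  expect_equal(far_equilibrium(1e6 * cs$delta_c, cs)$w_star, 1,
    tolerance = 1e-5
  )
  expect_error(far_equilibrium(0.5 * cs$delta_c, cs), "delta > delta_c")
  expect_error(far_equilibrium(cs$delta_c / 0.95, cs), "eps_max")
})

test_that("equilibrium pair-fraction series coincides with the phi series", {
  # the two retained orders of x*(eps) are exactly phi's coefficients
  cs <- poisson_cs()
  co <- far_series_coefficients(cs)
  for (eps in c(0.3, 0.1, 0.01)) {
    fe <- far_equilibrium(cs$delta_c / eps, cs)
    expect_equal(fe$x_star, co$phi1 * eps + co$phi2 * eps^2,
      tolerance = 1e-14
    )
    # and phi itself differs from that series only at O(eps^3)
    phi <- far_linearization(eps, cs)$phi
    expect_lt(abs(phi - fe$x_star), 10 * abs(co$phi2) * eps^3 / eps * 10)
  }
})

test_that("far-threshold remainder shrinks quadratically in eps", {
  for (cs in list(bimodal_cs(), poisson_cs())) {
    epss <- c(0.5, 0.05, 0.005)
    ratio <- vapply(epss, function(eps) {
      d <- cs$delta_c / eps
      w_exact <- solve_endemic(d, cs)$w
      w_far <- far_equilibrium(d, cs)$w_star
      abs(w_exact - w_far) / eps^2
    }, numeric(1))
    expect_true(all(is.finite(ratio)))
    expect_true(all(ratio[-1] < 3 * ratio[-length(ratio)] + 1e-8))
  }
})

test_that("implied threshold estimate and its moment-rule classification", {
  # Poisson(10): boundary case <k^2> = <k>^2 + <k>; estimate 0.11 > 0.1
  est <- far_threshold_estimate(poisson_cs())
  expect_equal(est$delta_estimate, 0.11, tolerance = 1e-12)
  expect_equal(est$classification, "overestimate")
  expect_true(est$moment_rule_overestimate)

  # bimodal: <k^2> = 17 < 20; estimate 4/15 < 4/13
  est <- far_threshold_estimate(bimodal_cs())
  expect_equal(est$delta_estimate, 4 / 15, tolerance = 1e-12)
  expect_equal(est$classification, "underestimate")
  expect_false(est$moment_rule_overestimate)

  # a nonnegative prevalence slope admits no w* = 0 crossing
  fake <- bimodal_cs()
  fake$sigma <- fake$delta_c + fake$mu + 1 # makes the slope positive
  expect_error(far_threshold_estimate(fake), "no crossing")
})

test_that("approximation table labels regimes and respects domain guards", {
  cs <- bimodal_cs()
  tab <- approximation_table(
    cs,
    cs$delta_c * c(1.1, 1.5, 3, 10)
  )
  expect_equal(tab$regime, c("near", "near", "far", "far"))
  expect_true(all(!is.na(tab$w_near[1:2])))
  expect_true(all(!is.na(tab$w_far[3:4])))
  # outside the near guard the near column is NA
  expect_true(is.na(tab$w_near[4]))
})
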