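# Reference networks and randomized-case generators shared across tests.

bimodal_cs <- function() model_constants(network_moments(dist_bimodal()))

# Analytic Poisson mean-10 moments (factorial-moment identities).
poisson_cs <- function() model_constants(as_network_moments(10, 110, 1310))

# Random feasible moment triples: k1 in [1.5, 8], k2 strictly above the
# Jensen bound, k3 strictly above the Cauchy-Schwarz bound.
random_moments <- function(n) {
  k1 <- stats::runif(n, 1.5, 8)
  k2 <- k1^2 * (1 + stats::runif(n, 0.05, 1))
  k3 <- k2^2 / k1 * (1 + stats::runif(n, 0.05, 1))
  tibble::tibble(k1 = k1, k2 = k2, k3 = k3)
}

# Random interior nondimensional state: v + w = 1, 2x + y + z = 1.
random_state5 <- function() {
  w <- stats::runif(1, 0.05, 0.9)
  abc <- stats::rexp(3) + 0.05
  s <- 2 * abc[1] + abc[2] + abc[3]
  c(
    v = 1 - w, w = w,
    x = abc[1] / s, y = abc[2] / s, z = abc[3] / s
  )
}

# Matching dimensional state for node count N and mean degree k1.
dimensional_state <- function(state5, N, k1) {
  c(
    S = state5[["v"]] * N, I = state5[["w"]] * N,
    SI = state5[["x"]] * k1 * N, SS = state5[["y"]] * k1 * N,
    II = state5[["z"]] * k1 * N
  )
}
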