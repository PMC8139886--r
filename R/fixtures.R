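#' Reference degree-sequence generators
#'
#' Generators for the two example networks used throughout the toolkit's
#' documentation and tests.
#'
#' `bimodal_sequence()` is deterministic: exact counts of the two
#' degrees (errors if `frac * size` is not a whole number). The default
#' 10,000-node half-3 / half-5 network has moments exactly (4, 17, 76).
#'
#' `poisson_sequence()` draws `size` Poisson degrees with a mandatory
#' seed (no silent global randomness; the caller's random state is left
#' untouched). If the degree sum comes out odd — such a sequence cannot
#' be realized as a graph — the whole sample is redrawn.
#'
#' @param size Number of nodes.
#' @param k_lo,k_hi,frac Bimodal parameters: the two degrees and the
#'   fraction of nodes at `k_lo`.
#' @param mean Poisson mean degree.
#' @param seed Integer seed (required for the Poisson generator).
#' @return Integer degree sequence of length `size`.
#' @examples
#' network_moments(bimodal_sequence(10000)) # exactly 4, 17, 76
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
bimodal_sequence <- function(size = 10000L, k_lo = 3L, k_hi = 5L,
                             frac = 0.5) {
  if (size <= 0 || abs(size - round(size)) > 0) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  if (k_lo <= 0 || k_hi <= 0 || k_lo >= k_hi) {
    stop("need positive degrees with k_lo < k_hi", call. = FALSE)
  }
  n_lo <- frac * size
  if (abs(n_lo - round(n_lo)) > 1e-9) {
    stop("`frac * size` must be a whole number of nodes", call. = FALSE)
  }
  n_lo <- as.integer(round(n_lo))
  if (n_lo < 1L || n_lo > size - 1L) {
    stop("both degree classes must be nonempty", call. = FALSE)
  }
  c(rep(as.integer(k_lo), n_lo), rep(as.integer(k_hi), size - n_lo))
}

#' @rdname fixtures
#' @export
poisson_sequence <- function(size = 10000L, mean = 10, seed) {
  if (missing(seed)) {
    stop("`seed` is required: stochastic fixtures must be reproducible",
      call. = FALSE
    )
  }
  if (size <= 0 || abs(size - round(size)) > 0) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    for (try in 1:1000) {
      degs <- stats::rpois(size, lambda = mean)
      if (sum(degs) %% 2L == 0L) {
        return(as.integer(degs))
      }
    }
    stop("failed to draw an even-sum degree sequence", call. = FALSE)
  })
}
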