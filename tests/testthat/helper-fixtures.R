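# small fixtures shared across test files; everything is built in code

# two-phase toy count table with named types
toy_counts <- function() {
  m <- rbind(c(30, 20, 0, 0),
             c(10, 25, 10, 5))
  dimnames(m) <- list(c("phase1", "phase2"), c("A", "B", "C", "D"))
  m
}

# a small scenario that fits in well under a second per simulation
tiny_scenario <- function(b = 0, seed = 1, mu = 0.02, ...) {
  synthetic_scenario(n = c(40, 60, 80, 60), H = c(4, 6, 8, 6), b = b,
                     mu = mu, w_years = 2, rho = 1, r = 2,
                     burn_in = 500, seed = seed, ...)
}

# random pool counts for property-style loops
random_pool_counts <- function(k = NULL) {
  if (is.null(k)) k <- sample(1:8, 1)
  stats::setNames(sample(1:20, k, replace = TRUE), paste0("t", seq_len(k)))
}
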