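# internal helpers

# round-half-up; base round() is half-to-even, which would make population
# sizes N_i = round(n_i * r) depend on parity
round_half_up <- function(x) floor(x + 0.5)

# a fresh 31-bit seed drawn from R's RNG stream, so that functions with
# `seed = NULL` are still reproducible under set.seed()
new_seed <- function() sample.int(2147483647L, 1L)

#' Integerize a production schedule under an exact sum constraint
#'
#' Scales a vector of positive target values to sum to `total` and rounds it
#' to integers by the largest-remainder method, keeping every entry at least
#' 1 (every production event produces at least one item). Ties in the
#' remainders are broken by position.
#'
#' @param x numeric vector of positive target values (one per event).
#' @param total integer; the required sum (the phase population size `N_i`).
#' @return integer vector of `length(x)` summing exactly to `total`.
#' @examples
#' largest_remainder(rep(1, 4), 10)  # (3, 3, 2, 2)
#' @export
largest_remainder <- function(x, total) {
  k <- length(x)
  total <- as.integer(total)
  if (k == 0) stop("empty schedule")
  if (any(x <= 0)) stop("schedule targets must be positive")
  if (total < k)
    stop("infeasible schedule: N_i = ", total, " is smaller than eta_i = ", k)
  x <- x / sum(x) * total
  v <- floor(x)
  rem <- x - v
  need <- total - sum(v)
  if (need > 0) {
    idx <- order(-rem, seq_along(rem))[seq_len(need)]
    v[idx] <- v[idx] + 1
  }
  while (any(v == 0)) {
    for (i in which(v == 0)) {
      j <- which.max(v)
      if (v[j] <= 1) stop("infeasible schedule")
      v[j] <- v[j] - 1
      v[i] <- 1
    }
  }
  as.integer(v)
}

# near-constant schedule: eta events of size v with the remainder absorbed in
# the final event; falls back to largest-remainder if that would leave the
# final event empty
constant_schedule <- function(N, eta, v) {
  vs <- rep(as.integer(v), eta)
  vs[eta] <- vs[eta] + as.integer(N) - sum(vs)
  if (vs[eta] < 1L) vs <- largest_remainder(rep(v, eta), N)
  vs
}

# build a phases x types count matrix from the engine's sparse per-phase
# (id, count) lists; `labels` maps 0-based type ids to column names
counts_from_sparse <- function(sparse, labels, phase_names) {
  ids <- sort(unique(unlist(lapply(sparse, function(s) s$id))))
  mat <- matrix(0L, nrow = length(sparse), ncol = length(ids),
                dimnames = list(phase_names, labels[ids + 1L]))
  for (p in seq_along(sparse)) {
    s <- sparse[[p]]
    mat[p, match(s$id, ids)] <- s$count
  }
  mat
}
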