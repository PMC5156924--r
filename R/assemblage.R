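#' Per-phase bookkeeping
#'
#' Derives the quantities describing one archaeological phase: the deposited
#' population size `N = round(n * r)` (round-half-up; the observed sample of
#' size `n` is a fraction `1/r` of the population), the number of production
#' events `eta`, and the per-event production sizes `v_sched` which sum
#' exactly to `N`.
#'
#' Exactly one of `v`, `eta` or `v_sched` must be given: with constant `v`,
#' `eta = round(N / v)` and the remainder is absorbed in the final event;
#' with `eta`, an even schedule is built by largest-remainder rounding; a
#' full `v_sched` is validated against `N`.
#'
#' @param n positive integer observed sample size.
#' @param r recovery factor `>= 1` (the sample is a fraction `1/r` of the
#'   population).
#' @param v constant per-event production size.
#' @param eta number of production events in the phase.
#' @param v_sched integer vector of per-event production sizes.
#' @return an object of class `"phase_spec"`: list with `n`, `r`, `N`,
#'   `eta`, `v_sched`.
#' @export
phase_spec <- function(n, r = 1, v = NULL, eta = NULL, v_sched = NULL) {
  if (n < 0) stop("`n` must be non-negative")
  if (r < 1) stop("`r` must be >= 1 so that n <= N")
  N <- as.integer(round_half_up(n * r))
  if (!is.null(v_sched)) {
    v_sched <- as.integer(v_sched)
    if (sum(v_sched) != N)
      stop("inconsistent spec: sum(v_sched) = ", sum(v_sched),
           " but N = ", N)
    if (any(v_sched < 1)) stop("every production event must have v >= 1")
    eta <- length(v_sched)
  } else if (!is.null(v)) {
    if (v < 1) stop("`v` must be >= 1")
    eta <- max(1L, as.integer(round_half_up(N / v)))
    v_sched <- constant_schedule(N, eta, v)
  } else if (!is.null(eta)) {
    v_sched <- largest_remainder(rep(1, eta), N)
  } else {
    stop("provide one of `v`, `eta` or `v_sched`")
  }
  structure(list(n = as.integer(n), r = r, N = N, eta = as.integer(eta),
                 v_sched = v_sched),
            class = "phase_spec")
}

#' Accumulate one phase into a time-averaged population
#'
#' Runs the `eta` production events of a phase, collecting all produced
#' variants (not just the final pool) into the phase population of size
#' `N = sum(v_sched)`. This is the time-averaging step: the archaeological
#' assemblage accumulates the output of every event of the phase.
#'
#' @param pool a seeded [sampling_pool].
#' @param params a [transmission_params] object.
#' @param spec a [phase_spec] object.
#' @return list with `population` (named integer counts, summing to `N`),
#'   `tokens` (the produced items in production order) and `pool` (the pool
#'   after the phase).
#' @export
accumulate_phase <- function(pool, params, spec) {
  stopifnot(inherits(spec, "phase_spec"))
  tokens <- vector("list", spec$eta)
  for (tau in seq_len(spec$eta)) {
    ev <- production_event(pool, params, spec$v_sched[tau])
    pool <- advance_pool(ev$pool, ev$variants, ev$pool$event_index + 1L)
    tokens[[tau]] <- ev$variants
  }
  tokens <- unlist(tokens, use.names = FALSE)
  tab <- table(tokens)
  list(population = stats::setNames(as.integer(tab), names(tab)),
       tokens = tokens, pool = pool)
}

#' Draw the archaeological sample from a phase population
#'
#' Simple random sample without replacement of `n` items from a population
#' of counts; emulates the `1/r` archaeological recovery of the deposited
#' assemblage.
#'
#' @param population named integer vector of population counts (size `N`).
#' @param n sample size; must satisfy `n <= sum(population)`.
#' @return named integer vector over the population's types, summing to `n`.
#' @export
sample_assemblage <- function(population, n) {
  N <- sum(population)
  if (n > N)
    stop("sample size n exceeds population size N; ",
         "the recovery rate prior must keep r >= 1")
  out <- stats::setNames(integer(length(population)), names(population))
  if (n == 0) return(out)
  tokens <- rep(names(population), population)
  s <- sample(tokens, n)
  tab <- table(factor(s, levels = names(population)))
  stats::setNames(as.integer(tab), names(population))
}

#' Per-event production schedule from house counts
#'
#' Builds the time-dependent production sizes v(t) for the variable
#' population regimes. Production intensity is taken proportional to
#' `rho * H_i` (potters per household times houses in phase i): the number
#' of events per phase is `eta_i = round(N_i / (rho * H_i))`, so each event
#' produces on average one item per social learner, and the within-phase
#' sizes interpolate `rho * H` piecewise-linearly between phase midpoints,
#' integerized by largest remainder so that the within-phase sum is exactly
#' `N_i = round(n_i * r)`.
#'
#' @param H positive numeric vector of per-phase house counts.
#' @param rho potters per household (positive real).
#' @param n integer vector of observed per-phase sample sizes.
#' @param r recovery factor `>= 1`.
#' @return list with `N` (integer population sizes), `eta` (integer event
#'   counts) and `v` (list of integer per-event schedules, one per phase).
#' @examples
#' production_schedule(H = c(4, 8), rho = 1, n = c(40, 80), r = 1)
#' @export
production_schedule <- function(H, rho, n, r = 1) {
  P <- length(n)
  if (length(H) != P) stop("`H` must have one entry per phase")
  if (any(H <= 0)) stop("house counts must be strictly positive")
  if (rho <= 0) stop("`rho` must be positive")
  if (r < 1) stop("`r` must be >= 1")
  N <- as.integer(round_half_up(n * r))
  y <- rho * H
  eta <- pmax(1L, as.integer(round_half_up(N / y)))
  if (any(N < eta))
    stop("infeasible schedule: N_i < eta_i in phase ",
         paste(which(N < eta), collapse = ", "))
  ends <- cumsum(eta)
  mids <- ends - eta / 2
  v <- vector("list", P)
  for (i in seq_len(P)) {
    tt <- ends[i] - eta[i] + seq_len(eta[i]) - 0.5
    if (P == 1) {
      target <- rep(y, eta[i])
    } else {
      # piecewise-linear in y between phase midpoints, flat beyond the ends
      j <- findInterval(tt, mids, rightmost.closed = FALSE)
      j <- pmin(pmax(j, 1L), P - 1L)
      frac <- (tt - mids[j]) / (mids[j + 1L] - mids[j])
      frac <- pmin(pmax(frac, 0), 1)
      target <- y[j] * (1 - frac) + y[j + 1L] * frac
    }
    v[[i]] <- largest_remainder(target, N[i])
  }
  list(N = N, eta = eta, v = v)
}
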