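# Orchestration of the three generative regimes. All three are thin drivers
# of the compiled event engine; the engine's RNG state is part of the run
# result so that runs can be chained exactly (used by the reduction checks
# and the per-phase version).

.as_run <- function(res, labels, n, N, version, params, seed, retain_pop,
                    phase_names = NULL) {
  P <- length(n)
  if (is.null(phase_names)) phase_names <- paste0("phase", seq_len(P))
  samples <- counts_from_sparse(res$samples, labels, phase_names)
  populations <- if (!is.null(res$populations))
    counts_from_sparse(res$populations, labels, phase_names) else NULL
  structure(
    list(samples = samples, populations = populations, n = n, N = N,
         version = version, params = params, seed = seed,
         labels = labels,
         final_pool = list(events = res$final_events,
                           loose = res$final_loose,
                           next_id = res$next_id),
         rng_state = res$rng_state),
    class = "transmission_run")
}

#' @export
print.transmission_run <- function(x, ...) {
  cat("simulated assemblage series (", x$version, " version)\n", sep = "")
  cat(" ", nrow(x$samples), "phases,", ncol(x$samples),
      "variant types in the samples\n")
  cat("  sample sizes:", paste(rowSums(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the equilibrium version
#'
#' Constant parameters throughout: the pool is seeded with `v` distinct
#' types, a burn-in of `burn_in` production events (default 5,000) brings the
#' instantaneous variant-frequency distribution to the innovation-drift
#' equilibrium, then each phase accumulates `eta_i = round(N_i / v)` events
#' of `v` items (the final event absorbs the rounding remainder) and a sample
#' of size `n_i` is drawn from the phase population of size `N_i`.
#'
#' @param params a [transmission_params] (with constant `v`).
#' @param n integer vector of per-phase sample sizes.
#' @param r recovery factor `>= 1`; `N_i = round(n_i * r)`.
#' @param burn_in number of burn-in production events.
#' @param seed integer seed for the simulation substream; drawn from R's RNG
#'   if `NULL`.
#' @param retain_pop keep the per-phase populations in the result.
#' @param initial_pool optional list of integer vectors (stamped event
#'   groups of 0-based type ids) overriding the default seed pool.
#' @param rng_state optional 32-byte raw engine state to continue an earlier
#'   run exactly (overrides `seed`).
#' @return a `"transmission_run"`: list with `samples` (phases x types count
#'   matrix), optional `populations`, the final pool and engine RNG state.
#' @export
run_equilibrium <- function(params, n, r = 1, burn_in = 5000, seed = NULL,
                            retain_pop = FALSE, initial_pool = NULL,
                            rng_state = NULL) {
  stopifnot(inherits(params, "transmission_params"))
  n <- as.integer(n)
  P <- length(n)
  v <- params$v
  N <- as.integer(round_half_up(n * r))
  if (any(n > N)) stop("n > N; the recovery rate r must be >= 1")
  eta <- pmax(1L, as.integer(round_half_up(N / v)))
  v_sched <- lapply(seq_len(P), function(i) constant_schedule(N[i], eta[i], v))
  init_events <- if (is.null(initial_pool)) list(seq_len(v) - 1L)
                 else initial_pool
  if (is.null(seed)) seed <- new_seed()
  res <- .engine_run(v, init_events, integer(0), 0L,
                     as.integer(burn_in), v,
                     eta, v_sched, rep(params$mu, P), rep(params$b, P),
                     rep(params$w_events, P), n, retain_pop,
                     integer(0), TRUE, rng_state, seed)
  labels <- paste0("t", seq_len(res$next_id))
  .as_run(res, labels, n, N, "equilibrium", params, seed, retain_pop)
}

#' Reconstruct an initial sampling pool from observed frequencies
#'
#' Draws a plausible population composition from a Dirichlet distribution
#' with concentration equal to the observed counts (optionally plus a
#' smoothing constant), then samples `w_events * v1` pool entries from it,
#' under the constraint that every observed type is present. The constraint
#' is enforced by rejection (regenerating the draw) up to `max_retry` times,
#' after which missing types are force-inserted over random tokens of
#' non-singleton types. The resulting entries carry no event stamp: as the
#' simulation proceeds, `v1` randomly chosen unmarked entries are displaced
#' per production event until every pool entry has a chronological marker.
#'
#' @param observed named vector of observed type counts (zeros are dropped).
#' @param w_events memory window, in production events.
#' @param v1 production size of the first event; the pool holds
#'   `w_events * v1` entries.
#' @param smoothing additive Dirichlet smoothing constant (default 0: the
#'   concentration is the raw observed counts).
#' @param max_retry rejection attempts before forced insertion.
#' @param seed integer seed; drawn from R's RNG if `NULL`.
#' @return a [sampling_pool] whose entries are all unmarked, with
#'   `displace = v1`.
#' @export
dirichlet_initial_pool <- function(observed, w_events, v1, smoothing = 0,
                                   max_retry = 100, seed = NULL) {
  observed <- observed[observed > 0]
  K <- length(observed)
  if (K == 0) stop("observed assemblage is empty")
  pool_n <- as.integer(w_events) * as.integer(v1)
  if (pool_n < K)
    stop("infeasible: pool size w * v1 = ", pool_n,
         " is smaller than the number of observed types (", K, ")")
  if (is.null(seed)) seed <- new_seed()
  dp <- .engine_dirichlet_pool(as.numeric(observed) + smoothing, pool_n,
                               as.integer(max_retry), NULL, seed)
  pool <- sampling_pool(w_events)
  pool$loose <- names(observed)[dp$tokens + 1L]
  pool$displace <- as.integer(v1)
  pool
}

#' Simulate the variable population version
#'
#' The transmission process (`mu`, `b`, `w_events`) is constant but the
#' per-event production size v(t) follows the demographic schedule of
#' [production_schedule()]. There is no burn-in: the initial sampling pool is
#' reconstructed from the observed first-phase frequencies by the Dirichlet
#' procedure of [dirichlet_initial_pool()], and the pool carries over between
#' phases.
#'
#' @inheritParams run_equilibrium
#' @param params a [transmission_params]; its `v` is ignored (the schedule
#'   supplies v(t)).
#' @param observed_first named vector of observed first-phase counts.
#' @param H per-phase house counts.
#' @param rho potters per household.
#' @param smoothing,max_retry passed to the Dirichlet pool construction.
#' @param initial_pool optional list `list(events =, loose =, next_id =)` of
#'   0-based ids overriding the Dirichlet pool (used for exact chaining).
#' @return a `"transmission_run"`; type labels of the observed first-phase
#'   types are preserved, innovations are labelled `nov1`, `nov2`, ...
#' @export
run_variable_population <- function(params, observed_first, H, rho, n, r = 1,
                                    seed = NULL, retain_pop = FALSE,
                                    smoothing = 0, max_retry = 100,
                                    initial_pool = NULL, rng_state = NULL) {
  stopifnot(inherits(params, "transmission_params"))
  n <- as.integer(n)
  P <- length(n)
  observed_first <- observed_first[observed_first > 0]
  K <- length(observed_first)
  if (K == 0) stop("observed first-phase assemblage is empty")
  sched <- production_schedule(H, rho, n, r)
  v1 <- sched$v[[1]][1]
  if (is.null(seed)) seed <- new_seed()
  if (is.null(initial_pool)) {
    pool_n <- params$w_events * v1
    if (pool_n < K)
      stop("infeasible: pool size w * v1 = ", pool_n,
           " is smaller than the number of observed types (", K, ")")
    dp <- .engine_dirichlet_pool(as.numeric(observed_first) + smoothing,
                                 pool_n, as.integer(max_retry),
                                 rng_state, seed)
    init_events <- list()
    init_loose <- dp$tokens
    state <- dp$rng_state
    n_seed <- K
  } else {
    init_events <- initial_pool$events
    init_loose <- initial_pool$loose
    state <- rng_state
    n_seed <- initial_pool$next_id
  }
  res <- .engine_run(n_seed, init_events, init_loose, v1, 0L, 0L,
                     sched$eta, sched$v, rep(params$mu, P),
                     rep(params$b, P), rep(params$w_events, P), n,
                     retain_pop, integer(0), TRUE, state, seed)
  labels <- c(names(observed_first),
              if (res$next_id > K) paste0("nov", seq_len(res$next_id - K)))
  out <- .as_run(res, labels, n, sched$N, "variable_population", params,
                 seed, retain_pop)
  out$schedule <- sched
  out
}

#' Simulate the variable population-transmission mode version
#'
#' Each phase is simulated separately with its own transmission parameters
#' (`b_i`, `mu_i`, `w_i`): the sampling pool of phase i is re-seeded by the
#' Dirichlet procedure from the observed frequencies at the end of phase
#' i-1, the phase's `eta_i` production events are run under the demographic
#' schedule, and a sample of size `n_i` is drawn. `b` varies between phases
#' but not within a phase. Phase 1 has no predecessor and is therefore not
#' simulated (unless `chain_pools = TRUE`).
#'
#' @inheritParams run_variable_population
#' @param params_by_phase list of [transmission_params], one per phase of
#'   `observed` (entries for unsimulated phases may be `NULL`), or a single
#'   [transmission_params] recycled to all phases.
#' @param observed phases x types count matrix of observed assemblages.
#' @param phases integer vector of phases to simulate (default `2:P`; phase
#'   i requires observed counts for phase i-1).
#' @param chain_pools debug flag: instead of re-seeding each phase from the
#'   observed predecessor, seed phase 1 from the observed first phase and
#'   carry the simulated pool (and engine RNG state) across phases. With
#'   identical parameters in every phase this reproduces
#'   [run_variable_population()] exactly under the same seed.
#' @return a `"transmission_run"` with one sample row per simulated phase
#'   and `params_used`, the per-phase parameter list.
#' @export
run_variable_population_transmission <- function(params_by_phase, observed,
                                                 H, rho, n = NULL, r = 1,
                                                 phases = NULL, seed = NULL,
                                                 retain_pop = FALSE,
                                                 smoothing = 0,
                                                 max_retry = 100,
                                                 chain_pools = FALSE,
                                                 rng_state = NULL) {
  observed <- as.matrix(observed)
  P <- nrow(observed)
  if (is.null(n)) n <- rowSums(observed)
  n <- as.integer(n)
  if (inherits(params_by_phase, "transmission_params"))
    params_by_phase <- rep(list(params_by_phase), P)
  if (length(params_by_phase) != P)
    stop("`params_by_phase` must have one entry per phase")
  if (is.null(phases)) phases <- if (chain_pools) seq_len(P) else 2:P
  if (!chain_pools && any(phases < 2))
    stop("phase 1 has no predecessor: observed end-of-previous-phase ",
         "counts are required to seed the pool")
  sched <- production_schedule(H, rho, n, r)
  if (is.null(seed)) seed <- new_seed()

  types <- colnames(observed)
  if (is.null(types)) types <- paste0("t", seq_len(ncol(observed)))
  state <- rng_state
  carry <- NULL
  sparse_s <- list()
  sparse_p <- list()
  labels <- types
  n_nov <- 0L
  for (i in phases) {
    pp <- params_by_phase[[i]]
    if (is.null(pp)) stop("missing parameters for phase ", i)
    v1 <- sched$v[[i]][1]
    if (chain_pools && !is.null(carry)) {
      init_events <- carry$events
      init_loose <- carry$loose
      n_seed <- carry$next_id
    } else {
      src <- if (chain_pools) i else i - 1L
      obs_prev <- observed[src, ]
      keep <- obs_prev > 0
      if (!any(keep))
        stop("observed predecessor counts for phase ", i, " are empty")
      pool_n <- pp$w_events * v1
      if (pool_n < sum(keep))
        stop("infeasible: pool size w * v1 = ", pool_n, " is smaller than ",
             "the number of observed types in phase ", src)
      ids <- which(keep) - 1L
      alpha <- as.numeric(obs_prev[keep]) + smoothing
      dp <- .engine_dirichlet_pool(alpha, pool_n, as.integer(max_retry),
                                   state, seed)
      init_events <- list()
      init_loose <- ids[dp$tokens + 1L]
      state <- dp$rng_state
      n_seed <- ncol(observed)
    }
    res <- .engine_run(n_seed, init_events, init_loose, v1, 0L, 0L,
                       sched$eta[i], sched$v[i], pp$mu, pp$b, pp$w_events,
                       n[i], retain_pop, integer(0), TRUE, state,
                       seed)
    state <- res$rng_state
    carry <- list(events = res$final_events, loose = res$final_loose,
                  next_id = res$next_id)
    K_all <- ncol(observed)
    ss <- res$samples[[1]]
    ps <- if (retain_pop) res$populations[[1]] else NULL
    if (chain_pools) {
      # ids are globally consistent across the chained calls
      new_n <- res$next_id - K_all
      if (new_n > n_nov) {
        labels <- c(labels, paste0("nov", seq.int(n_nov + 1L, new_n)))
        n_nov <- new_n
      }
    } else {
      # each phase mints its own novel ids starting at K_all; offset them so
      # novel types of different phases stay distinct columns
      new_this <- res$next_id - K_all
      if (new_this > 0) {
        remap <- function(sp) {
          nov <- sp$id >= K_all
          sp$id[nov] <- sp$id[nov] + n_nov
          sp
        }
        ss <- remap(ss)
        if (!is.null(ps)) ps <- remap(ps)
        labels <- c(labels, paste0("p", i, ".nov", seq_len(new_this)))
        n_nov <- n_nov + new_this
      }
    }
    sparse_s[[length(sparse_s) + 1L]] <- ss
    if (retain_pop) sparse_p[[length(sparse_p) + 1L]] <- ps
  }
  phase_names <- paste0("phase", phases)
  samples <- counts_from_sparse(sparse_s, labels, phase_names)
  populations <- if (retain_pop)
    counts_from_sparse(sparse_p, labels, phase_names) else NULL
  structure(
    list(samples = samples, populations = populations, n = n[phases],
         N = sched$N[phases], version = "variable_transmission",
         params = params_by_phase, params_used = params_by_phase[phases],
         phases = phases, seed = seed, labels = labels,
         final_pool = carry, rng_state = state),
    class = "transmission_run")
}
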