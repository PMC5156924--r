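#' Copying probabilities under frequency-dependent transmission
#'
#' Probability that the next produced item copies each variant type currently
#' in the sampling pool. The probability of copying type j is
#' \deqn{\pi_j = (1-\mu)\, \frac{m_j^{\,1-b}}{\sum_{l=1}^{k} m_l^{\,1-b}},}
#' where \eqn{m_j} is the relative frequency of type j among the items of the
#' last w production events, k the number of types present, \eqn{\mu} the
#' innovation rate and b the strength of frequency-dependent bias. For
#' \eqn{b = 0} this reduces to unbiased copying proportional to relative
#' frequency; \eqn{b > 0} disproportionately favours rare types
#' (anti-conformity) and \eqn{b < 0} common types (conformity). With
#' probability \eqn{\mu} a novel, never seen type is produced instead.
#'
#' Weights are computed in log space and renormalized after exponentiation,
#' so large \eqn{|b|} does not overflow.
#'
#' @param counts named vector of positive type counts in the sampling pool,
#'   or a [sampling_pool] object.
#' @param b frequency-dependence strength (real; 0 = unbiased).
#' @param mu innovation rate in `[0, 1]`.
#' @return list with `p`, the named copy probabilities (summing to `1 - mu`),
#'   and `innovation`, the innovation mass `mu`.
#' @examples
#' copy_probabilities(c(A = 3, B = 1))             # 0.75 / 0.25
#' copy_probabilities(c(A = 3, B = 1), b = 0.5)    # rare type boosted
#' @export
copy_probabilities <- function(counts, b = 0, mu = 0) {
  if (inherits(counts, "sampling_pool")) counts <- pool_counts(counts)
  if (any(counts < 0)) stop("variant counts must be non-negative integers")
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    stop("sampling pool is empty: seed the pool before transmission")
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  lw <- (1 - b) * log(as.numeric(counts) / sum(counts))
  lw <- lw - max(lw)
  p <- exp(lw)
  p <- p / sum(p) * (1 - mu)
  names(p) <- names(counts)
  list(p = p, innovation = mu)
}

#' Transmission parameters
#'
#' Bundle of the parameters governing one simulated transmission regime:
#' innovation rate `mu`, frequency-dependence strength `b`, memory window
#' `w_events` (number of production events whose output forms the sampling
#' pool) and `v`, the number of items produced per event.
#'
#' @param mu innovation rate in `[0, 1]`.
#' @param b frequency-dependence strength; negative = conformity, positive =
#'   anti-conformity.
#' @param w_events positive integer window length, in production events.
#' @param v positive integer items per production event (constant-`v`
#'   regimes only; time-varying schedules are built with
#'   [production_schedule()]).
#' @return an object of class `"transmission_params"`.
#' @export
transmission_params <- function(mu, b = 0, w_events = 1, v = 1) {
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  if (w_events < 1) stop("`w_events` must be >= 1")
  if (v < 1) stop("`v` must be >= 1")
  structure(list(mu = mu, b = b, w_events = as.integer(w_events),
                 v = as.integer(v)),
            class = "transmission_params")
}

#' @export
print.transmission_params <- function(x, ...) {
  cat("transmission parameters: mu =", x$mu, ", b =", x$b,
      ", w =", x$w_events, "events, v =", x$v, "\n")
  invisible(x)
}

#' Sliding-window sampling pool
#'
#' The multiset of variants produced in the last `window` production events;
#' the social information available to a learner. Entries are grouped by the
#' event that produced them, so that groups older than `window` events can be
#' expired. A pool may additionally hold "loose" entries without an event
#' stamp (used when the initial pool is reconstructed from observed
#' frequencies, see [dirichlet_initial_pool()]); these are displaced a fixed
#' number at a time as stamped events arrive.
#'
#' @param window positive integer; number of production events retained.
#' @param init optional character vector of variant ids seeding the pool as
#'   one stamped event group (e.g. `v` distinct types for an equilibrium run).
#' @return an object of class `"sampling_pool"`.
#' @seealso [advance_pool()], [pool_counts()], [production_event()]
#' @export
sampling_pool <- function(window, init = NULL) {
  if (window < 1) stop("`window` must be >= 1")
  pool <- structure(
    list(window = as.integer(window), events = list(), stamps = integer(0),
         loose = character(0), displace = 0L, event_index = 0L,
         n_novel = 0L),
    class = "sampling_pool")
  if (!is.null(init) && length(init) > 0) {
    pool$events <- list(as.character(init))
    pool$stamps <- 0L
  }
  pool
}

#' @export
print.sampling_pool <- function(x, ...) {
  cat("sampling pool: window", x$window, "events,", pool_size(x), "entries (",
      length(x$loose), "unmarked ),", length(x$events), "event groups\n")
  invisible(x)
}

#' Type counts in a sampling pool
#' @param pool a [sampling_pool] object.
#' @return named integer vector of counts by variant type.
#' @export
pool_counts <- function(pool) {
  tokens <- c(unlist(pool$events, use.names = FALSE), pool$loose)
  if (length(tokens) == 0) return(integer(0))
  tab <- table(tokens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Number of entries in a sampling pool
#' @param pool a [sampling_pool] object.
#' @return integer pool size.
#' @export
pool_size <- function(pool) {
  length(pool$loose) + sum(lengths(pool$events))
}

#' One production event
#'
#' Produces `v_now` items from a sampling pool: each item is independently a
#' novel type with probability `mu` or a copy drawn with the
#' frequency-dependent probabilities of [copy_probabilities()]. Novel types
#' are minted under the infinite-alleles convention: every innovation is a
#' globally new id, never reused. Uses R's RNG, so results are reproducible
#' under [set.seed()].
#'
#' @param pool a seeded [sampling_pool].
#' @param params a [transmission_params] object.
#' @param v_now positive integer; number of items to produce.
#' @return list with `variants` (character vector of the `v_now` produced
#'   type ids) and `pool` (the pool with its innovation counter advanced; pass
#'   it to [advance_pool()] together with `variants`).
#' @export
production_event <- function(pool, params, v_now) {
  if (v_now < 1) stop("`v_now` must be >= 1")
  mu <- params$mu
  innov <- stats::runif(v_now) < mu
  out <- character(v_now)
  if (any(innov)) {
    out[innov] <- paste0("nov", pool$n_novel + seq_len(sum(innov)))
    pool$n_novel <- pool$n_novel + sum(innov)
  }
  if (any(!innov)) {
    cp <- copy_probabilities(pool_counts(pool), b = params$b, mu = 0)
    out[!innov] <- sample(names(cp$p), sum(!innov), replace = TRUE,
                          prob = cp$p)
  }
  list(variants = out, pool = pool)
}

#' Advance a sampling pool by one event
#'
#' Appends the output of a production event with stamp `event_index` and
#' removes entries older than the window. During the first `window` events of
#' a run the pool simply grows. If the pool holds unmarked (loose) entries,
#' `pool$displace` of them, randomly chosen, are deleted per event until all
#' are associated with a chronological marker.
#'
#' @param pool a [sampling_pool].
#' @param new_variants character vector of produced variant ids.
#' @param event_index integer event stamp; must be strictly increasing across
#'   calls.
#' @return the updated pool.
#' @export
advance_pool <- function(pool, new_variants, event_index) {
  event_index <- as.integer(event_index)
  if (event_index <= pool$event_index)
    stop("`event_index` must be strictly increasing")
  pool$events <- c(pool$events, list(as.character(new_variants)))
  pool$stamps <- c(pool$stamps, event_index)
  keep <- pool$stamps > event_index - pool$window
  pool$events <- pool$events[keep]
  pool$stamps <- pool$stamps[keep]
  if (length(pool$loose) > 0 && pool$displace > 0) {
    nd <- min(pool$displace, length(pool$loose))
    pool$loose <- pool$loose[-sample.int(length(pool$loose), nd)]
  }
  pool$event_index <- event_index
  pool
}
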