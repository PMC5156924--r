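# ABC rejection inference for the three model versions.
#
# The per-draw simulation paths used here are lean wrappers around the
# compiled engine: they return only the cells entering the error level
# (tracked type counts, or rank-matched relative-frequency series), so the
# rejection loop stays cheap. Each draw runs in its own RNG substream, which
# makes the loop invariant to execution order and allows parallel chunks to
# reproduce the serial result exactly.

# A runner encapsulates one model version applied to one observed table:
#   $sim(par, seed) -> list(cells = numeric, extra_sq = scalar)
#   $obs            -> observed cells on the same scale
#   $meta           -> data.frame(phase, type) describing the cells
# epsilon = sqrt(sum((obs - cells)^2) + extra_sq)
.make_runner <- function(version, observed, houses, priors, burn_in,
                         smoothing, max_retry, phase = NULL) {
  observed <- as.matrix(observed)
  n <- as.integer(rowSums(observed))
  P <- nrow(observed)
  types <- colnames(observed)
  pd <- priors$phase_duration

  if (version == "equilibrium") {
    O <- .rel_freq(observed)
    j1 <- which(O[1, ] > 0)
    j1 <- j1[order(-O[1, j1], j1)]
    k1 <- length(j1)
    if (k1 == 0) stop("observed first phase is empty")
    obs_cells <- O[, j1, drop = FALSE]
    meanH <- mean(houses)
    sim <- function(par, seed) {
      v <- max(1L, as.integer(round_half_up(par[["rho"]] * meanH)))
      N <- as.integer(round_half_up(n * par[["r"]]))
      eta <- pmax(1L, as.integer(round_half_up(N / v)))
      w <- w_events_from_years(par[["w_years"]], eta[1], pd)
      v_sched <- lapply(seq_len(P), function(i)
        constant_schedule(N[i], eta[i], v))
      res <- .engine_run(v, list(seq_len(v) - 1L), integer(0), 0L,
                         as.integer(burn_in), v, eta, v_sched,
                         rep(par[["mu"]], P), rep(par[["b"]], P),
                         rep(w, P), n, FALSE, integer(0), TRUE, NULL, seed)
      s1 <- res$samples[[1]]
      ord <- order(-s1$count, s1$id)
      sel <- s1$id[ord][seq_len(min(length(ord), k1))]
      cells <- matrix(0, P, k1)
      if (length(sel) > 0) {
        for (p in seq_len(P)) {
          sp <- res$samples[[p]]
          idx <- match(sel, sp$id)
          cnt <- ifelse(is.na(idx), 0L, sp$count[idx])
          cells[p, seq_along(sel)] <- cnt / n[p]
        }
      }
      list(cells = cells, extra_sq = 0)
    }
    meta <- data.frame(
      phase = rep(rownames(observed) %||% paste0("phase", seq_len(P)), k1),
      type = rep(types[j1], each = P))
    return(list(sim = sim, obs = obs_cells, meta = meta, scale = "relative"))
  }

  # the schedule depends only on (rho, r); with fixed demography it is
  # identical across draws, so memoize the last one
  sched_cache <- NULL
  get_sched <- function(rho, r) {
    sc <- sched_cache
    if (!is.null(sc) && sc$rho == rho && sc$r == r) return(sc$sched)
    sched <- production_schedule(houses, rho, n, r)
    sched_cache <<- list(rho = rho, r = r, sched = sched)
    sched
  }

  if (version == "variable_population") {
    j1 <- which(observed[1, ] > 0)
    K1 <- length(j1)
    if (K1 == 0) stop("observed first phase is empty")
    obs_cells <- t(observed[, j1, drop = FALSE])       # K1 x P, counts
    alpha1 <- as.numeric(observed[1, j1])
    sim <- function(par, seed) {
      sched <- get_sched(par[["rho"]], par[["r"]])
      w <- w_events_from_years(par[["w_years"]], sched$eta[1], pd)
      v1 <- sched$v[[1]][1]
      pool_n <- w * v1
      if (pool_n < K1)
        stop("pool size w * v1 smaller than observed first-phase richness")
      dp <- .engine_dirichlet_pool(alpha1 + smoothing, pool_n,
                                   as.integer(max_retry), NULL, seed)
      res <- .engine_run(K1, list(), dp$tokens, v1, 0L, 0L,
                         sched$eta, sched$v, rep(par[["mu"]], P),
                         rep(par[["b"]], P), rep(w, P), n, FALSE,
                         seq_len(K1) - 1L, FALSE, dp$rng_state, 0)
      list(cells = res$tracked, extra_sq = 0)
    }
    meta <- data.frame(
      phase = rep(rownames(observed) %||% paste0("phase", seq_len(P)),
                  each = K1),
      type = rep(types[j1], P))
    return(list(sim = sim, obs = obs_cells, meta = meta, scale = "absolute"))
  }

  # variable_transmission: one runner per target phase
  if (is.null(phase) || phase < 2 || phase > P)
    stop("the variable transmission runner needs a target phase in 2..P")
  K <- ncol(observed)
  jprev <- which(observed[phase - 1, ] > 0)
  if (length(jprev) == 0)
    stop("observed predecessor counts for phase ", phase, " are empty")
  alpha_prev <- as.numeric(observed[phase - 1, jprev])
  # The comparison cells are the types present in the observed predecessor
  # phase: only these exist in the re-seeded pool's label space, so only
  # they can be matched one-to-one. Observed types absent from the
  # predecessor contribute a constant term to epsilon (simulated 0 against
  # the observed count), and simulated innovations enter as unobserved
  # types; both are folded into extra_sq, so epsilon equals the fully
  # matched euclidean distance over the union of types.
  obs_cells <- observed[phase, jprev]
  const_sq <- sum(as.numeric(observed[phase, -jprev])^2)
  i <- phase
  sim <- function(par, seed) {
    sched <- get_sched(par[["rho"]], par[["r"]])
    w <- w_events_from_years(par[["w_years"]], sched$eta[1], pd)
    v1 <- sched$v[[i]][1]
    pool_n <- w * v1
    if (pool_n < length(jprev))
      stop("pool size w * v1 smaller than predecessor-phase richness")
    dp <- .engine_dirichlet_pool(alpha_prev + smoothing, pool_n,
                                 as.integer(max_retry), NULL, seed)
    tokens <- (jprev - 1L)[dp$tokens + 1L]
    res <- .engine_run(K, list(), tokens, v1, 0L, 0L,
                       sched$eta[i], sched$v[i], par[["mu"]], par[["b"]],
                       w, n[i], FALSE, jprev - 1L, TRUE,
                       dp$rng_state, 0)
    sp <- res$samples[[1]]
    new_t <- !(sp$id %in% (jprev - 1L))
    list(cells = res$tracked[, 1],
         extra_sq = const_sq + sum(as.numeric(sp$count[new_t])^2))
  }
  meta <- data.frame(
    phase = rep((rownames(observed) %||% paste0("phase", seq_len(P)))[i],
                length(jprev)),
    type = types[jprev])
  list(sim = sim, obs = obs_cells, meta = meta, scale = "absolute")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.eps_from_sim <- function(runner, par, seed) {
  out <- tryCatch(runner$sim(par, seed), error = function(e) NULL)
  if (is.null(out)) return(Inf)
  sqrt(sum((runner$obs - out$cells)^2) + out$extra_sq)
}

# indices of the m smallest values, ties broken by position (stable)
retain_smallest <- function(eps, m) {
  if (m < 1 || m > length(eps)) stop("invalid retention count")
  order(eps)[seq_len(m)]
}

.run_eps <- function(runner, draws, seeds, cores) {
  s <- nrow(draws)
  par_mat <- as.matrix(draws)
  one <- function(i) .eps_from_sim(runner, par_mat[i, ], seeds[i])
  if (cores > 1 && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(s), cut(seq_len(s), cores, labels = FALSE))
    res <- parallel::mclapply(chunks, function(ix)
      vapply(ix, one, numeric(1)), mc.cores = cores)
    unsplit(res, cut(seq_len(s), cores, labels = FALSE))
  } else {
    vapply(seq_len(s), one, numeric(1))
  }
}

#' Fit a cultural transmission model by ABC rejection
#'
#' Samples `s` parameter vectors from the priors, simulates the chosen model
#' version for each, measures the euclidean error level epsilon between the
#' simulated and observed count tables (rank-matched relative frequencies
#' for the equilibrium version, first-phase-matched counts for the variable
#' population version, fully matched counts for the variable
#' population-transmission mode version), and retains the `round(s * alpha)`
#' draws with the smallest epsilon. The retained draws approximate the joint
#' posterior distribution.
#'
#' Draws for which the model fails (e.g. an infeasible pool size) are
#' assigned `epsilon = Inf` and reported, never silently dropped. Each draw
#' runs in its own RNG substream, so `cores > 1` reproduces the serial
#' result exactly.
#'
#' For the variable population-transmission mode version each phase from 2
#' to P is assessed independently (its pool is seeded from the observed
#' end-of-previous-phase frequencies) with its own `s` draws and retention.
#'
#' @param observed phases x types matrix of observed counts (phases in
#'   temporal order).
#' @param houses numeric vector of per-phase house counts.
#' @param version one of `"equilibrium"`, `"variable_population"`,
#'   `"variable_transmission"`.
#' @param priors a [prior_spec].
#' @param s number of simulations.
#' @param alpha retention proportion in (0, 1); `s * alpha >= 1`.
#' @param seed master seed; all randomness derives from it.
#' @param fixed named list of parameters held at known values instead of
#'   being drawn (any of `mu`, `b`, `w_years`, `rho`, `r`).
#' @param burn_in burn-in events for the equilibrium version.
#' @param phases target phases for the variable transmission version
#'   (default `2:P`).
#' @param smoothing,max_retry Dirichlet pool settings, see
#'   [dirichlet_initial_pool()].
#' @param cores number of worker processes for the rejection loop.
#' @param keep_eps keep the full epsilon vector (all `s` draws) in the
#'   result as `$eps_all` (and, for the variable transmission version, a
#'   per-phase list).
#' @return an object of class `"transmission_fit"` with the retained draws
#'   in `$retained` (columns `mu`, `b`, `w_years`, `rho`, `r`, `eps`, plus
#'   `phase` for the variable transmission version). Methods: `print`,
#'   `summary` (posterior medians and HPD intervals), `coef`, `plot`,
#'   `simulate`, `predict` and `residuals`.
#' @seealso [posterior_predictive()], [hpdi()]
#' @export
fit_transmission <- function(observed, houses,
                             version = c("equilibrium",
                                         "variable_population",
                                         "variable_transmission"),
                             priors = prior_spec(), s = 10000, alpha = 0.01,
                             seed = NULL, fixed = list(), burn_in = 5000,
                             phases = NULL, smoothing = 0, max_retry = 100,
                             cores = 1, keep_eps = FALSE) {
  version <- match.arg(version)
  observed <- as.matrix(observed)
  P <- nrow(observed)
  if (length(houses) != P) stop("`houses` must have one entry per phase")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  m <- as.integer(round(s * alpha))
  if (m < 1) stop("s * alpha must be >= 1")
  bad <- setdiff(names(fixed), c("mu", "b", "w_years", "rho", "r"))
  if (length(bad) > 0) stop("unknown fixed parameter: ", bad[1])

  # the innovation range must be able to mint the types observed to appear
  n_tot <- sum(observed)
  k_new <- if (version == "equilibrium") ncol(observed) else
    sum(colSums(observed[-1, , drop = FALSE] > 0) > 0 & observed[1, ] == 0)
  mu_hi <- if (is.null(fixed$mu)) priors$mu[2] else fixed$mu
  if (version != "equilibrium" && mu_hi * n_tot * priors$r[2] < k_new)
    warning("the innovation-rate range cannot plausibly produce the ",
            k_new, " types absent from the first phase")

  if (is.null(seed)) seed <- new_seed()
  set.seed(seed)
  draws <- draw_priors(priors, s)
  for (nm in names(fixed)) draws[[nm]] <- fixed[[nm]]
  seeds <- sample.int(2147483647L, s, replace = TRUE)

  t0 <- proc.time()[["elapsed"]]
  if (version == "variable_transmission") {
    if (is.null(phases)) phases <- seq.int(2L, P)
    if (any(phases < 2 | phases > P))
      stop("phase 1 has no predecessor; `phases` must lie in 2..P")
    retained <- vector("list", length(phases))
    eps_all <- if (keep_eps) vector("list", length(phases)) else NULL
    n_failed <- 0L
    for (k in seq_along(phases)) {
      runner <- .make_runner(version, observed, houses, priors, burn_in,
                             smoothing, max_retry, phase = phases[k])
      # a distinct substream of draws per phase
      set.seed(seed + phases[k])
      draws_k <- draw_priors(priors, s)
      for (nm in names(fixed)) draws_k[[nm]] <- fixed[[nm]]
      seeds_k <- sample.int(2147483647L, s, replace = TRUE)
      eps <- .run_eps(runner, draws_k, seeds_k, cores)
      if (keep_eps) eps_all[[k]] <- eps
      n_failed <- n_failed + sum(is.infinite(eps))
      keep <- retain_smallest(eps, m)
      retained[[k]] <- cbind(phase = phases[k], draws_k[keep, ],
                             eps = eps[keep])
    }
    retained <- do.call(rbind, retained)
    rownames(retained) <- NULL
  } else {
    runner <- .make_runner(version, observed, houses, priors, burn_in,
                           smoothing, max_retry)
    eps <- .run_eps(runner, draws, seeds, cores)
    eps_all <- if (keep_eps) eps else NULL
    n_failed <- sum(is.infinite(eps))
    keep <- retain_smallest(eps, m)
    retained <- cbind(draws[keep, ], eps = eps[keep])
    rownames(retained) <- NULL
    phases <- NULL
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  structure(
    list(version = version, observed = observed, houses = houses,
         priors = priors, fixed = fixed, s = s, alpha = alpha,
         n_retained = m, retained = retained, phases = phases,
         seed = seed, burn_in = burn_in, smoothing = smoothing,
         max_retry = max_retry, n_failed = n_failed, eps_all = eps_all,
         elapsed = elapsed),
    class = "transmission_fit")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted values containing
#' `ceiling(level * n)` of them; ties between equally short windows are
#' broken towards the leftmost.
#'
#' @param x numeric vector of posterior draws (at least 2).
#' @param level interval mass in (0, 1].
#' @return named numeric `c(lower, upper)`.
#' @examples
#' hpdi(c(1, 2, 3, 4, 100), level = 0.8)  # c(1, 4)
#' @export
hpdi <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) stop("at least 2 draws are required")
  if (n * level < 1) stop("n * level must be >= 1")
  m <- ceiling(level * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior summary: median and HPD interval
#' @param x numeric vector of retained posterior draws.
#' @param level HPD interval mass.
#' @return named numeric `c(median, lower, upper)`.
#' @export
posterior_summary <- function(x, level = 0.95) {
  c(median = stats::median(x), hpdi(x, level))
}

#' @export
print.transmission_fit <- function(x, ...) {
  cat("ABC rejection fit (", x$version, " version)\n", sep = "")
  cat("  s =", format(x$s, big.mark = ","), "simulations, alpha =", x$alpha,
      "->", x$n_retained, "retained draws",
      if (!is.null(x$phases)) paste("per phase (", length(x$phases),
                                    "phases )"), "\n")
  if (x$n_failed > 0)
    cat("  ", x$n_failed, "failed simulations assigned epsilon = Inf\n")
  if (is.null(x$phases)) {
    ps <- posterior_summary(x$retained$b)
    cat(sprintf("  posterior b: median %.3f, 95%% HPDI [%.3f, %.3f]\n",
                ps[1], ps[2], ps[3]))
  } else {
    for (p in x$phases) {
      ps <- posterior_summary(x$retained$b[x$retained$phase == p])
      cat(sprintf("  phase %d posterior b: median %.3f, 95%% HPDI [%.3f, %.3f]\n",
                  p, ps[1], ps[2], ps[3]))
    }
  }
  invisible(x)
}

#' @export
summary.transmission_fit <- function(object, level = 0.95, ...) {
  pars <- c("mu", "b", "w_years", "rho", "r")
  summ <- function(df) {
    out <- t(vapply(pars, function(nm) posterior_summary(df[[nm]], level),
                    numeric(3)))
    data.frame(parameter = pars, median = out[, 1], lower = out[, 2],
               upper = out[, 3], row.names = NULL)
  }
  if (is.null(object$phases)) {
    tab <- summ(object$retained)
  } else {
    tab <- do.call(rbind, lapply(object$phases, function(p) {
      cbind(phase = p, summ(object$retained[object$retained$phase == p, ]))
    }))
  }
  structure(list(version = object$version, level = level, table = tab,
                 eps_range = range(object$retained$eps),
                 n_retained = object$n_retained),
            class = "summary.transmission_fit")
}

#' @export
print.summary.transmission_fit <- function(x, ...) {
  cat("posterior summaries (", x$version, " version, ",
      x$level * 100, "% HPDI)\n", sep = "")
  print(x$table, digits = 4)
  cat(sprintf("retained epsilon range: [%.4g, %.4g]\n",
              x$eps_range[1], x$eps_range[2]))
  invisible(x)
}

#' @export
coef.transmission_fit <- function(object, ...) {
  pars <- c("mu", "b", "w_years", "rho", "r")
  if (is.null(object$phases))
    return(vapply(pars, function(nm) stats::median(object$retained[[nm]]),
                  numeric(1)))
  out <- t(vapply(object$phases, function(p)
    vapply(pars, function(nm)
      stats::median(object$retained[[nm]][object$retained$phase == p]),
      numeric(1)), numeric(length(pars))))
  rownames(out) <- paste0("phase", object$phases)
  out
}

#' @export
plot.transmission_fit <- function(x, parameter = "b", level = 0.95, ...) {
  if (is.null(x$phases)) {
    vals <- x$retained[[parameter]]
    graphics::hist(vals, breaks = 30, freq = FALSE, col = "grey85",
                   main = paste("posterior of", parameter,
                                "(", x$version, ")"),
                   xlab = parameter, ...)
    h <- hpdi(vals, level)
    graphics::abline(v = stats::median(vals), lwd = 2)
    graphics::abline(v = h, lty = 2)
  } else {
    med <- lo <- hi <- numeric(length(x$phases))
    for (k in seq_along(x$phases)) {
      vals <- x$retained[[parameter]][x$retained$phase == x$phases[k]]
      med[k] <- stats::median(vals)
      h <- hpdi(vals, level)
      lo[k] <- h[1]; hi[k] <- h[2]
    }
    graphics::plot(x$phases, med, ylim = range(lo, hi), pch = 19,
                   xlab = "phase", ylab = parameter,
                   main = paste("per-phase posterior of", parameter), ...)
    graphics::segments(x$phases, lo, x$phases, hi)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Simulate assemblage series from the posterior
#'
#' Resamples joint parameter vectors from the retained draws (with
#' replacement, preserving the joint structure) and reruns the fitted model
#' version in full, returning one [run_equilibrium()]-style result per
#' simulation.
#'
#' @param object a [fit_transmission()] result.
#' @param nsim number of posterior simulations.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `"transmission_run"` objects (for the variable
#'   transmission version, each a per-phase run).
#' @export
simulate.transmission_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$observed
  n <- as.integer(rowSums(obs))
  pd <- object$priors$phase_duration
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    if (is.null(object$phases)) {
      par <- object$retained[sample.int(nrow(object$retained), 1), ]
      if (object$version == "equilibrium") {
        v <- max(1L, as.integer(round_half_up(par$rho * mean(object$houses))))
        N1 <- round_half_up(n[1] * par$r)
        eta1 <- max(1, round_half_up(N1 / v))
        w <- w_events_from_years(par$w_years, eta1, pd)
        out[[k]] <- run_equilibrium(
          transmission_params(par$mu, par$b, w, v), n, par$r,
          burn_in = object$burn_in, seed = new_seed())
      } else {
        sched <- production_schedule(object$houses, par$rho, n, par$r)
        w <- w_events_from_years(par$w_years, sched$eta[1], pd)
        out[[k]] <- run_variable_population(
          transmission_params(par$mu, par$b, w), obs[1, ], object$houses,
          par$rho, n, par$r, seed = new_seed(),
          smoothing = object$smoothing, max_retry = object$max_retry)
      }
    } else {
      params <- vector("list", nrow(obs))
      rhos <- rs <- numeric(0)
      for (p in object$phases) {
        par <- object$retained[object$retained$phase == p, ]
        par <- par[sample.int(nrow(par), 1), ]
        sched <- production_schedule(object$houses, par$rho, n, par$r)
        w <- w_events_from_years(par$w_years, sched$eta[1], pd)
        params[[p]] <- transmission_params(par$mu, par$b, w)
        rhos <- c(rhos, par$rho); rs <- c(rs, par$r)
      }
      out[[k]] <- run_variable_population_transmission(
        params, obs, object$houses, stats::median(rhos), n,
        stats::median(rs), phases = object$phases, seed = new_seed(),
        smoothing = object$smoothing, max_retry = object$max_retry)
    }
  }
  out
}
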