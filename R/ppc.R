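#' Posterior predictive check
#'
#' Resamples joint parameter vectors from the retained draws (with
#' replacement, never marginally), reruns the fitted model version for each,
#' and computes the central (equal-tailed) `level` interval of every
#' (phase, type) frequency cell entering the fit's error level. Observed
#' values outside their interval are flagged. Frequencies are compared on
#' the same scale as the distance mode used in fitting: relative frequencies
#' of the rank-matched first-phase types for the equilibrium version,
#' absolute counts of the first-phase types for the variable population
#' version, absolute counts of all observed types (per phase) for the
#' variable transmission version.
#'
#' @param fit a [fit_transmission()] result.
#' @param n_reps number of posterior replications (>= 100 advised; default
#'   1,000).
#' @param level interval mass.
#' @param seed integer seed.
#' @param cores worker processes for the replication loop.
#' @return a data frame of class `"transmission_ppc"` with columns `phase`,
#'   `type`, `low`, `med`, `high`, `observed`, `inside`.
#' @export
posterior_predictive <- function(fit, n_reps = 1000, level = 0.95,
                                 seed = NULL, cores = 1) {
  stopifnot(inherits(fit, "transmission_fit"))
  if (nrow(fit$retained) == 0) stop("empty posterior")
  if (is.null(seed)) seed <- new_seed()
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)

  band_block <- function(runner, ret) {
    set.seed(seed)
    idx <- sample.int(nrow(ret), n_reps, replace = TRUE)
    seeds <- sample.int(2147483647L, n_reps, replace = TRUE)
    par_mat <- as.matrix(ret[, c("mu", "b", "w_years", "rho", "r")])
    one <- function(j) {
      out <- tryCatch(runner$sim(par_mat[idx[j], ], seeds[j]),
                      error = function(e) NULL)
      if (is.null(out)) rep(NA_real_, length(runner$obs))
      else as.numeric(out$cells)
    }
    reps <- if (cores > 1 && .Platform$OS.type == "unix") {
      do.call(cbind, parallel::mclapply(seq_len(n_reps), function(j)
        one(j), mc.cores = cores))
    } else {
      vapply(seq_len(n_reps), one, numeric(length(runner$obs)))
    }
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
    q <- apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE)
    obs <- as.numeric(runner$obs)
    data.frame(runner$meta, low = q[1, ], med = q[2, ], high = q[3, ],
               observed = obs,
               inside = obs >= q[1, ] & obs <= q[3, ])
  }

  if (is.null(fit$phases)) {
    runner <- .make_runner(fit$version, fit$observed, fit$houses,
                           fit$priors, fit$burn_in, fit$smoothing,
                           fit$max_retry)
    bands <- band_block(runner, fit$retained)
  } else {
    bands <- do.call(rbind, lapply(fit$phases, function(p) {
      runner <- .make_runner(fit$version, fit$observed, fit$houses,
                             fit$priors, fit$burn_in, fit$smoothing,
                             fit$max_retry, phase = p)
      band_block(runner, fit$retained[fit$retained$phase == p, ])
    }))
  }
  rownames(bands) <- NULL
  structure(bands, class = c("transmission_ppc", "data.frame"),
            level = level, n_reps = n_reps, version = fit$version)
}

#' @export
print.transmission_ppc <- function(x, ...) {
  cat("posterior predictive check (", attr(x, "version"), " version, ",
      attr(x, "level") * 100, "% bands, ", attr(x, "n_reps"),
      " replications)\n", sep = "")
  cat("  ", sum(!x$inside), "of", nrow(x),
      "(phase, type) cells outside their band\n")
  out <- x[!x$inside, c("phase", "type", "low", "high", "observed")]
  if (nrow(out) > 0) print(out, digits = 3)
  invisible(x)
}

#' @export
plot.transmission_ppc <- function(x, ...) {
  phases <- unique(x$phase)
  np <- length(phases)
  mfrow <- c(ceiling(np / 2), min(np, 2))
  old <- graphics::par(mfrow = mfrow, mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in phases) {
    d <- x[x$phase == p, ]
    i <- seq_len(nrow(d))
    graphics::plot(i, d$observed, ylim = range(d$low, d$high, d$observed),
                   pch = 19, col = ifelse(d$inside, "black", "red"),
                   xaxt = "n", xlab = "", ylab = "frequency",
                   main = paste("phase", p), ...)
    graphics::axis(1, at = i, labels = d$type, las = 2, cex.axis = 0.7)
    graphics::segments(i, d$low, i, d$high, col = "grey50")
  }
  invisible(x)
}

#' Bands via predict
#'
#' Convenience wrapper: `predict(fit)` runs [posterior_predictive()].
#' @param object a [fit_transmission()] result.
#' @param n_reps,level,seed passed on.
#' @param ... unused.
#' @export
predict.transmission_fit <- function(object, n_reps = 1000, level = 0.95,
                                     seed = NULL, ...) {
  posterior_predictive(object, n_reps = n_reps, level = level, seed = seed)
}

#' Posterior predictive residuals
#'
#' Observed minus posterior-predictive median frequency, per (phase, type)
#' cell of the fit's comparison set.
#'
#' @param object a [fit_transmission()] result.
#' @param ppc optionally, a precomputed [posterior_predictive()] table.
#' @param n_reps,seed used to compute the bands when `ppc` is missing.
#' @param ... unused.
#' @export
residuals.transmission_fit <- function(object, ppc = NULL, n_reps = 200,
                                       seed = NULL, ...) {
  if (is.null(ppc)) ppc <- posterior_predictive(object, n_reps, seed = seed)
  data.frame(phase = ppc$phase, type = ppc$type,
             residual = ppc$observed - ppc$med)
}

#' @export
`[.transmission_ppc` <- function(x, ...) {
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}
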