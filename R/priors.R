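#' Prior specification for the ABC inference
#'
#' Uniform prior ranges for the model parameters, with the archaeologically
#' informed defaults: the memory window `w` is drawn in years between 0.2
#' and 5 (pottery life-span), converted to production events assuming
#' phases of `phase_duration` years (default 20, one house generation);
#' `rho` is the number of potters per household; `r >= 1` the recovery
#' factor (the observed sample is a fraction `1/r` of the deposited
#' population); `mu` the innovation rate and `b` the frequency-dependence
#' strength.
#'
#' @param mu,b,w_years,rho,r length-2 numeric ranges `c(lower, upper)`.
#' @param phase_duration phase length in years, used by the year-to-events
#'   conversion of `w`.
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(mu = c(5e-4, 0.05), b = c(-0.5, 0.5),
                       w_years = c(0.2, 5), rho = c(0.5, 5),
                       r = c(1, 50), phase_duration = 20) {
  chk <- function(x, nm) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      stop("`", nm, "` must be a valid range c(lower, upper)")
    x
  }
  mu <- chk(mu, "mu"); b <- chk(b, "b"); w_years <- chk(w_years, "w_years")
  rho <- chk(rho, "rho"); r <- chk(r, "r")
  if (mu[1] < 0 || mu[2] > 1) stop("`mu` range must lie within [0, 1]")
  if (w_years[1] <= 0) stop("`w_years` must be positive")
  if (rho[1] <= 0) stop("`rho` must be positive")
  if (r[1] < 1) stop("`r` must be >= 1 so that n_i <= N_i")
  if (phase_duration <= 0) stop("`phase_duration` must be positive")
  structure(list(mu = mu, b = b, w_years = w_years, rho = rho, r = r,
                 phase_duration = phase_duration),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("uniform priors:\n")
  for (nm in c("mu", "b", "w_years", "rho", "r"))
    cat(sprintf("  %-8s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  cat("  phase duration:", x$phase_duration, "years\n")
  invisible(x)
}

#' Draw parameter vectors from the priors
#'
#' Independent uniform draws of `(mu, b, w_years, rho, r)`. Uses R's RNG.
#'
#' @param priors a [prior_spec].
#' @param n number of draws.
#' @return data frame with one row per draw.
#' @export
draw_priors <- function(priors, n = 1) {
  stopifnot(inherits(priors, "prior_spec"))
  u <- function(rg) stats::runif(n, rg[1], rg[2])
  data.frame(mu = u(priors$mu), b = u(priors$b),
             w_years = u(priors$w_years), rho = u(priors$rho),
             r = u(priors$r))
}

#' Convert a memory window from years to production events
#'
#' `w_events = max(1, round(w_years * eta_ref / phase_duration))`, where
#' `eta_ref` is the number of production events of the reference (first)
#' phase and `phase_duration` its length in years.
#'
#' @param w_years window length in years.
#' @param eta_ref production events in the reference phase.
#' @param phase_duration phase length in years.
#' @return integer number of events (at least 1).
#' @export
w_events_from_years <- function(w_years, eta_ref, phase_duration = 20) {
  pmax(1L, as.integer(round_half_up(w_years * eta_ref / phase_duration)))
}
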