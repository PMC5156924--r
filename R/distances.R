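# Version-specific euclidean error levels between observed and simulated
# phase x type tables. All three return 0 on self-comparison.

.rel_freq <- function(x) {
  tot <- rowSums(x)
  tot[tot == 0] <- 1
  x / tot
}

.check_phases <- function(observed, simulated) {
  if (nrow(observed) != nrow(simulated))
    stop("observed and simulated tables must have the same number of phases")
}

#' Fully matched euclidean error level
#'
#' Distance for the variable population-transmission mode version, where
#' simulated variants carry the observed type names (one-to-one
#' correspondence): the euclidean distance over all (phase, type) cells of
#' the union of the two type sets. Types simulated but unobserved, and vice
#' versa, enter as zeros.
#'
#' @param observed,simulated phases x types matrices with column names;
#'   counts by default.
#' @param scale `"absolute"` (counts, the default) or `"relative"`
#'   (per-phase relative frequencies).
#' @return nonnegative error level `epsilon`.
#' @export
epsilon_fully_matched <- function(observed, simulated,
                                  scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  observed <- as.matrix(observed); simulated <- as.matrix(simulated)
  .check_phases(observed, simulated)
  types <- union(colnames(observed), colnames(simulated))
  P <- nrow(observed)
  pad <- function(x) {
    out <- matrix(0, P, length(types), dimnames = list(NULL, types))
    out[, colnames(x)] <- x
    out
  }
  A <- pad(observed); B <- pad(simulated)
  if (scale == "relative") { A <- .rel_freq(A); B <- .rel_freq(B) }
  sqrt(sum((A - B)^2))
}

#' First-phase matched euclidean error level
#'
#' Distance for the variable population version: variants can be matched by
#' name only for the types present in the observed first phase (the
#' simulation is seeded from them), so the euclidean distance is restricted
#' to those types, across all phases. Differences confined to other types do
#' not contribute.
#'
#' @inheritParams epsilon_fully_matched
#' @export
epsilon_first_phase_matched <- function(observed, simulated,
                                        scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  observed <- as.matrix(observed); simulated <- as.matrix(simulated)
  .check_phases(observed, simulated)
  if (scale == "relative") {
    observed <- .rel_freq(observed); simulated <- .rel_freq(simulated)
  }
  types <- colnames(observed)[observed[1, ] > 0]
  if (length(types) == 0) stop("observed first phase is empty")
  P <- nrow(observed)
  B <- matrix(0, P, length(types), dimnames = list(NULL, types))
  hit <- intersect(types, colnames(simulated))
  B[, hit] <- simulated[, hit]
  sqrt(sum((observed[, types, drop = FALSE] - B)^2))
}

#' Rank-matched euclidean error level
#'
#' Distance for the equilibrium version, where simulated types have no
#' correspondence to observed ones. Observed and simulated types are
#' reordered at the beginning of the first phase by their relative
#' frequency, highest matched with highest (ties broken by the stable input
#' order, i.e. order of first appearance); the matched simulated types are
#' then tracked through the remaining phases and the euclidean distance is
#' computed on relative frequencies over all phases and all observed
#' first-phase ranks. If the simulated first-phase richness exceeds the
#' observed one only the top observed-richness simulated frequencies are
#' kept; if it is smaller, the missing ranks are padded with a constant
#' relative frequency of 0.
#'
#' @param observed,simulated phases x types count matrices.
#' @param scale `"relative"` (the default) or `"absolute"`.
#' @export
epsilon_rank_matched <- function(observed, simulated,
                                 scale = c("relative", "absolute")) {
  scale <- match.arg(scale)
  observed <- as.matrix(observed); simulated <- as.matrix(simulated)
  .check_phases(observed, simulated)
  O <- if (scale == "relative") .rel_freq(observed) else observed
  S <- if (scale == "relative") .rel_freq(simulated) else simulated
  k_obs <- which(O[1, ] > 0)
  if (length(k_obs) == 0) stop("observed first phase is empty")
  k_obs <- k_obs[order(-O[1, k_obs], k_obs)]
  k_sim <- which(S[1, ] > 0)
  k_sim <- k_sim[order(-S[1, k_sim], k_sim)]
  m <- min(length(k_obs), length(k_sim))
  Ot <- O[, k_obs, drop = FALSE]
  St <- matrix(0, nrow(S), length(k_obs))
  if (m > 0) St[, seq_len(m)] <- S[, k_sim[seq_len(m)], drop = FALSE]
  sqrt(sum((Ot - St)^2))
}
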