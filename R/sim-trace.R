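#' Reference conformational-state positions of DNA-bound CTCF
#'
#' Single-molecule DNA-unzipping maps four conformational states of the
#' CTCF-DNA complex to fork positions (bp relative to the motif center):
#' conformation I (all ZFs bound, fork held far out), II (N-terminal ZFs
#' released), III (only C-terminal ZFs bound) and IV (loosely associated).
#'
#' @return list with `means_bp` and `sds_bp`, length-4 numeric vectors in
#'   ascending position order (conformations I-IV).
#' @export
ctcf_state_positions <- function() {
  list(means_bp = c(-27.1, -15.5, -3.0, 20.1),
       sds_bp = c(5.5, 5.7, 5.7, 11.4))
}

#' Sequential rate matrix from occupancies and lifetimes
#'
#' Builds the generator of a birth-death (strictly sequential) continuous
#' time Markov chain with a prescribed stationary distribution and
#' prescribed mean lifetimes for states `1..K-1`.  The lifetime of the last
#' state is implied by flux balance: writing `f_k = pi_k / tau_k` for the
#' turnover of state k and `phi_k` for the net exchange flux across the
#' edge k <-> k+1, stationarity forces `phi_k = f_k - phi_{k-1}`, and all
#' edge fluxes must come out positive for the requested combination to be
#' realizable.
#'
#' @param occupancy stationary probabilities (length K, sums to 1).
#' @param lifetimes_s mean lifetimes (s) of states `1..K-1`.
#' @return K x K rate matrix (1/s) with zero nonadjacent entries and
#'   rows summing to 0; the implied lifetime of state K is attached as
#'   attribute `lifetime_K_s`.
#' @export
ensemble_rate_matrix <- function(occupancy, lifetimes_s) {
  K <- length(occupancy)
  stopifnot(K >= 2, length(lifetimes_s) == K - 1,
            abs(sum(occupancy) - 1) < 1e-9, all(occupancy > 0),
            all(lifetimes_s > 0))
  f <- occupancy[seq_len(K - 1)] / lifetimes_s
  phi <- numeric(K - 1)
  phi[1] <- f[1]
  for (k in seq_len(K - 1)[-1]) phi[k] <- f[k] - phi[k - 1]
  if (any(phi <= 0))
    stop("requested occupancies/lifetimes are not realizable by a ",
         "sequential chain (non-positive edge flux)")
  Q <- matrix(0, K, K)
  for (k in seq_len(K - 1)) {
    Q[k, k + 1] <- phi[k] / occupancy[k]        # up rate
    Q[k + 1, k] <- phi[k] / occupancy[k + 1]    # down rate
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "lifetime_K_s") <- occupancy[K] / phi[K - 1]
  Q
}

#' Stationary distribution of a sequential rate matrix
#'
#' @param Q rate matrix with rows summing to zero.
#' @return stationary probability vector.
#' @export
ctmc_stationary <- function(Q) {
  K <- nrow(Q)
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- stats::lm.fit(A, b)$coefficients
  pi / sum(pi)
}

#' Calibrated four-state ensemble conditions
#'
#' Preset parameter sets for the four-state conformational ensemble of
#' DNA-bound CTCF under different chromatin contexts, built from the
#' published occupancies and conformation II lifetimes: the endogenous
#' insulator with WT CTCF (conformation II 76% occupancy, 5.8 ms
#' lifetime), the consensus motif (82%, 9.6 ms), the CpG-methylated
#' insulator (II 52%, III 47%), and the insulator in the presence of PDS5A
#' (II 83%).  Occupancies and lifetimes of the sparse states I and IV are
#' not published per condition; realistic millisecond values compatible
#' with sequential-flux balance were fixed once (see the package vignette).
#'
#' @return named list of conditions; each holds `occupancy`,
#'   `lifetimes_s` (states 1..3; state 4 implied), `rate_matrix`,
#'   `means_bp` and `sds_bp`.
#' @export
ctcf_conditions <- function() {
  pos <- ctcf_state_positions()
  build <- function(occ, tau) {
    Q <- ensemble_rate_matrix(occ, tau)
    list(occupancy = occ, lifetimes_s = tau, rate_matrix = Q,
         means_bp = pos$means_bp, sds_bp = pos$sds_bp)
  }
  list(
    insulator_wt = build(c(0.08, 0.76, 0.13, 0.03), c(0.0010, 0.0058, 0.0020)),
    consensus = build(c(0.03, 0.82, 0.11, 0.04), c(0.0015, 0.0096, 0.0014)),
    methylated = build(c(0.012, 0.515, 0.465, 0.008),
                       c(0.0010, 0.0058, 0.0058)),
    insulator_pds5a = build(c(0.05, 0.83, 0.09, 0.03),
                            c(0.0010, 0.0058, 0.0008))
  )
}

#' Configuration for the synthetic unzipping-fork trace generator
#'
#' @param state_means_bp per-state emission means (bp relative to motif
#'   center), strictly increasing.
#' @param state_sds_bp per-state emission standard deviations (bp).
#' @param rate_matrix K x K transition rate matrix (1/s); must be strictly
#'   sequential (nonzero off-diagonals only for adjacent states).
#' @param sample_rate_hz sampling frequency.
#' @param duration_s trace length in seconds.
#' @param unbound_pad_s length of unbound (no CTCF) fork fluctuation
#'   appended on each side of the bound segment; 0 for a fully bound trace.
#' @param unbound_sd_bp white-noise SD of the unbound fork position.
#' @param seed RNG seed.
#' @return object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(state_means_bp, state_sds_bp, rate_matrix,
                             sample_rate_hz = 5000, duration_s = 60,
                             unbound_pad_s = 0, unbound_sd_bp = 30,
                             seed = 1L) {
  K <- length(state_means_bp)
  stopifnot(length(state_sds_bp) == K, all(state_sds_bp > 0),
            nrow(rate_matrix) == K, ncol(rate_matrix) == K,
            sample_rate_hz > 0, duration_s > 0)
  if (K > 1 && any(diff(state_means_bp) <= 0))
    stop("state means must be strictly increasing")
  off <- rate_matrix
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  nonadj <- abs(row(off) - col(off)) > 1
  if (any(off[nonadj] != 0))
    stop("rate matrix must be sequential: nonadjacent rates must be 0")
  exit <- -diag(rate_matrix)
  if (any(exit > 0)) {
    min_dwell <- 1 / max(exit)
    if (sample_rate_hz * min_dwell < 5)
      warning("sampling resolves the shortest expected dwell with fewer ",
              "than 5 samples")
  }
  structure(list(
    state_means_bp = state_means_bp, state_sds_bp = state_sds_bp,
    rate_matrix = rate_matrix, sample_rate_hz = sample_rate_hz,
    duration_s = duration_s, unbound_pad_s = unbound_pad_s,
    unbound_sd_bp = unbound_sd_bp, seed = as.integer(seed)
  ), class = "trace_sim_config")
}

#' Generate a synthetic unzipping-fork trace with ground truth
#'
#' Simulates the hidden conformational path as a continuous-time Markov
#' chain by the Gillespie algorithm (exact exponential event times), then
#' snapshots the state at the sampling grid and adds Gaussian emission
#' noise.  Optional unbound padding flanks the bound segment with
#' high-variance white noise, mimicking free fork breathing before CTCF
#' binding.  Deterministic under the config seed.
#'
#' @param cfg a [trace_sim_config()].
#' @return list with
#'   \describe{
#'     \item{trace}{data.frame `time_s, value, channel` (channel
#'       `"fork_bp"`), carrying `sample_rate_hz` as an attribute.}
#'     \item{truth}{list with `states` (per-sample hidden state over the
#'       bound segment), `dwells` (exact continuous-time dwells), and
#'       `bound_interval` (start/end seconds of the bound segment).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
gen_fork_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  set.seed(cfg$seed)
  K <- length(cfg$state_means_bp)
  Q <- cfg$rate_matrix
  exit <- -diag(Q)
  pi0 <- if (K == 1) 1 else ctmc_stationary(Q)
  # Gillespie: exact jump chain
  s <- sample.int(K, 1, prob = pi0)
  t_now <- 0
  ev_t <- numeric(0)
  ev_s <- integer(0)
  ev_t[1] <- 0
  ev_s[1] <- s
  while (t_now < cfg$duration_s) {
    if (exit[s] <= 0) break  # absorbing (single-state) chain
    t_now <- t_now + stats::rexp(1, exit[s])
    if (t_now >= cfg$duration_s) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(K, 1, prob = probs)
    ev_t <- c(ev_t, t_now)
    ev_s <- c(ev_s, s)
  }
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  t_samp <- (seq_len(n) - 1L) / cfg$sample_rate_hz
  states <- ev_s[findInterval(t_samp, ev_t)]
  value <- cfg$state_means_bp[states] +
    stats::rnorm(n) * cfg$state_sds_bp[states]

  n_pad <- round(cfg$unbound_pad_s * cfg$sample_rate_hz)
  if (n_pad > 0) {
    pad_pre <- stats::rnorm(n_pad, 0, cfg$unbound_sd_bp)
    pad_post <- stats::rnorm(n_pad, 0, cfg$unbound_sd_bp)
    value <- c(pad_pre, value, pad_post)
  }
  time_s <- (seq_along(value) - 1L) / cfg$sample_rate_hz
  trace <- data.frame(time_s = time_s, value = value, channel = "fork_bp")
  attr(trace, "sample_rate_hz") <- cfg$sample_rate_hz
  dwell_end <- c(ev_t[-1], cfg$duration_s)
  truth <- list(
    states = states,
    dwells = data.frame(state = ev_s, start_s = ev_t,
                        duration_s = dwell_end - ev_t),
    bound_interval = c(start_s = n_pad / cfg$sample_rate_hz,
                       end_s = (n_pad + n) / cfg$sample_rate_hz)
  )
  list(trace = trace, truth = truth, config = cfg)
}
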