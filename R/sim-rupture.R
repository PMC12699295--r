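#' Reference two-population rupture-force parameters
#'
#' N-terminal ZF rupture forces of CTCF in the presence of PDS5A and
#' cohesin decompose into a main population (mean 19.6 pN, SE 0.3, n = 73)
#' and a high-force population (mean 27.8 pN, SE 0.9, n = 10).  The
#' printed uncertainties are standard errors of the means, so the
#' component SDs are `SE * sqrt(n)`.
#'
#' @return list with `means_pN`, `sds_pN`, `n` (per component) and
#'   `high_fraction`.
#' @export
rupture_mixture_reference <- function() {
  n <- c(73, 10)
  se <- c(0.3, 0.9)
  list(means_pN = c(19.6, 27.8), sds_pN = se * sqrt(n), n = n,
       high_fraction = n[2] / sum(n))
}

#' Configuration for the synthetic rupture-force generator
#'
#' @param component_means_pN,component_sds_pN two-component Gaussian
#'   parameters (low, high).
#' @param high_fraction weight of the high-force component.
#' @param n_events events to draw.
#' @param sampling `"quota"` draws exactly `round(high_fraction *
#'   n_events)` high-component events (exact-fraction default);
#'   `"bernoulli"` draws the component per event.
#' @param rip_positions_bp optional rip positions for curve synthesis
#'   (bp relative to motif center).
#' @param rip_forces_pN optional per-rip rupture forces; drawn from the
#'   mixture when NULL.
#' @param baseline_force_pN naked-DNA unzipping plateau (pN).
#' @param noise_sd_pN measurement noise SD (pN).
#' @param seed RNG seed.
#' @return object of class `rupture_sim_config`.
#' @export
rupture_sim_config <- function(component_means_pN = c(19.6, 27.8),
                               component_sds_pN = c(0.3 * sqrt(73),
                                                    0.9 * sqrt(10)),
                               high_fraction = 10 / 83,
                               n_events = 83L,
                               sampling = c("quota", "bernoulli"),
                               rip_positions_bp = NULL,
                               rip_forces_pN = NULL,
                               baseline_force_pN = 13,
                               noise_sd_pN = 0.1,
                               seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(length(component_means_pN) == 2, length(component_sds_pN) == 2,
            all(component_sds_pN > 0), high_fraction >= 0,
            high_fraction <= 1, n_events >= 1, noise_sd_pN >= 0)
  structure(list(
    component_means_pN = component_means_pN,
    component_sds_pN = component_sds_pN,
    high_fraction = high_fraction, n_events = as.integer(n_events),
    sampling = sampling, rip_positions_bp = rip_positions_bp,
    rip_forces_pN = rip_forces_pN,
    baseline_force_pN = baseline_force_pN, noise_sd_pN = noise_sd_pN,
    seed = as.integer(seed)
  ), class = "rupture_sim_config")
}

#' Draw rupture forces from the configured two-component mixture
#'
#' @param cfg a [rupture_sim_config()].
#' @return list with `forces` (pN) and `truth` (per-event component,
#'   `"low"`/`"high"`).
#' @export
gen_rupture_samples <- function(cfg) {
  stopifnot(inherits(cfg, "rupture_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_events
  if (cfg$sampling == "quota") {
    n_high <- round(cfg$high_fraction * n)
    comp <- sample(c(rep(2L, n_high), rep(1L, n - n_high)))
  } else {
    comp <- 1L + stats::rbinom(n, 1L, cfg$high_fraction)
  }
  forces <- stats::rnorm(n, cfg$component_means_pN[comp],
                         cfg$component_sds_pN[comp])
  list(forces = forces,
       truth = data.frame(event = seq_len(n),
                          component = c("low", "high")[comp]))
}

#' Synthesize an unzipping force-vs-position curve with discrete rips
#'
#' The curve follows the naked-DNA baseline with Gaussian noise; at each
#' rip position the force ramps up linearly over a few bp to the event's
#' rupture force and collapses back to baseline within 2 bp, reproducing
#' the sawtooth signature of a protein-DNA contact being disrupted.
#'
#' @param cfg a [rupture_sim_config()] with `rip_positions_bp` set.
#' @param bp_range curve extent (bp relative to motif center).
#' @param ramp_bp rise length of each rip (bp).
#' @return list with `curve` (data.frame `bp, force_pN`) and `truth`
#'   (data.frame `position_bp, force_pN`).
#' @export
gen_unzip_curve <- function(cfg, bp_range = c(-150L, 150L), ramp_bp = 6L) {
  stopifnot(inherits(cfg, "rupture_sim_config"))
  rips <- cfg$rip_positions_bp
  set.seed(cfg$seed)
  bp <- seq.int(bp_range[1], bp_range[2])
  if (!is.null(rips) && length(rips) &&
      (any(rips < bp_range[1] + ramp_bp) || any(rips > bp_range[2] - 2)))
    stop("rip positions outside the curve's bp range")
  force <- rep(cfg$baseline_force_pN, length(bp))
  truth <- data.frame(position_bp = numeric(0), force_pN = numeric(0))
  if (!is.null(rips) && length(rips)) {
    f_rip <- cfg$rip_forces_pN
    if (is.null(f_rip)) {
      f_rip <- gen_rupture_samples(
        rupture_sim_config(cfg$component_means_pN, cfg$component_sds_pN,
                           cfg$high_fraction, length(rips), cfg$sampling,
                           seed = cfg$seed))$forces
    }
    stopifnot(length(f_rip) == length(rips))
    for (i in seq_along(rips)) {
      peak <- which(bp == round(rips[i]))
      up <- seq.int(peak - ramp_bp, peak)
      force[up] <- pmax(force[up],
                        seq(cfg$baseline_force_pN, f_rip[i],
                            length.out = length(up)))
      # collapse to baseline within 2 bp past the peak
      force[peak + 1L] <- max(cfg$baseline_force_pN,
                              force[peak + 1L])
    }
    truth <- data.frame(position_bp = rips, force_pN = f_rip)
  }
  force <- force + stats::rnorm(length(bp), 0, cfg$noise_sd_pN)
  list(curve = data.frame(bp = bp, force_pN = force), truth = truth)
}
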