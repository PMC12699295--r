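#' Configuration for the synthetic kymograph trajectory generator
#'
#' Particles perform 1D Brownian motion on a taut DNA substrate (step
#' variance `2 * D * dt`), observed with Gaussian localization error.  An
#' optional static binding site intercepts diffusing particles: each
#' encounter resolves to a dock (particle immobilized at the site for an
#' exponential lifetime) with probability `dock_prob`, otherwise the
#' particle bounces off (reflects).
#'
#' @param diffusion_coeff D in kb^2/s.
#' @param frame_interval_s frame interval (s).
#' @param n_frames frames per trajectory.
#' @param localization_sd_kb localization error SD (kb).
#' @param n_particles number of trajectories.
#' @param substrate_kb substrate length (kb); particles reflect at 0 and L.
#' @param ctcf_site_kb static site position, or `NA` for none.
#' @param bind_rate landing rate (1/s); 0 starts every particle at frame 1.
#' @param unbind_rate nonspecific unbinding rate (1/s); 0 keeps particles
#'   to the last frame.
#' @param dock_prob probability an encounter docks.
#' @param docked_unbind_rate unbinding rate while docked (1/s).
#' @param seed RNG seed.
#' @return object of class `kymo_sim_config`.
#' @export
kymo_sim_config <- function(diffusion_coeff = 0.62, frame_interval_s = 0.1,
                            n_frames = 200L, localization_sd_kb = 0.05,
                            n_particles = 50L, substrate_kb = 20,
                            ctcf_site_kb = NA_real_, bind_rate = 0,
                            unbind_rate = 0, dock_prob = 0.5,
                            docked_unbind_rate = 1 / 60, seed = 1L) {
  stopifnot(diffusion_coeff >= 0, frame_interval_s > 0, n_frames >= 2,
            localization_sd_kb >= 0, substrate_kb > 0,
            bind_rate >= 0, unbind_rate >= 0, docked_unbind_rate >= 0,
            dock_prob >= 0, dock_prob <= 1)
  structure(list(
    diffusion_coeff = diffusion_coeff, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    localization_sd_kb = localization_sd_kb,
    n_particles = as.integer(n_particles), substrate_kb = substrate_kb,
    ctcf_site_kb = ctcf_site_kb, bind_rate = bind_rate,
    unbind_rate = unbind_rate, dock_prob = dock_prob,
    docked_unbind_rate = docked_unbind_rate, seed = as.integer(seed)
  ), class = "kymo_sim_config")
}

#' Generate synthetic kymograph trajectories with ground truth
#'
#' @param cfg a [kymo_sim_config()].
#' @return list with
#'   \describe{
#'     \item{trajectories}{data.frame `particle_id, channel, time_s,
#'       pos_kb` (observed, with localization noise).}
#'     \item{truth}{list with `true_pos` (same rows, noiseless),
#'       `encounters` (particle, time_s, outcome), and `docked_intervals`
#'       (particle, start_s, end_s).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
gen_kymograph <- function(cfg) {
  stopifnot(inherits(cfg, "kymo_sim_config"))
  set.seed(cfg$seed)
  dt <- cfg$frame_interval_s
  step_sd <- sqrt(2 * cfg$diffusion_coeff * dt)
  site <- cfg$ctcf_site_kb
  p_unbind <- 1 - exp(-cfg$unbind_rate * dt)
  rows <- list()
  enc <- list()
  docked <- list()
  for (p in seq_len(cfg$n_particles)) {
    start_frame <- if (cfg$bind_rate > 0)
      1L + stats::rgeom(1, 1 - exp(-cfg$bind_rate * dt)) else 1L
    if (start_frame >= cfg$n_frames) next
    x <- stats::runif(1, 0, cfg$substrate_kb)
    pos <- numeric(0)
    t_idx <- integer(0)
    dock_until <- -1
    f <- start_frame
    while (f <= cfg$n_frames) {
      pos <- c(pos, x)
      t_idx <- c(t_idx, f)
      if (cfg$unbind_rate > 0 && stats::runif(1) < p_unbind) break
      if (f == cfg$n_frames) break
      if (f <= dock_until) { f <- f + 1L; next }  # immobilized at the site
      x_new <- x + stats::rnorm(1, 0, step_sd)
      # reflect at substrate ends
      if (x_new < 0) x_new <- -x_new
      if (x_new > cfg$substrate_kb) x_new <- 2 * cfg$substrate_kb - x_new
      if (!is.na(site) && (x - site) * (x_new - site) < 0) {
        # the step would carry the particle across the site: an encounter
        if (stats::runif(1) < cfg$dock_prob) {
          dur <- stats::rexp(1, max(cfg$docked_unbind_rate, 1e-12))
          dock_frames <- max(1L, round(dur / dt))
          dock_until <- min(f + dock_frames, cfg$n_frames)
          enc[[length(enc) + 1L]] <- data.frame(
            particle = p, time_s = (f - 1) * dt, outcome = "dock")
          docked[[length(docked) + 1L]] <- data.frame(
            particle = p, start_s = f * dt, end_s = dock_until * dt)
          x_new <- site
        } else {
          x_new <- 2 * site - x_new   # bounce: reflect off the site
          enc[[length(enc) + 1L]] <- data.frame(
            particle = p, time_s = (f - 1) * dt, outcome = "bounce")
        }
      }
      x <- x_new
      f <- f + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      particle_id = sprintf("p%03d", p), channel = "mobile",
      time_s = (t_idx - 1) * dt, true_kb = pos,
      stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, rows)
  traj$pos_kb <- traj$true_kb +
    stats::rnorm(nrow(traj), 0, cfg$localization_sd_kb)
  truth <- list(
    true_pos = traj[, c("particle_id", "time_s", "true_kb")],
    encounters = if (length(enc)) do.call(rbind, enc) else
      data.frame(particle = integer(), time_s = numeric(),
                 outcome = character()),
    docked_intervals = if (length(docked)) do.call(rbind, docked) else
      data.frame(particle = integer(), start_s = numeric(),
                 end_s = numeric())
  )
  traj <- traj[, c("particle_id", "channel", "time_s", "pos_kb")]
  list(trajectories = traj, truth = truth, config = cfg)
}
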