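test_that("Brownian increments have the configured variance", {
  cfg <- kymo_sim_config(diffusion_coeff = 1, frame_interval_s = 0.1,
                         n_frames = 2000, localization_sd_kb = 0.05,
                         n_particles = 5, substrate_kb = 500, seed = 1)
  g <- gen_kymograph(cfg)
  tr <- split(g$trajectories, g$trajectories$particle_id)[[1]]
  d1 <- diff(tr$pos_kb)
  # lag-1 displacement variance = 2 D dt + 2 sigma_loc^2
  expected <- 2 * 1 * 0.1 + 2 * 0.05^2
  expect_lt(abs(var(d1) - expected) / expected, 0.15)

  # D = 0: positions constant up to localization noise
  cfg0 <- kymo_sim_config(diffusion_coeff = 0, n_frames = 500,
                          n_particles = 2, seed = 2)
  g0 <- gen_kymograph(cfg0)
  tr0 <- split(g0$trajectories, g0$trajectories$particle_id)[[1]]
  expect_lt(var(diff(tr0$pos_kb)), 4 * 2 * 0.05^2)
})

test_that("MSD estimator recovers the diffusion coefficient", {
  cfg <- kymo_sim_config(diffusion_coeff = 1, frame_interval_s = 0.1,
                         n_frames = 1000, localization_sd_kb = 0.05,
                         n_particles = 1, substrate_kb = 1000, seed = 3)
  g <- gen_kymograph(cfg)
  est <- estimate_diffusion(split(g$trajectories,
                                  g$trajectories$particle_id)[[1]])
  expect_lt(abs(est$D - 1), 0.15)
  # stationary trajectory: D indistinguishable from 0
  st <- data.frame(time_s = (1:500 - 1) / 10,
                   pos_kb = 5 + rnorm(500, 0, 0.05))
  est0 <- estimate_diffusion(st)
  expect_lt(est0$D, 2 * est0$se + 0.01)
  expect_error(estimate_diffusion(st[1:10, ]), "at least 20")
})

test_that("ensemble MSD recovery is unbiased over seeded replicates", {
  Ds <- vapply(1:10, function(s) {
    g <- gen_kymograph(kymo_sim_config(diffusion_coeff = 0.62,
                                       n_frames = 200, n_particles = 10,
                                       substrate_kb = 100, seed = s))
    ensemble_diffusion(g$trajectories)$D_mean
  }, numeric(1))
  expect_lt(abs(mean(Ds) - 0.62) / 0.62, 0.05)
})

test_that("docking outcomes follow the configured probability", {
  cfg <- kymo_sim_config(diffusion_coeff = 0.5, n_frames = 400,
                         n_particles = 60, substrate_kb = 6,
                         ctcf_site_kb = 3, dock_prob = 1,
                         docked_unbind_rate = 0.05, seed = 4)
  g <- gen_kymograph(cfg)
  expect_gt(nrow(g$truth$encounters), 10)
  expect_true(all(g$truth$encounters$outcome == "dock"))

  cfg2 <- kymo_sim_config(diffusion_coeff = 0.5, n_frames = 600,
                          n_particles = 120, substrate_kb = 6,
                          ctcf_site_kb = 3, dock_prob = 0.5,
                          docked_unbind_rate = 2, seed = 5)
  g2 <- gen_kymograph(cfg2)
  enc <- g2$truth$encounters
  expect_gt(nrow(enc), 200)
  expect_lt(abs(mean(enc$outcome == "dock") - 0.5), 0.08)
})

test_that("dwell survival median matches order statistics and theory", {
  dw <- dwell_survival(c(1, 2, 3, 4, 5), n_boot = 100)
  expect_equal(dw$median, 3)
  expect_true(all(diff(dw$surv$surv) <= 0))
  expect_equal(dw$surv$surv[1], 1)
  expect_equal(dw$surv$surv[nrow(dw$surv)], 0)
  set.seed(6)
  d <- rexp(1000, 1 / 10)
  dwe <- dwell_survival(d, n_boot = 200)
  expect_lt(abs(dwe$median - 10 * log(2)), 0.7)
  expect_error(dwell_survival(c(1, 2, 3), ), "at least 5")
  expect_error(dwell_survival(rep(1, 6), censored = rep(TRUE, 6)),
               "censored")
})

test_that("Kaplan-Meier handles censoring and matches survfit", {
  set.seed(7)
  d <- rexp(60, 1 / 20)
  cens <- d > 30
  d[cens] <- 30
  dw <- dwell_survival(d, censored = cens, n_boot = 200)
  f <- survival::survfit(survival::Surv(d, !cens) ~ 1)
  # package convention: smallest time with survival <= 0.5
  expect_equal(dw$median, min(f$time[f$surv <= 0.5]))
  expect_true(all(diff(dw$surv$surv) <= 0))
})

test_that("colocalization detection is symmetric and respects distance", {
  t_s <- (1:100 - 1) / 10
  a <- data.frame(time_s = t_s, pos_kb = sin(t_s))
  cc <- detect_colocalization(a, a)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$start_s, 0)
  expect_equal(cc$end_s, max(t_s))
  b <- data.frame(time_s = t_s, pos_kb = sin(t_s) + 1)
  expect_equal(nrow(detect_colocalization(a, b)), 0)
  # symmetry
  set.seed(8)
  c1 <- data.frame(time_s = t_s, pos_kb = cumsum(rnorm(100, 0, 0.2)))
  c2 <- data.frame(time_s = t_s, pos_kb = cumsum(rnorm(100, 0, 0.2)))
  expect_identical(detect_colocalization(c1, c2),
                   detect_colocalization(c2, c1))
})

test_that("encounters partition into bounce and dock by duration", {
  short <- data.frame(start_s = 1, end_s = 1.5, n_frames = 5)
  long <- data.frame(start_s = 1, end_s = 68, n_frames = 670)
  expect_equal(classify_encounter(short)$outcome, "bounce")
  expect_equal(classify_encounter(long)$outcome, "dock")
  none <- short[0, ]
  expect_equal(classify_encounter(none)$outcome, "no_contact")
  # a mobile particle crossing the target while free counts as a bypass
  t_s <- (1:50 - 1) / 10
  mob <- data.frame(time_s = t_s, pos_kb = seq(-2, 2, length.out = 50))
  tgt <- data.frame(time_s = t_s, pos_kb = rep(0, 50))
  cc <- detect_colocalization(mob, tgt)
  res <- classify_encounter(cc, mob, tgt)
  expect_true(res$bypass_count >= 0)
})

test_that("nearest-motif distances and their median are exact", {
  expect_equal(nearest_motif_distance(100, c(0, 100), n_boot = 50)$median, 0)
  nm <- nearest_motif_distance(c(90, 110), c(0, 100), n_boot = 50)
  expect_equal(sort(nm$distances), c(-10, 10))
  expect_equal(nm$median, 0)
  # ties: equidistant between motifs resolves to the leftmost motif
  nm2 <- nearest_motif_distance(50, c(0, 100), n_boot = 50)
  expect_equal(nm2$distances, 50)
})
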