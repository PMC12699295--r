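test_that("rip detection: trivial and constructed cases", {
  set.seed(1)
  flat <- data.frame(bp = -100:100, force_pN = 13 + rnorm(201, 0, 0.1))
  expect_equal(nrow(detect_rips(flat)), 0)
  expect_error(detect_rips(flat[1:30, ]), "50 bp")

  one <- gen_unzip_curve(rupture_sim_config(rip_positions_bp = 12,
                                            rip_forces_pN = 18,
                                            noise_sd_pN = 0.1, seed = 2))
  ev <- detect_rips(one$curve)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$position_bp - 12), 2)
  expect_lte(abs(ev$force_pN - 18), 0.3)

  two <- gen_unzip_curve(rupture_sim_config(rip_positions_bp = c(-20, 5),
                                            rip_forces_pN = c(16, 18),
                                            noise_sd_pN = 0.1, seed = 3))
  ev2 <- detect_rips(two$curve)
  expect_equal(nrow(ev2), 2)
  expect_true(all(abs(sort(ev2$position_bp) - c(-20, 5)) <= 2))

  # rips 8 bp apart stay separate (above the 5 bp merge distance)
  close8 <- gen_unzip_curve(rupture_sim_config(rip_positions_bp = c(0, 8),
                                               rip_forces_pN = c(17, 19),
                                               noise_sd_pN = 0.1, seed = 4))
  expect_equal(nrow(detect_rips(close8$curve)), 2)
  expect_error(gen_unzip_curve(rupture_sim_config(rip_positions_bp = 400)),
               "outside")
})

test_that("rip detection recall/false positives on generator curves", {
  hits <- 0; total <- 0; fp <- 0
  for (s in 1:20) {
    pos <- sort(sample(seq(-120, 120, by = 15), 3))
    cu <- gen_unzip_curve(rupture_sim_config(
      rip_positions_bp = pos, rip_forces_pN = c(16, 18, 20),
      noise_sd_pN = 0.3, seed = s))   # prominence >= 3x noise sd
    ev <- detect_rips(cu$curve)
    total <- total + 3
    for (p in pos) hits <- hits + any(abs(ev$position_bp - p) <= 2)
    fp <- fp + sum(vapply(ev$position_bp,
                          function(q) all(abs(pos - q) > 2), logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_lte(fp / (20 * 3), 0.02 * 3)   # per 100 bp on a 300 bp curve
})

test_that("region assignment is correct and mirror-equivariant", {
  ev <- data.frame(position_bp = c(0, -10, 10, 200, -30))
  lab <- assign_region(ev, orientation = "N_terminal")
  expect_equal(lab$region,
               c("N_ZF_region", "N_ZF_region", "C_ZF_region", "off_motif",
                 "N_ZF_region"))
  # flipping orientation and mirroring coordinates swaps N/C exactly
  ev_m <- data.frame(position_bp = -ev$position_bp)
  lab_m <- assign_region(ev_m, orientation = "C_terminal")
  swap <- c(N_ZF_region = "C_ZF_region", C_ZF_region = "N_ZF_region",
            off_motif = "off_motif")
  expect_equal(unname(swap[lab$region]), lab_m$region)
})

test_that("force summaries use the standard error of the mean", {
  s <- summarize_forces(data.frame(force_pN = c(14, 15, 16),
                                   condition = "wt"))
  expect_equal(s$mean_pN, 15)
  expect_equal(s$se_pN, sd(c(14, 15, 16)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(s$se_pN, 3), 0.577)
  s2 <- summarize_forces(data.frame(force_pN = rep(12, 5),
                                    condition = "x"))
  expect_equal(s2$se_pN, 0)
  expect_warning(summarize_forces(data.frame(force_pN = c(1, 2),
                                             condition = "tiny")),
                 "fewer than 3")
})

test_that("mixture decomposition: one-component and separable limits", {
  set.seed(5)
  x1 <- rnorm(200, 20, 2)
  m1 <- fit_force_mixture(x1)
  expect_false(m1$prefer_two)
  expect_equal(m1$high_fraction, 0)

  comp <- rep(1:2, each = 200)
  x2 <- rnorm(400, c(10, 30)[comp], 1)   # 10 sigma apart (pooled sd ~2)
  m2 <- fit_force_mixture(x2)
  expect_true(m2$prefer_two)
  expect_lt(abs(m2$high_fraction - 0.5), 0.05)
  expect_equal(mean((m2$membership == "high") == (comp == 2)), 1)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)
  expect_true(m2$means_pN[1] < m2$means_pN[2])
})

test_that("mixture EM recovers weights at 3-sigma separation", {
  set.seed(6)
  ok <- 0
  for (r in 1:5) {
    comp <- rep(1:2, c(300, 100))
    x <- rnorm(400, c(15, 24)[comp], 3)
    m <- fit_force_mixture(x)
    ok <- ok + (abs(m$weight_high - 0.25) <= 0.05)
  }
  expect_gte(ok, 4)
})

test_that("quota sampling reproduces exact component counts", {
  s <- gen_rupture_samples(rupture_sim_config(seed = 7))
  expect_equal(sum(s$truth$component == "high"), round(0.12 * 83 + 1e-9))
  expect_equal(length(s$forces), 83)
  sb <- gen_rupture_samples(rupture_sim_config(sampling = "bernoulli",
                                               n_events = 2000,
                                               high_fraction = 0,
                                               seed = 8))
  expect_true(all(sb$truth$component == "low"))
  # mixture-mean oracle: means (15, 35), 50/50, n = 2000
  sm <- gen_rupture_samples(rupture_sim_config(
    component_means_pN = c(15, 35), component_sds_pN = c(1, 1),
    high_fraction = 0.5, n_events = 2000, seed = 9))
  expect_lt(abs(mean(sm$forces) - 25), 0.3)
})

test_that("KS statistic and p-value match hand values and enumeration", {
  k0 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k0$D, 0)
  expect_equal(k0$p, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  set.seed(10)
  for (r in 1:5) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1), 0.5)
    got <- ks_two_sample(x, y)
    orc <- oracle_ks(x, y)
    expect_equal(got$D, orc$D, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  # asymptotic branch against stats::ks.test's D and approximate p
  x <- rnorm(60); y <- rnorm(80, 0.4)
  got <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(got$p - ref$p.value), 0.05)
})
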