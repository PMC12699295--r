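test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(1)
  for (rep in 1:3) {
    x <- rnorm(8)
    mu <- c(-1, 1.5)
    sigma <- c(0.8, 1.2)
    A <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
    pi0 <- c(0.6, 0.4)
    e <- hmm_estep(x, mu, sigma, A, pi0)
    expect_equal(e$loglik, oracle_hmm_loglik(x, mu, sigma, A, pi0),
                 tolerance = 1e-10)
  }
  # three states, shorter trace
  x <- rnorm(6)
  mu <- c(-2, 0, 2); sigma <- c(1, 0.5, 1.5)
  A <- matrix(c(0.8, 0.15, 0.05,
                0.2, 0.6, 0.2,
                0.1, 0.2, 0.7), 3, 3, byrow = TRUE)
  pi0 <- c(0.3, 0.4, 0.3)
  e <- hmm_estep(x, mu, sigma, A, pi0)
  expect_equal(e$loglik, oracle_hmm_loglik(x, mu, sigma, A, pi0),
               tolerance = 1e-10)
})

test_that("Viterbi equals argmax over all enumerated paths", {
  set.seed(2)
  mu <- c(0, 3); sigma <- c(1, 1)
  A <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  for (rep in 1:5) {
    x <- rnorm(6, sample(mu, 6, replace = TRUE))
    expect_equal(hmm_viterbi(x, mu, sigma, A, pi0),
                 oracle_viterbi(x, mu, sigma, A, pi0))
  }
  mu3 <- c(-2, 0, 2); s3 <- c(1, 1, 1)
  A3 <- matrix(1 / 3, 3, 3); pi3 <- rep(1 / 3, 3)
  x <- rnorm(5)
  expect_equal(hmm_viterbi(x, mu3, s3, A3, pi3),
               oracle_viterbi(x, mu3, s3, A3, pi3))
})

test_that("EM log-likelihood is non-decreasing and recovers a square wave", {
  set.seed(3)
  x <- rnorm(2000, rep(c(0, 4), each = 50))
  fit <- fit_hmm(x, 2, n_restarts = 2, seed = 1)
  expect_true(all(diff(fit$loglik_history) > -1e-6))
  expect_true(all(diff(fit$mu) > 0))   # states sorted ascending
  expect_equal(rowSums(fit$A), c(1, 1), tolerance = 1e-10)

  # noiseless 2-level square wave: means recovered exactly
  sq <- rep(rep(c(0, 5), 10), each = 10)
  fit_sq <- fit_hmm(sq, 2, n_restarts = 2, seed = 1)
  expect_equal(fit_sq$mu, c(0, 5), tolerance = 1e-6)
})

test_that("BIC selects the true number of states", {
  set.seed(4)
  x1 <- rnorm(600)
  expect_equal(select_num_states(x1, K_range = 1:3, seed = 1,
                                 n_restarts = 2)$K, 1)
  states <- rep(rep(1:2, 25), each = 20)
  x2 <- rnorm(1000, mean = c(0, 10)[states], sd = 1)   # 10 sigma apart
  expect_equal(select_num_states(x2, K_range = 1:3, seed = 1,
                                 n_restarts = 2)$K, 2)
})

test_that("state-position mapping uses the ML Gaussian fit", {
  path <- structure(list(states = rep(1L, 7), K = 1L, sample_rate_hz = 1,
                         dwells = path_dwells(rep(1L, 7), 1)),
                    class = "state_path")
  pos <- map_states_to_positions(path, c(-3, -2, -1, 0, 1, 2, 3),
                                 min_samples = 5)
  expect_equal(pos$mean_bp, 0)
  expect_equal(pos$sd_bp, 2.0)    # ML denominator n
  # degenerate repeated value flagged
  path2 <- structure(list(states = rep(1L, 120), K = 1L, sample_rate_hz = 1,
                          dwells = path_dwells(rep(1L, 120), 1)),
                     class = "state_path")
  pos2 <- map_states_to_positions(path2, rep(2.5, 120))
  expect_equal(pos2$sd_bp, 0)
  expect_true(pos2$flagged)
})

test_that("ensemble statistics match hand arithmetic", {
  # A 10 ms, B 5 ms, A 10 ms at 1 kHz; boundary dwells are truncated
  states <- c(rep(1L, 10), rep(2L, 5), rep(1L, 10))
  path <- structure(list(states = states, K = 2L, sample_rate_hz = 1000,
                         dwells = path_dwells(states, 1000)),
                    class = "state_path")
  ens <- ensemble_stats(path, min_dwells = 1)
  expect_equal(ens$per_state$occupancy, c(20, 5) / 25)
  expect_equal(ens$per_state$lifetime_ms[2], 5)
  expect_true(is.na(ens$per_state$lifetime_ms[1]))  # only truncated dwells
  expect_equal(ens$rate_matrix[2, 1], 1 / 0.005)    # 200/s
  # single-state path occupancy
  one <- structure(list(states = rep(1L, 50), K = 4L, sample_rate_hz = 1000,
                        dwells = path_dwells(rep(1L, 50), 1000)),
                   class = "state_path")
  expect_equal(ensemble_stats(one)$per_state$occupancy, c(1, 0, 0, 0))
})

test_that("sequentiality scoring counts adjacent transitions", {
  expect_equal(sequentiality_score(c(1, 2, 3, 4, 3, 2, 1))$score, 1.0)
  path <- c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 3, 1)  # 11 transitions, one 3->1 skip
  sc <- sequentiality_score(path)
  expect_equal(sc$n_transitions, 11)
  expect_equal(sc$score, 10 / 11)
})

test_that("force calibration is monotone, invertible, and clips", {
  tr <- data.frame(time_s = 0:2 / 10, value = c(1, 2, 3),
                   channel = "force_pN")
  out <- calibrate_force_to_bp(tr, a = 2, b = 0)
  expect_equal(out$value, c(2, 4, 6))
  expect_equal(out$channel[1], "fork_bp")
  ident <- calibrate_force_to_bp(tr, map = identity)
  expect_equal(ident$value, tr$value)
  # round trip with the inverse map
  fwd <- calibrate_force_to_bp(tr, map = function(p) p^3 + 2 * p)
  back <- vapply(fwd$value, function(y)
    uniroot(function(p) p^3 + 2 * p - y, c(-10, 10), tol = 1e-12)$root,
    numeric(1))
  expect_equal(back, tr$value, tolerance = 1e-9)
  expect_error(calibrate_force_to_bp(tr, map = function(p) (p - 2)^2),
               "monotone")
  expect_warning(calibrate_force_to_bp(tr, range = c(1.5, 3)), "clipped")
})

test_that("bound-region segmentation finds variance-suppressed intervals", {
  set.seed(5)
  n <- 30000
  sd_prof <- rep(2, n)
  sd_prof[10001:20000] <- 1        # variance quartered in the middle third
  tr <- data.frame(time_s = (seq_len(n) - 1) / 1000,
                   value = rnorm(n, 0, sd_prof))
  seg <- segment_bound_region(tr, window_s = 0.2)
  expect_equal(nrow(seg), 1)
  w <- 200   # samples per window
  expect_lt(abs(seg$start_idx - 10001), 2 * w + 1)
  expect_lt(abs(seg$end_idx - 20000), 2 * w + 1)
  # constant variance: nothing is bound
  tr2 <- data.frame(time_s = (1:5000 - 1) / 1000, value = rnorm(5000))
  expect_equal(nrow(segment_bound_region(tr2, window_s = 0.2)), 0)
})

test_that("segmentation overlaps generator truth (Jaccard >= 0.9)", {
  cond <- ctcf_conditions()$insulator_wt
  cfg <- trace_sim_config(cond$means_bp, cond$sds_bp, cond$rate_matrix,
                          duration_s = 6, unbound_pad_s = 3, seed = 6)
  g <- gen_fork_trace(cfg)
  seg <- segment_bound_region(g$trace, window_s = 0.2)
  expect_gte(nrow(seg), 1)
  got <- c(seg$start_s[1], seg$end_s[nrow(seg)])
  tru <- g$truth$bound_interval
  inter <- max(0, min(got[2], tru[2]) - max(got[1], tru[1]))
  union <- max(got[2], tru[2]) - min(got[1], tru[1])
  expect_gte(inter / union, 0.9)
})

test_that("two-state parameter recovery at moderate separation", {
  # dwells ~25 samples, means 2 sigma apart
  Q <- matrix(c(-40, 40, 40, -40), 2, 2, byrow = TRUE)
  for (s in 1:3) {
    cfg <- trace_sim_config(c(0, 2), c(1, 1), Q, sample_rate_hz = 1000,
                            duration_s = 20, seed = s)
    g <- gen_fork_trace(cfg)
    fit <- fit_hmm(g$trace$value, 2, n_restarts = 3, seed = 1)
    expect_true(all(abs(fit$mu - c(0, 2)) <= 0.3))
    p <- viterbi_decode(fit, g$trace$value, sample_rate_hz = 1000)
    occ <- ensemble_stats(p, min_dwells = 1)$per_state$occupancy
    expect_true(all(abs(occ - 0.5) <= 0.03))
    ml <- model_lifetimes(fit, 1000)
    expect_true(all(abs(ml$lifetimes_ms - 25) / 25 <= 0.15))
  }
})
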