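sites <- seq(-120L, 120L, by = 3L)

read_with <- function(id, meth_at = integer(0), missing_at = integer(0),
                      motif_id = "m1") {
  call <- rep("U", length(sites))
  call[sites %in% meth_at] <- "M"
  call[sites %in% missing_at] <- "."
  make_read(id, sites, call, motif_id)
}

test_that("archetypal reads classify as expected", {
  all_meth <- make_read("r_unb", sites, rep("M", length(sites)))
  nuc <- read_with("r_nuc", meth_at = sites[abs(sites) > 73])
  ctcf <- read_with("r_ctcf", meth_at = sites[abs(sites) > 20])
  calls <- rbind(all_meth, nuc, ctcf)
  cls <- classify_reads(calls)
  got <- setNames(cls$label, cls$read_id)
  expect_equal(got[["r_unb"]], "unbound")
  expect_equal(got[["r_nuc"]], "nucleosomal")
  expect_equal(got[["r_ctcf"]], "ctcf_bound")
  expect_equal(cls$sub_label[cls$read_id == "r_ctcf"], "protected")
  # one methylated ZF window makes the CTCF read partially protected
  part <- read_with("r_part", meth_at = c(sites[abs(sites) > 20], 15L))
  cls2 <- classify_reads(rbind(calls, part))
  expect_equal(cls2$sub_label[cls2$read_id == "r_part"],
               "partially_protected")
})

test_that("reads without core or NDR coverage are flagged, not dropped", {
  bare <- make_read("r_bare", c(-40L, 40L), c("U", "U"))
  cls <- classify_reads(bare)
  expect_equal(cls$label, "unclassifiable")
  expect_match(cls$reason, "core")
  expect_equal(nrow(cls), 1)
})

test_that("classification recovers generator truth", {
  cfg <- footprint_sim_config(n_motifs = 20, reads_per_motif = 100, seed = 7)
  g <- gen_methyl_reads(cfg)
  cls <- classify_reads(g$calls)
  truth <- g$truth$classes$class[match(cls$read_id, g$truth$classes$read_id)]
  truth_lab <- ifelse(truth %in% c("ctcf_full", "ctcf_partial"),
                      "ctcf_bound", truth)
  ok <- cls$label != "unclassifiable"
  expect_gt(mean(cls$label[ok] == truth_lab[ok]), 0.95)
  fr <- class_fractions(cls)
  expect_equal(sum(fr), 1)
  tr <- table(truth_lab) / length(truth_lab)
  expect_true(all(abs(fr[names(tr)] - tr) < 0.03))
})

test_that("per-ZF protection matches hand counts", {
  # ZF1 window holds the +15 site; five reads give calls M, U, U, U, missing
  zf1_calls <- c("M", "U", "U", "U", ".")
  calls <- do.call(rbind, lapply(1:5, function(i)
    read_with(paste0("r", i),
              meth_at = if (zf1_calls[i] == "M") 15L else integer(0),
              missing_at = if (zf1_calls[i] == ".") 15L else integer(0))))
  classified <- data.frame(read_id = paste0("r", 1:5), label = "ctcf_bound")
  prot <- zf_protection(calls, classified, n_boot = 10)
  p_zf1 <- prot$per_motif$protection[prot$per_motif$zf == "ZF1"]
  expect_equal(p_zf1, 1 - 1 / 4)
  # a window with zero methylated calls is fully protected
  p_zf4 <- prot$per_motif$protection[prot$per_motif$zf == "ZF4"]
  expect_equal(p_zf4, 1.0)
})

test_that("protection is invariant to read order and strand flipping", {
  cfg <- footprint_sim_config(n_motifs = 6, reads_per_motif = 30, seed = 5)
  g <- gen_methyl_reads(cfg)
  cls <- classify_reads(g$calls)
  p1 <- zf_protection(g$calls, cls, n_boot = 10)
  shuffled <- g$calls[sample.int(nrow(g$calls)), ]
  p2 <- zf_protection(shuffled, cls, n_boot = 10)
  expect_equal(p1$profile$mean, p2$profile$mean)
  # mirror site positions and mark motifs minus-strand: statistics unchanged
  flipped <- g$calls
  flipped$rel_pos <- -flipped$rel_pos
  motifs <- data.frame(motif_id = unique(g$calls$motif_id), strand = "-")
  oriented <- orient_calls(flipped, motifs)
  p3 <- zf_protection(oriented, classify_reads(oriented), n_boot = 10)
  expect_equal(p1$profile$mean, p3$profile$mean)
})

test_that("co-binding conditional probabilities match enumeration", {
  # 25 fully protected reads: every defined cell is 1
  calls <- do.call(rbind, lapply(1:25, function(i)
    read_with(paste0("r", i), meth_at = sites[abs(sites) > 20])))
  classified <- data.frame(read_id = paste0("r", 1:25), label = "ctcf_bound")
  cb <- cobinding_conditional(calls, classified, n_boot = 20)
  expect_true(all(cb$p[!is.na(cb$p)] == 1))
  expect_true(all(diag(cb$p)[!is.na(diag(cb$p))] == 1))

  # 4-read toy against a hand computation (ZF1 site +15, ZF2 site +12)
  meth_sets <- list(integer(0), 15L, 12L, c(15L, 12L))
  calls4 <- do.call(rbind, lapply(1:4, function(i)
    read_with(paste0("t", i), meth_at = meth_sets[[i]])))
  cls4 <- data.frame(read_id = paste0("t", 1:4), label = "ctcf_bound")
  cb4 <- cobinding_conditional(calls4, cls4, min_n = 1, n_boot = 10)
  # ZF1 protected in reads 1,3; ZF2 protected in reads 1,2
  expect_equal(cb4$p["ZF1", "ZF2"], 1 / 2)
  expect_equal(cb4$p["ZF2", "ZF1"], 1 / 2)
  expect_equal(cb4$p["ZF1", "ZF3"], 1)
})

test_that("protected-fraction estimators behave in the limits", {
  cfg <- footprint_sim_config(
    n_motifs = 5, reads_per_motif = 30,
    class_mixture = c(ctcf_full = 1, ctcf_partial = 0, nucleosomal = 0,
                      unbound = 0),
    background_methylation = 0, missing_rate = 0, seed = 2)
  g <- gen_methyl_reads(cfg)
  cls <- classify_reads(g$calls)
  pf <- estimate_protected_fraction(g$calls, cls, method = "raw",
                                    n_boot = 20)
  expect_equal(pf$protected, 1.0)
  expect_equal(pf$protected + pf$partial, 1.0)
})

test_that("model-based estimator recovers a 60/40 protected split", {
  cal <- calibrate_zf_protection()
  qp <- setNames(cal$q_partial, cal$zf)
  cfg <- footprint_sim_config(
    n_motifs = 50, reads_per_motif = 100,
    class_mixture = c(ctcf_full = 0.6, ctcf_partial = 0.4, nucleosomal = 0,
                      unbound = 0),
    zf_protection_prob = qp, seed = 4)
  g <- gen_methyl_reads(cfg)
  cls <- classify_reads(g$calls)
  pf <- estimate_protected_fraction(g$calls, cls, n_boot = 30)
  expect_lt(abs(pf$protected - 0.60), 0.02)
  expect_true(pf$ci[1] <= pf$ci[2])
})

test_that("ChIP stratification: identical strata give p near 1, and the
          Mann-Whitney path matches enumeration", {
  set.seed(1)
  base <- rep(seq(0.1, 0.9, length.out = 20), 10)
  pmc <- data.frame(motif_id = sprintf("m%03d", 1:200), cluster = "ZF3-8",
                    protection = base)
  chip <- data.frame(motif_id = sprintf("m%03d", 1:200), score = 1:200)
  st <- stratify_by_chip(pmc, chip, n_boot = 100)
  expect_gt(st$tests$p[1], 0.9)
  expect_equal(sort(unique(st$deciles$decile)), 1:10)
  # exact two-tailed U test on {1,2} vs {3,4}: p = 2/6
  expect_equal(stats::wilcox.test(c(1, 2), c(3, 4), exact = TRUE)$p.value,
               1 / 3, tolerance = 1e-12)
  for (i in 1:5) {
    x <- sample(100, 5)
    y <- sample(200, 4) + 0.5   # no ties
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 oracle_mann_whitney_p(x, y), tolerance = 1e-12)
  }
})

test_that("ChIP-ZF correlation matches the closed form and masks
          zero variance", {
  pmz <- data.frame(motif_id = c("a", "b", "c"), zf = "ZF1",
                    protection = c(1, 2, 3))
  chip <- data.frame(motif_id = c("a", "b", "c"), protein = "PDS5A",
                     score = c(2, 4, 7))
  r <- correlate_chip_zf(pmz, chip, min_motifs = 3)
  expect_equal(r$r, 15 / sqrt(228), tolerance = 1e-10)
  chip$score <- pmz$protection
  r2 <- correlate_chip_zf(pmz, chip, min_motifs = 3)
  expect_equal(r2$r, 1)
  pmz$protection <- c(1, 1, 1)
  r3 <- correlate_chip_zf(pmz, chip, min_motifs = 3)
  expect_true(is.na(r3$r))
})

test_that("bootstrap intervals reach near-nominal coverage", {
  hits <- 0
  for (i in 1:50) {
    set.seed(i)
    x <- rnorm(40, mean = 3)
    ci <- boot_ci(x, stat = median, n_boot = 400)
    hits <- hits + (ci[1] <= 3 && 3 <= ci[2])
  }
  expect_gte(hits / 50, 0.85)
})
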