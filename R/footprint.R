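#' Orient per-read calls by motif strand
#'
#' Motif-relative positions are signed so that negative coordinates lie on
#' the N-terminal-protein side.  For minus-strand motifs this requires
#' mirroring the genome-relative offsets.  Per-ZF statistics are invariant
#' under flipping a motif's strand together with mirroring its positions.
#'
#' @param calls data.frame `read_id, motif_id, rel_pos, call`.
#' @param motifs data.frame with `motif_id` and `strand` (`"+"`/`"-"`);
#'   motifs absent from the table are assumed plus-strand.
#' @return calls with `rel_pos` flipped for minus-strand motifs.
#' @export
orient_calls <- function(calls, motifs) {
  if (is.null(motifs)) return(calls)
  neg <- motifs$motif_id[motifs$strand == "-"]
  flip <- calls$motif_id %in% neg
  calls$rel_pos[flip] <- -calls$rel_pos[flip]
  calls
}

#' Default thresholds for single-read footprint classification
#'
#' @param core_max maximum methylated fraction over core ZF windows (3-8)
#'   for a CTCF call.
#' @param ndr_min minimum methylated fraction over the pooled NDR windows
#'   for a CTCF call (bound CTCF keeps its flanks accessible).
#' @param broad_max maximum methylated fraction over the broad window for a
#'   nucleosomal call.
#' @param broad_halfwidth half-width (bp) of the broad nucleosome window.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(core_max = 0.2, ndr_min = 0.6,
                                broad_max = 0.2, broad_halfwidth = 73L) {
  list(core_max = core_max, ndr_min = ndr_min, broad_max = broad_max,
       broad_halfwidth = as.integer(broad_halfwidth))
}

# per-read methylated / called counts over a site mask
.read_counts <- function(calls, mask) {
  sub <- calls[mask & calls$call != ".", , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(read_id = character(), n = integer(), m = integer()))
  n <- rowsum(rep(1L, nrow(sub)), sub$read_id)
  m <- rowsum(as.integer(sub$call == "M"), sub$read_id)
  data.frame(read_id = rownames(n), n = n[, 1], m = m[, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify single reads at CTCF motifs
#'
#' Each read is summarized by three methylated fractions over called sites:
#' the motif core (ZF3-8 windows), the pooled flanking NDR windows, and a
#' broad 147-bp window centered on the motif.  A read is `ctcf_bound` when
#' the core is protected but the NDRs are accessible, `nucleosomal` when
#' the whole broad window is protected, and `unbound` otherwise.  CTCF
#' reads additionally get a sub-label: `protected` when every ZF window
#' with at least one call has zero methylated calls, else
#' `partially_protected`.  Reads lacking a called site in the core or in
#' either NDR window are labeled `unclassifiable` with a reason, never
#' silently dropped.
#'
#' @param calls data.frame `read_id, motif_id, rel_pos, call` with call in
#'   `"M"`, `"U"`, `"."`.
#' @param zfmap ZF window map, see [zf_map()].
#' @param thresholds see [classify_thresholds()].
#' @param motifs optional motif table with strand for [orient_calls()].
#' @return data.frame per read: `read_id, motif_id, label, sub_label,
#'   m_core, m_ndr, m_broad, reason`.
#' @export
classify_reads <- function(calls, zfmap = zf_map(),
                           thresholds = classify_thresholds(),
                           motifs = NULL) {
  calls <- orient_calls(calls, motifs)
  region <- zf_region_of(calls$rel_pos, zfmap)
  core_zf <- paste0("ZF", 3:8)
  in_core <- !is.na(region) & region %in% core_zf
  in_ndr <- !is.na(region) & region %in% c("NDR_N", "NDR_C")
  in_ndr_n <- !is.na(region) & region == "NDR_N"
  in_ndr_c <- !is.na(region) & region == "NDR_C"
  in_broad <- abs(calls$rel_pos) <= thresholds$broad_halfwidth
  in_zf <- !is.na(region) & region %in% zf_numbers()

  reads <- unique(calls[, c("read_id", "motif_id")])
  frac <- function(mask) {
    cc <- .read_counts(calls, mask)
    f <- cc$m / cc$n
    names(f) <- cc$read_id
    f
  }
  m_core <- frac(in_core)
  m_ndr <- frac(in_ndr)
  m_broad <- frac(in_broad)
  n_ndr_n <- frac(in_ndr_n)
  n_ndr_c <- frac(in_ndr_c)

  # strict sub-label: any methylated call inside any ZF window
  zf_sub <- calls[in_zf & calls$call != ".", , drop = FALSE]
  meth_in_zf <- rowsum(as.integer(zf_sub$call == "M"), zf_sub$read_id)
  any_zf_meth <- stats::setNames(meth_in_zf[, 1] > 0, rownames(meth_in_zf))

  id <- reads$read_id
  res <- data.frame(
    read_id = id, motif_id = reads$motif_id,
    label = NA_character_, sub_label = NA_character_,
    m_core = unname(m_core[id]), m_ndr = unname(m_ndr[id]),
    m_broad = unname(m_broad[id]), reason = NA_character_,
    stringsAsFactors = FALSE
  )
  no_core <- !(id %in% names(m_core))
  no_ndr <- !(id %in% names(n_ndr_n)) | !(id %in% names(n_ndr_c))
  res$label[no_core | no_ndr] <- "unclassifiable"
  res$reason[no_core] <- "no called site in motif core"
  res$reason[no_ndr & !no_core] <- "no called site in an NDR window"

  ok <- is.na(res$label)
  is_ctcf <- ok & res$m_core <= thresholds$core_max &
    res$m_ndr >= thresholds$ndr_min
  is_nuc <- ok & !is_ctcf & res$m_broad <= thresholds$broad_max &
    res$m_ndr < thresholds$ndr_min
  res$label[is_ctcf] <- "ctcf_bound"
  res$label[is_nuc] <- "nucleosomal"
  res$label[ok & !is_ctcf & !is_nuc] <- "unbound"
  has_meth <- unname(any_zf_meth[res$read_id])
  has_meth[is.na(has_meth)] <- FALSE
  res$sub_label[is_ctcf] <- ifelse(has_meth[is_ctcf],
                                   "partially_protected", "protected")
  res
}

#' Fractions of classified reads per label
#'
#' @param classified output of [classify_reads()].
#' @param drop_unclassifiable exclude unclassifiable reads from the
#'   denominator (they are still counted separately).
#' @return named numeric vector of fractions summing to 1 over classified
#'   reads, with attribute `n`.
#' @export
class_fractions <- function(classified, drop_unclassifiable = TRUE) {
  lab <- classified$label
  if (drop_unclassifiable) lab <- lab[lab != "unclassifiable"]
  tab <- table(factor(lab, levels = c("ctcf_bound", "nucleosomal", "unbound")))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  attr(out, "n") <- sum(tab)
  out
}

# per-read per-ZF methylated/called counts as N x 11 matrices
.read_zf_counts <- function(calls, zfmap) {
  region <- zf_region_of(calls$rel_pos, zfmap)
  keep <- !is.na(region) & region %in% zf_numbers() & calls$call != "."
  sub <- calls[keep, , drop = FALSE]
  sub$region <- region[keep]
  ids <- unique(calls$read_id)
  n <- matrix(0L, length(ids), 11, dimnames = list(ids, zf_numbers()))
  m <- n
  key_n <- rowsum(rep(1L, nrow(sub)), paste(sub$read_id, sub$region, sep = "\r"))
  key_m <- rowsum(as.integer(sub$call == "M"),
                  paste(sub$read_id, sub$region, sep = "\r"))
  parts <- strsplit(rownames(key_n), "\r", fixed = TRUE)
  ri <- vapply(parts, `[`, "", 1L)
  zi <- vapply(parts, `[`, "", 2L)
  n[cbind(ri, zi)] <- key_n[, 1]
  m[cbind(ri, zi)] <- key_m[, 1]
  list(called = n, meth = m)
}

#' Per-ZF protection profile across motifs
#'
#' Protection (GpC inaccessibility) of a ZF triplet is 1 minus the
#' methylated fraction of called GpCs in its window, pooled over the kept
#' reads of one motif; the profile reports the mean and SD of these
#' per-motif values across motifs, following the convention that n refers
#' to motifs (with read counts alongside).  Cluster summaries (ZF1-2,
#' ZF3-8, ZF9-11) are medians across motifs with percentile-bootstrap
#' confidence intervals.
#'
#' @param calls data.frame of per-read calls.
#' @param classified output of [classify_reads()] (or any data.frame with
#'   `read_id` and `label`); only reads whose label is in `read_filter` are
#'   used.
#' @param zfmap ZF window map.
#' @param read_filter labels to keep (default CTCF-bound reads).
#' @param exclude_zf ZF names to flag as excluded (e.g. `"ZF5"` when its
#'   triplet lacks GpCs in real data).
#' @param n_boot bootstrap resamples for cluster CIs.
#' @param conf confidence level.
#' @return list with `per_motif` (motif x ZF protection), `profile`
#'   (per-ZF mean, sd, n_motifs, n_reads, excluded flag), `per_motif_cluster`
#'   and `clusters` (median with CI).
#' @export
zf_protection <- function(calls, classified, zfmap = zf_map(),
                          read_filter = "ctcf_bound",
                          exclude_zf = character(0),
                          n_boot = 1000L, conf = 0.95) {
  keep_ids <- classified$read_id[classified$label %in% read_filter]
  sub <- calls[calls$read_id %in% keep_ids & calls$call != ".", , drop = FALSE]
  region <- zf_region_of(sub$rel_pos, zfmap)
  zf_keep <- !is.na(region) & region %in% zf_numbers()
  sub <- sub[zf_keep, , drop = FALSE]
  sub$region <- region[zf_keep]

  key <- paste(sub$motif_id, sub$region, sep = "\r")
  called <- rowsum(rep(1L, nrow(sub)), key)
  meth <- rowsum(as.integer(sub$call == "M"), key)
  parts <- strsplit(rownames(called), "\r", fixed = TRUE)
  per_motif <- data.frame(
    motif_id = vapply(parts, `[`, "", 1L),
    zf = vapply(parts, `[`, "", 2L),
    n_calls = called[, 1],
    protection = 1 - meth[, 1] / called[, 1],
    stringsAsFactors = FALSE, row.names = NULL
  )

  n_reads_per_motif <- table(unique(
    calls[calls$read_id %in% keep_ids, c("read_id", "motif_id")])$motif_id)
  profile <- do.call(rbind, lapply(zf_numbers(), function(zf) {
    v <- per_motif$protection[per_motif$zf == zf]
    mot <- per_motif$motif_id[per_motif$zf == zf]
    data.frame(
      zf = zf,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n_motifs = length(v),
      n_reads = sum(n_reads_per_motif[mot]),
      excluded = zf %in% exclude_zf || length(v) == 0,
      stringsAsFactors = FALSE
    )
  }))

  # per-motif cluster protection (pooled calls over the cluster's windows)
  cl_of <- stats::setNames(zfmap$cluster[zfmap$type == "zf"],
                           zfmap$region[zfmap$type == "zf"])
  sub$cluster <- cl_of[sub$region]
  keyc <- paste(sub$motif_id, sub$cluster, sep = "\r")
  calledc <- rowsum(rep(1L, nrow(sub)), keyc)
  methc <- rowsum(as.integer(sub$call == "M"), keyc)
  partsc <- strsplit(rownames(calledc), "\r", fixed = TRUE)
  per_motif_cluster <- data.frame(
    motif_id = vapply(partsc, `[`, "", 1L),
    cluster = vapply(partsc, `[`, "", 2L),
    protection = 1 - methc[, 1] / calledc[, 1],
    stringsAsFactors = FALSE, row.names = NULL
  )
  clusters <- do.call(rbind, lapply(unique(per_motif_cluster$cluster),
    function(cl) {
      v <- per_motif_cluster$protection[per_motif_cluster$cluster == cl]
      ci <- boot_ci(v, stats::median, n_boot = n_boot, conf = conf)
      data.frame(cluster = cl, median = stats::median(v), lo = ci[1],
                 hi = ci[2], n_motifs = length(v), stringsAsFactors = FALSE)
    }))
  list(per_motif = per_motif, profile = profile,
       per_motif_cluster = per_motif_cluster, clusters = clusters)
}

#' Estimate the fully protected fraction of CTCF-bound molecules
#'
#' The strict per-read sub-label (zero methylated calls in every ZF window)
#' systematically undercounts fully protected molecules because background
#' methylation of protected sites flips single windows: with an 11-site
#' motif grid and 5% background, barely more than half of truly protected
#' reads survive the strict rule.  The default `"em"` method therefore fits
#' a two-population model by maximum likelihood: labeling rates are
#' estimated from sites whose state is known (core ZF windows are protected
#' in every CTCF read, NDR sites are accessible), and an EM algorithm then
#' estimates the fully protected mixture weight together with per-ZF
#' binding probabilities for the partially protected population, treating
#' peripheral-ZF methylation counts per read as binomial draws under either
#' the protected or the accessible labeling rate.  `method = "raw"` returns
#' the uncorrected sub-label fractions.
#'
#' @param calls per-read calls.
#' @param classified output of [classify_reads()].
#' @param zfmap ZF window map.
#' @param method `"em"` (model-based, default) or `"raw"` (sub-label
#'   fractions).
#' @param thresholds the [classify_thresholds()] used to label the reads;
#'   needed to undo the selection the labeling imposes on the estimated
#'   background and labeling-efficiency rates.
#' @param n_boot bootstrap resamples over reads for the CI.
#' @param conf confidence level.
#' @param max_iter,tol EM controls.
#' @return list with `protected`, `partial`, `ci` (for the protected
#'   fraction), `n_reads`, `method` and fitted nuisance parameters.
#' @export
estimate_protected_fraction <- function(calls, classified, zfmap = zf_map(),
                                        method = c("em", "raw"),
                                        thresholds = classify_thresholds(),
                                        n_boot = 200L, conf = 0.95,
                                        max_iter = 2000L, tol = 1e-6) {
  method <- match.arg(method)
  ctcf <- classified[classified$label == "ctcf_bound", , drop = FALSE]
  n <- nrow(ctcf)
  if (n < 50)
    warning("fewer than 50 CTCF-bound reads; interval will be wide")
  if (n == 0) stop("no CTCF-bound reads")
  if (method == "raw") {
    p <- mean(ctcf$sub_label == "protected")
    idx <- as.integer(ctcf$sub_label == "protected")
    ci <- boot_ci(idx, mean, n_boot = n_boot, conf = conf)
    return(list(protected = p, partial = 1 - p, ci = ci, n_reads = n,
                method = "raw"))
  }

  sub <- calls[calls$read_id %in% ctcf$read_id, , drop = FALSE]
  cz <- .read_zf_counts(sub, zfmap)
  periph <- c("ZF1", "ZF2", "ZF9", "ZF10", "ZF11")
  core <- paste0("ZF", 3:8)
  # Labeling rates from sites of known state: core ZF windows are protected
  # and NDR sites accessible in every CTCF-bound read.  Because the CTCF
  # label itself selects reads with low core and high NDR methylation, the
  # naive rates are truncation-biased; both are estimated by truncated
  # binomial maximum likelihood at the classification thresholds.
  core_m <- rowSums(cz$meth[ctcf$read_id, core, drop = FALSE])
  core_n <- rowSums(cz$called[ctcf$read_id, core, drop = FALSE])
  bg <- .truncated_binom_ml(core_m, core_n, thresholds$core_max,
                            side = "upper")
  region <- zf_region_of(sub$rel_pos, zfmap)
  ndr <- !is.na(region) & region %in% c("NDR_N", "NDR_C") & sub$call != "."
  nd <- sub[ndr, , drop = FALSE]
  ndr_n <- rowsum(rep(1L, nrow(nd)), nd$read_id)
  ndr_m <- rowsum(as.integer(nd$call == "M"), nd$read_id)
  le <- .truncated_binom_ml(ndr_m[, 1], ndr_n[, 1], thresholds$ndr_min,
                            side = "lower")
  bg <- min(max(bg, 1e-4), 0.49)
  le <- min(max(le, bg + 0.05), 1 - 1e-4)

  mm <- cz$meth[ctcf$read_id, periph, drop = FALSE]
  nn <- cz$called[ctcf$read_id, periph, drop = FALSE]

  fit <- .protected_em(mm, nn, bg, le, max_iter = max_iter, tol = tol)
  boot <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    .protected_em(mm[i, , drop = FALSE], nn[i, , drop = FALSE], bg, le,
                  max_iter = 1000L, tol = 1e-5,
                  w_init = fit$w, q_init = fit$q)$w
  })
  a <- (1 - conf) / 2
  list(protected = fit$w, partial = 1 - fit$w,
       ci = unname(stats::quantile(boot, c(a, 1 - a))), n_reads = n,
       method = "em", background = bg, label_efficiency = le,
       q_partial = fit$q, loglik = fit$loglik, iterations = fit$iter)
}

# ML for a binomial rate observed subject to per-read truncation of the
# methylated fraction (side = "upper": only reads with m/n <= thr observed;
# side = "lower": only m/n >= thr).  Corrects the selection bias the read
# classification imposes on the labeling-rate estimates.
.truncated_binom_ml <- function(m, n, thr, side = c("upper", "lower")) {
  side <- match.arg(side)
  keep <- n > 0
  m <- m[keep]
  n <- n[keep]
  nll <- function(p) {
    ll <- m * log(p) + (n - m) * log(1 - p)
    norm <- if (side == "upper")
      stats::pbinom(floor(thr * n + 1e-9), n, p)
    else
      1 - stats::pbinom(ceiling(thr * n - 1e-9) - 1, n, p)
    -sum(ll - log(pmax(norm, 1e-300)))
  }
  stats::optimize(nll, c(1e-4, 1 - 1e-4))$minimum
}

# EM for the protected/partial mixture on per-read peripheral-ZF counts.
# The likelihood ridge between the mixture weight and the per-ZF binding
# probabilities is flat, so convergence is judged on the parameter change
# (tol), not the log-likelihood gain, which stalls long before the ML point.
.protected_em <- function(mm, nn, bg, le, max_iter = 2000L, tol = 1e-6,
                          w_init = 0.5, q_init = NULL) {
  # per-read per-ZF log binomial likelihood under protected / accessible rates
  lA <- mm * log(bg) + (nn - mm) * log(1 - bg)     # window bound
  lB <- mm * log(le) + (nn - mm) * log(1 - le)     # window accessible
  lA[nn == 0] <- 0
  lB[nn == 0] <- 0
  w <- w_init
  q <- if (is.null(q_init)) rep(0.5, ncol(mm)) else q_init
  ll <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    lfull <- rowSums(lA)
    # partial: per-window mixture over bound/accessible
    lmixw <- sweep(lA, 2, log(q), "+")
    lmixu <- sweep(lB, 2, log(1 - q), "+")
    M <- pmax(lmixw, lmixu)
    lpart_w <- M + log(exp(lmixw - M) + exp(lmixu - M))
    lpart_w[nn == 0] <- 0
    lpart <- rowSums(lpart_w)
    m2 <- pmax(log(w) + lfull, log(1 - w) + lpart)
    ll <- sum(m2 + log(exp(log(w) + lfull - m2) + exp(log(1 - w) + lpart - m2)))
    r <- 1 / (1 + exp(log(1 - w) + lpart - log(w) - lfull))
    # posterior a window is bound, within the partial population
    b <- 1 / (1 + exp(lmixu - lmixw))
    b[nn == 0] <- q[col(b)][nn == 0]
    w_new <- min(max(mean(r), 1e-6), 1 - 1e-6)
    q_new <- colSums((1 - r) * b) / max(sum(1 - r), 1e-12)
    q_new <- pmin(pmax(q_new, 1e-6), 1 - 1e-6)
    delta <- max(abs(w_new - w), abs(q_new - q))
    w <- w_new
    q <- q_new
    if (delta < tol && it > 5) break
  }
  list(w = w, q = q, loglik = ll, iter = it)
}

#' Conditional co-binding probabilities between ZFs
#'
#' Within single CTCF-bound molecules, computes
#' `P(ZF_j protected | ZF_i protected)` from per-read per-ZF protection
#' flags (a window is protected when it has at least one call and zero
#' methylated calls).  Cells with fewer than `min_n` jointly observed reads
#' are masked.  The neighbor contrast statistic is the mean over adjacent
#' pairs (|i-j| = 1) minus the mean over distant pairs (|i-j| >= 4),
#' positive when neighboring ZFs co-bind.
#'
#' @param calls per-read calls.
#' @param classified output of [classify_reads()]; only `ctcf_bound` reads
#'   are used.
#' @param zfmap ZF window map.
#' @param min_n minimum joint observations per cell.
#' @param n_boot bootstrap resamples for the contrast CI.
#' @param conf confidence level.
#' @return list with `p` (11 x 11 conditional probability matrix),
#'   `counts`, `neighbor_contrast` and its bootstrap `ci`.
#' @export
cobinding_conditional <- function(calls, classified, zfmap = zf_map(),
                                  min_n = 20L, n_boot = 200L, conf = 0.95) {
  ctcf_ids <- classified$read_id[classified$label == "ctcf_bound"]
  sub <- calls[calls$read_id %in% ctcf_ids, , drop = FALSE]
  cz <- .read_zf_counts(sub, zfmap)
  obs <- cz$called > 0
  prot <- obs & cz$meth == 0

  contrast <- function(prot, obs) {
    P <- matrix(NA_real_, 11, 11, dimnames = list(zf_numbers(), zf_numbers()))
    cnt <- matrix(0L, 11, 11, dimnames = dimnames(P))
    both_obs <- crossprod(obs)                     # reads observing i and j
    i_prot_obs <- crossprod(prot, obs)             # i protected, j observed
    both_prot <- crossprod(prot)
    cnt[] <- both_obs
    ok <- both_obs >= min_n & i_prot_obs > 0
    P[ok] <- both_prot[ok] / i_prot_obs[ok]
    list(p = P, counts = cnt)
  }
  full <- contrast(prot, obs)
  nc_stat <- function(P) {
    d <- abs(row(P) - col(P))
    mean(P[d == 1], na.rm = TRUE) - mean(P[d >= 4], na.rm = TRUE)
  }
  nc <- nc_stat(full$p)
  n <- nrow(prot)
  boot <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    nc_stat(contrast(prot[i, , drop = FALSE], obs[i, , drop = FALSE])$p)
  })
  a <- (1 - conf) / 2
  list(p = full$p, counts = full$counts, neighbor_contrast = nc,
       ci = unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE)))
}

#' Stratify per-motif protection by ChIP enrichment deciles
#'
#' Motifs are ranked by their ChIP score (ties broken deterministically by
#' motif id) and split into deciles; per ZF cluster and decile the median
#' protection is reported with a percentile-bootstrap confidence interval,
#' and the 1st and 10th deciles are compared with a two-tailed
#' Mann-Whitney test.
#'
#' @param per_motif_cluster data.frame `motif_id, cluster, protection`
#'   (e.g. `zf_protection(...)$per_motif_cluster`).
#' @param chip data.frame `motif_id, score`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level.
#' @return list with `strata` (cluster x decile medians and CIs), `tests`
#'   (per-cluster Mann-Whitney p for decile 1 vs 10), `missing_motifs`,
#'   and the decile assignment.  No multiple-testing correction is applied
#'   across clusters; p-values are raw two-tailed.
#' @export
stratify_by_chip <- function(per_motif_cluster, chip, n_boot = 10000L,
                             conf = 0.95) {
  missing <- setdiff(unique(per_motif_cluster$motif_id), chip$motif_id)
  if (length(missing))
    warning(length(missing), " motif id(s) missing from the ChIP table")
  chip <- chip[order(chip$score, chip$motif_id), , drop = FALSE]
  n <- nrow(chip)
  if (n < 100) warning("fewer than 10 motifs per decile")
  chip$decile <- ceiling(10 * seq_len(n) / n)
  dat <- merge(per_motif_cluster, chip[, c("motif_id", "decile")],
               by = "motif_id")
  a <- (1 - conf) / 2
  strata <- do.call(rbind, lapply(split(dat, dat[c("cluster", "decile")]),
    function(d) {
      if (nrow(d) == 0) return(NULL)
      if (nrow(d) < 3) return(NULL)   # too few motifs in this stratum
      ci <- boot_ci(d$protection, stats::median, n_boot = n_boot, conf = conf)
      data.frame(cluster = d$cluster[1], decile = d$decile[1],
                 median = stats::median(d$protection), lo = ci[1], hi = ci[2],
                 n_motifs = nrow(d), stringsAsFactors = FALSE)
    }))
  row.names(strata) <- NULL
  tests <- do.call(rbind, lapply(unique(dat$cluster), function(cl) {
    lo <- dat$protection[dat$cluster == cl & dat$decile == 1]
    hi <- dat$protection[dat$cluster == cl & dat$decile == 10]
    if (length(lo) < 3 || length(hi) < 3) return(NULL)
    exact <- length(lo) <= 50 && length(hi) <= 50 &&
      !anyDuplicated(c(lo, hi))      # exact p is unavailable under ties
    p <- stats::wilcox.test(lo, hi, alternative = "two.sided",
                            exact = exact, correct = TRUE)$p.value
    data.frame(cluster = cl, n_low = length(lo), n_high = length(hi),
               median_low = stats::median(lo), median_high = stats::median(hi),
               p = p, stringsAsFactors = FALSE)
  }))
  list(strata = strata, tests = tests, missing_motifs = missing,
       deciles = chip[, c("motif_id", "decile")])
}

#' Correlate per-motif per-ZF inaccessibility with ChIP enrichment
#'
#' Pearson correlation (two-tailed p via the t approximation) between each
#' protein's ChIP score and per-motif protection at each ZF, typically on
#' the partially protected molecule subset where ZF occupancy varies.
#'
#' @param per_motif_zf data.frame `motif_id, zf, protection`
#'   (e.g. `zf_protection(...)$per_motif`).
#' @param chip data.frame `motif_id, protein, score`.
#' @param min_motifs minimum paired motifs per (protein, ZF).
#' @return data.frame `protein, zf, r, p, n`; zero-variance columns give
#'   `NA` (masked).
#' @export
correlate_chip_zf <- function(per_motif_zf, chip, min_motifs = 30L) {
  out <- list()
  for (prot in unique(chip$protein)) {
    cp <- chip[chip$protein == prot, c("motif_id", "score")]
    for (zf in unique(per_motif_zf$zf)) {
      pz <- per_motif_zf[per_motif_zf$zf == zf, c("motif_id", "protection")]
      d <- merge(pz, cp, by = "motif_id")
      n <- nrow(d)
      if (n < min_motifs) next
      if (stats::sd(d$protection) == 0 || stats::sd(d$score) == 0) {
        out[[length(out) + 1L]] <- data.frame(protein = prot, zf = zf,
                                              r = NA_real_, p = NA_real_,
                                              n = n)
        next
      }
      ct <- stats::cor.test(d$protection, d$score, method = "pearson")
      out[[length(out) + 1L]] <- data.frame(protein = prot, zf = zf,
                                            r = unname(ct$estimate),
                                            p = ct$p.value, n = n,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
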