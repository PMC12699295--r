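#' Detect discrete force rips in an unzipping curve
#'
#' The local baseline is a rolling median over `baseline_window_bp`.
#' Candidate peaks are local maxima whose excess over baseline reaches
#' `prominence_threshold_pN` and that collapse back toward baseline within
#' `drop_window_bp` (excess falls below half the threshold), the sawtooth
#' signature of a rupturing protein-DNA contact.  Peaks closer than
#' `merge_bp` are merged keeping the higher.
#'
#' @param curve data.frame `bp, force_pN` (bp strictly increasing).
#' @param prominence_threshold_pN minimum excess over baseline (pN).
#' @param baseline_window_bp rolling-median window (bp, odd).
#' @param drop_window_bp maximum bp for the post-peak collapse.
#' @param merge_bp peaks closer than this merge.
#' @return data.frame of events `position_bp, force_pN, prominence_pN`
#'   (possibly zero rows).
#' @export
detect_rips <- function(curve, prominence_threshold_pN = 2,
                        baseline_window_bp = 31L, drop_window_bp = 3L,
                        merge_bp = 5L) {
  bp <- curve$bp
  f <- curve$force_pN
  n <- length(f)
  if (n < 50) stop("curve must span at least 50 bp")
  k <- baseline_window_bp
  if (k %% 2 == 0) k <- k + 1L
  base <- stats::runmed(f, k, endrule = "median")
  excess <- f - base
  cand <- which(excess >= prominence_threshold_pN)
  # local maxima of the excess among candidates
  cand <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - 2L)
    hi <- min(n, i + 2L)
    excess[i] >= max(excess[lo:hi])
  }, logical(1))]
  # require a collapse back toward baseline shortly after the peak
  cand <- cand[vapply(cand, function(i) {
    hi <- min(n, i + drop_window_bp)
    any(excess[(i + 1L):hi] <= prominence_threshold_pN / 2)
  }, logical(1))]
  if (length(cand) == 0)
    return(data.frame(position_bp = numeric(0), force_pN = numeric(0),
                      prominence_pN = numeric(0)))
  # merge peaks closer than merge_bp, keeping the higher
  cand <- cand[order(bp[cand])]
  keep <- logical(length(cand))
  i <- 1L
  while (i <= length(cand)) {
    grp <- i
    while (grp < length(cand) && bp[cand[grp + 1L]] - bp[cand[grp]] < merge_bp)
      grp <- grp + 1L
    idx <- cand[i:grp]
    keep[i:grp] <- FALSE
    keep[i - 1L + which.max(f[idx])] <- TRUE
    i <- grp + 1L
  }
  cand <- cand[keep]
  data.frame(position_bp = bp[cand], force_pN = f[cand],
             prominence_pN = excess[cand])
}

#' Assign rupture events to zinc-finger regions
#'
#' Events within the motif (plus a margin) are labeled by the terminus
#' whose ZF block they fall in: with the package's coordinate convention
#' (negative bp = N-terminal-protein side, motif center at 0) events at or
#' below the center belong to the N-terminal ZF region and events above it
#' to the C-terminal one.  Events farther than `margin_bp` outside the
#' motif are `off_motif`.  The labeling is equivariant: flipping the
#' orientation and mirroring the bp coordinates swaps the N/C labels
#' exactly.
#'
#' @param events data.frame with `position_bp` (e.g. from
#'   [detect_rips()]).
#' @param motif_span length-2 motif extent in bp.
#' @param orientation `"N_terminal"` or `"C_terminal"`: the side from
#'   which the fork approaches; recorded on the output (the proximal
#'   region is the one probed first).
#' @param margin_bp margin outside the motif still assigned to a ZF
#'   region.
#' @return the events with added `region` (`N_ZF_region`, `C_ZF_region`,
#'   `off_motif`), `orientation` and `proximal` (logical: the region
#'   encountered first by the fork).
#' @export
assign_region <- function(events, motif_span = c(-16L, 16L),
                          orientation = c("N_terminal", "C_terminal"),
                          margin_bp = 20L) {
  orientation <- match.arg(orientation)
  center <- floor(mean(motif_span))
  pos <- events$position_bp
  # the motif center belongs to the terminus probed first by the fork, so
  # that mirroring coordinates while flipping orientation swaps labels
  n_side <- if (orientation == "N_terminal") pos <= center else pos < center
  region <- ifelse(pos < motif_span[1] - margin_bp |
                     pos > motif_span[2] + margin_bp, "off_motif",
                   ifelse(n_side, "N_ZF_region", "C_ZF_region"))
  events$region <- region
  events$orientation <- orientation
  first <- if (orientation == "N_terminal") "N_ZF_region" else "C_ZF_region"
  events$proximal <- region == first
  events
}

#' Summarize rupture forces by condition
#'
#' @param events data.frame with `force_pN` and `condition`.
#' @return data.frame per condition: `mean_pN`, `se_pN` (SD/sqrt(n)), `n`,
#'   `small_n` flag (n < 3).
#' @export
summarize_forces <- function(events) {
  out <- do.call(rbind, lapply(split(events, events$condition), function(d) {
    n <- nrow(d)
    data.frame(condition = d$condition[1],
               mean_pN = mean(d$force_pN),
               se_pN = if (n > 1) stats::sd(d$force_pN) / sqrt(n) else 0,
               n = n, small_n = n < 3, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$small_n)) warning("condition(s) with fewer than 3 events")
  out
}

# two-component Gaussian EM; quantile-grid initialization over restarts
.gmm2_em <- function(x, n_restarts = 20L, variance_model = "equal",
                     min_sd = 0.05, max_iter = 1000L, tol = 1e-8) {
  n <- length(x)
  best <- NULL
  qgrid <- seq(0.1, 0.9, length.out = n_restarts)
  for (r in seq_len(n_restarts)) {
    cut <- stats::quantile(x, qgrid[r])
    lo <- x[x <= cut]
    hi <- x[x > cut]
    if (length(lo) < 2 || length(hi) < 2) next
    mu <- c(mean(lo), mean(hi))
    s <- rep(max(stats::sd(x) / 2, min_sd), 2)
    w <- c(length(lo), length(hi)) / n
    ll_old <- -Inf
    ll <- -Inf
    g <- NULL
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
      tot <- pmax(d1 + d2, 1e-300)
      g <- d1 / tot
      ll <- sum(log(tot))
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
      w <- pmax(c(mean(g), 1 - mean(g)), 1e-6)
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      if (variance_model == "equal") {
        sv <- sqrt((sum(g * (x - mu[1])^2) +
                      sum((1 - g) * (x - mu[2])^2)) / n)
        s <- rep(max(sv, min_sd), 2)
      } else {
        s <- pmax(c(sqrt(sum(g * (x - mu[1])^2) / sum(g)),
                    sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))),
                  min_sd)
      }
    }
    if (any(s <= min_sd + 1e-12) && variance_model == "free") next  # degenerate
    if (is.null(best) || ll > best$loglik)
      best <- list(mu = mu, s = s, w = w, loglik = ll, posterior_low = g)
  }
  best
}

#' Decompose rupture forces into two Gaussian populations
#'
#' Fits a two-component Gaussian mixture by EM (20 quantile-initialized
#' restarts, equal component variances by default for stability with
#' small high-force populations) and compares it against a one-component
#' fit by BIC.  The high-force fraction is the weight of the upper-mean
#' component, set to 0 when a single component is preferred; membership is
#' the posterior-0.5 rule.
#'
#' @param forces rupture forces (pN), at least 20.
#' @param seed optional RNG seed (the initialization grid is
#'   deterministic; the seed only matters for downstream use).
#' @param n_restarts EM restarts.
#' @param variance_model `"equal"` or `"free"`.
#' @param min_sd component SD floor (pN); free-variance components at the
#'   floor are treated as degenerate and restarted.
#' @return object of class `force_mixture`: `means_pN`, `sds_pN`,
#'   `weights` (ascending means), `se_means_pN`, `high_fraction`
#'   (BIC-gated), `weight_high` (ungated upper-component weight),
#'   `membership` (`"low"`/`"high"` per event), `posterior_high`,
#'   `prefer_two`, `bic_one`, `bic_two`, `loglik`.
#' @export
fit_force_mixture <- function(forces, seed = NULL, n_restarts = 20L,
                              variance_model = c("equal", "free"),
                              min_sd = 0.05) {
  variance_model <- match.arg(variance_model)
  x <- as.numeric(forces)
  n <- length(x)
  if (n < 20) stop("need at least 20 events for the mixture fit")
  if (!is.null(seed)) set.seed(seed)
  fit <- .gmm2_em(x, n_restarts = n_restarts,
                  variance_model = variance_model, min_sd = min_sd)
  if (is.null(fit)) stop("all mixture restarts degenerated")
  # order components by ascending mean
  ord <- order(fit$mu)
  mu <- fit$mu[ord]
  s <- fit$s[ord]
  w <- fit$w[ord]
  post_low <- if (ord[1] == 1) fit$posterior_low else 1 - fit$posterior_low
  post_high <- 1 - post_low
  p_two <- if (variance_model == "equal") 4 else 5
  ll1 <- sum(stats::dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)),
                          log = TRUE))
  bic_two <- -2 * fit$loglik + p_two * log(n)
  bic_one <- -2 * ll1 + 2 * log(n)
  prefer_two <- bic_two < bic_one
  n_eff <- c(sum(post_low), sum(post_high))
  structure(list(
    means_pN = mu, sds_pN = s, weights = w,
    se_means_pN = s / sqrt(pmax(n_eff, 1)),
    weight_high = w[2],
    high_fraction = if (prefer_two) w[2] else 0,
    membership = ifelse(post_high >= 0.5, "high", "low"),
    posterior_high = post_high,
    prefer_two = prefer_two, bic_one = bic_one, bic_two = bic_two,
    loglik = fit$loglik, n = n
  ), class = "force_mixture")
}

#' @export
print.force_mixture <- function(x, ...) {
  cat("Two-component rupture-force mixture (n =", x$n, ")\n")
  cat(sprintf("  low : %.2f +/- %.2f pN (w = %.3f)\n", x$means_pN[1],
              x$se_means_pN[1], x$weights[1]))
  cat(sprintf("  high: %.2f +/- %.2f pN (w = %.3f)\n", x$means_pN[2],
              x$se_means_pN[2], x$weights[2]))
  cat("  two components preferred by BIC:", x$prefer_two,
      " high-force fraction:", round(x$high_fraction, 4), "\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs.  For
#' `n + m <= 12` the two-tailed p-value is exact, by enumerating all
#' `choose(n+m, n)` assignments of the pooled sample; otherwise it uses
#' the asymptotic Kolmogorov distribution with effective sample size
#' `n m / (n + m)`.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `D`, `p`, `n`, `m`, `method`.
#' @export
ks_two_sample <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(n >= 2, m >= 2)
  ks_D <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
    Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
    max(abs(Fx - Fy))
  }
  D <- ks_D(x, y)
  if (n + m <= 12) {
    pool <- c(x, y)
    idx <- utils::combn(n + m, n)
    Ds <- apply(idx, 2, function(i) ks_D(pool[i], pool[-i]))
    p <- mean(Ds >= D - 1e-12)
    method <- "exact enumeration"
  } else {
    ne <- n * m / (n + m)
    lambda <- sqrt(ne) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(max(p, 0), 1)
    method <- "asymptotic"
  }
  list(D = D, p = p, n = n, m = m, method = method)
}
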