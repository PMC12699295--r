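#' Estimate a 1D diffusion coefficient from a trajectory
#'
#' Computes the mean squared displacement over overlapping pairs at lags
#' `1..max_lag` and fits `MSD(tau) = 2 D tau + 2 sigma_loc^2` by weighted
#' least squares, the intercept absorbing the localization error.  Weights
#' default to `(n - lag) / lag`, an approximation to the inverse variance
#' of the overlapping-pair MSD estimator (longer lags average fewer,
#' more correlated pairs); `method = "ols"` gives the unweighted fallback.
#' Negative fitted D is clipped to 0 and flagged.
#'
#' @param traj data.frame with `time_s` and `pos_kb` for one particle.
#' @param max_lag number of lags used (default 4; at most n/4).
#' @param method `"wls"` or `"ols"`.
#' @return list with `D` (kb^2/s), `se`, `intercept`, `msd`
#'   (data.frame lag_s, msd, n_pairs), `clipped`.
#' @export
estimate_diffusion <- function(traj, max_lag = 4L, method = c("wls", "ols")) {
  method <- match.arg(method)
  x <- traj$pos_kb
  n <- length(x)
  if (n < 20) stop("trajectory must have at least 20 frames")
  max_lag <- min(max_lag, n %/% 4L)
  if (max_lag < 2) stop("too few frames for the requested lags")
  dt <- stats::median(diff(traj$time_s))
  msd <- vapply(seq_len(max_lag), function(L) mean((x[-(1:L)] - x[1:(n - L)])^2),
                numeric(1))
  n_pairs <- n - seq_len(max_lag)
  lag_s <- seq_len(max_lag) * dt
  w <- if (method == "wls") n_pairs / seq_len(max_lag) else rep(1, max_lag)
  fit <- stats::lm(msd ~ lag_s, weights = w)
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2] / 2
  D <- slope / 2
  clipped <- D < 0
  list(D = max(D, 0), se = se, intercept = unname(stats::coef(fit)[1]),
       msd = data.frame(lag_s = lag_s, msd = msd, n_pairs = n_pairs),
       clipped = clipped)
}

#' Ensemble diffusion coefficient over many trajectories
#'
#' @param trajectories data.frame `particle_id, time_s, pos_kb`.
#' @param ... passed to [estimate_diffusion()].
#' @return list with `D_mean`, `D_sd`, `D_se`, `n`, and per-particle `D`.
#' @export
ensemble_diffusion <- function(trajectories, ...) {
  per <- vapply(split(trajectories, trajectories$particle_id),
                function(tr) estimate_diffusion(tr, ...)$D, numeric(1))
  list(D_mean = mean(per), D_sd = stats::sd(per),
       D_se = stats::sd(per) / sqrt(length(per)), n = length(per), D = per)
}

#' Dwell-time survival analysis
#'
#' Builds the survival curve (1 - CDF) of binding dwell times.  When any
#' event is flagged censored (the trace ended before unbinding) the
#' Kaplan-Meier estimator is used; otherwise the empirical survival
#' function.  The median is the smallest time at which survival drops to
#' 0.5 or below.  Without censoring its confidence interval is the exact
#' distribution-free order-statistic interval (a percentile bootstrap of
#' a small-sample median undercovers: ~90% observed at n = 22 for a
#' nominal 95%); with censoring, a percentile bootstrap of the
#' Kaplan-Meier median over events is used.
#'
#' @param durations event dwell durations (s).
#' @param censored logical flags (TRUE = censored); NULL for none.
#' @param n_boot bootstrap resamples (censored path only).
#' @param conf confidence level.
#' @return list of class `dwell_table`: `median`, `ci`, `surv`
#'   (data.frame time, surv), `n`, `n_censored`.
#' @export
dwell_survival <- function(durations, censored = NULL, n_boot = 10000L,
                           conf = 0.95) {
  n <- length(durations)
  if (n < 5) stop("need at least 5 dwell events")
  if (is.null(censored)) censored <- rep(FALSE, n)
  stopifnot(length(censored) == n)
  if (all(censored)) stop("all events censored; no dwell information")

  km_median <- function(dur, cens) {
    if (any(cens)) {
      f <- survival::survfit(survival::Surv(dur, !cens) ~ 1)
      tt <- f$time
      ss <- f$surv
    } else {
      tt <- sort(dur)
      ss <- 1 - seq_along(tt) / length(tt)
    }
    i <- which(ss <= 0.5)
    if (length(i) == 0) return(NA_real_)
    tt[min(i)]
  }
  med <- km_median(durations, censored)
  a <- (1 - conf) / 2
  if (any(censored)) {
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      km_median(durations[i], censored[i])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  } else {
    # exact nonparametric median CI from binomial order statistics
    s <- sort(durations)
    j <- max(stats::qbinom(a, n, 0.5), 1L)
    k <- min(stats::qbinom(1 - a, n, 0.5) + 1L, n)
    ci <- c(s[j], s[k])
  }
  if (any(censored)) {
    f <- survival::survfit(survival::Surv(durations, !censored) ~ 1)
    surv <- data.frame(time = c(0, f$time), surv = c(1, f$surv))
  } else {
    tt <- sort(durations)
    surv <- data.frame(time = c(0, tt), surv = c(1, 1 - seq_along(tt) / n))
  }
  structure(list(median = med, ci = ci, surv = surv, n = n,
                 n_censored = sum(censored)),
            class = "dwell_table")
}

#' Detect colocalization intervals between two trajectories
#'
#' Frames (matched on time) where the two particles are within
#' `dist_threshold_kb` are contact frames; single-frame gaps are bridged
#' and runs of at least `min_frames` become contact intervals.  The
#' operation is symmetric in its two arguments.
#'
#' @param mobile,target data.frames `time_s, pos_kb` (optionally
#'   `channel`).
#' @param dist_threshold_kb colocalization distance (kb), default 0.3
#'   (roughly the diffraction limit).
#' @param min_frames minimum contact run length.
#' @return data.frame of contact intervals `start_s, end_s, n_frames`.
#' @export
detect_colocalization <- function(mobile, target, dist_threshold_kb = 0.3,
                                  min_frames = 2L) {
  if (!is.null(mobile$channel) && !is.null(target$channel) &&
      length(unique(c(mobile$channel[1], target$channel[1]))) == 1L)
    warning("both trajectories are from the same imaging channel")
  m <- merge(mobile[, c("time_s", "pos_kb")],
             target[, c("time_s", "pos_kb")], by = "time_s",
             suffixes = c("_m", "_t"))
  if (nrow(m) == 0) stop("trajectories have no overlapping time support")
  m <- m[order(m$time_s), ]
  contact <- abs(m$pos_kb_m - m$pos_kb_t) <= dist_threshold_kb
  # bridge single-frame gaps
  if (length(contact) >= 3) {
    gap <- which(!contact[-c(1, length(contact))]) + 1L
    bridge <- gap[contact[gap - 1L] & contact[gap + 1L]]
    contact[bridge] <- TRUE
  }
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_s = m$time_s[starts[keep]],
             end_s = m$time_s[ends[keep]],
             n_frames = r$lengths[keep])
}

#' Classify an encounter as bounce or dock, and count bypasses
#'
#' An encounter docks when its longest contact interval lasts at least
#' `dock_threshold_s`; otherwise it bounces.  A bypass is a crossing of
#' the target position by the mobile particle while not in contact
#' (expected absent for CTCF-blocking particles).
#'
#' @param contacts output of [detect_colocalization()].
#' @param mobile,target the trajectories (for bypass counting; matched on
#'   time).
#' @param dock_threshold_s docking threshold in seconds (default 10).
#' @return list with `outcome` (`"dock"`, `"bounce"`, or `"no_contact"`),
#'   `longest_contact_s`, `colocalized_s` (total), `bypass_count`.
#' @export
classify_encounter <- function(contacts, mobile = NULL, target = NULL,
                               dock_threshold_s = 10) {
  longest <- if (nrow(contacts)) max(contacts$end_s - contacts$start_s) else 0
  total <- if (nrow(contacts)) sum(contacts$end_s - contacts$start_s) else 0
  outcome <- if (nrow(contacts) == 0) "no_contact"
             else if (longest >= dock_threshold_s) "dock" else "bounce"
  bypass <- NA_integer_
  if (!is.null(mobile) && !is.null(target)) {
    m <- merge(mobile[, c("time_s", "pos_kb")],
               target[, c("time_s", "pos_kb")], by = "time_s",
               suffixes = c("_m", "_t"))
    m <- m[order(m$time_s), ]
    in_contact <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(contacts)))
      in_contact <- in_contact |
        (m$time_s >= contacts$start_s[i] & m$time_s <= contacts$end_s[i])
    d <- m$pos_kb_m - m$pos_kb_t
    crossing <- d[-1] * d[-length(d)] < 0
    free <- !in_contact[-1] & !in_contact[-length(in_contact)]
    bypass <- sum(crossing & free)
  }
  list(outcome = outcome, longest_contact_s = longest,
       colocalized_s = total, bypass_count = bypass)
}

#' Signed distance to the nearest motif
#'
#' For each particle position, the signed distance to the nearest motif
#' (particle minus motif); equidistant ties resolve to the smaller
#' absolute distance and then to the leftmost motif.  The median is
#' reported with a percentile-bootstrap confidence interval.
#'
#' @param positions particle positions (bp).
#' @param motifs motif positions (bp), at least one.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return list with `distances`, `median`, `ci`, `n`.
#' @export
nearest_motif_distance <- function(positions, motifs, n_boot = 10000L,
                                   conf = 0.95) {
  stopifnot(length(motifs) >= 1, all(is.finite(positions)),
            all(is.finite(motifs)))
  motifs <- sort(motifs)
  dist <- vapply(positions, function(p) {
    d <- p - motifs
    i <- order(abs(d), motifs)[1]
    d[i]
  }, numeric(1))
  med <- stats::median(dist)
  ci <- boot_ci(dist, stats::median, n_boot = n_boot, conf = conf)
  list(distances = dist, median = med, ci = ci, n = length(dist))
}
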