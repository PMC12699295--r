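#' Convert a force trace to fork position
#'
#' Applies a strictly monotone calibration map pointwise.  The default map
#' is affine (`bp = a * pN + b`); an arbitrary function can be supplied and
#' is checked for monotonicity over the observed range.  Identity passes
#' fork-position traces through unchanged.
#'
#' @param trace data.frame `time_s, value, channel`.
#' @param a,b affine coefficients (used when `map` is NULL).
#' @param map optional function pN -> bp, strictly monotone over the
#'   observed force range.
#' @param range optional length-2 valid input range; out-of-range values
#'   are clipped with a warning.
#' @return the trace with `value` converted and `channel = "fork_bp"`.
#' @export
calibrate_force_to_bp <- function(trace, a = 1, b = 0, map = NULL,
                                  range = NULL) {
  x <- trace$value
  if (!is.null(range)) {
    out <- x < range[1] | x > range[2]
    if (any(out)) {
      warning(sum(out), " force value(s) outside the calibration range; clipped")
      x <- pmin(pmax(x, range[1]), range[2])
    }
  }
  if (is.null(map)) {
    if (a == 0) stop("affine calibration must have nonzero slope")
    y <- a * x + b
  } else {
    grid <- sort(unique(stats::quantile(x, seq(0, 1, length.out = 101))))
    fg <- map(grid)
    d <- diff(fg)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      stop("calibration map is not strictly monotone over the observed range")
    y <- map(x)
  }
  trace$value <- y
  trace$channel <- "fork_bp"
  trace
}

#' Segment a fork trace into bound and unbound intervals
#'
#' Protein binding suppresses fork fluctuations, so bound intervals are
#' detected as runs of low rolling variance: the trace is cut into
#' consecutive windows of `window_s`, windows whose variance is at most
#' `var_ratio_threshold` times the unbound reference variance (an upper
#' quantile of the window variances) are marked bound, adjacent bound
#' windows are merged, and intervals shorter than `min_windows` are
#' dropped.
#'
#' @param trace data.frame `time_s, value` (uniformly sampled).
#' @param window_s window length in seconds.
#' @param var_ratio_threshold bound/unbound variance ratio cut.
#' @param min_windows minimum bound interval length in windows.
#' @param ref_quantile quantile of window variances used as the unbound
#'   reference.
#' @return data.frame of bound intervals `start_s, end_s, start_idx,
#'   end_idx` (possibly zero rows, with a `diagnostic` attribute).
#' @export
segment_bound_region <- function(trace, window_s = 0.2,
                                 var_ratio_threshold = 0.5,
                                 min_windows = 5L, ref_quantile = 0.95) {
  x <- trace$value
  dt <- stats::median(diff(trace$time_s))
  w <- max(2L, round(window_s / dt))
  n_win <- length(x) %/% w
  if (n_win < 10) stop("trace must span at least 10 windows")
  m <- matrix(x[seq_len(n_win * w)], nrow = w)
  v <- apply(m, 2, stats::var)
  ref <- stats::quantile(v, ref_quantile)
  bound <- v <= var_ratio_threshold * ref
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_windows
  out <- data.frame(
    start_idx = (starts[keep] - 1L) * w + 1L,
    end_idx = ends[keep] * w
  )
  out$start_s <- trace$time_s[out$start_idx]
  out$end_s <- trace$time_s[out$end_idx]
  out <- out[, c("start_s", "end_s", "start_idx", "end_idx")]
  if (nrow(out) == 0)
    attr(out, "diagnostic") <- "no bound interval found below the variance threshold"
  out
}

# kmeans++-style seeding of K means on (a subsample of) x
kmeanspp_means <- function(x, K, max_points = 20000L) {
  if (length(x) > max_points) x <- x[sample.int(length(x), max_points)]
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1)]
  if (K > 1) {
    d2 <- (x - centers[1])^2
    for (k in 2:K) {
      p <- d2 / sum(d2)
      centers[k] <- x[sample.int(length(x), 1, prob = p)]
      d2 <- pmin(d2, (x - centers[k])^2)
    }
  }
  # a few Lloyd refinement passes
  for (it in 1:5) {
    assign <- max.col(-abs(outer(x, centers, "-")))
    for (k in seq_len(K)) {
      xk <- x[assign == k]
      if (length(xk) > 0) centers[k] <- mean(xk)
    }
  }
  sort(centers)
}

#' Fit a Gaussian-emission hidden Markov model by Baum-Welch EM
#'
#' Fits state means, SDs, initial probabilities and the per-sample
#' transition matrix by expectation-maximization, with multiple random
#' restarts seeded by kmeans++-style mean initialization; the restart with
#' the best log-likelihood is kept and states are relabeled in ascending
#' mean order.  The log-likelihood is non-decreasing across iterations.
#' Restarts that collapse a state (vanishing SD or near-zero expected
#' count) are discarded; if every restart degenerates an error is raised.
#'
#' Several traces can be fitted jointly by passing a list of numeric
#' vectors: sufficient statistics are accumulated per trace so transitions
#' never bridge trace boundaries.
#'
#' @param x numeric vector of observations, or a list of vectors.
#' @param K number of states.
#' @param n_restarts random restarts.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood gain).
#' @param seed optional integer seed for reproducible restarts.
#' @param self_prob initial self-transition probability.
#' @param min_sigma_frac SD floor as a fraction of the data range.
#' @return object of class `hmm_model`: `K, mu, sigma, pi0, A, loglik,
#'   loglik_history, bic, n_obs, n_params, iterations, converged`.
#' @export
fit_hmm <- function(x, K, n_restarts = 10L, max_iter = 500L, tol = 1e-6,
                    seed = NULL, self_prob = 0.95, min_sigma_frac = 1e-6) {
  xs <- if (is.list(x)) lapply(x, as.numeric) else list(as.numeric(x))
  n_tot <- sum(lengths(xs))
  if (n_tot < 10 * K) stop("need at least 10*K samples to fit K states")
  allx <- unlist(xs, use.names = FALSE)
  sigma_floor <- max(min_sigma_frac * diff(range(allx)), 1e-12)
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  n_degenerate <- 0L
  for (r in seq_len(n_restarts)) {
    mu <- kmeanspp_means(allx, K)
    sigma <- rep(max(stats::sd(allx) / max(K, 1), sigma_floor), K)
    A <- matrix((1 - self_prob) / max(K - 1, 1), K, K)
    diag(A) <- if (K == 1) 1 else self_prob
    pi0 <- rep(1 / K, K)
    ll_old <- -Inf
    ll <- -Inf
    ll_hist <- numeric(0)
    converged <- FALSE
    degenerate <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      g_sum <- g_x <- g_x2 <- numeric(K)
      xi <- matrix(0, K, K)
      g1 <- numeric(K)
      ll <- 0
      for (xv in xs) {
        e <- hmm_estep(xv, mu, sigma, A, pi0)
        ll <- ll + e$loglik
        g_sum <- g_sum + e$gamma_sum
        g_x <- g_x + e$gamma_x
        g_x2 <- g_x2 + e$gamma_x2
        xi <- xi + e$xi_sum
        g1 <- g1 + e$gamma1
      }
      ll_hist <- c(ll_hist, ll)
      if (any(g_sum < 1e-3)) { degenerate <- TRUE; break }
      mu_new <- g_x / g_sum
      var_new <- g_x2 / g_sum - mu_new^2
      if (any(var_new < 0)) var_new <- pmax(var_new, 0)
      sigma_new <- pmax(sqrt(var_new), sigma_floor)
      if (K > 1) {
        rs <- rowSums(xi)
        A_new <- xi / ifelse(rs > 0, rs, 1)
        A_new[rs == 0, ] <- 1 / K
      } else {
        A_new <- matrix(1, 1, 1)
      }
      pi_new <- g1 / sum(g1)
      mu <- mu_new; sigma <- sigma_new; A <- A_new; pi0 <- pi_new
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    if (degenerate) { n_degenerate <- n_degenerate + 1L; next }
    if (is.null(best) || ll > best$loglik) {
      best <- list(mu = mu, sigma = sigma, A = A, pi0 = pi0, loglik = ll,
                   loglik_history = ll_hist, iterations = iter,
                   converged = converged)
    }
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts degenerated; reduce K")
  ord <- order(best$mu)
  n_params <- K^2 + 2 * K - 1
  structure(list(
    K = K, mu = best$mu[ord], sigma = best$sigma[ord],
    pi0 = best$pi0[ord], A = best$A[ord, ord, drop = FALSE],
    loglik = best$loglik, loglik_history = best$loglik_history,
    bic = -2 * best$loglik + n_params * log(n_tot),
    n_obs = n_tot, n_params = n_params,
    iterations = best$iterations, converged = best$converged,
    n_degenerate_restarts = n_degenerate
  ), class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("Gaussian-emission HMM with", x$K, "states on", x$n_obs, "samples\n")
  cat("  means (bp):", paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat("  sds   (bp):", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat("  logLik:", format(x$loglik), " BIC:", format(x$bic), "\n")
  invisible(x)
}

#' Select the number of HMM states by BIC
#'
#' Fits each candidate K and picks the minimizer of
#' `BIC = -2 logL + p log(n)` with `p = K^2 + 2K - 1` free parameters;
#' ties break toward smaller K.
#'
#' @param x observations (vector or list of vectors).
#' @param K_range candidate state counts (subset of 1..8).
#' @param ... passed to [fit_hmm()].
#' @param seed optional seed, reused for every K.
#' @return list with `K` (selected), `bic` (named vector), and `model`
#'   (the selected fit).
#' @export
select_num_states <- function(x, K_range = 1:6, seed = NULL, ...) {
  stopifnot(all(K_range >= 1), all(K_range <= 8))
  K_range <- sort(unique(as.integer(K_range)))
  fits <- lapply(K_range, function(K)
    tryCatch(fit_hmm(x, K, seed = seed, ...), error = function(e) NULL))
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, numeric(1))
  names(bics) <- paste0("K", K_range)
  best <- which(bics == min(bics))[1]   # ties toward smaller K
  list(K = K_range[best], bic = bics, model = fits[[best]])
}

#' Viterbi decoding of the most probable state path
#'
#' Dynamic-programming decoding with ties broken toward the lower state
#' index; dwell segments are extracted by run-length encoding.
#'
#' @param model a fitted [fit_hmm()] model.
#' @param x observations (vector, or list for several traces).
#' @param sample_rate_hz sampling rate used to express dwells in seconds.
#' @return for a vector input, a list of class `state_path` with `states`
#'   (per-sample), `dwells`, `K` and `sample_rate_hz`; for a list input, a
#'   list of such objects.
#' @export
viterbi_decode <- function(model, x, sample_rate_hz = 1) {
  stopifnot(inherits(model, "hmm_model"))
  decode1 <- function(xv) {
    p <- hmm_viterbi(as.numeric(xv), model$mu, model$sigma, model$A,
                     model$pi0)
    structure(list(states = p,
                   dwells = path_dwells(p, sample_rate_hz),
                   K = model$K, sample_rate_hz = sample_rate_hz),
              class = "state_path")
  }
  if (is.list(x)) lapply(x, decode1) else decode1(x)
}

#' Map decoded states to fork positions
#'
#' Pools the samples assigned to each state and reports their
#' maximum-likelihood Gaussian fit (sample mean and SD with denominator
#' n), relabeling states I, II, ... in ascending position order.
#'
#' @param path a `state_path` (or list of them, pooled).
#' @param x the matching observations (vector or list).
#' @param min_samples states with fewer pooled samples are flagged.
#' @return data.frame `state, conformation, mean_bp, sd_bp, n_samples,
#'   flagged`.
#' @export
map_states_to_positions <- function(path, x, min_samples = 100L) {
  if (inherits(path, "state_path")) {
    paths <- list(path)
    xs <- list(as.numeric(x))
  } else {
    paths <- path
    xs <- lapply(x, as.numeric)
  }
  K <- paths[[1]]$K
  st <- unlist(lapply(paths, `[[`, "states"))
  xv <- unlist(xs)
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    v <- xv[st == k]
    n <- length(v)
    m <- if (n > 0) mean(v) else NA_real_
    s <- if (n > 0) sqrt(sum((v - m)^2) / n) else NA_real_
    data.frame(state = k, mean_bp = m, sd_bp = s, n_samples = n)
  }))
  out <- out[order(out$mean_bp, out$state), ]
  out$conformation <- as.character(utils::as.roman(seq_len(nrow(out))))
  out$flagged <- out$n_samples < min_samples |
    (!is.na(out$sd_bp) & out$sd_bp == 0)
  rownames(out) <- NULL
  out[, c("state", "conformation", "mean_bp", "sd_bp", "n_samples", "flagged")]
}

#' Ensemble summary: occupancy, lifetimes and transition rates
#'
#' Occupancy is the fraction of samples per state.  Lifetimes are mean
#' dwell durations with the first and last (boundary-truncated) dwell of
#' every trace excluded, since truncation biases lifetimes downward.
#' Transition rates are `k_ij = (transitions i -> j) / (total time in i)`;
#' expressed as a generator its diagonal satisfies
#' `k_ii = -sum_j k_ij`.
#'
#' @param path a `state_path` or list of them (pooled).
#' @param min_dwells states with fewer complete dwells get their rate
#'   estimates flagged.
#' @return object of class `ensemble_summary`: data.frame `per_state`
#'   (occupancy, lifetime_ms, n_dwells, visit_count, flagged), matrix
#'   `rate_matrix` (1/s), `transition_counts`, `sequentiality`, `n_samples`.
#' @export
ensemble_stats <- function(path, min_dwells = 20L) {
  paths <- if (inherits(path, "state_path")) list(path) else path
  K <- paths[[1]]$K
  fs <- paths[[1]]$sample_rate_hz
  st_all <- unlist(lapply(paths, `[[`, "states"))
  n_tot <- length(st_all)
  occupancy <- tabulate(st_all, nbins = K) / n_tot

  dw <- do.call(rbind, lapply(paths, function(p) {
    d <- p$dwells
    if (nrow(d) > 2) d[-c(1, nrow(d)), ] else d[0, ]
  }))
  trans <- matrix(0, K, K)
  for (p in paths) {
    s <- p$states
    if (length(s) > 1) {
      from <- s[-length(s)]
      to <- s[-1]
      chg <- from != to
      if (any(chg))
        trans <- trans + unclass(table(factor(from[chg], levels = 1:K),
                                       factor(to[chg], levels = 1:K)))
    }
  }
  time_in <- tabulate(st_all, nbins = K) / fs
  rate <- trans / ifelse(time_in > 0, time_in, NA)
  per_state <- do.call(rbind, lapply(seq_len(K), function(k) {
    dk <- dw$duration_s[dw$state == k]
    data.frame(
      state = k,
      occupancy = occupancy[k],
      lifetime_ms = if (length(dk)) mean(dk) * 1000 else NA_real_,
      n_dwells = length(dk),
      visit_count = sum(trans[, k]),
      flagged = length(dk) < min_dwells
    )
  }))
  seq_sc <- sequentiality_score(paths)
  structure(list(per_state = per_state, rate_matrix = rate,
                 transition_counts = trans,
                 sequentiality = seq_sc$score, n_samples = n_tot,
                 sample_rate_hz = fs),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Conformational ensemble over", x$n_samples, "samples\n")
  print(transform(x$per_state, occupancy = round(occupancy, 4),
                  lifetime_ms = round(lifetime_ms, 2)))
  cat("sequentiality:", round(x$sequentiality, 4), "\n")
  invisible(x)
}

#' Continuous-time rates and lifetimes from a fitted HMM
#'
#' Recovers the continuous-time generator `Q = logm(A) / dt` from the
#' fitted per-sample transition matrix by eigendecomposition, and reports
#' per-state lifetimes `-1 / Q_kk`.  This undoes the discretization bias
#' that affects both naive conversions (`(A - I) / dt` and geometric dwell
#' lengths) when neighboring states exchange on a timescale comparable to
#' a few sample intervals: round trips completed within one interval are
#' invisible to the sampled chain but are restored by the matrix
#' logarithm.  Falls back to `(A - I) / dt` (with a flag) when `A` has
#' non-positive or complex eigenvalues.
#'
#' @param model a fitted [fit_hmm()] model.
#' @param sample_rate_hz sampling rate of the fitted trace.
#' @return list with `Q` (generator, 1/s), `lifetimes_ms`, and
#'   `method` (`"logm"` or `"linear"`).
#' @export
model_lifetimes <- function(model, sample_rate_hz) {
  stopifnot(inherits(model, "hmm_model"))
  dt <- 1 / sample_rate_hz
  A <- model$A
  ev <- eigen(A)
  ok <- all(abs(Im(ev$values)) < 1e-8) && all(Re(ev$values) > 1e-12)
  if (ok) {
    V <- Re(ev$vectors)
    Q <- Re(V %*% diag(log(Re(ev$values)), nrow(A)) %*% solve(V)) / dt
    method <- "logm"
  } else {
    Q <- (A - diag(nrow(A))) / dt
    method <- "linear"
  }
  # clean tiny negative off-diagonals from numerical error
  off <- Q
  diag(off) <- 0
  off[off < 0] <- 0
  diag(off) <- -rowSums(off)
  Q <- off
  list(Q = Q, lifetimes_ms = -1000 / diag(Q), method = method)
}

#' Relative transition rates versus a reference condition
#'
#' @param summary,reference `ensemble_summary` objects.
#' @return matrix of rate ratios (condition / reference).
#' @export
relative_rates <- function(summary, reference) {
  summary$rate_matrix / reference$rate_matrix
}

#' Sequentiality of state exchange
#'
#' Fraction of state transitions that move between adjacent states
#' (|delta state| = 1); 1.0 for a strictly sequential path.
#'
#' @param path a `state_path`, list of them, or an integer state vector.
#' @return list with `score`, `n_transitions` and the transition `counts`
#'   matrix.
#' @export
sequentiality_score <- function(path) {
  states_of <- function(p) if (inherits(p, "state_path")) p$states else
    as.integer(p)
  paths <- if (inherits(path, "state_path") || !is.list(path)) list(path)
           else path
  K <- max(unlist(lapply(paths, function(p) max(states_of(p)))))
  counts <- matrix(0, K, K)
  for (p in paths) {
    s <- states_of(p)
    if (length(s) < 2) next
    from <- s[-length(s)]
    to <- s[-1]
    chg <- from != to
    if (any(chg))
      counts <- counts + unclass(table(factor(from[chg], levels = 1:K),
                                       factor(to[chg], levels = 1:K)))
  }
  n_trans <- sum(counts)
  adj <- abs(row(counts) - col(counts)) == 1
  score <- if (n_trans > 0) sum(counts[adj]) / n_trans else NA_real_
  list(score = score, n_transitions = n_trans, counts = counts)
}
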