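# Independent brute-force oracles, kept deliberately naive and separate from
# the implementations they check.

# HMM likelihood by explicit summation over all K^n state paths
oracle_hmm_loglik <- function(x, mu, sigma, A, pi0) {
  n <- length(x)
  K <- length(mu)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- pi0[s[1]] * dnorm(x[1], mu[s[1]], sigma[s[1]])
    if (n > 1) for (t in 2:n)
      p <- p * A[s[t - 1], s[t]] * dnorm(x[t], mu[s[t]], sigma[s[t]])
    total <- total + p
  }
  log(total)
}

# most probable path by explicit argmax over all K^n paths
oracle_viterbi <- function(x, mu, sigma, A, pi0) {
  n <- length(x)
  K <- length(mu)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    lp <- log(pi0[s[1]]) + dnorm(x[1], mu[s[1]], sigma[s[1]], log = TRUE)
    if (n > 1) for (t in 2:n)
      lp <- lp + log(A[s[t - 1], s[t]]) +
        dnorm(x[t], mu[s[t]], sigma[s[t]], log = TRUE)
    if (lp > best) { best <- lp; best_path <- s }
  }
  unname(best_path)
}

# exact two-tailed Mann-Whitney p by enumerating all C(n+m, n) assignments
oracle_mann_whitney_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  U_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- U_stat(x, y)
  pool <- c(x, y)
  idx <- utils::combn(n + m, n)
  Us <- apply(idx, 2, function(i) U_stat(pool[i], pool[-i]))
  mu <- n * m / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# exact two-sample KS p by enumeration
oracle_ks <- function(x, y) {
  ksD <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  D <- ksD(x, y)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  Ds <- apply(idx, 2, function(i) ksD(pool[i], pool[-i]))
  list(D = D, p = mean(Ds >= D - 1e-12))
}

# simple wrapper: a single synthetic read as a calls data.frame
make_read <- function(read_id, rel_pos, call, motif_id = "m1") {
  data.frame(read_id = read_id, motif_id = motif_id, rel_pos = rel_pos,
             call = call, stringsAsFactors = FALSE)
}
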