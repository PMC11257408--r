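# Shared builders and independent oracles used across test files.

# Consensus-site table with explicit per-library frequencies, bypassing the
# caller, for testing the concordance filter in isolation.
make_consensus <- function(fmat, design) {
  # fmat: matrix sites x libraries, columns ordered as design_keys would be:
  # control reps then each kd's reps.
  samples <- c(design$control, design$kd)
  cols <- as.vector(vapply(samples, function(s)
    paste0("f_", s, "_", seq_len(design$replicates)),
    character(design$replicates)))
  out <- data.frame(ref = "r", pos = seq_len(nrow(fmat)) - 1L, edit = "C>U")
  for (j in seq_along(cols)) out[[cols[j]]] <- fmat[, j]
  attr(out, "design") <- design
  out
}

# Independent re-implementation of the two concordance rules, loop-by-loop.
naive_classify <- function(fmat, design, mode) {
  R <- design$replicates
  n_kd <- length(design$kd)
  keep <- logical(nrow(fmat))
  pd <- rep(NA_real_, nrow(fmat))
  for (i in seq_len(nrow(fmat))) {
    ctrl <- fmat[i, 1:R]
    ctrl_mean <- mean(ctrl)
    kd_means <- numeric(n_kd)
    ok <- TRUE
    for (s in seq_len(n_kd)) {
      reps <- fmat[i, (R * s + 1):(R * s + R)]
      kd_means[s] <- mean(reps)
      if (mode == "all_replicates_decrease") {
        for (f in reps) if (!(f < ctrl_mean)) ok <- FALSE
      } else {
        if (!(kd_means[s] < ctrl_mean)) ok <- FALSE
      }
    }
    keep[i] <- ok
    if (ok) pd[i] <- 100 * (ctrl_mean - mean(kd_means)) / ctrl_mean
  }
  list(keep = keep, pd = pd[keep])
}

# Exact binomial upper tail by direct summation of point masses.
binom_tail_oracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(dbinom(k:n, n, p))
}

# Two-sided Fisher p by full hypergeometric enumeration (min-likelihood rule).
fisher_p_oracle <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  probs <- dhyper(support, K, N - K, n)
  obs <- dhyper(k, K, N - K, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive windowed motif scan: explicit substring comparison per window.
naive_window_scan <- function(seq, motif, L) {
  n <- nchar(seq); m <- nchar(motif)
  starts <- seq(0, max(0, n - 1), by = L)
  vapply(starts, function(ws) {
    cnt <- 0L
    for (i in ws:min(ws + L - 1, n - 1)) {
      if (i + m <= n && substr(seq, i + 1, i + m) == motif) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}
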