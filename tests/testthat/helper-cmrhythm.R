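# Shared fixtures and small oracles, built in code at test time.

# Match detected against true event times within a tolerance; greedy 1-1.
match_times <- function(detected, truth, tol_s) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(tp = tp, fn = length(truth) - tp, fp = length(detected) - tp)
}

# Brute-force Poincare descriptors by explicit variance sums (independent of
# compute_brv): sample variances with the n-1 denominator.
brute_brv <- function(ibis) {
  n <- length(ibis)
  m <- sum(ibis) / n
  v <- sum((ibis - m)^2) / (n - 1)
  d <- ibis[-1] - ibis[-n]
  md <- sum(d) / (n - 1)
  vd <- sum((d - md)^2) / (n - 2)
  sd1 <- sqrt(vd / 2)
  list(mean = m, cv = 100 * sqrt(v) / m, sd1 = sd1,
       sd2 = sqrt(max(2 * v - sd1^2, 0)))
}

# Regular beat series helper.
regular_beats <- function(ibi, n, t0 = 0, modality = "ap")
  beat_series(t0 + ibi * (0:(n - 1)), modality)
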