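# From-scratch reference implementation of the daily recursion, kept
# deliberately naive: the history coefficient is recomputed every day by an
# explicit O(t) attenuated sum over the stored per-day contributions, instead
# of the package's O(1) incremental carry.
oracle_series <- function(mt, k = 1, w = 0.5, cc = 2, tail_eps = NULL) {
  n <- length(mt)
  aaei <- numeric(n); alpha <- rep(NA_real_, n)
  e <- numeric(n); x <- numeric(n)
  prev <- 0
  for (t in seq_len(n)) {
    started <- t > 1 && any(mt[seq_len(t - 1)] > 0)
    if (started) {
      wts <- w^(seq_len(t - 1) - 1)          # weight of day t - i, i = 1..t-1
      xs <- x[(t - 1):1]
      if (!is.null(tail_eps)) {
        keep <- abs(wts) >= tail_eps
        wts <- wts[keep]; xs <- xs[keep]
      }
      alpha[t] <- sum(wts * xs)
    }
    A <- prev / 7
    e[t] <- if (!is.na(alpha[t]) && A > 0) A * cc^(-alpha[t]) else 0
    aaei[t] <- max(0, prev + k * (mt[t] - e[t]))
    x[t] <- if (aaei[t] > 0) mt[t] / (aaei[t] / 7) - 1 else 0
    prev <- aaei[t]
  }
  data.frame(mt = mt, alpha = alpha, e = e, aaei = aaei, x = x)
}

# Random MET-minute log with a realistic mix of rest and exercise days.
random_log <- function(n, p_exercise = 0.6,
                       start = as.Date("2024-01-01")) {
  mt <- ifelse(stats::runif(n) < p_exercise,
               round(stats::runif(n, 10, 400), 1), 0)
  data.frame(date = start + seq_len(n) - 1L, met_minutes = mt)
}

const_log <- function(n, m, start = as.Date("2024-01-01")) {
  data.frame(date = start + seq_len(n) - 1L, met_minutes = rep(m, n))
}
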