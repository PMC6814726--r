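# Independent brute-force oracles used across tests.

# Forward-Euler integration of dE/dt = -E/tau + stim(t) for a
# piecewise-constant signal given as (t_on, t_off, value) rows in ms.
# Deliberately naive: fixed step, no closed forms.
euler_leaky <- function(signal, tau, h = 1e-6) {
  if (nrow(signal) == 0L) return(0)
  t_end <- max(signal$t_off) / 1000
  t0 <- min(signal$t_on) / 1000
  n <- ceiling((t_end - t0) / h)
  E <- 0
  t <- t0
  for (i in seq_len(n)) {
    s <- 0
    hit <- signal$t_on / 1000 <= t & t < signal$t_off / 1000
    if (any(hit)) s <- signal$value[which(hit)[1]]
    E <- E + h * (-E / tau + s)
    t <- t + h
  }
  E
}

# Monte-Carlo rejection rate of the two-sided paired t test when the
# paired differences are N(d, 1): a brute-force power/type-I oracle.
# Vectorised over replicates for speed.
mc_paired_t_rejection <- function(d, n, n_rep = 10000, alpha = 0.05) {
  x <- matrix(stats::rnorm(n * n_rep, mean = d, sd = 1), nrow = n)
  m <- colMeans(x)
  s <- sqrt(colSums((x - rep(m, each = n))^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, df = n - 1))
}
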