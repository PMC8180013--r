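# Independent oracle: maximize the binomial log-likelihood of a logistic
# temperature trend by iterative grid refinement, no IRLS involved.
logistic_mle_grid <- function(successes, trials, temperatures,
                              rounds = 8L, width_a = 40, width_b = 4) {
  trials <- rep_len(trials, length(temperatures))
  loglik <- function(a, b) {
    eta <- a + b * temperatures
    sum(successes * eta - trials * log1p(exp(eta)))
  }
  a0 <- 0; b0 <- 0
  wa <- width_a; wb <- width_b
  for (r in seq_len(rounds)) {
    as <- seq(a0 - wa, a0 + wa, length.out = 41)
    bs <- seq(b0 - wb, b0 + wb, length.out = 41)
    ll <- outer(as, bs, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    a0 <- as[best[1L]]; b0 <- bs[best[2L]]
    wa <- wa * 0.15; wb <- wb * 0.15
  }
  c(alpha = a0, beta = b0)
}
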