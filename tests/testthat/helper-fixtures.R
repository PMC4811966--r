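# Small fixture builders used across the suite.

# a modest ZINB dataset with known truth
make_zinb_fixture <- function(n = 400, k = 6, seed = 1, h_total = 0.3,
                              rho = 0, maf = 0.25, zero_inflation = 0.5) {
  des <- simulation_design(n = n, k = k, maf = maf, rho = rho,
                           causal_idx = seq_len(min(2L, k)), h_total = h_total,
                           zero_inflation = zero_inflation)
  replicate_data(des, seed, 1)
}

# the standard 50-SNP simulation design (one cell of the study grid)
grid_design <- function(n, rho = 0, mv = 0.01) {
  simulation_design(n = n, rho = rho, h_total = 5 * mv)
}

# independent step-up implementation of Benjamini-Yekutieli used as the
# test oracle for the packaged adjustment
by_reject_oracle <- function(p, alpha) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  thresh <- alpha * seq_len(m) / (m * cm)
  ok <- p[o] <= thresh
  kmax <- if (any(ok)) max(which(ok)) else 0L
  reject <- logical(m)
  if (kmax > 0L) reject[o[seq_len(kmax)]] <- TRUE
  reject
}
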