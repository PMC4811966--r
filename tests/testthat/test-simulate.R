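test_that("design validation rejects impossible settings", {
  expect_error(simulation_design(n = 100, maf = 0.6), "maf")
  expect_error(simulation_design(n = 100, rho = 1), "rho")
  expect_error(simulation_design(n = 100, zero_inflation = 1), "zero_inflation")
  expect_error(simulation_design(n = 100, k = 10, causal_idx = 11), "range")
  d <- simulation_design(n = 100)
  expect_identical(d$causal_idx, c(1L, 11L, 21L, 31L, 41L))
})

test_that("genotypes are 0/1/2 with allele frequency matching the MAF", {
  des <- simulation_design(n = 50000, k = 20, maf = 0.05, rho = 0, h_total = 0)
  G <- simulate_genotypes(des, seed = 71)
  expect_true(all(G$G %in% 0:2))
  expect_lt(max(abs(G$maf_hat - 0.05)), 0.004)
  # Hardy-Weinberg class frequencies under independence
  tab <- tabulate(G$G + 1L, 3) / length(G$G)
  expect_equal(tab, c(0.95^2, 2 * 0.05 * 0.95, 0.05^2), tolerance = 0.02)
})

test_that("latent AR(1) correlation induces monotone linkage disequilibrium", {
  corr_adj <- function(rho) {
    des <- simulation_design(n = 20000, k = 10, maf = 0.2, rho = rho, h_total = 0)
    G <- simulate_genotypes(des, seed = 73)$G
    mean(diag(cor(G[, -10], G[, -1])))
  }
  r0 <- corr_adj(0); r5 <- corr_adj(0.5); r9 <- corr_adj(0.9)
  expect_lt(abs(r0), 0.03)
  expect_gt(r5, r0 + 0.1)
  expect_gt(r9, r5 + 0.1)
})

test_that("effect sizes follow the marginal-variance calibration", {
  des0 <- simulation_design(n = 10, h_total = 0)
  expect_identical(effect_sizes_from_h2(des0), numeric(50))
  des <- simulation_design(n = 10, h_total = 0.05)
  b <- effect_sizes_from_h2(des)
  expect_equal(unname(b[1]), sqrt(0.01 / (2 * 0.05 * 0.95)), tolerance = 1e-12)
  expect_equal(unname(b[1]), 0.3244428, tolerance = 1e-6)
  expect_true(all(b[-des$causal_idx] == 0))
  des6 <- simulation_design(n = 10, h_total = 0.30)
  expect_equal(unname(effect_sizes_from_h2(des6)[1]), 0.7947194, tolerance = 1e-6)
  # empirical Var(x_j beta_j) matches h_j^2 at large n
  big <- simulation_design(n = 200000, k = 5, maf = 0.05, causal_idx = 1:5,
                           h_total = 0.05)
  G <- simulate_genotypes(big, seed = 79)$G
  bb <- effect_sizes_from_h2(big)
  expect_lt(abs(var(G[, 1] * bb[1]) - 0.01), 0.001)
})

test_that("phenotypes honour the structural-zero bookkeeping", {
  des <- simulation_design(n = 10000, k = 5, causal_idx = 1:2, h_total = 0.1)
  G <- simulate_genotypes(des, seed = 83)
  dat <- simulate_zinb_phenotype(G, seed = 84)
  z <- attr(dat, "latent_zero")
  expect_equal(mean(z), 0.5, tolerance = 0.015)
  expect_true(all(dat$y[z == 1] == 0))
  expect_gte(mean(dat$y == 0), mean(z))
  # no inflation, null effects: geometric counts with mean 1
  des0 <- simulation_design(n = 20000, k = 3, causal_idx = 1, h_total = 0,
                            zero_inflation = 0)
  d0 <- simulate_zinb_phenotype(simulate_genotypes(des0, seed = 85), seed = 86)
  expect_equal(mean(d0$y), 1, tolerance = 0.03)
  expect_equal(var(d0$y), 2, tolerance = 0.1)
})

test_that("replicate streams are deterministic and distinct", {
  des <- simulation_design(n = 60, k = 8, causal_idx = 1:2, h_total = 0.1)
  a <- generate_replicates(des, 3, base_seed = 91)
  b <- generate_replicates(des, 3, base_seed = 91)
  for (s in 1:3) {
    expect_identical(a[[s]]$y, b[[s]]$y)
    expect_identical(a[[s]]$X_count, b[[s]]$X_count)
  }
  expect_false(identical(a[[1]]$y, a[[2]]$y))
  expect_error(generate_replicates(des, 0, 1), "R must be")
})

test_that("codominant expansion produces paired indicators", {
  G <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  E <- codominant_expand(G)
  expect_identical(ncol(E), 4L)
  expect_identical(unname(E[, "a_het"]), c(0, 1, 0))
  expect_identical(unname(E[, "a_hom"]), c(0, 0, 1))
  expect_identical(colSums(E)[["b_hom"]], 1)
  # 10 SNPs -> 20 main effects
  des <- simulation_design(n = 30, k = 10, causal_idx = 1, h_total = 0.01)
  expect_identical(ncol(codominant_expand(simulate_genotypes(des, seed = 95))), 20L)
})

test_that("frequency-based sampler and text readers handle user genotypes", {
  freqs <- rbind(c(0.81, 0.18, 0.01), c(0.5, 0.4, 0.1))
  G <- simulate_genotypes_freq(freqs, n = 30000, seed = 97)
  expect_true(all(G %in% 0:2))
  expect_equal(mean(G[, 2] == 1), 0.4, tolerance = 0.02)
  f <- tempfile(fileext = ".tsv")
  write_genotypes(G[1:20, ], f)
  G2 <- read_genotypes(f, sep = "\t")
  expect_equal(unname(G2), unname(G[1:20, ]) * 1.0)
  # missing entries are filled with the column mean
  writeLines(c("s1\ts2", "0\t1", "NA\t2", "2\t0"), f)
  G3 <- read_genotypes(f, sep = "\t")
  expect_equal(unname(G3[2, 1]), 1)
  unlink(f)
})

test_that("designs round-trip through YAML and JSON configs", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n: 120", "k: 10", "maf: 0.1", "rho: 0.5",
               "h_total: 0.2", "causal_idx: [1, 5]"), f)
  d <- read_design(f)
  expect_identical(d$n, 120L)
  expect_identical(d$causal_idx, c(1L, 5L))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 50, k = 5, h_total = 0.1, causal_idx = 1:2),
                       fj, auto_unbox = TRUE)
  expect_identical(read_design(fj)$n, 50L)
  writeLines("n: 10\nbogus: 3", f)
  expect_error(read_design(f), "unknown design fields")
  unlink(c(f, fj))
})
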