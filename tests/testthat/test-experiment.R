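test_that("experiment configs are validated with informative messages", {
  des <- simulation_design(n = 100, k = 8, causal_idx = 1:2, h_total = 0.1)
  expect_error(experiment_config(des, R = 0), "R must be")
  expect_error(experiment_config(des, methods = "SCAD"), "unknown methods")
  expect_error(experiment_config(des, alpha = 0), "alpha")
  expect_error(experiment_config(des, metrics = "auc"), "unknown metrics")
  cfg <- experiment_config(des, methods = c("PR", "NB"), R = 3)
  expect_s3_class(cfg, "experiment_config")
})

test_that("experiments are deterministic and resumable from the replicate ledger", {
  des <- simulation_design(n = 150, k = 8, causal_idx = 1:2, h_total = 0.2)
  cfg <- experiment_config(des, methods = c("PR", "NB"), R = 4, base_seed = 107,
                           metrics = c("mse", "tests"))
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$replicates$sq_err, b$replicates$sq_err)
  # interrupted run resumes without recomputation
  dir1 <- tempfile(); dir.create(dir1)
  cfg1 <- experiment_config(des, methods = c("PR", "NB"), R = 2, base_seed = 107,
                            metrics = c("mse", "tests"), output_dir = dir1)
  run_experiment(cfg1)
  cfg2 <- experiment_config(des, methods = c("PR", "NB"), R = 4, base_seed = 107,
                            metrics = c("mse", "tests"), output_dir = dir1)
  c2 <- run_experiment(cfg2)
  # the resumed half round-trips through the CSV ledger at print precision
  expect_equal(c2$summary$mse, a$summary$mse, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir1, "summary.csv")))
  expect_true(file.exists(file.path(dir1, "summary.json")))
  unlink(dir1, recursive = TRUE)
})

test_that("summaries carry the evaluation battery per method", {
  des <- simulation_design(n = 250, k = 10, causal_idx = c(1L, 5L), h_total = 0.4)
  cfg <- experiment_config(des, methods = c("NB", "AL"), R = 5, base_seed = 109)
  s <- run_experiment(cfg)$summary
  expect_identical(s$method, c("NB", "AL"))
  expect_true(all(s$n_converged <= s$R))
  expect_true(all(s$nonconv_pct >= 0 & s$nonconv_pct <= 100))
  al <- s[s$method == "AL", ]
  expect_true(al$sensitivity >= 0 && al$sensitivity <= 1)
  expect_true(al$specificity >= 0 && al$specificity <= 1)
  expect_true(is.finite(al$mse) && al$mse >= 0)
  expect_true(all(is.na(s$sensitivity[s$method == "NB"])))
})

test_that("reference tables expose the published cells for comparison", {
  t3 <- reference_mse_table("T3")
  expect_identical(nrow(t3), 108L)
  expect_equal(t3$reference[t3$n == 500 & t3$mv == 0.01 & t3$method == "PR"], 0.14)
  expect_equal(t3$reference[t3$n == 1000 & t3$mv == 0.06 & t3$method == "AL"], 0.02)
  t5 <- reference_mse_table("T5")
  expect_equal(t5$reference[t5$n == 500 & t5$mv == 0.01 & t5$method == "ZIP"], 0.72)
  expect_identical(unique(t5$rho), 0.9)
})

test_that("reproduce_table assembles recomputed cells next to reference values", {
  tab <- reproduce_table("T3", n = 500, mv = 0.01, methods = "PR", R = 8,
                         base_seed = 113)
  expect_identical(nrow(tab), 1L)
  expect_true(all(c("mse", "mc_se", "reference", "n_converged") %in% names(tab)))
  expect_equal(tab$reference, 0.14)
  expect_true(is.finite(tab$mse))
  expect_message(reproduce_table("T3", n = 200, mv = 0.01, methods = "PR", R = 2,
                                 base_seed = 1), "qualitative")
  expect_error(reproduce_table("T9"))
})
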