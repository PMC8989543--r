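test_that("generators are seed-deterministic", {
  a <- simulate_burden(sim_config(n_genes = 200, seed = 8))
  b <- simulate_burden(sim_config(n_genes = 200, seed = 8))
  expect_identical(a, b)
  da <- simulate_background(sim_config(n_genes = 50, seed = 8))
  db <- simulate_background(sim_config(n_genes = 50, seed = 8))
  expect_identical(da, db)
  dc <- simulate_background(sim_config(n_genes = 50, seed = 9))
  expect_false(identical(da$records, dc$records))
})

test_that("simulated counts match their analytic mean and over-disperse", {
  rows <- simulate_burden(sim_config(n_genes = 50000, seed = 12))
  truth <- attr(rows, "truth")
  expect_equal(mean(rows$y), mean(truth$mu), tolerance = 0.02)
  # variance exceeds the mean whenever theta is finite
  expect_gt(var(rows$y) / mean(rows$y), 1)
})

test_that("causal injection raises the expected burden of target genes", {
  ds <- simulate_background(sim_config(n_genes = 80, seed = 33,
                                       n_controls = 450))
  same <- inject_causal(ds, genes = character(0))
  expect_identical(same$records, ds$records)
  inj <- inject_causal(ds, genes = "G00001", seed = 2)
  new <- inj$records[inj$records$chrom == "2", ]
  expect_true(all(new$gene_id == "G00001"))
  expect_gte(nrow(new), 4)
  # expected injected case count alone exceeds the gene's baseline mean
  base_mu <- 2 * 450 * mean(new$af_eas)
  expect_gt(sum(2 * 450 * 0.01 * nrow(new) / nrow(new)), base_mu)
  expect_gt(inj$rows$y[inj$rows$gene_id == "G00001"],
            ds$rows$y[ds$rows$gene_id == "G00001"])
  # infinite odds ratio silences controls entirely
  inf <- inject_causal(ds, genes = "G00002", or_range = c(Inf, Inf),
                       seed = 3)
  expect_true(all(inf$records$ctrl_ac[inf$records$chrom == "2"] == 0))
})

test_that("chi-squared burden comparator matches hand computation", {
  cc <- chisq_burden_test(10, 1, 500, 500)
  expect_equal(cc$statistic, 7.3636, tolerance = 1e-4)
  expect_equal(cc$p_value, 0.00666, tolerance = 1e-3)
  expect_equal(cc$pooled_freq, 0.0055)
  expect_equal(unname(cc$expected), c(5.5, 5.5))
  eq <- chisq_burden_test(5, 5, 500, 500)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # generic 2x2 contingency oracle (without continuity correction)
  cc2 <- chisq_burden_test(20, 2, 500, 500)
  tab <- matrix(c(20, 1000 - 20, 2, 1000 - 2), 2, 2)
  orc <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(cc2$statistic, unname(orc$statistic), tolerance = 0.03)
})

test_that("baseline-tail testing dominates the case-control comparison", {
  ex <- burden_intuition_example()
  expect_equal(ex$population_freq, 0.00109)
  expect_equal(ex$baseline_mu, 1.09)
  # the same signal is orders of magnitude stronger against the baseline
  expect_lt(ex$p_tail, ex$p_chisq / 1e3)
  # a tripled (biased) baseline erodes it sharply
  expect_gt(ex$p_tail_biased, ex$p_tail * 1e3)
})

test_that("type-1-error evaluation reports rejection rates and MLFC", {
  out <- type1_error_eval(n_replicates = 2,
                          config = sim_config(n_genes = 800, seed = 40),
                          alpha = c(0.05, 1))
  expect_equal(nrow(out), 2)
  expect_true(all(out$rej_1 == 1))
  expect_true(all(out$rej_0.05 >= 0 & out$rej_0.05 <= 1))
  expect_true(all(out$mlfc >= 0))
})

test_that("a saturating signal reaches near-certain power", {
  pw <- power_eval(sample_sizes = 600, n_replicates = 10,
                   config = sim_config(n_genes = 600, seed = 61),
                   or_range = c(Inf, Inf), freq_range = c(0.015, 0.015),
                   n_variants_range = 5)
  expect_gte(pw$power, 0.9)
})
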