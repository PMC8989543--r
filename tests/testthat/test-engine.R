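test_that("MLFC measures departure from uniformity", {
  n <- 100
  expect_equal(mlfc((1:n) / n), 0)
  expect_equal(mlfc(c(0.25, 0.5)),
               (abs(log2(0.25 / 0.5)) + abs(log2(0.5 / 1))) / 2)
  set.seed(1)
  expect_gte(mlfc(runif(50)^3), 0)
})

test_that("BH q-values step up and stay monotone", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p & q <= 1))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("null data keeps nearly all genes in the background", {
  rows <- simulate_burden(sim_config(n_genes = 3000, seed = 101))
  fit <- recursive_fit(rows, t = 0)
  expect_lte(length(fit$iterations), 2)
  ins <- fit$scores$in_support
  expect_gte(mean(fit$background[ins]), 0.99)
  expect_true(fit$model$converged)
  # q monotone in p among scored genes
  sc <- fit$scores[ins, ]
  expect_true(all(diff(sc$q[order(sc$p)]) >= -1e-12))
})

test_that("recursion excludes burdened genes and sharpens their P-values", {
  rows <- simulate_burden(sim_config(n_genes = 4000, seed = 55))
  hot <- rows$gene_id[1:5]
  idx <- match(hot, rows$gene_id)
  # five genes with counts inflated to 5x their baseline mean
  mu <- attr(rows, "truth")$mu
  rows$y[idx] <- as.integer(round(5 * pmax(rows$y[idx], mu[idx])))
  rec <- recursive_fit(rows, t = 0)
  single <- recursive_fit(rows, t = 0, single_pass = TRUE)
  expect_true(all(!rec$background[idx]))
  expect_true(all(rec$scores$p[idx] <= single$scores$p[idx] + 1e-12))
})

test_that("a collapsing background aborts rather than fits", {
  rows <- simulate_burden(sim_config(n_genes = 400, seed = 9))
  # a degenerate exclusion threshold would flag every gene: abort
  expect_error(recursive_fit(rows, t = 0, exclusion_fdr = 1),
               "half|shrank")
})

test_that("grid enumeration and ranking follow the rank-sum rule", {
  expect_equal(nrow(grid_candidates()), 120)
  expect_error(grid_candidates(b_values = c(0, 0.5)), "\\(0,1\\]")
  # competition ranking with a brute-force check
  g <- grid_candidates(b_values = c(0.1, 0.2, 0.3), t_values = 0:1)
  set.seed(3)
  g$mlfc <- c(0.02, 0.05, 0.02, 0.08, 0.01, 0.03)
  g$n_significant <- c(4L, 9L, 4L, 2L, 1L, 4L)
  g$failed <- FALSE
  rg <- rvburden:::rank_grid(g)
  for (j in seq_len(nrow(rg))) {
    expect_equal(rg$rank_mlfc[j], sum(rg$mlfc < rg$mlfc[j]) + 1L)
    expect_equal(rg$rank_sig[j],
                 sum(rg$n_significant > rg$n_significant[j]) + 1L)
  }
  best <- rg[order(rg$rank_sum, rg$mlfc, rg$b, rg$t), ][1, ]
  expect_true(all(best$rank_sum <= rg$rank_sum))
})

test_that("grid search picks a cell with minimal rank sum", {
  ds <- simulate_background(sim_config(n_genes = 400, seed = 77))
  gs <- grid_search(ds$records, ds$annotation,
                    b_values = c(0.1, 0.5, 1), t_values = 0:1,
                    fast = TRUE)
  expect_equal(nrow(gs$grid), 6)
  chosen <- gs$grid[gs$grid$b == gs$b & gs$grid$t == gs$t, ]
  expect_true(all(chosen$rank_sum <= gs$grid$rank_sum))
})

test_that("the end-to-end driver is deterministic and honours fixed (b, t)", {
  ds <- simulate_background(sim_config(n_genes = 500, seed = 13))
  r1 <- run_burden(ds$records, ds$annotation,
                   config = weight_config(b = 0.1, d = NULL), t = 1)
  r2 <- run_burden(ds$records, ds$annotation,
                   config = weight_config(b = 0.1, d = NULL), t = 1)
  expect_identical(r1$results, r2$results)
  expect_match(r1$log$grid, "skipped")
  expect_null(r1$grid)
  expect_equal(r1$t, 1)
  # out-of-support genes report p = 1 and no background membership
  oos <- r1$results[!r1$results$in_support, ]
  expect_true(all(oos$p == 1))
  expect_true(all(!oos$background))
  # case-only input (no control columns) completes
  expect_false("ctrl_ac" %in% names(ds$records))
})

test_that("burden-table input runs without variant records", {
  rows <- simulate_burden(sim_config(n_genes = 600, seed = 4))
  r <- run_burden(rows = rows, t = 0)
  expect_s3_class(r, "burden_result")
  expect_equal(nrow(r$results), 600)
  expect_error(run_burden(), "supply either")
})
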