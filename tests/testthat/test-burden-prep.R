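test_that("rarity filter keeps rare and reference-absent variants", {
  rec <- toy_records()
  rec$af_eas <- c(0.02, 0.005, NA, 0.001)
  rec$af_eur <- c(0.02, 0.005, NA, 0.001)
  out <- filter_rare(rec, rare_af_max = 0.01)
  expect_equal(out$pos, c(200, 300, 300))
  # idempotent on its own output
  expect_identical(filter_rare(out, 0.01), out)
})

test_that("case-enrichment filter follows the d-fold rule", {
  rec <- data.frame(gene_id = "G", case_ac = c(10, 1), case_an = 1000,
                    ctrl_ac = c(1, 10), ctrl_an = 1000)
  out <- filter_case_enriched(rec, d = 2)
  expect_equal(out$case_ac, 10) # enriched in cases: kept
  # no control columns: identity
  rec2 <- rec[, c("gene_id", "case_ac", "case_an")]
  expect_identical(filter_case_enriched(rec2, d = 2), rec2)
  # strict reading keeps only case AF > d * control AF
  rec3 <- data.frame(gene_id = "G", case_ac = c(3, 1), case_an = 1000,
                     ctrl_ac = c(1, 1), ctrl_an = 1000)
  expect_equal(filter_case_enriched(rec3, d = 2, strict = TRUE)$case_ac, 3)
})

test_that("least-integer weighting floors at one", {
  expect_equal(score_to_weight(1.0, b = 1), 1L)
  expect_equal(score_to_weight(0.5, b = 0.05), 10L)
  expect_equal(score_to_weight(0.51, b = 0.05), 11L)
  expect_equal(score_to_weight(0, b = 0.05), 1L) # floored
  expect_equal(score_to_weight(c(0.9, 0.1), b = 0.5,
                               equal_weights = TRUE), c(1L, 1L))
  expect_error(score_to_weight(0.5, b = 0), "\\(0, 1\\]")
  expect_error(score_to_weight(1.2, b = 0.5), "\\[0, 1\\]")
})

test_that("missing scores are imputed from gene then global means", {
  rec <- data.frame(gene_id = c("A", "A", "A", "B"),
                    score = c(0.2, NA, 0.4, NA))
  out <- impute_missing_scores(rec)
  expect_equal(out$score, c(0.2, 0.3, 0.4, 0.3)) # B gets the global mean
  rec2 <- data.frame(gene_id = "A", score = 0.7)
  expect_identical(impute_missing_scores(rec2), rec2)
})

test_that("weighted counts aggregate per gene, overlaps counted per gene", {
  rec <- toy_records()[1:2, ]
  out <- weighted_gene_counts(rec, weights = c(3L, 1L))
  expect_equal(out$y, 1 * 3 + 2 * 1)
  expect_equal(out$y_raw, 3)
  expect_equal(out$m, 2)
  # a variant overlapping two genes contributes to both
  rec2 <- toy_records()[3:4, ]
  out2 <- weighted_gene_counts(rec2, weights = c(1L, 1L))
  expect_equal(out2$y, c(1, 1))
  # equal weights reproduce the raw tally; 61 alleles stay 61
  rec3 <- data.frame(gene_id = "RETlike", case_ac = rep(1L, 61),
                     case_an = 886L)
  expect_equal(weighted_gene_counts(rec3, rep(1L, 61))$y, 61)
})

test_that("frequency score averages panels then weights", {
  rec <- toy_records()[3:3, ]
  # panels 0.004 and 0.002 average to 0.003 at weight 1
  expect_equal(frequency_score(rec, weights = 1L)$x2, 0.003)
  rec2 <- toy_records()[1:2, ]
  expect_equal(frequency_score(rec2, weights = c(2L, 1L))$x2,
               0.001 * 2 + 0.002 * 1)
})

test_that("predictor assembly enforces the interaction and imputes", {
  ann <- toy_annotation()
  x2 <- data.frame(gene_id = c("GA", "GB"), x2 = c(0.5, 0))
  out <- assemble_predictors(ann, x2)
  expect_equal(out$x3, out$x1 * out$x2)
  expect_equal(out$x3[out$gene_id == "GA"], 2 * 0.5)
  expect_equal(out$x2[out$gene_id == "GC"], 0) # no variants: score 0
  ann$oe_lof[2] <- NA
  out2 <- assemble_predictors(ann, x2)
  expect_equal(out2$x6[2], median(toy_annotation()$oe_lof[c(1, 3)], ))
  expect_true(out2$imputed_flag[2])
  expect_false(any(out2$imputed_flag[-2]))
  expect_error(assemble_predictors(ann[, -2], x2), "length_kb")
})

test_that("the burden table pipeline is consistent end to end", {
  ds <- simulate_background(sim_config(n_genes = 60, seed = 21))
  wc_eq <- weight_config(b = 1, equal_weights = TRUE, d = NULL)
  rows_eq <- build_burden_table(ds$records, ds$annotation, wc_eq)
  # equal weights reproduce raw tallies
  expect_equal(rows_eq$y, rows_eq$y_raw)
  wc_w <- weight_config(b = 0.05, d = NULL)
  rows_w <- build_burden_table(ds$records, ds$annotation, wc_w)
  expect_true(all(rows_w$y >= rows_eq$y))
  expect_equal(rows_w$x3, rows_w$x1 * rows_w$x2)
  # every annotated gene appears exactly once
  expect_setequal(rows_w$gene_id, ds$annotation$gene_id)
  expect_equal(anyDuplicated(rows_w$gene_id), 0L)
  # missense + lof tallies never exceed the raw total
  expect_true(all(rows_w$missense_alleles + rows_w$lof_alleles <=
                    rows_w$y_raw))
})
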