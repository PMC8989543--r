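## Variant-level preparation: genotype QC, rarity and case-enrichment
## filters, score-to-weight conversion, weighted counting, frequency
## scores and predictor assembly.
##
## A "variant record" table has one row per (variant, gene) mapping with
## columns: chrom, pos, ref, alt, gene_id, consequence, score, case_ac,
## case_an, optional ctrl_ac / ctrl_an, and one `af_<panel>` column per
## reference panel. A variant overlapping several genes appears once per
## gene and contributes to each.

#' Weighting and filtering configuration
#'
#' @param b Score bin length in `(0, 1]`; the integer weight of a variant
#'   with functional score `s` is `ceiling(s / b)` (floored at 1).
#' @param equal_weights Use weight 1 everywhere (raw minor-allele counts).
#' @param d Case-enrichment fold (`> 1`), or `NULL` to disable. Rare-variant
#'   odds ratios for complex disease are typically above 2, hence the
#'   default.
#' @param rare_af_max Reference allele-frequency ceiling defining "rare".
#' @param consequences Consequence classes retained for counting.
#' @param strict_enrichment If `TRUE`, keep only variants with case AF
#'   strictly greater than `d` times the control AF (the stricter reading
#'   of the d-fold filter); default removes variants whose control AF is at
#'   least `d` times the case AF.
#' @return A `weight_config` list.
#' @export
weight_config <- function(b = 0.05, equal_weights = FALSE, d = 2,
                          rare_af_max = 0.01,
                          consequences = c("missense", "start-loss",
                                           "stop-loss", "stop-gain",
                                           "splicing", "frameshift",
                                           "non-frameshift"),
                          strict_enrichment = FALSE) {
  if (b <= 0 || b > 1) stop("'b' must lie in (0, 1]")
  if (!is.null(d) && d <= 1) stop("'d' must exceed 1 (or be NULL)")
  structure(list(b = b, equal_weights = equal_weights, d = d,
                 rare_af_max = rare_af_max, consequences = consequences,
                 strict_enrichment = strict_enrichment),
            class = "weight_config")
}

af_panel_cols <- function(records, panels = NULL) {
  cols <- grep("^af_", names(records), value = TRUE)
  if (!is.null(panels)) {
    want <- paste0("af_", panels)
    missing <- setdiff(want, cols)
    if (length(missing))
      stop("reference panel column(s) not found: ",
           paste(missing, collapse = ", "))
    cols <- want
  }
  cols
}

## Mean reference AF across panels; a variant absent from every panel
## (all NA) is treated as AF 0 — absence from a large reference is itself
## evidence of rarity.
mean_ref_af <- function(records, panels = NULL) {
  cols <- af_panel_cols(records, panels)
  if (length(cols) == 0L) return(rep(0, nrow(records)))
  af <- as.matrix(records[, cols, drop = FALSE])
  out <- rowMeans(af, na.rm = TRUE)
  out[!is.finite(out)] <- 0
  out
}

#' Keep rare variants
#'
#' Retains records whose reference allele frequency (maximum across the
#' enabled panels) is at most `rare_af_max`; variants absent from every
#' reference panel are kept.
#'
#' @param records Variant record table.
#' @param rare_af_max AF ceiling (default 1%).
#' @param panels Optional character vector of panel names (matching the
#'   `af_<panel>` columns) to use.
#' @return Filtered records.
#' @export
filter_rare <- function(records, rare_af_max = 0.01, panels = NULL) {
  cols <- af_panel_cols(records, panels)
  if (length(cols) == 0L) return(records)
  af <- as.matrix(records[, cols, drop = FALSE])
  mx <- suppressWarnings(apply(af, 1, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0
  records[mx <= rare_af_max, , drop = FALSE]
}

#' Keep case-enriched variants
#'
#' When control counts are present, removes variants whose case allele
#' frequency is `d`-fold smaller than the control frequency (i.e. drops a
#' record when `ctrl_af >= d * case_af`). Without controls this is the
#' identity. `strict = TRUE` instead keeps only `case_af > d * ctrl_af`.
#'
#' @param records Variant record table.
#' @param d Enrichment fold (`> 1`); `NULL` disables the filter.
#' @param strict Use the stricter reading (see [weight_config()]).
#' @return Filtered records.
#' @export
filter_case_enriched <- function(records, d = 2, strict = FALSE) {
  if (is.null(d)) return(records)
  if (!all(c("ctrl_ac", "ctrl_an") %in% names(records))) return(records)
  ok <- is.finite(records$ctrl_ac) & is.finite(records$ctrl_an) &
    records$ctrl_an > 0
  if (!any(ok)) return(records)
  case_af <- records$case_ac / records$case_an
  ctrl_af <- records$ctrl_ac / records$ctrl_an
  drop <- if (strict) !(case_af > d * ctrl_af) else ctrl_af >= d * case_af
  drop[!ok] <- FALSE
  records[!drop, , drop = FALSE]
}

#' Convert functional scores to integer weights
#'
#' Least-integer conversion `w = ceiling(s / b)`, floored at 1 so that
#' every retained allele contributes at least one count; with
#' `equal_weights` every variant gets weight 1 (the raw-count mode).
#'
#' @param s Functional scores in `[0, 1]`.
#' @param b Score bin length in `(0, 1]`.
#' @param equal_weights Return weight 1 for every score.
#' @return Positive integer weights.
#' @export
score_to_weight <- function(s, b, equal_weights = FALSE) {
  if (b <= 0 || b > 1) stop("'b' must lie in (0, 1]")
  if (equal_weights) return(rep(1L, length(s)))
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  as.integer(pmax(ceiling(s / b), 1))
}

#' Impute missing functional scores
#'
#' A missing score becomes the mean of the non-missing scores in the same
#' gene; genes with no scored variant get the global mean.
#'
#' @param records Variant record table with `gene_id` and `score`.
#' @return Records with `score` complete.
#' @export
impute_missing_scores <- function(records) {
  if (!any(is.na(records$score))) return(records)
  glob <- mean(records$score, na.rm = TRUE)
  if (!is.finite(glob)) {
    warning("no scored variants at all; imputing 0.5 everywhere")
    glob <- 0.5
  }
  gm <- tapply(records$score, records$gene_id, mean, na.rm = TRUE)
  gm[!is.finite(gm)] <- glob
  miss <- is.na(records$score)
  records$score[miss] <- gm[as.character(records$gene_id[miss])]
  records
}

#' Weighted per-gene allele counts
#'
#' Aggregates `y = sum(case_ac * w)` (the weighted minor-allele count),
#' the raw tally `y_raw = sum(case_ac)` and the variant count `m` per gene.
#'
#' @param records Variant record table.
#' @param weights Integer weights aligned with `records`.
#' @return Data frame `gene_id, m, y, y_raw`.
#' @export
weighted_gene_counts <- function(records, weights) {
  stopifnot(length(weights) == nrow(records))
  agg <- stats::aggregate(
    cbind(y = records$case_ac * weights, y_raw = records$case_ac,
          m = rep(1L, nrow(records))),
    by = list(gene_id = records$gene_id), FUN = sum)
  agg[order(agg$gene_id), , drop = FALSE]
}

#' Per-gene frequency score
#'
#' Weighted sum of mean reference allele frequencies over a gene's
#' retained rare variants: `x2 = sum(f_bar * w)`, where `f_bar` averages
#' the enabled reference panels. Genes with no retained variant score 0.
#'
#' @param records Variant record table.
#' @param weights Integer weights aligned with `records`.
#' @param panels Optional panel names.
#' @return Data frame `gene_id, x2`.
#' @export
frequency_score <- function(records, weights, panels = NULL) {
  fbar <- mean_ref_af(records, panels)
  agg <- stats::aggregate(list(x2 = fbar * weights),
                          by = list(gene_id = records$gene_id), FUN = sum)
  agg[order(agg$gene_id), , drop = FALSE]
}

#' Assemble the eight-predictor matrix for a gene set
#'
#' Joins per-gene annotation (coding length, constraint and mutation-rate
#' columns, GC) with the frequency score into the predictor layout
#' `x1` length (kb), `x2` frequency score, `x3 = x1 * x2`, `x4` oe_mis,
#' `x5` mu_mis, `x6` oe_lof, `x7` mu_lof, `x8` exon GC. Missing annotation
#' values are imputed with the column median and the gene flagged.
#'
#' @param annotation Data frame with `gene_id, length_kb, gc, oe_mis,
#'   mu_mis, oe_lof, mu_lof`.
#' @param x2_table Data frame `gene_id, x2` (e.g. from
#'   [frequency_score()]); genes absent from it get `x2 = 0`.
#' @return Data frame `gene_id, x1..x8, imputed_flag`.
#' @export
assemble_predictors <- function(annotation, x2_table) {
  need <- c("gene_id", "length_kb", "gc", "oe_mis", "mu_mis",
            "oe_lof", "mu_lof")
  missing <- setdiff(need, names(annotation))
  if (length(missing))
    stop("annotation lacks required column(s): ",
         paste(missing, collapse = ", "))
  x2 <- x2_table$x2[match(annotation$gene_id, x2_table$gene_id)]
  x2[is.na(x2)] <- 0
  out <- data.frame(gene_id = annotation$gene_id,
                    x1 = annotation$length_kb, x2 = x2,
                    x3 = annotation$length_kb * x2,
                    x4 = annotation$oe_mis, x5 = annotation$mu_mis,
                    x6 = annotation$oe_lof, x7 = annotation$mu_lof,
                    x8 = annotation$gc, stringsAsFactors = FALSE)
  flag <- rep(FALSE, nrow(out))
  for (col in c("x1", "x4", "x5", "x6", "x7", "x8")) {
    miss <- is.na(out[[col]])
    if (any(miss)) {
      out[[col]][miss] <- stats::median(out[[col]], na.rm = TRUE)
      flag <- flag | miss
    }
  }
  out$x3 <- out$x1 * out$x2 # recompute after any x1 imputation
  out$imputed_flag <- flag
  out
}

#' Build the gene burden table from variant records
#'
#' Runs the fixed preparation pipeline on QC-passed records: rarity
#' filter, case-enrichment filter, score imputation, weighting, weighted
#' counting, frequency scoring and predictor assembly. Genes present in
#' the annotation but with no retained variant are emitted with `y = 0`.
#'
#' @param records Variant record table (post-QC).
#' @param annotation Per-gene annotation table.
#' @param config A [weight_config()].
#' @param panels Optional reference panel names.
#' @return Gene burden table: `gene_id, m, y, y_raw, missense_alleles,
#'   lof_alleles, x1..x8, imputed_flag`.
#' @export
build_burden_table <- function(records, annotation,
                               config = weight_config(), panels = NULL) {
  records <- records[records$consequence %in% config$consequences, ,
                     drop = FALSE]
  records <- filter_rare(records, config$rare_af_max, panels)
  records <- filter_case_enriched(records, config$d,
                                  config$strict_enrichment)
  records <- impute_missing_scores(records)
  w <- score_to_weight(records$score, config$b, config$equal_weights)
  cnt <- weighted_gene_counts(records, w)
  fs <- frequency_score(records, w, panels)
  lof_classes <- c("stop-gain", "splicing", "frameshift", "start-loss",
                   "stop-loss")
  cls <- stats::aggregate(
    cbind(missense_alleles = records$case_ac *
            (records$consequence == "missense"),
          lof_alleles = records$case_ac *
            (records$consequence %in% lof_classes)),
    by = list(gene_id = records$gene_id), FUN = sum)
  pred <- assemble_predictors(annotation, fs)
  out <- merge(pred, cnt, by = "gene_id", all.x = TRUE)
  out <- merge(out, cls, by = "gene_id", all.x = TRUE)
  for (col in c("m", "y", "y_raw", "missense_alleles", "lof_alleles"))
    out[[col]][is.na(out[[col]])] <- 0L
  out <- out[order(out$gene_id),
             c("gene_id", "m", "y", "y_raw", "missense_alleles",
               "lof_alleles", paste0("x", 1:8), "imputed_flag")]
  rownames(out) <- NULL
  out
}
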