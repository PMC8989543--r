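## Readers and writers: minimal VCF genotype extraction (via vcfR),
## annotation/resource tables, result tables and the run manifest.

#' Read genotypes from a VCF with multi-allelic splitting
#'
#' Extracts per-sample alternate-allele dosages (0/1/2, `NA` when
#' missing), splitting multi-allelic sites into one record per alternate
#' allele. Sites with more than four alleles are flagged for QC removal.
#' GQ and DP matrices are returned when the FORMAT carries them.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param samples Optional sample-name subset.
#' @return List: `sites` (chrom, pos, ref, alt, n_alleles, flagged),
#'   `gt` integer dosage matrix (records x samples), `gq`, `dp` (numeric
#'   matrices or `NULL`).
#' @export
read_vcf_minimal <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  has <- function(el) {
    any(grepl(paste0("(^|:)", el, "($|:)"), vcf@gt[, "FORMAT"]))
  }
  gq_raw <- if (has("GQ"))
    vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE) else NULL
  dp_raw <- if (has("DP"))
    vcfR::extract.gt(vcf, "DP", as.numeric = TRUE) else NULL
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt_raw))
    if (length(missing))
      stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
    gt_raw <- gt_raw[, samples, drop = FALSE]
    if (!is.null(gq_raw)) gq_raw <- gq_raw[, samples, drop = FALSE]
    if (!is.null(dp_raw)) dp_raw <- dp_raw[, samples, drop = FALSE]
  }
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  src <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  sites <- data.frame(chrom = fix$CHROM[src],
                      pos = as.integer(fix$POS[src]),
                      ref = fix$REF[src],
                      alt = unlist(alt_list),
                      n_alleles = n_alt[src] + 1L,
                      flagged = n_alt[src] + 1L > 4L,
                      stringsAsFactors = FALSE)
  gt <- matrix(NA_integer_, nrow(sites), ncol(gt_raw),
               dimnames = list(NULL, colnames(gt_raw)))
  tok <- apply(gt_raw, 2, function(col) strsplit(col, "[/|]"))
  for (r in seq_len(nrow(sites))) {
    a <- as.character(alt_idx[r])
    s <- src[r]
    for (j in seq_len(ncol(gt_raw))) {
      al <- tok[[j]][[s]]
      if (is.null(al) || any(al == ".") || is.na(gt_raw[s, j])) next
      gt[r, j] <- sum(al == a)
    }
  }
  expand <- function(m) if (is.null(m)) NULL else m[src, , drop = FALSE]
  list(sites = sites, gt = gt, gq = expand(gq_raw), dp = expand(dp_raw))
}

## Hardy-Weinberg chi-squared test from dosages (0/1/2) at one site.
hwe_pvalue <- function(dos) {
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  if (n == 0) return(1)
  n_het <- sum(dos == 1)
  n_hom <- sum(dos == 2)
  p <- (n_het + 2 * n_hom) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n - n_het - n_hom, n_het, n_hom)
  x2 <- sum((o - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Genotype and variant quality control
#'
#' Applies the standard sequencing QC thresholds: genotypes with
#' GQ < 20 or depth < 8 are set missing; sites with more than four
#' alleles, genotyping rate below 90%, or Hardy-Weinberg P-value
#' at or below 0.001 are removed. A filter whose annotation (GQ/DP) is
#' absent is skipped with a warning. Set a threshold to `NULL` to disable
#' it.
#'
#' @param vcf_data Output of [read_vcf_minimal()].
#' @param gq_min,dp_min Per-genotype minimums.
#' @param max_alleles Maximum alleles at a site.
#' @param rate_min Minimum per-variant genotyping rate.
#' @param hwe_p_min Sites with HWE P-value `<=` this are removed.
#' @return A filtered object of the same shape.
#' @export
apply_genotype_qc <- function(vcf_data, gq_min = 20, dp_min = 8,
                              max_alleles = 4, rate_min = 0.9,
                              hwe_p_min = 0.001) {
  gt <- vcf_data$gt
  if (!is.null(gq_min)) {
    if (is.null(vcf_data$gq))
      warning("no GQ field in input; genotype-quality filter skipped")
    else gt[!is.na(vcf_data$gq) & vcf_data$gq < gq_min] <- NA_integer_
  }
  if (!is.null(dp_min)) {
    if (is.null(vcf_data$dp))
      warning("no DP field in input; depth filter skipped")
    else gt[!is.na(vcf_data$dp) & vcf_data$dp < dp_min] <- NA_integer_
  }
  keep <- rep(TRUE, nrow(vcf_data$sites))
  if (!is.null(max_alleles))
    keep <- keep & vcf_data$sites$n_alleles <= max_alleles
  if (!is.null(rate_min))
    keep <- keep & rowMeans(!is.na(gt)) >= rate_min
  if (!is.null(hwe_p_min))
    keep <- keep & apply(gt, 1, hwe_pvalue) > hwe_p_min
  out <- list(sites = vcf_data$sites[keep, , drop = FALSE],
              gt = gt[keep, , drop = FALSE],
              gq = if (is.null(vcf_data$gq)) NULL
                   else vcf_data$gq[keep, , drop = FALSE],
              dp = if (is.null(vcf_data$dp)) NULL
                   else vcf_data$dp[keep, , drop = FALSE])
  rownames(out$sites) <- NULL
  out
}

#' Build variant records from QC'd genotypes and a resource table
#'
#' Joins each (chrom, pos, ref, alt) site with the variant resource table
#' (gene mapping, consequence, functional score, reference panel AFs) and
#' computes case allele counts and numbers. A variant mapped to several
#' genes yields one record per gene. Sites with no resource entry are
#' dropped.
#'
#' @param vcf_data QC'd output of [apply_genotype_qc()].
#' @param resources Resource table from [read_resources()].
#' @param cohort Column prefix for the counts (`"case"` or `"ctrl"`).
#' @return Variant record table (see [build_burden_table()]).
#' @export
variant_records <- function(vcf_data, resources, cohort = "case") {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  ac <- rowSums(vcf_data$gt, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(vcf_data$gt))
  site_tab <- data.frame(k = key(vcf_data$sites), ac = ac, an = an,
                         stringsAsFactors = FALSE)
  m <- match(key(resources), site_tab$k)
  rec <- resources[!is.na(m), , drop = FALSE]
  rec[[paste0(cohort, "_ac")]] <- as.integer(site_tab$ac[m[!is.na(m)]])
  rec[[paste0(cohort, "_an")]] <- as.integer(site_tab$an[m[!is.na(m)]])
  rownames(rec) <- NULL
  rec
}

check_columns <- function(tab, need, what) {
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(tab)
}

#' Read the per-gene annotation table
#'
#' Tab-separated with header; requires `gene_id, length_kb, gc, oe_mis,
#' mu_mis, oe_lof, mu_lof`. Unknown columns are preserved. Duplicate gene
#' ids are an error.
#'
#' @param path TSV file.
#' @return Typed data frame.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("gene_id", "length_kb", "gc", "oe_mis", "mu_mis",
                       "oe_lof", "mu_lof"), "annotation table")
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s) in annotation: ",
         paste(utils::head(dup, 10), collapse = ", "))
  tab
}

#' Read the variant resource table
#'
#' Tab-separated with header; requires `chrom, pos, ref, alt, gene_id,
#' consequence, score` plus one `af_<panel>` column per reference panel.
#' Genes present here but absent from an annotation table can be reported
#' via the `annotation` argument.
#'
#' @param path TSV file.
#' @param annotation Optional annotation table for cross-reporting.
#' @return Typed data frame.
#' @export
read_resources <- function(path, annotation = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("chrom", "pos", "ref", "alt", "gene_id",
                       "consequence", "score"), "resource table")
  tab$chrom <- as.character(tab$chrom)
  ## single-base alleles like "T" must not be parsed as logicals
  for (col in c("ref", "alt"))
    tab[[col]] <- if (is.logical(tab[[col]]))
      ifelse(tab[[col]], "T", "F") else as.character(tab[[col]])
  if (!is.null(annotation)) {
    extra <- setdiff(unique(tab$gene_id), annotation$gene_id)
    if (length(extra))
      message(length(extra),
              " gene(s) in resources but not in annotation: ",
              paste(utils::head(extra, 10), collapse = ", "))
  }
  tab
}

results_column_map <- c(
  gene = "gene_id", m = "m", minor_alleles = "y_raw",
  weighted_alleles = "y", missense_alleles = "missense_alleles",
  lof_alleles = "lof_alleles", region_length = "x1", freq_score = "x2",
  mu_mis = "x5", mu_lof = "x7", oe_mis = "x4", oe_lof = "x6",
  exon_gc = "x8", expected = "mu_hat", residual = "e",
  residual_std = "e_std", p = "p", q = "q",
  background_flag = "background")

#' Write the results table and run manifest
#'
#' Writes a tab-separated per-gene report (gene, allele counts, the eight
#' predictors, residual, standardized residual, `p`, `q`, background
#' flag) and, optionally, a JSON manifest recording the chosen `(b, t)`,
#' the converged model, the iteration log and a configuration hash. The
#' TSV round-trips losslessly through [read_results()].
#'
#' @param result A `burden_result` from [run_burden()].
#' @param path Output TSV path.
#' @param manifest_path Optional JSON manifest path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, manifest_path = NULL) {
  res <- result$results
  cols <- results_column_map[results_column_map %in% names(res)]
  tab <- res[, cols, drop = FALSE]
  names(tab) <- names(cols)
  for (col in c("p", "q"))
    tab[[col]] <- formatC(tab[[col]], format = "e", digits = 16)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(
      tool = paste0("rvburden ",
                    as.character(utils::packageVersion("rvburden"))),
      b = result$b, t = result$t,
      model = list(beta = as.list(result$model$beta),
                   theta = result$model$theta,
                   loglik = result$model$loglik,
                   converged = result$model$converged,
                   n_fit = result$model$n_fit),
      iterations = result$iterations,
      n_genes = nrow(res),
      config = result$config[c("b", "equal_weights", "d", "rare_af_max",
                               "strict_enrichment")],
      config_hash = config_hash(result$config))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(config))], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Read back a results table written by [write_results()]
#'
#' @param path TSV file.
#' @return Data frame with the written columns, numerics restored.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
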