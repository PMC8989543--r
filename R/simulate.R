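## Synthetic data with the statistical structure the burden test assumes:
## gene-level predictors, NB-distributed weighted counts, variant-level
## records with rare reference frequencies and functional scores, and
## injected susceptibility genes. Everything is seed-deterministic.

#' Simulation configuration
#'
#' Defaults describe a whole-exome-scale null study: 15,000 genes, 450
#' sequenced cases, dispersion 10, and coefficient/predictor scales chosen
#' so that the mean weighted burden per gene is about 36 weighted alleles
#' (a few rare alleles per gene amplified by functional weights of order
#' `1/b`). Counts scale linearly with `n_cases` relative to the reference
#' 450 cases.
#'
#' @param n_genes Number of genes.
#' @param beta True coefficients (intercept first). With
#'   `design = "genomic"` length 9; with `design = "simple"` any length,
#'   predictors drawn i.i.d. standard normal.
#' @param theta True NB dispersion.
#' @param n_cases,n_controls Diploid sample sizes; `n_controls = 0` gives a
#'   case-only dataset (no control columns, enrichment filter inactive).
#' @param design `"genomic"` (eight realistic predictors) or `"simple"`.
#' @param b_ref Score bin used when the generator itself weights variants.
#' @param seed Integer seed; every generator call is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 15000,
                       beta = c(1.8, 0.35, 8, -0.2, 0.3, 0.02,
                                0.15, 0.1, 0.5),
                       theta = 10, n_cases = 450, n_controls = 0,
                       design = c("genomic", "simple"),
                       b_ref = 0.05, seed = 1L) {
  design <- match.arg(design)
  if (theta <= 0) stop("'theta' must be positive")
  if (design == "genomic" && length(beta) != 9L)
    stop("'beta' must have 9 elements for the genomic design")
  structure(list(n_genes = n_genes, beta = beta, theta = theta,
                 n_cases = n_cases, n_controls = n_controls,
                 design = design, b_ref = b_ref, seed = as.integer(seed)),
            class = "sim_config")
}

ref_cases <- 450 # sample size at which the default burden scale is set

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

## Draw the gene-level predictor matrix (without x2/x3 for the genomic
## design, which are derived from variants or drawn directly).
sim_predictors <- function(config, with_x2 = TRUE) {
  n <- config$n_genes
  if (config$design == "simple") {
    k <- length(config$beta) - 1L
    X <- matrix(stats::rnorm(n * k), n, k)
    colnames(X) <- paste0("x", seq_len(k))
    return(X)
  }
  x1 <- stats::rlnorm(n, 0.3, 0.55)            # coding length, kb
  x4 <- stats::runif(n, 0.4, 1.2)              # oe_mis
  x5 <- stats::rlnorm(n, log(13), 0.4)         # mu_mis
  x6 <- stats::runif(n, 0.1, 1.2)              # oe_lof
  x7 <- stats::rlnorm(n, 0, 0.5)               # mu_lof
  x8 <- stats::rbeta(n, 20, 18)                # exon GC
  X <- cbind(x1 = x1, x2 = NA_real_, x3 = NA_real_, x4 = x4, x5 = x5,
             x6 = x6, x7 = x7, x8 = x8)
  if (with_x2) {
    X[, "x2"] <- x1 * stats::rgamma(n, 2, 2) * 0.01 # frequency score
    X[, "x3"] <- x1 * X[, "x2"]
  }
  X
}

#' Simulate a gene-level burden table
#'
#' Draws predictors and weighted counts `y ~ NB(mu, theta)` with
#' `mu = exp(X beta) * n_cases / 450`, i.e. data exactly under the count
#' model the test fits. The truth (`beta`, `theta`, `mu`) is attached as
#' the `"truth"` attribute.
#'
#' @param config A [sim_config()].
#' @return Gene burden table with `gene_id`, `y` and predictor columns.
#' @export
simulate_burden <- function(config = sim_config()) {
  set.seed(config$seed)
  X <- sim_predictors(config)
  scale <- config$n_cases / ref_cases
  mu <- exp(clamp_eta(drop(cbind(1, X) %*% config$beta))) * scale
  ## a gene's burden sums independent per-individual contributions, so the
  ## NB shape parameter scales with the sample size alongside the mean
  y <- stats::rnbinom(config$n_genes, size = config$theta * scale, mu = mu)
  rows <- data.frame(gene_id = sim_gene_ids(config$n_genes), y = y,
                     X, stringsAsFactors = FALSE)
  attr(rows, "truth") <- list(beta = config$beta, theta = config$theta,
                              mu = mu, config = config)
  rows
}

#' Simulate variant-level records, annotation and burden rows
#'
#' Full emulation of the pipeline inputs: per-gene variant counts grow
#' with coding length; per-variant reference frequencies are rare
#' (mean ~0.15%, two ancestry panels with correlated jitter); functional
#' scores are Uniform(0, 1]. The gene's raw minor-allele total is drawn so
#' that its weighted total (at `b_ref`) is approximately
#' `NB(exp(X beta), theta)`, and the total is split across variants by a
#' symmetric Dirichlet-multinomial. With `n_controls > 0`, null control
#' counts are binomial at the case frequency.
#'
#' @param config A [sim_config()] (genomic design).
#' @return `list(records, annotation, rows, truth)`; `rows` is the burden
#'   table built by the real pipeline at `b_ref`.
#' @export
simulate_background <- function(config = sim_config()) {
  if (config$design != "genomic")
    stop("variant-level simulation requires the genomic design")
  set.seed(config$seed)
  n <- config$n_genes
  gid <- sim_gene_ids(n)
  X <- sim_predictors(config, with_x2 = FALSE)
  m <- 1L + stats::rpois(n, 3 * X[, "x1"])
  total_m <- sum(m)
  vg <- rep(seq_len(n), m)

  f <- pmin(stats::rexp(total_m, rate = 1 / 0.0015), 0.009)
  jit <- function() pmin(f * stats::rlnorm(total_m, 0, 0.3), 0.0099)
  af_eas <- jit(); af_eur <- jit()
  fbar <- (af_eas + af_eur) / 2
  score <- stats::runif(total_m)
  w_ref <- score_to_weight(score, config$b_ref)

  x2 <- as.numeric(tapply(fbar * w_ref, vg, sum))
  X[, "x2"] <- x2
  X[, "x3"] <- X[, "x1"] * x2
  scale <- config$n_cases / ref_cases
  mu_w <- exp(clamp_eta(drop(cbind(1, X) %*% config$beta))) * scale
  wbar <- as.numeric(tapply(w_ref, vg, mean))
  ## dispersion scales with sample size: the total sums per-individual
  ## contributions and NB shape parameters add over independent subjects
  y_raw <- stats::rnbinom(n, size = config$theta * scale,
                          mu = mu_w / wbar)

  ## Dirichlet(1)-multinomial split of each gene's total across variants
  alloc <- numeric(total_m)
  pr <- stats::rgamma(total_m, 1)
  idx <- split(seq_len(total_m), vg)
  for (i in seq_len(n)) {
    ii <- idx[[i]]
    if (y_raw[i] > 0)
      alloc[ii] <- stats::rmultinom(1, y_raw[i], pr[ii] / sum(pr[ii]))
  }
  consequence <- sample(c("missense", "stop-gain", "splicing",
                          "frameshift", "non-frameshift"),
                        total_m, replace = TRUE,
                        prob = c(0.75, 0.08, 0.07, 0.05, 0.05))
  records <- data.frame(
    chrom = "1", pos = seq_len(total_m) * 100L,
    ref = "A", alt = "T", gene_id = gid[vg], consequence = consequence,
    score = score, case_ac = as.integer(alloc),
    case_an = 2L * config$n_cases,
    af_eas = af_eas, af_eur = af_eur, stringsAsFactors = FALSE)
  if (config$n_controls > 0) {
    case_af <- pmax(records$case_ac / records$case_an, 1e-6)
    records$ctrl_ac <- stats::rbinom(total_m, 2L * config$n_controls,
                                     pmin(case_af, 0.5))
    records$ctrl_an <- 2L * config$n_controls
  }
  annotation <- data.frame(gene_id = gid, length_kb = X[, "x1"],
                           gc = X[, "x8"], oe_mis = X[, "x4"],
                           mu_mis = X[, "x5"], oe_lof = X[, "x6"],
                           mu_lof = X[, "x7"], stringsAsFactors = FALSE)
  wc <- weight_config(b = config$b_ref,
                      d = if (config$n_controls > 0) 2 else NULL)
  rows <- build_burden_table(records, annotation, wc)
  list(records = records, annotation = annotation, rows = rows,
       truth = list(beta = config$beta, theta = config$theta,
                    causal = character(0), config = config))
}

#' Inject susceptibility variants into a synthetic dataset
#'
#' Adds 4-5 risk variants to each chosen gene: case allele counts are
#' `Binomial(2 n_cases, freq)` with per-variant risk-allele frequencies
#' drawn from `freq_range`, and control frequencies equal the case
#' frequency divided by an odds ratio drawn from `or_range`
#' (`Inf` yields zero control counts). Reference-panel frequencies are set
#' near the control frequency so the variants stay rare. Burden rows are
#' rebuilt after injection.
#'
#' @param dataset Output of [simulate_background()].
#' @param genes Gene ids to make causal; `n_causal` random genes if `NULL`.
#' @param n_causal Number of random causal genes when `genes` is `NULL`.
#' @param freq_range Risk-allele frequency range in cases.
#' @param or_range Odds-ratio range (may include `Inf`).
#' @param n_variants_range Variants injected per gene.
#' @param seed Seed for the injection draws.
#' @return The dataset with injected records, rebuilt `rows` and
#'   `truth$causal` updated.
#' @export
inject_causal <- function(dataset, genes = NULL, n_causal = 5,
                          freq_range = c(0.010, 0.015), or_range = c(2, 5),
                          n_variants_range = 4:5, seed = 1L) {
  config <- dataset$truth$config
  set.seed(seed)
  if (is.null(genes)) {
    if (n_causal == 0) return(dataset)
    genes <- sample(dataset$annotation$gene_id, n_causal)
  }
  if (length(genes) == 0) return(dataset)
  new <- list()
  for (g in genes) {
    nv <- if (length(n_variants_range) == 1L) n_variants_range
          else sample(n_variants_range, 1)
    freq <- stats::runif(nv, freq_range[1], freq_range[2])
    or <- if (all(is.infinite(or_range))) rep(Inf, nv)
          else stats::runif(nv, or_range[1], or_range[2])
    case_ac <- stats::rbinom(nv, 2L * config$n_cases, freq)
    f_ctrl <- ifelse(is.infinite(or), 0, freq / or)
    rec <- data.frame(
      chrom = "2", pos = seq_len(nv) + 1000000L * match(g, genes),
      ref = "G", alt = "C", gene_id = g, consequence = "missense",
      score = stats::runif(nv, 0.5, 1), case_ac = case_ac,
      case_an = 2L * config$n_cases,
      ## inserted variants are effectively absent from reference panels:
      ## rare enough to pass the AF filter, negligible frequency score
      af_eas = 1e-5, af_eur = 1e-5, stringsAsFactors = FALSE)
    if (config$n_controls > 0) {
      rec$ctrl_ac <- stats::rbinom(nv, 2L * config$n_controls, f_ctrl)
      rec$ctrl_an <- 2L * config$n_controls
    }
    new[[g]] <- rec
  }
  dataset$records <- rbind(dataset$records, do.call(rbind, new))
  wc <- weight_config(b = config$b_ref,
                      d = if (config$n_controls > 0) 2 else NULL)
  dataset$rows <- build_burden_table(dataset$records, dataset$annotation,
                                     wc)
  dataset$truth$causal <- union(dataset$truth$causal, genes)
  dataset
}

#' Empirical type-1-error evaluation on null replicates
#'
#' Simulates null burden tables, runs the recursive fit, and reports the
#' fraction of in-support genes with `p <= alpha` plus the MLFC per
#' replicate.
#'
#' @param n_replicates Number of null replicates.
#' @param config A [sim_config()]; its seed offsets per replicate.
#' @param alpha Rejection thresholds to tally.
#' @param t Truncation point used in the fit.
#' @return Data frame, one row per replicate, with `rej_<alpha>` columns
#'   and `mlfc`.
#' @export
type1_error_eval <- function(n_replicates = 10, config = sim_config(),
                             alpha = c(1e-4, 0.001, 0.01, 0.05), t = 0) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    rows <- simulate_burden(cfg)
    fit <- recursive_fit(rows, t = t)
    p <- fit$scores$p[fit$scores$in_support]
    rej <- vapply(alpha, function(a) mean(p <= a), numeric(1))
    names(rej) <- paste0("rej_", alpha)
    out[[r]] <- data.frame(replicate = r, seed = cfg$seed, t(rej),
                           mlfc = mlfc(p), n = length(p),
                           check.names = FALSE)
  }
  do.call(rbind, out)
}

#' Power estimation for an injected susceptibility gene
#'
#' For each sample size, simulates `n_replicates` datasets with one
#' injected causal gene, runs the burden test (fixed `b_ref`, `t`), and
#' estimates power as `k / t_hat`: the fraction of replicates whose causal
#' gene reaches `p <= alpha`.
#'
#' @param sample_sizes Total subjects (half cases) per scenario.
#' @param n_replicates Replicates per scenario.
#' @param config A [sim_config()]; `n_genes` may be scaled down for speed.
#' @param alpha Significance threshold (exome-wide 2.5e-6 by default).
#' @param t Truncation point for the fit.
#' @param freq_range,or_range,n_variants_range Injection parameters, see
#'   [inject_causal()].
#' @return Data frame `sample_size, k, replicates, power, alpha`.
#' @export
power_eval <- function(sample_sizes = c(300, 600, 900), n_replicates = 100,
                       config = sim_config(n_genes = 2000), alpha = 2.5e-6,
                       t = 0, freq_range = c(0.010, 0.015),
                       or_range = c(2, 5), n_variants_range = 4:5) {
  out <- vector("list", length(sample_sizes))
  for (s in seq_along(sample_sizes)) {
    k <- 0L
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$n_cases <- sample_sizes[s] %/% 2L
      cfg$n_controls <- 0L
      ## common random numbers across sample sizes: replicate r reuses the
      ## same seed at every n, pairing the power comparisons
      cfg$seed <- config$seed + r
      ds <- simulate_background(cfg)
      ## inject into a gene of typical baseline burden (a fixed absolute
      ## signal is diluted in long, high-baseline genes), chosen by the
      ## scale-free population mean so the target is the same gene at
      ## every sample size under a shared seed
      mu0 <- exp(clamp_eta(
        drop(cbind(1, burden_design(ds$rows)) %*% cfg$beta)))
      target <- ds$rows$gene_id[which.min(abs(mu0 -
                                                stats::median(mu0)))]
      ds <- inject_causal(ds, genes = target,
                          freq_range = freq_range, or_range = or_range,
                          n_variants_range = n_variants_range,
                          seed = cfg$seed)
      fit <- recursive_fit(ds$rows, t = t)
      pg <- fit$scores$p[fit$scores$gene_id == ds$truth$causal[1]]
      if (length(pg) && pg <= alpha) k <- k + 1L
    }
    out[[s]] <- data.frame(sample_size = sample_sizes[s], k = k,
                           replicates = n_replicates,
                           power = k / n_replicates, alpha = alpha)
  }
  do.call(rbind, out)
}
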