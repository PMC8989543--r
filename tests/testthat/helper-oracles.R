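# Independent oracles used to check the package's own computations.

# Zero-truncated NB regression fit written from the explicit formula
# (lgamma terms, truncation denominator 1 - (theta/(mu+theta))^theta),
# optimized with numerical gradients. Deliberately shares no code with
# fit_tnb().
oracle_ztnb_fit <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  p <- ncol(Xd)
  negll <- function(par) {
    beta <- par[seq_len(p)]
    th <- exp(par[p + 1])
    mu <- exp(drop(Xd %*% beta))
    lf <- lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
      y * log(mu) + th * log(th) - (y + th) * log(mu + th)
    lp0 <- th * (log(th) - log(mu + th)) # log P(Y = 0)
    -sum(lf - log1p(-exp(lp0)))
  }
  init <- c(coef(glm.fit(Xd, y, family = poisson())), 0)
  o <- optim(init, negll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  o <- optim(o$par, negll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  list(beta = o$par[seq_len(p)], theta = unname(exp(o$par[p + 1])),
       loglik = -o$value)
}

# Dense 1-D grid maximizer of the truncated-NB log-likelihood in mu.
oracle_saturated_mu <- function(y, theta, t, grid_n = 40000) {
  mu <- seq(1e-8, 10 * max(y, 1), length.out = grid_n)
  ll <- dnbinom(y, size = theta, mu = mu, log = TRUE) -
    pnbinom(t, size = theta, mu = mu, lower.tail = FALSE, log.p = TRUE)
  mu[which.max(ll)]
}

# Central finite differences of the truncated-NB total log-likelihood.
oracle_fd_grad <- function(beta, log_theta, y, X, t, h = 1e-5) {
  par <- c(beta, log_theta)
  p <- length(beta)
  f <- function(pp)
    tnb_loglik_grad(pp[seq_len(p)], pp[p + 1], y, X, t)$loglik
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# A small hand-assembled variant record table (two genes, one variant
# shared between them).
toy_records <- function() {
  data.frame(
    chrom = "1", pos = c(100, 200, 300, 300),
    ref = "A", alt = "T",
    gene_id = c("GA", "GA", "GA", "GB"),
    consequence = c("missense", "stop-gain", "missense", "missense"),
    score = c(0.2, NA, 0.4, 0.4),
    case_ac = c(1L, 2L, 1L, 1L), case_an = 20L,
    af_eas = c(0.001, 0.002, 0.004, 0.004),
    af_eur = c(0.001, 0.002, 0.002, 0.002),
    stringsAsFactors = FALSE)
}

toy_annotation <- function() {
  data.frame(gene_id = c("GA", "GB", "GC"),
             length_kb = c(2, 1.5, 3.477), gc = c(0.5, 0.4, 0.585),
             oe_mis = c(0.9, 1.0, 0.896), mu_mis = c(10, 12, 44.853),
             oe_lof = c(0.5, 0.8, 0.039), mu_lof = c(1, 0.9, 2.678),
             stringsAsFactors = FALSE)
}

# Write a small VCF 4.2 fixture: 5 samples; sites exercising missingness,
# low depth, a penta-allelic record and a multi-allelic split.
write_toy_vcf <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Qual\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste0("S", 1:5, collapse = "\t")))
  g <- function(gt, gq = 50, dp = 30) paste(gt, gq, dp, sep = ":")
  rows <- c(
    paste("1", 100, ".", "A", "T", ".", "PASS", ".", "GT:GQ:DP",
          g("0/1"), g("0/0"), g("1/1"), g("0/0"), g("0/0"), sep = "\t"),
    paste("1", 200, ".", "G", "C", ".", "PASS", ".", "GT:GQ:DP",
          g("./."), g("0/1"), g("0/0"), g("0/0"), g("0/0"), sep = "\t"),
    paste("1", 300, ".", "T", "A,G", ".", "PASS", ".", "GT:GQ:DP",
          g("1/2"), g("0/1"), g("0/0"), g("0/2"), g("0/0"), sep = "\t"),
    paste("1", 400, ".", "C", "A,G,T,CT", ".", "PASS", ".", "GT:GQ:DP",
          g("0/1"), g("0/2"), g("0/3"), g("0/4"), g("0/0"), sep = "\t"),
    paste("1", 500, ".", "A", "G", ".", "PASS", ".", "GT:GQ:DP",
          g("0/1", dp = 6), g("0/0"), g("0/0"), g("0/0"), g("0/0"),
          sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
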