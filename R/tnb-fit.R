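## Maximum-likelihood fitting of the truncated NB log-link regression.
## Parameterized as (beta, log theta) so the dispersion stays positive
## without constraints; optimized by BFGS with the analytic gradient.

#' Truncated-NB regression log-likelihood and gradient
#'
#' Total log-likelihood \eqn{\sum_i \log g(y_i \mid \mu_i, \theta, t)} with
#' \eqn{\mu_i = \exp(x_i' \beta)}, together with its analytic gradient over
#' `(beta, log theta)`. The truncation denominator contributes
#' `-d log P(Y > t)` terms, accumulated over `j = 0..t`.
#'
#' @param beta Coefficient vector matching `ncol(X)`.
#' @param log_theta Log-dispersion (scalar).
#' @param y Integer counts, all `> t`.
#' @param X Design matrix including the intercept column.
#' @param t Integer truncation point `>= -1`.
#' @param fixed_theta If non-`NULL`, dispersion held at this value and the
#'   gradient is over `beta` only (used for the truncated-Poisson contrast).
#' @return `list(loglik, grad)`; `grad` is over `c(beta, log_theta)` unless
#'   `fixed_theta` is given.
#' @export
tnb_loglik_grad <- function(beta, log_theta, y, X, t, fixed_theta = NULL) {
  t <- check_trunc(t)
  if (length(y) == 0L) stop("no observations supplied")
  if (any(y <= t)) stop("all counts must exceed the truncation point 't'")
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)")
  ## clamp so that wild line-search steps keep theta finite and positive
  theta <- if (is.null(fixed_theta)) exp(pmin(pmax(log_theta, -20), 25))
           else fixed_theta
  eta <- clamp_eta(drop(X %*% beta))
  mu <- exp(eta)
  ll <- sum(tnb_logdens(y, mu, theta, t))

  ## d log f / d mu at the observed counts
  dlf_dmu <- y / mu - (y + theta) / (mu + theta)
  finite_th <- is.finite(theta)
  if (finite_th)
    dlf_dth <- digamma(y + theta) - digamma(theta) + log(theta) + 1 -
      log(mu + theta) - (y + theta) / (mu + theta)
  ## truncation denominator S = P(Y > t): subtract d log S
  dlS_dmu <- 0
  dlS_dth <- 0
  if (t >= 0) {
    lS <- log_surv_t(mu, theta, t)
    for (j in 0:t) {
      r <- exp(nb_pmf(j, mu, theta, log = TRUE) - lS) # f(j)/S
      dlS_dmu <- dlS_dmu - r * (j / mu - (j + theta) / (mu + theta))
      if (finite_th)
        dlS_dth <- dlS_dth -
          r * (digamma(j + theta) - digamma(theta) + log(theta) + 1 -
                 log(mu + theta) - (j + theta) / (mu + theta))
    }
  }
  gbeta <- drop(crossprod(X, (dlf_dmu - dlS_dmu) * mu))
  if (is.null(fixed_theta)) {
    gth <- theta * sum(dlf_dth - dlS_dth)
    list(loglik = ll, grad = c(gbeta, gth))
  } else {
    list(loglik = ll, grad = gbeta)
  }
}

clamp_eta <- function(eta) pmin(pmax(eta, -30), 30)

#' Fit a truncated negative-binomial regression
#'
#' Maximizes the truncated-NB likelihood over `(beta, log theta)` by BFGS.
#' Initialization: `beta` from a Poisson log-linear fit on the in-support
#' counts, `log theta` from a method-of-moments dispersion estimate.
#' Convergence is declared when the per-observation gradient max-norm falls
#' below `grad_tol`.
#'
#' @param y Integer counts, all `> t`.
#' @param X Predictor matrix (without intercept; one is added). Columns are
#'   checked for zero variance and collinearity.
#' @param t Integer truncation point (`0` fits a zero-truncated model;
#'   `-1` an untruncated one).
#' @param init Optional starting values `c(beta0, beta..., log_theta)`.
#' @param fixed_theta Hold the dispersion at this value (e.g. a large value
#'   for a truncated-Poisson fit) instead of estimating it.
#' @param max_iter Maximum BFGS iterations.
#' @param grad_tol Convergence tolerance on `max |grad| / n`.
#' @return A `tnb_model`: coefficients `beta` (intercept first), `theta`,
#'   `t`, `converged`, `loglik`, `n_fit`, and observed-information `vcov`.
#' @export
fit_tnb <- function(y, X, t = 0, init = NULL, fixed_theta = NULL,
                    max_iter = 500L, grad_tol = 1e-6) {
  t <- check_trunc(t)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(y <= t)) stop("all counts must exceed the truncation point 't'")
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  n <- length(y)
  if (n < 10 * (p + is.null(fixed_theta)))
    stop("too few observations relative to the number of coefficients")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (qr(Xd)$rank < p)
    stop("collinear predictor columns: design matrix is rank deficient")

  if (is.null(init)) {
    b0 <- stats::glm.fit(Xd, y, family = stats::poisson())$coefficients
    lt0 <- if (is.null(fixed_theta)) {
      m <- mean(y); v <- stats::var(y)
      log(if (v > m) min(m^2 / (v - m), 1e4) else 1e2)
    } else numeric(0)
    init <- c(b0, lt0)
  }

  nll <- function(par) {
    b <- par[seq_len(p)]
    lt <- if (is.null(fixed_theta)) par[p + 1L] else NA_real_
    -tnb_loglik_grad(b, lt, y, Xd, t, fixed_theta)$loglik
  }
  ngr <- function(par) {
    b <- par[seq_len(p)]
    lt <- if (is.null(fixed_theta)) par[p + 1L] else NA_real_
    -tnb_loglik_grad(b, lt, y, Xd, t, fixed_theta)$grad
  }
  ## BFGS with restarts: reltol can trigger before the gradient criterion,
  ## so polish by re-starting from the current optimum (cheap when already
  ## converged)
  opt <- stats::optim(init, fn = nll, gr = ngr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  for (r in 1:2) {
    if (max(abs(ngr(opt$par))) / n < grad_tol) break
    opt <- stats::optim(opt$par, fn = nll, gr = ngr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
  }
  par <- opt$par
  ## damped Newton polish: BFGS can stall with the gradient just above
  ## the criterion once relative objective changes hit machine precision
  val <- opt$value
  for (k in 1:10) {
    g <- ngr(par)
    if (max(abs(g)) / n < grad_tol) break
    H <- tryCatch(stats::optimHess(par, nll, ngr), error = function(e) NULL)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      cand <- par - lam * step
      cv <- nll(cand)
      if (is.finite(cv) && cv <= val + 1e-10) { par <- cand; val <- cv; break }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (lam < 1e-4) break
  }
  beta <- par[seq_len(p)]
  names(beta) <- colnames(Xd)
  theta <- if (is.null(fixed_theta)) unname(exp(par[p + 1L]))
           else fixed_theta
  g <- ngr(par)
  converged <- max(abs(g)) / n < grad_tol
  if (!converged)
    warning("truncated-NB fit did not reach the gradient tolerance ",
            "(max |grad|/n = ", signif(max(abs(g)) / n, 3), ")")
  vcov <- tryCatch({
    H <- stats::optimHess(par, nll, ngr)
    solve(H)
  }, error = function(e) matrix(NA_real_, length(par), length(par)))

  structure(list(beta = beta, theta = theta, t = t, b = NA_real_,
                 converged = converged, loglik = -opt$value, n_fit = n,
                 vcov = vcov, counts = opt$counts), class = "tnb_model")
}

#' @exportS3Method base::print
print.tnb_model <- function(x, ...) {
  cat("Truncated negative-binomial regression (t =", x$t, ")\n")
  cat("  coefficients:\n")
  print(signif(x$beta, 4))
  cat("  theta:", signif(x$theta, 4),
      " loglik:", signif(x$loglik, 8),
      " n:", x$n_fit,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Fitted mean counts from a truncated-NB model
#'
#' \eqn{\hat\mu = \exp(\hat\beta_0 + \sum_k \hat\beta_k x_k)}.
#'
#' @param model A `tnb_model`.
#' @param X Predictor matrix with the same columns the model was fit on
#'   (no intercept column).
#' @return Positive fitted means.
#' @export
predict_mu <- function(model, X) {
  X <- as.matrix(X)
  exp(clamp_eta(drop(cbind(1, X) %*% model$beta)))
}

#' Standardize residuals and convert to one-sided P-values
#'
#' Deviance residuals are centred and scaled by the empirical mean and
#' standard deviation of the residuals over the background gene set, then
#' referred to the standard normal upper tail:
#' \eqn{p = 1 - \Phi((e - \bar e_{bg}) / s_{bg})}.
#'
#' @param e Residuals of all genes to score.
#' @param e_background Residuals of the background (null-model) genes used
#'   for the moments; needs at least two values with nonzero variance.
#' @return `list(e_std, p, mean, sd)`.
#' @export
standardize_scores <- function(e, e_background) {
  e_background <- e_background[is.finite(e_background)]
  if (length(e_background) < 2L)
    stop("need at least two background residuals to estimate moments")
  m <- mean(e_background)
  s <- stats::sd(e_background)
  if (s == 0) stop("background residuals have zero variance")
  z <- (e - m) / s
  list(e_std = z, p = stats::pnorm(z, lower.tail = FALSE), mean = m, sd = s)
}

#' Score genes under a fitted truncated-NB model
#'
#' Computes fitted means, saturated means and deviance residuals for
#' in-support genes (`y > t`); out-of-support genes get `p = 1` and `NA`
#' residuals since they cannot show excess burden.
#'
#' @param model A `tnb_model`.
#' @param rows Gene burden table with column `y` and predictor columns
#'   `x1, x2, ...` (see [build_burden_table()]).
#' @param background Logical vector marking the genes whose residual
#'   moments standardize the scores; defaults to all in-support genes.
#' @return Data frame with `mu_hat`, `mu_star`, `e`, `e_std`, `p`,
#'   `in_support` aligned with `rows`.
#' @export
tnb_score <- function(model, rows, background = NULL) {
  X <- burden_design(rows)
  y <- rows$y
  ins <- y > model$t
  mu_hat <- predict_mu(model, X)
  mu_star <- e <- rep(NA_real_, length(y))
  mu_star[ins] <- saturated_mu(y[ins], model$theta, model$t)
  e[ins] <- deviance_residual(y[ins], mu_hat[ins], model$theta, model$t,
                              mu_star = mu_star[ins])
  if (is.null(background)) background <- ins
  std <- standardize_scores(e, e[background & ins])
  p <- ifelse(ins, std$p, 1)
  e_std <- ifelse(ins, std$e_std, NA_real_)
  data.frame(gene_id = if (!is.null(rows$gene_id)) rows$gene_id
             else seq_along(y),
             y = y, mu_hat = mu_hat, mu_star = mu_star, e = e,
             e_std = e_std, p = p, in_support = ins,
             stringsAsFactors = FALSE)
}

## Extract the x1..xK predictor matrix from a burden table.
burden_design <- function(rows) {
  xc <- grep("^x[0-9]+$", names(rows), value = TRUE)
  xc <- xc[order(as.integer(sub("^x", "", xc)))]
  if (length(xc) == 0L) stop("no predictor columns (x1, x2, ...) found")
  as.matrix(rows[, xc, drop = FALSE])
}

#' Serialize a fitted model to JSON
#'
#' Plain-document form of a `tnb_model` (coefficients, dispersion,
#' truncation point, weighting bin, log-likelihood, convergence) for run
#' manifests.
#'
#' @param model A `tnb_model`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
tnb_model_json <- function(model, path = NULL) {
  doc <- list(beta = as.list(model$beta), theta = model$theta,
              t = model$t, b = model$b, loglik = model$loglik,
              n_fit = model$n_fit, converged = model$converged)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
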