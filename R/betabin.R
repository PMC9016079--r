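#' Beta-binomial test of allelic imbalance (heterozygous subjects only)
#'
#' The comparator model: for each heterozygous subject the effect-allele
#' count \eqn{y_A} out of the pair total \eqn{n = y_A + y_a} follows a
#' beta-binomial distribution with mean \eqn{\pi = \mathrm{logit}^{-1}(\beta)}
#' and precision \eqn{\theta} (shape parameters \eqn{\pi\theta},
#' \eqn{(1-\pi)\theta}). Testing \eqn{\beta = 0} tests the allelic
#' proportion against 1/2; the overdispersion absorbed by \eqn{\theta}
#' plays the role of the observation-level random effect of the HPMM.
#' Estimation is by direct maximization of the beta-binomial likelihood;
#' the p-value is a two-sided Wald test.
#'
#' @param design an [build_design()] object or data frame of observations;
#'   only subjects contributing the paired allelic patterns (two rows, `X`
#'   equal to 1 and 0) are used. Alternatively supply `y_eff`/`n` directly.
#' @param y_eff,n optional vectors of effect-allele counts and pair totals,
#'   bypassing `design`.
#' @return A list of class `betabin_fit`: `beta` (log-odds of the effect
#'   allele), `se_beta`, `p_value`, `theta` (precision), `rho`
#'   (intra-pair correlation \eqn{1/(1+\theta)}), `loglik`, `converged`,
#'   `n_pairs`.
#' @export
fit_betabin <- function(design = NULL, y_eff = NULL, n = NULL) {
  if (is.null(y_eff)) {
    obs <- as.data.frame(design)
    split_ids <- names(which(table(obs$subject_id) == 2L))
    obs <- obs[obs$subject_id %in% split_ids & obs$X %in% c(0, 1), ]
    if (nrow(obs) == 0L) stop("no heterozygous (paired) observations")
    ya <- obs$y[obs$X == 1][match(split_ids, obs$subject_id[obs$X == 1])]
    yo <- obs$y[obs$X == 0][match(split_ids, obs$subject_id[obs$X == 0])]
    y_eff <- ya
    n <- ya + yo
  }
  keep <- n > 0
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) with zero total count dropped")
    y_eff <- y_eff[keep]; n <- n[keep]
  }
  if (length(n) == 0L) stop("no usable pairs")

  nll <- function(par) {
    pi <- stats::plogis(par[1])
    th <- exp(par[2])
    a <- pi * th
    b <- (1 - pi) * th
    -sum(lchoose(n, y_eff) + lbeta(y_eff + a, n - y_eff + b) - lbeta(a, b))
  }
  p0 <- (sum(y_eff) + 0.5) / (sum(n) + 1)
  opt <- stats::nlminb(c(stats::qlogis(p0), log(10)), nll,
                       control = list(rel.tol = 1e-12, iter.max = 500))
  hess <- stats::optimHess(opt$par, nll)
  vc <- tryCatch(solve(hess), error = function(e)
    matrix(NA_real_, 2, 2))
  se <- sqrt(vc[1, 1])
  beta <- opt$par[1]
  structure(list(
    beta = beta, se_beta = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    theta = exp(opt$par[2]), rho = 1 / (1 + exp(opt$par[2])),
    loglik = -opt$objective, converged = opt$convergence == 0,
    n_pairs = length(n)
  ), class = "betabin_fit")
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat("Beta-binomial allelic-imbalance test\n")
  cat(sprintf("  pairs: %d  beta = %.4f (se %.4f), p = %.3g\n",
              x$n_pairs, x$beta, x$se_beta, x$p_value))
  cat(sprintf("  precision theta = %.3f (rho = %.4f)\n", x$theta, x$rho))
  invisible(x)
}
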