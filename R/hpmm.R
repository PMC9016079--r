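#' @useDynLib asehpmm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

VAR_LOWER <- 1e-10   # variance components bounded below; boundary => 0
VAR_UPPER <- 1e6

#' Fit the hierarchical Poisson mixed model
#'
#' Maximizes the Laplace-approximated marginal likelihood of
#' \deqn{y_{ij} \sim \mathrm{Pois}\{\exp(\mu + X_{ij}\beta + C_{ij}\gamma +
#'       b_i + \varepsilon_{ij}) \cdot K_{ij}\}}
#' over \eqn{(\mu, \beta, \gamma, \mathrm{Var}(b), \mathrm{Var}(\varepsilon))},
#' where \eqn{b_i} is a subject-level random intercept shared by the two
#' allelic observations of a heterozygous subject (pairing them) and
#' \eqn{\varepsilon_{ij}} an observation-level random intercept capturing
#' allele-level overdispersion. \eqn{K_{ij}} enters as a multiplicative
#' offset: the library size for single-observation subjects, half of it for
#' each allelic observation.
#'
#' The marginal likelihood factorizes by subject; each factor is a low
#' dimensional integral over \eqn{(b_i, \varepsilon_{i\cdot})} approximated
#' by Laplace's method at the joint mode (computed in compiled code).
#'
#' @param design an [build_design()] object, or any data frame with columns
#'   `subject_id`, `y`, `X`, `K` (plus covariate columns).
#' @param include_eps keep the observation-level random effect
#'   \eqn{\varepsilon_{ij}}? Set `FALSE` when summary statistics show no
#'   overdispersion.
#' @param covariates character vector of covariate column names in `design`
#'   (defaults to the design's recorded covariates).
#' @param test `"wald"` (default) or `"lrt"` for the p-value of
#'   \eqn{\beta = 0}.
#' @param auto_drop_eps if the estimate of \eqn{\mathrm{Var}(\varepsilon)}
#'   hits the lower boundary, refit without \eqn{\varepsilon_{ij}} and
#'   report that model (default `TRUE`).
#' @param fix_var_b,fix_var_eps optionally fix a variance component at a
#'   given value (0 removes the effect) instead of estimating it.
#' @param control list: `rel_tol` (relative convergence tolerance, default
#'   `1e-10`) and `max_iter` (default 500) for the outer optimizer.
#' @return An object of class `hpmm_fit` with elements `mu`, `beta`,
#'   `se_beta`, `gamma`, `var_b`, `var_eps`, `p_value`, `loglik`,
#'   `converged`, `n_obs`, `n_subjects`, `n_double_het`, `test`,
#'   `eps_included`, `coefficients`, `vcov`.
#' @seealso [test_beta()], [fit_interaction()], [fit_betabin()]
#' @export
fit_hpmm <- function(design, include_eps = TRUE, covariates = NULL,
                     test = c("wald", "lrt"), auto_drop_eps = TRUE,
                     fix_var_b = NULL, fix_var_eps = NULL, control = list()) {
  test <- match.arg(test)
  if (is.null(covariates)) covariates <- attr(design, "covariate_names")
  fit <- hpmm_fit_internal(design, xterms = c("X", covariates),
                           include_eps = include_eps,
                           fix_var_b = fix_var_b, fix_var_eps = fix_var_eps,
                           control = control)
  if (include_eps && auto_drop_eps && is.null(fix_var_eps) &&
      fit$var_eps == 0) {
    fit <- hpmm_fit_internal(design, xterms = c("X", covariates),
                             include_eps = FALSE, fix_var_b = fix_var_b,
                             fix_var_eps = NULL, control = control)
    fit$eps_dropped <- TRUE
  }
  fit$test <- test
  fit$p_value <- test_beta(fit, method = test, term = "X")
  fit
}

#' Fit the HPMM with a group-by-genotype interaction
#'
#' Adds a binary group main effect \eqn{D_i \alpha} and its interaction with
#' the genotype coding, \eqn{X_{ij} D_i \delta}, to the linear predictor of
#' the HPMM. A differential aseQTL effect between the two groups (e.g. AD
#' cases versus controls, or two age strata) is detected by testing
#' \eqn{\delta = 0}.
#'
#' @inheritParams fit_hpmm
#' @param design design containing a 0/1 column `D` (see [build_design()]'s
#'   `group` argument).
#' @return An `hpmm_interaction_fit` (inherits `hpmm_fit`) with the extra
#'   elements `alpha`, `delta`, `se_delta` and `p_delta`.
#' @export
fit_interaction <- function(design, include_eps = TRUE, covariates = NULL,
                            test = c("wald", "lrt"), auto_drop_eps = TRUE,
                            control = list()) {
  test <- match.arg(test)
  if (is.null(design$D)) stop("design has no group column 'D'")
  if (length(unique(design$D)) < 2L)
    stop("group label is constant; the interaction is not estimable")
  if (is.null(covariates)) covariates <- attr(design, "covariate_names")
  design$XD <- design$X * design$D
  fit <- hpmm_fit_internal(design, xterms = c("X", "D", "XD", covariates),
                           include_eps = include_eps,
                           fix_var_b = NULL, fix_var_eps = NULL,
                           control = control)
  if (include_eps && auto_drop_eps && fit$var_eps == 0) {
    fit <- hpmm_fit_internal(design, xterms = c("X", "D", "XD", covariates),
                             include_eps = FALSE, fix_var_b = NULL,
                             fix_var_eps = NULL, control = control)
    fit$eps_dropped <- TRUE
  }
  fit$test <- test
  fit$p_value <- test_beta(fit, method = test, term = "X")
  fit$alpha <- unname(fit$coefficients["D"])
  fit$delta <- unname(fit$coefficients["XD"])
  fit$se_delta <- sqrt(fit$vcov["XD", "XD"])
  fit$p_delta <- test_beta(fit, method = test, term = "XD")
  class(fit) <- c("hpmm_interaction_fit", class(fit))
  fit
}

# Shared machinery: builds the fixed-effect design matrix, optimizes the
# Laplace likelihood with nlminb, and assembles the fit object.
hpmm_fit_internal <- function(design, xterms, include_eps, fix_var_b,
                              fix_var_eps, control) {
  ctrl <- utils::modifyList(list(rel_tol = 1e-10, max_iter = 500), control)
  obs <- as.data.frame(design)
  if (nrow(obs) < 2L) stop("need at least 2 observations")
  if (any(obs$K <= 0)) stop("offsets K must be positive")
  if ("X" %in% xterms && stats::var(obs$X) == 0)
    stop("X is constant; the aseQTL effect is not testable")

  # contiguous subject blocks for the per-subject Laplace factorization
  ord <- order(match(obs$subject_id, unique(obs$subject_id)))
  obs <- obs[ord, ]
  rle_s <- rle(as.character(obs$subject_id))
  subj_len <- rle_s$lengths
  subj_start <- cumsum(c(0L, subj_len[-length(subj_len)]))

  Xf <- matrix(1, nrow(obs), 1L)
  for (v in xterms) {
    if (is.null(obs[[v]])) stop("design has no column '", v, "'")
    Xf <- cbind(Xf, obs[[v]])
  }
  colnames(Xf) <- c("(Intercept)", xterms)
  p <- ncol(Xf)
  y <- as.numeric(obs$y)
  logK <- log(obs$K)

  est_b <- is.null(fix_var_b)
  est_e <- include_eps && is.null(fix_var_eps)
  vb_fixed <- if (est_b) NA_real_ else fix_var_b
  ve_fixed <- if (!include_eps) 0 else if (est_e) NA_real_ else fix_var_eps

  warm <- numeric(length(subj_len) + length(y))  # random-effect modes
  nll <- function(par) {
    coef <- par[seq_len(p)]
    k <- p
    vb <- if (est_b) exp(par[k <- k + 1L]) else vb_fixed
    ve <- if (est_e) exp(par[k + 1L]) else ve_fixed
    hpmm_nll_cpp(coef, vb, ve, y, logK, Xf, subj_start, subj_len, warm)
  }

  # starting values from a plain Poisson regression with offset
  glm0 <- suppressWarnings(
    stats::glm.fit(Xf, y, offset = logK, family = stats::poisson()))
  start <- c(unname(glm0$coefficients),
             if (est_b) log(0.5), if (est_e) log(0.25))
  start[!is.finite(start)] <- 0
  lower <- c(rep(-Inf, p), rep(log(VAR_LOWER), est_b + est_e))
  upper <- c(rep(Inf, p), rep(log(VAR_UPPER), est_b + est_e))

  opt <- stats::nlminb(start, nll, lower = lower, upper = upper,
                       control = list(rel.tol = ctrl$rel_tol,
                                      iter.max = ctrl$max_iter,
                                      eval.max = 4L * ctrl$max_iter))
  par <- opt$par
  obj <- opt$objective

  # Newton polish with a fixed Hessian: nlminb's finite-difference stopping
  # rule leaves the solution ~1e-5 from the optimum, which is visible in
  # exact symmetries of the likelihood (allele relabelling, offset
  # rescaling). Skipped when a variance sits on its boundary.
  hess <- stats::optimHess(par, nll)
  if (!any(par <= lower + 1e-8 | par >= upper - 1e-8)) {
    grad_fd <- function(x) {
      h <- 1e-5 * pmax(1, abs(x))
      vapply(seq_along(x), function(j) {
        e <- numeric(length(x)); e[j] <- h[j]
        (nll(x + e) - nll(x - e)) / (2 * h[j])
      }, numeric(1))
    }
    for (it in 1:3) {
      step <- tryCatch(solve(hess, grad_fd(par)), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- pmin(pmax(par - step, lower), upper)
      cobj <- nll(cand)
      if (cobj > obj + 1e-9) break
      par <- cand; obj <- cobj
      if (max(abs(step)) < 1e-9) break
    }
  }
  coef <- par[seq_len(p)]
  names(coef) <- colnames(Xf)
  k <- p
  var_b <- if (est_b) exp(par[k <- k + 1L]) else vb_fixed
  var_eps <- if (est_e) exp(par[k + 1L]) else ve_fixed
  at_bound_b <- est_b && var_b <= 2 * VAR_LOWER
  at_bound_e <- est_e && var_eps <= 2 * VAR_LOWER
  if (at_bound_b) var_b <- 0
  if (at_bound_e) var_eps <- 0

  # observed information of the free parameters (the Hessian from the
  # polish point is reused; the polish moves par by ~1e-5 at most); fall
  # back to the fixed-effect block when a boundary makes it singular
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc)[seq_len(p)])) ||
      any(diag(vc)[seq_len(p)] < 0)) {
    nll_coef <- function(cf) nll(c(cf, par[-seq_len(p)]))
    hc <- stats::optimHess(coef, nll_coef)
    vc_c <- tryCatch(solve(hc), error = function(e)
      matrix(NA_real_, p, p))
    vc <- matrix(NA_real_, length(par), length(par))
    vc[seq_len(p), seq_len(p)] <- vc_c
  }
  vcov <- vc[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov) <- list(colnames(Xf), colnames(Xf))

  n_dh <- attr(design, "n_double_het")
  has_x <- "X" %in% colnames(Xf)
  structure(list(
    mu = unname(coef["(Intercept)"]),
    beta = if (has_x) unname(coef["X"]) else NA_real_,
    se_beta = if (has_x) sqrt(vcov["X", "X"]) else NA_real_,
    gamma = coef[setdiff(names(coef), c("(Intercept)", "X", "D", "XD"))],
    var_b = var_b, var_eps = var_eps,
    loglik = -obj,
    converged = opt$convergence == 0,
    n_obs = nrow(obs),
    n_subjects = length(subj_len),
    n_double_het = if (is.null(n_dh)) NA_integer_ else n_dh,
    eps_included = include_eps && !isTRUE(var_eps == 0),
    eps_dropped = FALSE,
    coefficients = coef, vcov = vcov,
    design = design, xterms = xterms, include_eps = include_eps,
    fix_var_b = fix_var_b, fix_var_eps = fix_var_eps, control = control
  ), class = "hpmm_fit")
}

#' Test a fixed effect of a fitted HPMM
#'
#' @param fit an [fit_hpmm()] or [fit_interaction()] object.
#' @param method `"wald"`: two-sided normal p-value from the estimate and
#'   its standard error; `"lrt"`: chi-squared(1) p-value from twice the
#'   log-likelihood difference against the nested null fit without the term.
#' @param term coefficient to test (default `"X"`, the aseQTL effect).
#' @return The p-value.
#' @export
test_beta <- function(fit, method = c("wald", "lrt"), term = "X") {
  method <- match.arg(method)
  est <- unname(fit$coefficients[term])
  if (method == "wald") {
    se <- sqrt(fit$vcov[term, term])
    if (!is.finite(se) || se == 0)
      stop("standard error of '", term, "' is zero or unavailable")
    return(2 * stats::pnorm(-abs(est / se)))
  }
  null_fit <- hpmm_fit_internal(fit$design,
                                xterms = setdiff(fit$xterms, term),
                                include_eps = fit$include_eps,
                                fix_var_b = fit$fix_var_b,
                                fix_var_eps = fit$fix_var_eps,
                                control = fit$control)
  stat <- max(0, 2 * (fit$loglik - null_fit$loglik))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @export
print.hpmm_fit <- function(x, ...) {
  cat("Hierarchical Poisson mixed model (Laplace)\n")
  cat(sprintf("  observations: %d  subjects: %d  split subjects: %s\n",
              x$n_obs, x$n_subjects, x$n_double_het))
  cat(sprintf("  beta = %.4f (se %.4f), p = %.3g [%s]\n",
              x$beta, x$se_beta, x$p_value, x$test))
  cat(sprintf("  Var(b) = %.4f  Var(eps) = %s%s\n", x$var_b,
              if (x$eps_included) sprintf("%.4f", x$var_eps) else "omitted",
              if (isTRUE(x$eps_dropped)) " (dropped at boundary)" else ""))
  cat(sprintf("  logLik = %.2f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
print.hpmm_interaction_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  interaction: delta = %.4f (se %.4f), p_delta = %.3g\n",
              x$delta, x$se_delta, x$p_delta))
  invisible(x)
}
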