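test_that("perfect allelic balance gives beta of zero", {
  set.seed(1)
  n <- 40
  subj <- subjects_table(rep(1, n), y_eff = rpois(n, 60) + 1L,
                         y_oth = 0L)
  subj$y_oth <- subj$y_eff   # y_iA = y_ia for every subject
  fit <- fit_hpmm(build_design(subj, mode = "exonic"))
  expect_lt(abs(fit$beta), 1e-6)
  expect_equal(test_beta(fit, "wald"), 1, tolerance = 1e-6)
})

test_that("estimates agree with the reference Poisson GLMM fitter", {
  skip_if_not_installed("lme4")
  des <- sim_dataset(n = 300, maf = 0.4, beta = 0.3, seed = 42)
  fit <- fit_hpmm(des)
  d <- as.data.frame(des)
  d$obs_id <- factor(seq_len(nrow(d)))
  ref <- suppressWarnings(lme4::glmer(
    y ~ X + (1 | subject_id) + (1 | obs_id), family = stats::poisson,
    data = d, offset = log(d$K),
    control = lme4::glmerControl(optimizer = "bobyqa")))
  expect_equal(fit$beta, unname(lme4::fixef(ref)["X"]), tolerance = 1e-3)
  expect_equal(fit$mu, unname(lme4::fixef(ref)["(Intercept)"]),
               tolerance = 1e-3)
  vc <- unlist(lme4::VarCorr(ref))
  expect_equal(fit$var_b, unname(vc["subject_id"]), tolerance = 0.01)
  expect_equal(fit$var_eps, unname(vc["obs_id"]), tolerance = 0.01)
  expect_equal(fit$se_beta,
               unname(summary(ref)$coefficients["X", "Std. Error"]),
               tolerance = 0.02)
})

test_that("relabelling alleles negates beta; rescaling offsets shifts mu", {
  des <- sim_dataset(n = 200, maf = 0.4, beta = 0.2, seed = 9)
  fit <- fit_hpmm(des)

  flipped <- des; flipped$X <- 1 - flipped$X
  fit_f <- fit_hpmm(flipped)
  expect_lt(abs(fit$beta + fit_f$beta), 1e-6)

  scaled <- des; scaled$K <- scaled$K * 7
  fit_s <- fit_hpmm(scaled)
  expect_lt(abs(fit_s$beta - fit$beta), 1e-6)
  expect_lt(abs(fit_s$mu - (fit$mu - log(7))), 1e-6)
})

test_that("with both variances forced to zero the fit is a Poisson GLM", {
  des <- sim_dataset(n = 60, maf = 0.4, beta = 0.2, var_b = 0,
                     var_eps = 0, seed = 3)
  fit <- fit_hpmm(des, include_eps = FALSE, fix_var_b = 0)
  ref <- stats::glm(y ~ X, family = stats::poisson, data = des,
                    offset = log(des$K))
  expect_equal(fit$beta, unname(stats::coef(ref)["X"]), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("wald p-values follow the normal quantiles and lrt is consistent", {
  des <- sim_dataset(n = 150, maf = 0.4, beta = 0.25, seed = 15)
  fit <- fit_hpmm(des)
  expect_equal(fit$p_value,
               2 * pnorm(-abs(fit$beta / fit$se_beta)))
  p_lrt <- test_beta(fit, "lrt")
  expect_gt(p_lrt, 0)
  # Wald and LRT agree in order of magnitude on a clear signal
  expect_lt(abs(log10(p_lrt) - log10(fit$p_value)), 1.5)
  expect_error(fit_hpmm(within(des, X <- 1)), "constant")
})

test_that("null p-values are uniform", {
  set.seed(77)
  n_rep <- 120
  p <- vapply(seq_len(n_rep), function(r) {
    des <- sim_dataset(n = 200, maf = 0.4, beta = 0)
    fit_hpmm(des)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the interaction model recovers differential allelic effects", {
  set.seed(21)
  n <- 400
  subj <- subjects_table(simulate_genotypes(n, 0.4), 0L, 0L)
  group <- data.frame(subject_id = subj$subject_id,
                      D = rep(c(0, 1), length.out = n))
  des <- build_design(subj, mode = "exonic", group = group)
  # beta = 0 in group 0, beta = 0.5 in group 1
  des <- simulate_counts(des, log(1e-4), beta = 0, var_b = 1,
                         var_eps = 0.5, alpha = 0, delta = 0.5)
  fit <- fit_interaction(des)
  expect_true(fit$converged)
  expect_equal(fit$delta, 0.5, tolerance = 0.35)
  expect_lt(fit$p_delta, 0.05)

  des$D <- 1
  expect_error(fit_interaction(des), "constant")
})

test_that("interaction p-values are calibrated when groups share beta", {
  set.seed(31)
  n_rep <- 60
  p <- vapply(seq_len(n_rep), function(r) {
    subj <- subjects_table(simulate_genotypes(250, 0.4), 0L, 0L)
    group <- data.frame(subject_id = subj$subject_id,
                        D = rep(c(0, 1), length.out = 250))
    des <- build_design(subj, mode = "exonic", group = group)
    des <- simulate_counts(des, log(1e-4), beta = 0.2, var_b = 1,
                           var_eps = 0.5, alpha = 0, delta = 0)
    fit_interaction(des)$p_delta
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("beta-binomial fit is symmetric, calibrated and matches glmmTMB", {
  # symmetry: y_A = y_a in every pair
  k <- c(10L, 25L, 40L, 55L, 80L)
  fb <- fit_betabin(y_eff = k, n = 2L * k)
  expect_lt(abs(fb$beta), 1e-4)

  skip_if_not_installed("glmmTMB")
  set.seed(4)
  des <- sim_dataset(n = 300, maf = 0.5, beta = 0.2, seed = 4)
  pairs <- het_pairs(des)
  fb <- fit_betabin(y_eff = pairs$yA, n = pairs$n)
  ref <- glmmTMB::glmmTMB(cbind(yA, ya) ~ 1, data = pairs,
                          family = glmmTMB::betabinomial())
  expect_equal(fb$beta, unname(glmmTMB::fixef(ref)$cond[1]),
               tolerance = 1e-3)
  expect_equal(fb$theta, unname(stats::sigma(ref)), tolerance = 0.02)

  expect_warning(fit_betabin(y_eff = c(3L, 0L), n = c(6L, 0L)), "dropped")
})

test_that("an eps variance at the boundary triggers the refit without eps", {
  # deep coverage without simulated overdispersion: Var(eps) hits the
  # floor and the eps-free model is reported
  des <- sim_dataset(n = 150, maf = 0.4, beta = 0.1, var_b = 1,
                     var_eps = 0, mu = log(1e-2), seed = 8)
  fit <- fit_hpmm(des)
  expect_true(fit$eps_dropped)
  expect_false(fit$eps_included)
  expect_true(fit$converged)
})
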