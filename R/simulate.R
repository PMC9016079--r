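#' Simulation configuration for the type-I-error / power study
#'
#' Defaults reproduce the conditions of the model-based simulation study:
#' allelic expression of 500 subjects, \eqn{\mathrm{Var}(b_i) = 1},
#' \eqn{\mathrm{Var}(\varepsilon_{ij}) = 0.5}, effect sizes \eqn{\beta}
#' from 0 to 0.3, minor allele frequencies from 0.1 to 0.4, evaluated at
#' the 5\% significance level. The baseline \eqn{\mu} and the library size
#' are set so that the expected count per allelic observation is about 50
#' at a constant library size of 10^6 (a moderate sequencing depth).
#'
#' @param n_subjects number of subjects (default 500).
#' @param maf minor-allele-frequency grid (default `c(0.1, 0.2, 0.3, 0.4)`).
#' @param beta effect-size grid on the log scale (default
#'   `c(0, 0.1, 0.2, 0.3)`).
#' @param var_b,var_eps variances of the subject- and observation-level
#'   random effects (defaults 1 and 0.5).
#' @param mu baseline log rate per unit offset (default `log(1e-4)`).
#' @param library_size constant library size \eqn{l_i} (default `1e6`).
#' @param ld_r haplotype allele correlation for the two-SNP mode (default 0).
#' @param n_replicates replicates per grid cell (default 2000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed making the whole study reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 500, maf = c(0.1, 0.2, 0.3, 0.4),
                       beta = c(0, 0.1, 0.2, 0.3), var_b = 1, var_eps = 0.5,
                       mu = log(1e-4), library_size = 1e6, ld_r = 0,
                       n_replicates = 2000, alpha = 0.05, seed = 1L) {
  stopifnot(n_subjects > 0, all(maf > 0 & maf <= 0.5), var_b >= 0,
            var_eps >= 0, library_size > 0, n_replicates > 0,
            alpha > 0, alpha < 1)
  structure(list(n_subjects = n_subjects, maf = maf, beta = beta,
                 var_b = var_b, var_eps = var_eps, mu = mu,
                 library_size = library_size, ld_r = ld_r,
                 n_replicates = n_replicates, alpha = alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes at one SNP under Hardy-Weinberg equilibrium
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional seed.
#' @return Integer vector of effect-allele dosages (0/1/2); the effect
#'   (major) allele has frequency `1 - maf`, so genotype probabilities are
#'   `maf^2`, `2 maf (1-maf)`, `(1-maf)^2` for dosages 0, 1, 2.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("'maf' must be in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, 1 - maf)
}

#' Simulate phased two-SNP genotypes with a given haplotype correlation
#'
#' Draws `2n` haplotypes over a GWAS SNP (alleles A/a, minor a) and an
#' exonic SNP (alleles B/b, minor b) from the four-haplotype distribution
#' whose allele-indicator correlation is `ld_r`, then pairs consecutive
#' haplotypes into phased genotypes. With `ld_r = 0` the haplotype relative
#' frequency is the product of the allele frequencies
#' (\eqn{P_{ab} = P_a P_b}).
#'
#' @param n subjects.
#' @param maf_gwas,maf_exonic minor allele frequencies at the two SNPs.
#' @param ld_r haplotype correlation between the minor-allele indicators;
#'   must imply haplotype frequencies in `[0, 1]`.
#' @param seed optional seed.
#' @return Data frame with one row per subject: `g1`, `g2`, `e1`, `e2`
#'   are 0/1 indicators of the *major* (effect) alleles A and B on
#'   haplotypes 1 and 2, plus dosage columns `gwas_dosage`, `exonic_dosage`.
#' @export
simulate_haplotypes <- function(n, maf_gwas, maf_exonic, ld_r = 0,
                                seed = NULL) {
  pa <- maf_gwas; pb <- maf_exonic
  stopifnot(pa > 0, pa < 1, pb > 0, pb < 1, abs(ld_r) <= 1)
  denom <- sqrt(pa * (1 - pa) * pb * (1 - pb))
  D <- ld_r * denom
  # haplotype frequencies over (a, b) minor-allele indicators
  f_ab <- pa * pb + D
  f_aB <- pa * (1 - pb) - D
  f_Ab <- (1 - pa) * pb - D
  f_AB <- (1 - pa) * (1 - pb) + D
  f <- c(AB = f_AB, Ab = f_Ab, aB = f_aB, ab = f_ab)
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
    lo <- max(-pa * pb, -(1 - pa) * (1 - pb)) / denom
    hi <- min(pa * (1 - pb), (1 - pa) * pb) / denom
    stop(sprintf("infeasible (ld_r, MAF) combination; feasible ld_r range is [%.4f, %.4f]",
                 lo, hi))
  }
  f <- pmax(f, 0); f <- f / sum(f)
  if (!is.null(seed)) set.seed(seed)
  hap <- sample.int(4L, 2L * n, replace = TRUE, prob = f)
  # haplotypes 1..4 = AB, Ab, aB, ab; indicator of major alleles
  gA <- as.integer(hap <= 2L)             # carries GWAS major allele A
  eB <- as.integer(hap %in% c(1L, 3L))    # carries exonic major allele B
  h1 <- seq(1L, 2L * n, by = 2L)
  out <- data.frame(subject_id = paste0("S", seq_len(n)),
                    g1 = gA[h1], g2 = gA[h1 + 1L],
                    e1 = eB[h1], e2 = eB[h1 + 1L])
  out$gwas_dosage <- out$g1 + out$g2
  out$exonic_dosage <- out$e1 + out$e2
  out
}

#' Build an exonic-mode design skeleton for simulation
#'
#' Generates Hardy-Weinberg genotypes at one exonic SNP and lays out the
#' HPMM observation rows (patterns, codings, offsets) with zero counts, to
#' be filled by [simulate_counts()].
#'
#' @inheritParams simulate_genotypes
#' @param library_size constant library size per subject.
#' @return An `hpmm_design` skeleton.
#' @export
simulate_ase_design <- function(n, maf, library_size = 1e6, seed = NULL) {
  dosage <- simulate_genotypes(n, maf, seed)
  subjects <- data.frame(subject_id = paste0("S", seq_len(n)),
                         dosage = dosage, y_eff = 0L, y_oth = 0L,
                         library_size = library_size)
  build_design(subjects, mode = "exonic")
}

#' Draw counts from the hierarchical Poisson mixed model
#'
#' Fills the `y` column of a design skeleton with counts drawn from
#' \eqn{y_{ij} \sim \mathrm{Pois}\{\exp(\mu + X_{ij}\beta + D_i\alpha +
#' X_{ij}D_i\delta + b_i + \varepsilon_{ij}) K_{ij}\}} with
#' \eqn{b_i \sim N(0, \mathrm{Var}(b))} per subject and
#' \eqn{\varepsilon_{ij} \sim N(0, \mathrm{Var}(\varepsilon))} per
#' observation. The group terms are used only when the design has a `D`
#' column.
#'
#' @param design an `hpmm_design` (or compatible data frame).
#' @param mu,beta,var_b,var_eps model parameters.
#' @param alpha,delta group main effect and interaction (default 0).
#' @param seed optional seed.
#' @return The design with simulated `y`.
#' @export
simulate_counts <- function(design, mu, beta, var_b, var_eps,
                            alpha = 0, delta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sid <- match(design$subject_id, unique(design$subject_id))
  b <- stats::rnorm(max(sid), 0, sqrt(var_b))[sid]
  e <- stats::rnorm(nrow(design), 0, sqrt(var_eps))
  eta <- mu + design$X * beta + b + e
  if (!is.null(design$D)) eta <- eta + design$D * alpha +
      design$X * design$D * delta
  design$y <- stats::rpois(nrow(design), exp(eta) * design$K)
  design
}

#' Run the type-I-error / power simulation study
#'
#' For every cell of the `beta` x `maf` grid, simulates `n_replicates`
#' data sets from the HPMM and records the fraction of replicates in which
#' each method rejects \eqn{\beta = 0} at level `alpha`:
#' \describe{
#'   \item{`hpmm_all`}{the HPMM fitted on all subjects (Wald test),}
#'   \item{`hpmm_het`}{the HPMM fitted on heterozygous subjects only,}
#'   \item{`betabin`}{the beta-binomial regression on heterozygous
#'     subjects ([fit_betabin()]).}
#' }
#' Non-converged fits are excluded from the rate denominator and counted.
#'
#' @param config a [sim_config()].
#' @param methods subset of `c("hpmm_all", "hpmm_het", "betabin")`.
#' @param keep_pvalues also return the matrix of raw p-values per cell.
#' @param verbose print progress per cell.
#' @return A data frame of class `sim_study_result` with columns `beta`,
#'   `maf`, `method`, `rate`, `mc_se`, `n_converged`, `n_replicates`;
#'   if `keep_pvalues`, an attribute `pvalues` (named list of matrices,
#'   replicates x methods).
#' @export
run_power_study <- function(config = sim_config(),
                            methods = c("hpmm_all", "hpmm_het", "betabin"),
                            keep_pvalues = FALSE, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(config$seed)
  res <- list(); pv_all <- list()
  for (b in config$beta) for (m in config$maf) {
    pv <- matrix(NA_real_, config$n_replicates, length(methods),
                 dimnames = list(NULL, methods))
    for (r in seq_len(config$n_replicates)) {
      des <- simulate_ase_design(config$n_subjects, m,
                                 config$library_size)
      des <- simulate_counts(des, config$mu, b, config$var_b,
                             config$var_eps)
      het <- des[des$pattern %in% c("A", "a"), , drop = FALSE]
      for (meth in methods) {
        fit <- tryCatch(switch(meth,
          hpmm_all = fit_hpmm(des),
          hpmm_het = fit_hpmm(het),
          betabin  = fit_betabin(des)), error = function(e) NULL)
        ok <- !is.null(fit) &&
          (inherits(fit, "betabin_fit") || fit$converged)
        if (ok) pv[r, meth] <- fit$p_value
      }
    }
    for (meth in methods) {
      p <- pv[, meth]
      nc <- sum(!is.na(p))
      rate <- mean(p < config$alpha, na.rm = TRUE)
      res[[length(res) + 1L]] <- data.frame(
        beta = b, maf = m, method = meth, rate = rate,
        mc_se = sqrt(rate * (1 - rate) / nc),
        n_converged = nc, n_replicates = config$n_replicates)
    }
    if (keep_pvalues) pv_all[[sprintf("beta%.2f_maf%.2f", b, m)]] <- pv
    if (verbose)
      message(sprintf("beta=%.2f maf=%.2f done", b, m))
  }
  out <- do.call(rbind, res)
  class(out) <- c("sim_study_result", "data.frame")
  if (keep_pvalues) attr(out, "pvalues") <- pv_all
  out
}
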