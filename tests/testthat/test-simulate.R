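test_that("genotypes follow Hardy-Weinberg proportions and the seed", {
  g <- simulate_genotypes(20000, 0.5, seed = 1)
  expect_equal(mean(g == 1L), 0.5, tolerance = 0.02)
  g2 <- simulate_genotypes(500, 0.1, seed = 2)
  # expected heterozygote count 2 * 0.1 * 0.9 * 500 = 90
  expect_equal(sum(g2 == 1L), 90, tolerance = 0.35)
  expect_identical(simulate_genotypes(100, 0.3, seed = 7),
                   simulate_genotypes(100, 0.3, seed = 7))
  expect_error(simulate_genotypes(10, 0.7), "maf")
})

test_that("haplotype frequencies factorize under no LD and collapse at r = 1", {
  hap <- simulate_haplotypes(20000, 0.3, 0.2, ld_r = 0, seed = 11)
  # P(ab) -> P(a) P(b): minor-minor haplotype among all 2n chromosomes
  p_ab <- mean(c(hap$g1, hap$g2) == 0L & c(hap$e1, hap$e2) == 0L)
  expect_equal(p_ab, 0.3 * 0.2, tolerance = 0.01)

  hap1 <- simulate_haplotypes(500, 0.25, 0.25, ld_r = 1, seed = 12)
  # perfect LD with equal MAFs: only AB and ab haplotypes exist
  expect_true(all(c(hap1$g1, hap1$g2) == c(hap1$e1, hap1$e2)))

  expect_error(simulate_haplotypes(10, 0.05, 0.05, ld_r = -0.9),
               "feasible")
})

test_that("rare double-heterozygotes show inflated allelic correlation", {
  # no population LD, low MAF, modest n: the allelic correlation among
  # double heterozygotes is frequently at its degenerate value |r| = 1
  set.seed(19)
  r_allelic <- replicate(60, {
    hap <- simulate_haplotypes(200, 0.05, 0.05, ld_r = 0)
    allelic_correlation_double_het(hap)
  })
  r_allelic <- r_allelic[!is.na(r_allelic)]
  expect_gt(mean(abs(r_allelic) > 0.99), 0.3)
})

test_that("simulated counts have the model's moments", {
  des <- simulate_ase_design(4000, 0.4, 1e6, seed = 23)
  # no random effects, beta = 0: y ~ Pois(exp(mu) K)
  d0 <- simulate_counts(des, log(1e-4), 0, 0, 0, seed = 23)
  expect_equal(mean(d0$y / d0$K), 1e-4, tolerance = 0.01)

  # within double heterozygotes, mean log(y_A / y_a) -> beta at high counts
  dd <- simulate_counts(simulate_ase_design(3000, 0.5, 1e8, seed = 24),
                        log(1e-4), 0.3, 1, 0, seed = 24)
  pairs <- het_pairs(dd)
  expect_equal(mean(log(pairs$yA / pairs$ya)), 0.3, tolerance = 0.02)

  expect_identical(simulate_counts(des, log(1e-4), 0.1, 1, 0.5, seed = 5)$y,
                   simulate_counts(des, log(1e-4), 0.1, 1, 0.5, seed = 5)$y)
})

test_that("random-effect draws match the requested variances", {
  des <- simulate_ase_design(5000, 0.5, 1e6, seed = 31)
  set.seed(31)
  d <- simulate_counts(des, log(1e-2), 0, 1, 0.5)
  # at ~10^4 expected counts the Poisson noise is negligible relative to
  # the random effects, so log(y/K) - mu estimates b_i + eps_ij
  z <- log(d$y / d$K) - log(1e-2)
  expect_equal(var(z), 1.5, tolerance = 0.1)
  # within-subject difference of paired rows isolates 2 Var(eps)
  pairs <- het_pairs(d)
  expect_equal(var(log(pairs$yA / pairs$ya)), 1.0, tolerance = 0.1)
})

test_that("the power study table is reproducible and well formed", {
  cfg <- sim_config(n_subjects = 60, maf = 0.4, beta = 0.3,
                    n_replicates = 8, seed = 99)
  r1 <- run_power_study(cfg, methods = c("hpmm_all", "betabin"))
  r2 <- run_power_study(cfg, methods = c("hpmm_all", "betabin"))
  expect_equal(r1, r2)
  expect_true(all(r1$rate >= 0 & r1$rate <= 1))
  expect_equal(r1$mc_se,
               sqrt(r1$rate * (1 - r1$rate) / r1$n_converged))
})
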