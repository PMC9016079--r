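test_that("genotype correlation handles the degenerate and exact cases", {
  expect_equal(genotype_correlation(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(genotype_correlation(c(0, 1, 2), c(2, 1, 0)), -1)
  expect_warning(r <- genotype_correlation(c(1, 1, 1), c(0, 1, 2)),
                 "zero variance")
  expect_true(is.na(r))
  # independent SNPs at n = 10^4: |r| near zero
  set.seed(2)
  r0 <- genotype_correlation(simulate_genotypes(1e4, 0.3),
                             simulate_genotypes(1e4, 0.3))
  expect_lt(abs(r0), 0.05)
})

test_that("allelic correlation in double heterozygotes hits the phase limits", {
  # every double het phased (A-b, a-B): complete negative correlation
  dh <- data.frame(g1 = 1, g2 = 0, e1 = 0, e2 = 1)[rep(1, 5), ]
  expect_equal(allelic_correlation_double_het(dh), -1)
  # mirror phase (A-B, a-b): +1
  dh2 <- data.frame(g1 = 1, g2 = 0, e1 = 1, e2 = 0)[rep(1, 5), ]
  expect_equal(allelic_correlation_double_het(dh2), 1)
  # equal numbers of the two phase configurations: r = 0, as the 2x2
  # chromosome table is balanced
  both <- rbind(dh, dh2)
  expect_equal(allelic_correlation_double_het(both), 0)
  expect_true(is.na(allelic_correlation_double_het(dh[1, ])))
})

test_that("category assignment follows relative significance then LD", {
  expect_equal(classify_category(1e-8, 1e-3, 0.2), 1L)
  expect_equal(classify_category(1e-6, 1e-10, 0.995), 2L)
  expect_equal(classify_category(1e-6, 1e-10, 0.3), 3L)
  # ties are not "less significant": they fall to the LD branch
  expect_equal(classify_category(1e-5, 1e-5, 0.9), 2L)
  expect_equal(classify_category(1e-5, 1e-5, 0.1), 3L)
  # negative LD counts through |r|
  expect_equal(classify_category(1e-6, 1e-10, -0.95), 2L)
  expect_true(is.na(classify_category(1e-6, NA, 0.5)))
})

test_that("categories are exhaustive and mutually exclusive", {
  set.seed(5)
  p_g <- runif(200, 1e-12, 1)
  p_e <- runif(200, 1e-12, 1)
  r <- runif(200, -1, 1)
  cat3 <- classify_category(p_g, p_e, r)
  expect_true(all(cat3 %in% 1:3))
  # manual rules agree everywhere
  manual <- ifelse(p_e > p_g, 1L, ifelse(abs(r) > 0.8, 2L, 3L))
  expect_identical(cat3, manual)
})

test_that("BH adjustment matches a brute-force step-up on random vectors", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))   # step-up monotonicity
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_bh(p))
  }
})

test_that("adjusted p-values dominate raw ones and preserve ordering", {
  set.seed(11)
  p <- runif(100)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_identical(order(q[order(p)]), seq_along(p))  # same ranking
})

test_that("association tables gain fdr and categories only when significant", {
  assoc <- data.frame(p = c(1e-6, 0.5, 1e-4),
                      p_exonic = c(1e-3, 0.2, 1e-8),
                      r_genotype = c(0.1, 0.9, 0.9))
  out <- classify_associations(assoc)
  expect_equal(out$fdr_p, bh_fdr(assoc$p))
  expect_equal(out$category, c(1L, NA, 2L))
})
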