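test_that("harmonization of identical tables needs no flips", {
  t1 <- toy_assoc(b = c(0.2, -0.1, 0.05), se = c(0.1, 0.1, 0.1))
  h <- harmonize(list(t1, t1, t1))
  expect_equal(h$b[, 1], h$b[, 2])
  expect_equal(rowSums(!is.na(h$b)), rep(3, 3), ignore_attr = TRUE)
  expect_equal(h$n_dropped, 0)
})

test_that("allele-swapped tables are flipped back (involution)", {
  t1 <- toy_assoc(b = c(0.2, -0.1), se = c(0.1, 0.2), freq = c(0.3, 0.6))
  t2 <- t1
  t2$a1 <- t1$a2; t2$a2 <- t1$a1
  t2$b <- -t1$b; t2$z <- -t1$z; t2$freq <- 1 - t1$freq
  h <- harmonize(list(t1, t2))
  expect_equal(h$b[, 1], h$b[, 2], tolerance = 1e-12)
  expect_equal(h$freq[, 1], h$freq[, 2], tolerance = 1e-12)
})

test_that("irreconcilable allele pairs are dropped and counted", {
  t1 <- toy_assoc(b = c(0.2, 0.1), se = c(0.1, 0.1))
  t2 <- t1
  t2$a2[2] <- "C"    # A/G vs A/C
  h <- harmonize(list(t1, t2))
  expect_equal(h$n_dropped, 1)
  expect_equal(nrow(h$map), 1)
})

test_that("duplicate SNP ids within a table are rejected", {
  t1 <- toy_assoc(b = c(0.2, 0.1), se = c(0.1, 0.1), snp = c("a", "a"))
  expect_error(harmonize(list(t1)), "duplicate")
})

test_that("Stouffer Z matches hand evaluation and its edge cases", {
  # single study: identity
  one <- stouffer_z(p = 0.04, b = -1, n = 50)
  expect_equal(one$z, -qnorm(1 - 0.02), tolerance = 1e-10)
  expect_equal(one$p, 0.04, tolerance = 1e-10)
  # two equal-n studies both at z = 1.96
  p196 <- 2 * pnorm(-1.96)
  two <- stouffer_z(p = c(p196, p196), b = c(1, 1), n = c(100, 100))
  expect_equal(two$z, 1.96 * sqrt(2), tolerance = 1e-10)
  # opposite effects cancel
  opp <- stouffer_z(p = c(p196, p196), b = c(1, -1), n = c(100, 100))
  expect_equal(opp$z, 0, tolerance = 1e-12)
  expect_equal(opp$p, 1, tolerance = 1e-12)
})

test_that("IVW matches the hand-evaluated two-study case", {
  r <- ivw(b = c(0.2, 0.4), se = c(0.1, 0.1))
  expect_equal(r$beta, 0.3, tolerance = 1e-12)
  expect_equal(r$v, 0.005, tolerance = 1e-12)
  expect_equal(r$q, 2, tolerance = 1e-12)
  expect_equal(r$i2, 50, tolerance = 1e-12)
  # identical studies: no heterogeneity
  r0 <- ivw(b = c(0.3, 0.3), se = c(0.1, 0.1))
  expect_equal(r0$beta, 0.3)
  expect_equal(r0$q, 0)
  expect_equal(r0$i2, 0)
  # single study edge
  r1 <- ivw(b = 0.25, se = 0.05)
  expect_equal(r1$beta, 0.25)
  expect_equal(r1$i2, 0)
})

test_that("IVW agrees with metafor as an independent route", {
  skip_if_not_installed("metafor")
  set.seed(40)
  for (i in 1:20) {
    b <- rnorm(4, 0, 0.3); se <- runif(4, 0.05, 0.3)
    r <- ivw(b, se)
    mf <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(r$beta, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(sqrt(r$v), mf$se, tolerance = 1e-8)
    expect_equal(r$q, mf$QE, tolerance = 1e-8)
    t2 <- dl_tau2(b, se)
    mfd <- metafor::rma(yi = b, sei = se, method = "DL")
    expect_equal(t2, mfd$tau2, tolerance = 1e-8)
  }
})

test_that("DerSimonian-Laird tau2 matches hand evaluation and truncates", {
  se <- c(0.1, 0.1)                       # w = (100, 100)
  expect_equal(dl_tau2(b = c(0.2, 0.4), se = se), 0.01, tolerance = 1e-12)
  expect_equal(dl_tau2(b = c(0.3, 0.31), se = se), 0)   # Q < N-1
  # symmetric in study order
  b <- c(0.1, 0.4, -0.2); s <- c(0.1, 0.2, 0.15)
  expect_equal(dl_tau2(b, s), dl_tau2(rev(b), rev(s)), tolerance = 1e-12)
  expect_equal(dl_tau2(b = 0.5, se = 0.1), 0)           # N < 2
})

test_that("Han-Eskin statistic decomposes and collapses to IVW at tau2 = 0", {
  b <- c(0.12, 0.18, 0.15); se <- c(0.05, 0.07, 0.06)
  he <- han_eskin(b, se, tau2 = 0)
  iv <- ivw(b, se)
  expect_equal(he$beta_star, iv$beta, tolerance = 1e-10)
  expect_equal(he$s_het, 0, tolerance = 1e-10)
  expect_equal(he$s_fe, iv$chisq, tolerance = 1e-10)
  expect_equal(he$s_rand, he$s_fe + he$s_het, tolerance = 1e-10)
})

test_that("heterogeneous effects raise S_rand above S_FE", {
  he <- han_eskin(b = c(0.5, -0.5), se = c(0.1, 0.1))
  expect_gt(he$tau2, 0)
  expect_gt(he$s_rand, he$s_fe)
  expect_equal(he$s_rand, he$s_fe + he$s_het, tolerance = 1e-10)
})

test_that("S_rand = S_FE + S_Het on random inputs and I2 is scale-free", {
  set.seed(44)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    b <- rnorm(k, 0, 0.5); se <- runif(k, 0.02, 0.4)
    he <- han_eskin(b, se)
    expect_lt(abs(he$s_rand - (he$s_fe + he$s_het)), 1e-8)
    iv <- ivw(b, se)
    expect_true(iv$i2 >= 0 && iv$i2 <= 100)
    ivs <- ivw(3 * b, 3 * se)
    expect_equal(iv$i2, ivs$i2, tolerance = 1e-10)
    expect_lte(iv$v, min(se^2) + 1e-12)
  }
})

test_that("z-to-effect conversion matches hand values and the exact identity", {
  r0 <- z_to_beta_se(z = 0, p = 0.5, n = 100)
  expect_equal(r0$b, 0)
  expect_equal(r0$se, 1 / sqrt(50), tolerance = 1e-12)
  r2 <- z_to_beta_se(z = 2, p = 0.5, n = 100)
  expect_equal(r2$b, 2 / sqrt(52), tolerance = 1e-12)
  expect_equal(r2$se, 1 / sqrt(52), tolerance = 1e-12)
  set.seed(46)
  z <- rnorm(100, 0, 3); p <- runif(100, 0.01, 0.99); n <- sample(50:5000, 100)
  r <- z_to_beta_se(z, p, n)
  expect_lt(max(abs(r$b / r$se - z)), 1e-12)
  expect_error(z_to_beta_se(1, 0, 100), "frequency")
})

test_that("run_meta on identical tables returns the input effects with Q = 0", {
  t1 <- toy_assoc(b = c(0.2, -0.3, 0.05), se = c(0.1, 0.08, 0.2))
  mt <- run_meta(list(t1, t1))
  expect_equal(mt$beta, t1$b, tolerance = 1e-10)
  expect_equal(mt$q, rep(0, 3), tolerance = 1e-10)
  expect_equal(mt$tau2, rep(0, 3))
  expect_equal(mt$directions, c("++", "--", "++"))
  expect_equal(mt$p_meta, mt$p_ivw)
})

test_that("meta p-value columns track the chosen method", {
  t1 <- toy_assoc(b = c(0.2, -0.3), se = c(0.1, 0.08))
  t2 <- toy_assoc(b = c(0.25, -0.2), se = c(0.12, 0.09))
  expect_equal(run_meta(list(t1, t2), "zscore")$p_meta,
               run_meta(list(t1, t2))$p_z)
  expect_equal(run_meta(list(t1, t2), "random")$p_meta,
               run_meta(list(t1, t2))$p_rand)
})

test_that("SNPs present in one population are carried through with N = 1", {
  t1 <- toy_assoc(b = c(0.2, 0.1), se = c(0.1, 0.1))
  t2 <- toy_assoc(b = 0.3, se = 0.1, snp = "s001")
  mt <- run_meta(list(t1, t2))
  expect_equal(mt$n_studies[mt$snp == "s002"], 1L)
  expect_equal(mt$beta[mt$snp == "s002"], 0.1, tolerance = 1e-10)
})

test_that("meta scans stay calibrated for unrelated null populations", {
  lams <- sapply(1:10, function(r) {
    cfg <- sim_config(pop_sizes = c(120, 120, 120), n_snps = 1000,
                      fst = 0.02, admixture = diag(3),
                      n_families_per_pop = 60, h2_poly = 0,
                      missing_rate = 0, hap_pool_size = 240)
    sim <- quiet_sim(cfg, seed = 600 + r)
    fit <- run_multipop_gwas(sim$panel, sim$pheno, qc_cfg = NULL)
    mt <- run_meta(lapply(fit$per_pop, `[[`, "assoc"))
    keep <- mt$n_studies >= 2
    c(genomic_lambda(chi2 = mt$z[keep]^2)$lambda,
      genomic_lambda(chi2 = mt$beta[keep]^2 / mt$se[keep]^2)$lambda)
  })
  expect_gt(mean(lams), 0.9)
  expect_lt(mean(lams), 1.1)
  expect_true(all(lams > 0.7 & lams < 1.3))
})
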