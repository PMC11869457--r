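# reference panel with controllable LD: SNP j duplicated/correlated columns
ld_panel <- function(n, blocks, seed = 1) {
  # blocks: list of integer vectors; SNPs within a block share a latent
  # genotype with small independent flips (high r2)
  set.seed(seed)
  m <- max(unlist(blocks))
  geno <- matrix(rbinom(n * m, 2L, 0.5), n, m)
  for (bl in blocks) {
    base <- geno[, bl[1]]
    for (j in bl[-1]) {
      flip <- rbinom(n, 1L, 0.05)
      geno[, j] <- ifelse(flip == 1L, rbinom(n, 2L, 0.5), base)
    }
  }
  toy_panel(geno)
}

test_that("clumping reproduces the hand-executed greedy example", {
  # A (p=1e-8) and B (p=1e-6) in strong LD 1 Mb apart; C (p=1e-7) unlinked
  panel <- ld_panel(400, blocks = list(c(1, 2), 3), seed = 50)
  panel$snp_id <- c("A", "B", "C")
  assoc <- toy_assoc(b = c(0.5, 0.4, 0.45), se = rep(0.05, 3),
                     p = c(1e-8, 1e-6, 1e-7),
                     bp = c(1e6, 2e6, 12e6), snp = c("A", "B", "C"))
  res <- clump(assoc, panel, clump_config(p1 = 1e-5, r2_min = 0.05,
                                          kb_max = 5000))
  expect_equal(res$n_qtl, 2)
  expect_equal(res$snp, c("A", "C"))
  expect_setequal(res$members[["A"]], c("A", "B"))
  expect_equal(res$members[["C"]], "C")
})

test_that("clumping with nothing significant returns an empty signal set", {
  panel <- ld_panel(100, blocks = list(1:2), seed = 51)
  assoc <- toy_assoc(b = c(0.1, 0.1, 0.1), se = rep(0.1, 3))
  res <- clump(assoc, panel, clump_config(p1 = 1e-8))
  expect_equal(res$n_qtl, 0)
  expect_equal(length(res$snp), 0)
})

test_that("mutually correlated significant SNPs form one clump led by the smallest p", {
  panel <- ld_panel(400, blocks = list(1:4), seed = 52)
  assoc <- toy_assoc(b = rep(0.5, 4), se = rep(0.05, 4),
                     p = c(1e-6, 1e-9, 1e-7, 1e-8), bp = (1:4) * 1e5)
  res <- clump(assoc, panel, clump_config(p1 = 1e-5, r2_min = 0.05,
                                          kb_max = 5000))
  expect_equal(res$n_qtl, 1)
  expect_equal(res$snp, "s002")
  expect_setequal(res$members[[1]], sprintf("s%03d", 1:4))
})

test_that("clumping partitions the significant set (brute-force agreement)", {
  brute_clump <- function(assoc, r2mat, p1, r2_min, kb_max) {
    sig <- which(assoc$p <= p1)
    assign <- list()
    while (length(sig)) {
      lead <- sig[order(assoc$p[sig], -abs(assoc$b[sig]),
                        assoc$chr[sig], assoc$bp[sig])[1]]
      memb <- sig[r2mat[lead, sig] >= r2_min &
                    assoc$chr[sig] == assoc$chr[lead] &
                    abs(assoc$bp[sig] - assoc$bp[lead]) <= kb_max * 1000]
      memb <- union(lead, memb)
      assign[[length(assign) + 1]] <- assoc$snp[sort(memb)]
      sig <- setdiff(sig, memb)
    }
    assign
  }
  for (r in 1:5) {
    set.seed(700 + r)
    m <- 60
    panel <- ld_panel(300, blocks = split(1:m, rep(1:12, each = 5)),
                      seed = 700 + r)
    assoc <- toy_assoc(b = rnorm(m, 0, 0.3), se = rep(0.05, m),
                       p = runif(m)^4, bp = (1:m) * 2e5)
    cfgc <- clump_config(p1 = 0.01, r2_min = 0.2, kb_max = 500)
    res <- clump(assoc, panel, cfgc)
    X <- scale(panel$geno)
    r2mat <- cor(panel$geno)^2
    oracle <- brute_clump(assoc, r2mat, 0.01, 0.2, 500)
    got <- lapply(res$members, sort)
    names(got) <- NULL
    expect_equal(got, oracle)
    # every significant SNP in exactly one clump
    sig_ids <- assoc$snp[assoc$p <= 0.01]
    expect_setequal(unlist(got), sig_ids)
    expect_equal(anyDuplicated(unlist(got)), 0)
  }
})

test_that("COJO with a single significant SNP returns its marginal estimate", {
  panel <- ld_panel(500, blocks = list(1:2, 3), seed = 54)
  assoc <- toy_assoc(b = c(0.4, 0.02, 0.01), se = c(0.05, 0.05, 0.05),
                     n = 500, bp = c(1e6, 40e6, 80e6))
  res <- cojo_select(assoc, panel, cojo_config(p_threshold = 1e-6))
  expect_equal(res$n_qtl, 1)
  expect_equal(res$snp, "s001")
  expect_equal(res$joint$b_joint, assoc$b[1], tolerance = 0.05)
})

test_that("a duplicate of the lead is never selected by COJO", {
  n <- 600
  set.seed(56)
  base <- rbinom(n, 2L, 0.4)
  geno <- cbind(base, base, rbinom(n, 2L, 0.5))
  panel <- toy_panel(geno)
  y <- 0.5 * base + rnorm(n)
  marg <- sapply(1:3, function(j) {
    f <- summary(lm(y ~ geno[, j]))$coefficients[2, ]
    c(f["Estimate"], f["Std. Error"], f["Pr(>|t|)"])
  })
  assoc <- toy_assoc(b = marg[1, ], se = marg[2, ], p = marg[3, ], n = n)
  res <- cojo_select(assoc, panel, cojo_config(p_threshold = 1e-4,
                                               collinearity_r2 = 0.05))
  expect_false(all(c("s001", "s002") %in% res$snp))
  expect_true(any(c("s001", "s002") %in% res$snp))
})

test_that("COJO on two unlinked planted QTL matches the raw joint regression", {
  ok <- 0
  for (r in 1:5) {
    n <- 800
    set.seed(800 + r)
    panel <- hwe_panel(n, 120, seed = 800 + r, maf_min = 0.2)
    j1 <- 20; j2 <- 100   # 8 Mb apart, independent genotypes
    x1 <- panel$geno[, j1]; x2 <- panel$geno[, j2]
    y <- 0.35 * x1 + 0.35 * x2 + rnorm(n)
    vc <- null_varcomp(panel)
    assoc <- mlma_scan(panel, y, vc)
    res <- cojo_select(assoc, panel,
                       cojo_config(p_threshold = 1e-6, collinearity_r2 = 0.05,
                                   window_bp = 1e8))
    truth <- coef(summary(lm(y ~ x1 + x2)))
    if (setequal(res$snp, panel$snp_id[c(j1, j2)])) {
      jt <- res$joint[match(panel$snp_id[c(j1, j2)], res$joint$snp), ]
      if (all(abs(jt$b_joint - truth[2:3, 1]) < 2 * truth[2:3, 2])) ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("COJO on orthogonal SNPs selects the marginally significant set with marginal estimates", {
  n <- 2000
  set.seed(58)
  m <- 12
  # orthogonalized dosage columns: r2 exactly 0
  raw <- matrix(rnorm(n * m), n, m)
  q <- qr.Q(qr(cbind(1, raw)))[, -1]
  geno <- apply(q, 2, function(x) {
    g <- cut(x, quantile(x, c(0, 0.25, 0.75, 1)), include.lowest = TRUE)
    as.integer(g) - 1L
  })
  panel <- toy_panel(geno, bp = (1:m) * 5e6)
  beta <- c(rep(0.3, 3), rep(0, m - 3))
  y <- drop(scale(geno) %*% beta) + rnorm(n)
  vc <- null_varcomp(panel)
  assoc <- mlma_scan(panel, y, vc)
  thr <- 1e-8
  res <- cojo_select(assoc, panel, cojo_config(p_threshold = thr,
                                               collinearity_r2 = 0.05))
  expect_setequal(res$snp, assoc$snp[assoc$p <= thr])
  jt <- res$joint
  marg <- assoc$b[match(jt$snp, assoc$snp)]
  # near-orthogonal designs keep joint and marginal estimates close
  expect_lt(max(abs(jt$b_joint - marg)), 0.05)
})

test_that("the COJO selected set respects the collinearity bound", {
  panel <- ld_panel(500, blocks = list(1:3, 4:6), seed = 60)
  m <- 6
  set.seed(60)
  y <- 0.4 * panel$geno[, 1] + 0.4 * panel$geno[, 4] + rnorm(500)
  vc <- null_varcomp(panel)
  assoc <- mlma_scan(panel, y, vc)
  res <- cojo_select(assoc, panel, cojo_config(p_threshold = 1e-4,
                                               collinearity_r2 = 0.05))
  if (res$n_qtl >= 2) {
    sel <- match(res$snp, panel$snp_id)
    r2 <- cor(panel$geno[, sel])^2
    expect_lt(max(r2[upper.tri(r2)]), 0.05)
  }
  expect_lte(res$n_qtl, 2)
})

test_that("QTL intervals span the attributed significant SNPs", {
  assoc <- toy_assoc(b = c(0.5, 0.4, 0.1), se = c(0.05, 0.05, 0.1),
                     p = c(1e-9, 1e-7, 0.5), bp = c(10000, 510000, 2e6))
  sig <- structure(list(snp = "s001", joint = NULL,
                        members = list(s001 = c("s001", "s002")),
                        n_qtl = 1L, method = "clump"),
                   class = "signal_set")
  iv <- qtl_intervals(sig, assoc, threshold = 1e-5)
  expect_equal(iv$interval_bp, 500000)
  # lead-only attribution without membership lists
  sig2 <- structure(list(snp = "s001", joint = NULL, members = NULL,
                         n_qtl = 1L, method = "cojo"),
                    class = "signal_set")
  iv2 <- qtl_intervals(sig2, assoc, threshold = 1e-5)
  expect_equal(iv2$interval_bp, 500000)
  # empty set
  empty <- structure(list(snp = character(0), joint = NULL, members = NULL,
                          n_qtl = 0L, method = "cojo"),
                     class = "signal_set")
  expect_equal(nrow(qtl_intervals(empty, assoc, 1e-5)), 0)
})
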