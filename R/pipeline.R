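#' Full multi-population GWAS pipeline on a simulated (or read) dataset
#'
#' Runs joint QC, then per-population GRM + null REML + mixed-model scan,
#' then the pooled mega-analysis with a population fixed effect.
#'
#' @param panel a `genotype_panel` spanning one or more populations.
#' @param pheno phenotype data.frame (sample_id, pop, score) aligned by
#'   sample id.
#' @param qc_cfg a [qc_config()]; NULL skips QC.
#' @return list: `panel` (post-QC), `pheno`, `qc_report`, `per_pop`
#'   (named list of list(assoc, vc)), `mega` (list(assoc, vc)),
#'   `grm_pooled`.
#' @export
run_multipop_gwas <- function(panel, pheno, qc_cfg = qc_config()) {
  qc_report <- NULL
  if (!is.null(qc_cfg)) {
    qc <- run_qc(panel, qc_cfg)
    panel <- qc$panel
    qc_report <- qc$report
  } else if (anyNA(panel$geno)) {
    stop("panel has missing genotypes and QC was skipped")
  }
  # drop SNPs monomorphic after QC edge cases (defensive; QC's MAF filter
  # normally guarantees this)
  p <- allele_freq(panel)
  panel <- subset_snps(panel, p > 0 & p < 1)
  pheno <- pheno[match(panel$sample_id, pheno$sample_id), ]
  y_all <- pheno$score

  per_pop <- list()
  for (k in unique(panel$pop)) {
    sub <- subset_population(panel, k)
    fr <- allele_freq(sub)
    poly <- fr > 0 & fr < 1
    sub2 <- subset_snps(sub, poly)
    y <- y_all[panel$pop == k]
    g <- compute_grm(sub2)
    vc <- reml_fit(y, grm = g)
    assoc <- mlma_scan(sub2, y, vc)
    per_pop[[k]] <- list(assoc = assoc, vc = vc)
  }

  grm_pooled <- compute_grm(panel)
  mega <- mega_scan(panel, y_all, grm_pooled)
  list(panel = panel, pheno = pheno, qc_report = qc_report,
       per_pop = per_pop, mega = mega, grm_pooled = grm_pooled)
}

#' Genomic inflation factors of every analysis route
#'
#' @param fit output of [run_multipop_gwas()].
#' @param meta_tab optionally a precomputed [run_meta()] table over the
#'   per-population scans.
#' @return named numeric vector: per-population lambdas, mega, meta_z,
#'   meta_ivw, meta_rand (decomposed S_FE + S_Het convention).
#' @export
pipeline_lambdas <- function(fit, meta_tab = NULL) {
  if (is.null(meta_tab))
    meta_tab <- run_meta(lapply(fit$per_pop, `[[`, "assoc"))
  out <- vapply(fit$per_pop, function(pp) {
    genomic_lambda(p = pp$assoc$p[!is.na(pp$assoc$p)])$lambda
  }, numeric(1))
  names(out) <- paste0("within_", names(fit$per_pop))
  pm <- fit$mega$assoc$p
  out["mega"] <- genomic_lambda(p = pm[!is.na(pm)])$lambda
  keep <- meta_tab$n_studies >= 2
  out["meta_z"] <- genomic_lambda(chi2 = meta_tab$z[keep]^2)$lambda
  out["meta_ivw"] <- genomic_lambda(chi2 = (meta_tab$beta[keep]^2 /
                                              meta_tab$se[keep]^2))$lambda
  out["meta_rand"] <- genomic_lambda(mode = "decomposed",
                                     s_fe = meta_tab$s_fe[keep],
                                     s_het = meta_tab$s_het[keep])$lambda
  out
}

#' Replicated mega-vs-meta inflation contrast on the admixed null preset
#'
#' For each replicate: simulate the admixed null preset (cryptic relatedness
#' on, polygenic liability, no QTL), run the full pipeline, and record the
#' genomic inflation factor of the mega-analysis and of each meta-analysis
#' estimator.
#'
#' @param n_rep replicates.
#' @param seed base seed; replicate r uses seed + r.
#' @param scale,n_snps preset size knobs.
#' @return data.frame of lambdas, one row per replicate.
#' @export
lambda_contrast_replicates <- function(n_rep = 20L, seed = 1L,
                                       scale = 0.1, n_snps = 3000L) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- salmon_preset(scale = scale, n_snps = n_snps, qtl_effect = 0,
                         admixture = "mixed")
    sim <- simulate_panel(cfg, seed = seed + r)
    fit <- run_multipop_gwas(sim$panel, sim$pheno)
    as.data.frame(as.list(pipeline_lambdas(fit)))
  })
  do.call(rbind, rows)
}

#' Mega-vs-meta concordance on the homogeneous QTL preset
#'
#' Simulates the salmon preset with its shared-effect QTL, runs the
#' pipeline, and returns the Spearman correlation of -log10 p between the
#' mega-analysis and each meta-analysis estimator over shared SNPs.
#'
#' @param seed RNG seed.
#' @param scale,n_snps preset size knobs.
#' @return named numeric vector of Spearman correlations (z, ivw, random).
#' @export
meta_mega_concordance <- function(seed = 1L, scale = 0.1, n_snps = 4000L) {
  cfg <- salmon_preset(scale = scale, n_snps = n_snps)
  sim <- simulate_panel(cfg, seed = seed)
  fit <- run_multipop_gwas(sim$panel, sim$pheno)
  meta_tab <- run_meta(lapply(fit$per_pop, `[[`, "assoc"))
  i <- match(meta_tab$snp, fit$mega$assoc$snp)
  ok <- !is.na(i) & meta_tab$n_studies >= 2
  mega_lp <- -log10(fit$mega$assoc$p[i[ok]])
  cors <- c(
    z = stats::cor(mega_lp, -log10(meta_tab$p_z[ok]), method = "spearman",
                   use = "complete.obs"),
    ivw = stats::cor(mega_lp, -log10(meta_tab$p_ivw[ok]), method = "spearman",
                     use = "complete.obs"),
    random = stats::cor(mega_lp, -log10(meta_tab$p_rand[ok]),
                        method = "spearman", use = "complete.obs"))
  cors
}

#' Secondary-signal benchmark on the single-QTL preset
#'
#' Per replicate: simulate the salmon preset with one planted QTL, run the
#' mega-analysis, derive the BH threshold at FDR < 0.05, then count
#' independent signals by conditional association, COJO and clumping, and
#' record whether the mega lead SNP falls within one LD block of the planted
#' position.
#'
#' @param n_rep replicates.
#' @param seed base seed.
#' @param scale,n_snps preset size knobs.
#' @return data.frame: one row per replicate with lead_hit, n_conditional,
#'   n_cojo, n_clump, widest interval per method.
#' @export
qtl_method_benchmark <- function(n_rep = 10L, seed = 1L,
                                 scale = 0.14, n_snps = 5000L) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- salmon_preset(scale = scale, n_snps = n_snps)
    sim <- simulate_panel(cfg, seed = seed + r)
    fit <- run_multipop_gwas(sim$panel, sim$pheno)
    assoc <- fit$mega$assoc
    ok <- !is.na(assoc$p)
    fdr <- bh_fdr(assoc$p[ok], q = 0.05)
    thr <- fdr$p_threshold
    lead <- pick_lead(assoc, which(ok))
    hit <- assoc$chr[lead] == cfg$qtl$chrom[1] &&
      abs(assoc$bp[lead] - cfg$qtl$bp[1]) <= cfg$ld_block_bp
    if (is.na(thr)) {
      return(data.frame(lead_hit = hit, n_conditional = 0L, n_cojo = 0L,
                        n_clump = 0L, cond_interval = NA_real_,
                        threshold = NA_real_))
    }
    pops <- unique(fit$panel$pop)
    pop_cols <- sapply(pops[-1L], function(k) as.numeric(fit$panel$pop == k))
    cond <- conditional_scan(fit$panel, fit$pheno$score, fit$grm_pooled,
                             threshold = thr, covariates = pop_cols)
    cj <- cojo_select(assoc[ok, ], fit$panel,
                      cojo_config(p_threshold = thr, collinearity_r2 = 0.05,
                                  window_bp = 1e8))
    cl <- clump(assoc[ok, ], fit$panel,
                clump_config(p1 = thr, r2_min = 0.05, kb_max = 5000))
    data.frame(lead_hit = hit, n_conditional = cond$n_signals,
               n_cojo = cj$n_qtl, n_clump = cl$n_qtl,
               cond_interval = if (nrow(cond$regions))
                 max(cond$regions$interval_bp) else NA_real_,
               threshold = thr)
  })
  do.call(rbind, rows)
}

#' REML variance-component recovery on a family-structured GRM
#'
#' Simulates one salmon-preset panel, computes its pooled GRM, then draws
#' `n_rep` phenotypes y = u + e with u ~ N(0, G sigma_u2), e ~ N(0, I
#' sigma_e2) and refits REML each time.
#'
#' @param n_rep phenotype replicates.
#' @param seed base seed.
#' @param sigma_u2,sigma_e2 true variance components.
#' @param scale,n_snps preset size knobs.
#' @return data.frame: sigma_u2, sigma_e2 estimates per replicate, with the
#'   truth attached as attributes.
#' @export
reml_recovery_replicates <- function(n_rep = 20L, seed = 1L,
                                     sigma_u2 = 1, sigma_e2 = 1,
                                     scale = 0.14, n_snps = 3000L) {
  cfg <- salmon_preset(scale = scale, n_snps = n_snps, qtl_effect = 0)
  sim <- simulate_panel(cfg, seed = seed)
  qc <- run_qc(sim$panel)
  g <- compute_grm(qc$panel)
  eg <- grm_eigen(g)
  n <- length(eg$d)
  rows <- lapply(seq_len(n_rep), function(r) {
    set.seed(seed + 1000L + r)
    u <- eg$U %*% (sqrt(pmax(eg$d, 0) * sigma_u2) * stats::rnorm(n))
    y <- drop(u) + stats::rnorm(n, sd = sqrt(sigma_e2))
    vc <- reml_fit(y, grm = eg)
    data.frame(sigma_u2 = vc$sigma_u2, sigma_e2 = vc$sigma_e2)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- c(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2)
  attr(out, "n") <- n
  out
}
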