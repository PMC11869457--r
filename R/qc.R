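#' Quality-control configuration
#'
#' @param min_call_rate_snp,min_call_rate_sample minimum call rates.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_min SNPs with an exact Hardy-Weinberg test p-value below this
#'   are removed.
#' @param het_low,het_high retained band of per-sample heterozygosity,
#'   computed on raw (pre-imputation) non-missing calls.
#' @param hwe_scope `"within"` tests Hardy-Weinberg within each population
#'   and removes a SNP failing in any population; `"pooled"` tests on the
#'   pooled panel.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(min_call_rate_snp = 0.95, min_call_rate_sample = 0.95,
                      min_maf = 0.01, hwe_p_min = 1e-25,
                      het_low = 0.25, het_high = 0.45,
                      hwe_scope = c("within", "pooled")) {
  stopifnot(het_low < het_high,
            all(c(min_call_rate_snp, min_call_rate_sample, min_maf,
                  het_low, het_high) >= 0),
            all(c(min_call_rate_snp, min_call_rate_sample, min_maf,
                  het_low, het_high) <= 1))
  structure(list(min_call_rate_snp = min_call_rate_snp,
                 min_call_rate_sample = min_call_rate_sample,
                 min_maf = min_maf, hwe_p_min = hwe_p_min,
                 het_low = het_low, het_high = het_high,
                 hwe_scope = match.arg(hwe_scope)),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, enumerate every
#' heterozygote count with the observed parity; the probability of a table
#' with k heterozygotes is proportional to 2^k n! / (n_AA! k! n_aa!) x
#' n_A! n_a! / (2n)!. The p-value is the summed probability of all tables no
#' more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts (hom, het, hom).
#' @return p-value in (0, 1]; monomorphic SNPs return 1.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype counts")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("empty genotype table")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probabilities, normalized at the end
  naa <- (n_a - hets) / 2
  nbb <- (n_b - hets) / 2
  lp <- hets * log(2) + lgamma(n + 1) -
    lgamma(naa + 1) - lgamma(hets + 1) - lgamma(nbb + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

count_genotypes <- function(x) {
  c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
    sum(x == 2L, na.rm = TRUE))
}

#' Allele frequency of the A2 (dosage-counted) allele per SNP
#' @param panel a `genotype_panel`.
#' @return numeric vector of frequencies in [0, 1].
#' @export
allele_freq <- function(panel) {
  colMeans(panel$geno, na.rm = TRUE) / 2
}

# within-population modal-genotype imputation; ties go toward the genotype
# carrying more copies of the locally more frequent allele
impute_mode <- function(geno, pop) {
  for (k in unique(pop)) {
    rows <- which(pop == k)
    sub <- geno[rows, , drop = FALSE]
    c0 <- colSums(sub == 0L, na.rm = TRUE)
    c1 <- colSums(sub == 1L, na.rm = TRUE)
    c2 <- colSums(sub == 2L, na.rm = TRUE)
    p2 <- colMeans(sub, na.rm = TRUE) / 2   # freq of the 2-coded allele
    p2[is.nan(p2)] <- 0
    top <- pmax(c0, c1, c2)
    cnt <- cbind(c0, c1, c2)
    is_mode <- cnt == top
    # lowest modal genotype, or highest when the 2-coded allele is major
    lo <- max.col(is_mode, ties.method = "first") - 1L
    hi <- max.col(is_mode, ties.method = "last") - 1L
    mode_g <- ifelse(p2 > 0.5, hi, lo)
    mode_g[top == 0L] <- 0L
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) {
      sub[idx] <- mode_g[idx[, 2]]
      geno[rows, ] <- sub
    }
  }
  geno
}

#' Joint genotype quality control
#'
#' Filters are applied in a fixed order: SNP call rate, sample call rate,
#' sample heterozygosity band (on raw calls), minor allele frequency, exact
#' Hardy-Weinberg test; remaining sporadic missing genotypes are then imputed
#' to the within-population modal genotype. The output panel has no missing
#' genotypes.
#'
#' @param panel a `genotype_panel`.
#' @param cfg a [qc_config()].
#' @return list(panel, report) where report itemizes removals per filter in
#'   application order.
#' @export
run_qc <- function(panel, cfg = qc_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  report <- list(input = dim(panel$geno))

  # 1. SNP call rate
  cr_snp <- colMeans(!is.na(panel$geno))
  keep <- cr_snp >= cfg$min_call_rate_snp
  report$snp_call_rate_removed <- sum(!keep)
  panel <- subset_snps(panel, keep)

  # 2. sample call rate
  cr_s <- rowMeans(!is.na(panel$geno))
  keep_s <- cr_s >= cfg$min_call_rate_sample
  report$sample_call_rate_removed <- sum(!keep_s)
  panel <- keep_samples(panel, keep_s)

  # 3. heterozygosity band on raw calls
  het <- rowMeans(panel$geno == 1L, na.rm = TRUE)
  keep_s <- het >= cfg$het_low & het <= cfg$het_high
  report$heterozygosity_removed <- sum(!keep_s)
  panel <- keep_samples(panel, keep_s)
  if (nrow(panel$geno) == 0L)
    stop_qc("all samples removed", report)

  # 4. MAF
  p <- allele_freq(panel)
  maf <- pmin(p, 1 - p)
  keep <- !is.nan(maf) & maf >= cfg$min_maf
  report$maf_removed <- sum(!keep)
  panel <- subset_snps(panel, keep)

  # 5. HWE exact test
  if (ncol(panel$geno)) {
    hwe_cols <- function(sub) {
      mapply(hwe_exact_p,
             colSums(sub == 0L, na.rm = TRUE),
             colSums(sub == 1L, na.rm = TRUE),
             colSums(sub == 2L, na.rm = TRUE))
    }
    if (cfg$hwe_scope == "within") {
      fail <- rep(FALSE, ncol(panel$geno))
      for (k in unique(panel$pop)) {
        pv <- hwe_cols(panel$geno[panel$pop == k, , drop = FALSE])
        fail <- fail | pv < cfg$hwe_p_min
      }
    } else {
      fail <- hwe_cols(panel$geno) < cfg$hwe_p_min
    }
    report$hwe_removed <- sum(fail)
    panel <- subset_snps(panel, !fail)
  } else report$hwe_removed <- 0L
  if (ncol(panel$geno) == 0L)
    stop_qc("all SNPs removed", report)

  # 6. impute sporadic missing genotypes
  report$imputed_genotypes <- sum(is.na(panel$geno))
  panel$geno <- impute_mode(panel$geno, panel$pop)
  report$output <- dim(panel$geno)
  list(panel = panel, report = report)
}

stop_qc <- function(msg, report) {
  e <- simpleError(paste0("QC failed: ", msg))
  e$report <- report
  stop(e)
}

keep_samples <- function(panel, keep) {
  genotype_panel(panel$geno[keep, , drop = FALSE], panel$snp_id, panel$chrom,
                 panel$bp, panel$a1, panel$a2,
                 panel$sample_id[keep], panel$pop[keep])
}
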