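# small in-code fixtures shared across tests

# panel from a raw genotype matrix, one chromosome, evenly spaced markers
toy_panel <- function(geno, pop = rep("p1", nrow(geno)), chrom = NULL,
                      bp = NULL) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) {
    bp <- stats::ave(seq_len(m), chrom, FUN = function(i) seq_along(i) * 1e5)
  }
  genotype_panel(geno,
                 snp_id = sprintf("s%03d", seq_len(m)),
                 chrom = chrom, bp = bp,
                 a1 = rep("A", m), a2 = rep("G", m),
                 sample_id = sprintf("i%03d", seq_len(nrow(geno))),
                 pop = pop)
}

# random polymorphic Hardy-Weinberg panel
hwe_panel <- function(n, m, pop = rep("p1", n), maf_min = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p <- runif(m, maf_min, 1 - maf_min)
    geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    fr <- colMeans(geno) / 2
    if (all(fr > 0 & fr < 1)) return(toy_panel(geno, pop = pop))
  }
}

# a varcomp with sigma_u2 = 0 against an identity-like GRM (fixed-effects
# limit of the mixed model)
null_varcomp <- function(panel, sigma_e2 = 1) {
  g <- compute_grm(panel)
  eg <- grm_eigen(g)
  structure(list(sigma_u2 = 0, sigma_e2 = sigma_e2, gamma = 0,
                 loglik = NA_real_, eigen = eg, converged = TRUE,
                 n = length(eg$d)),
            class = "varcomp")
}

# tiny association table built from explicit columns
toy_assoc <- function(b, se, p = NULL, n = 100, chr = NULL, bp = NULL,
                      freq = NULL, snp = NULL, a1 = "A", a2 = "G") {
  m <- length(b)
  if (is.null(p)) p <- pchisq((b / se)^2, 1, lower.tail = FALSE)
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(bp)) bp <- seq_len(m) * 1e5
  if (is.null(freq)) freq <- rep(0.5, m)
  if (is.null(snp)) snp <- sprintf("s%03d", seq_len(m))
  out <- data.frame(snp = snp, chr = chr, bp = bp,
                    a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                    freq = freq, b = b, se = se, z = b / se, p = p,
                    n = rep_len(n, m), stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

quiet_sim <- function(cfg, seed) suppressWarnings(simulate_panel(cfg, seed))
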