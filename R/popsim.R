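#' Simulation configuration for multi-population genotype/phenotype data
#'
#' Bundles all parameters of the generative model: Balding-Nichols drift per
#' population, block-copy admixture from per-population haplotype pools,
#' full-sib family structure, a sparse set of QTL, a polygenic liability and
#' ordinal scoring thresholds.
#'
#' @param pop_sizes integer vector, number of individuals per population.
#' @param n_snps number of SNPs, spread evenly over `n_chroms` chromosomes.
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param fst per-population drift parameter(s) in [0, 1]; recycled.
#' @param admixture n_pops x n_pops matrix of ancestry proportions; row i
#'   gives the probability that a haplotype block of a founder in population
#'   i is copied from population j's haplotype pool. Rows must sum to 1.
#' @param n_families_per_pop full-sib families per population; offspring are
#'   split as evenly as possible across families.
#' @param qtl data.frame with columns `chrom`, `bp`, `effect` (allele
#'   substitution effect on the liability scale); may have zero rows.
#' @param h2_poly proportion of the residual (non-QTL) liability variance
#'   that is polygenic.
#' @param score_thresholds five strictly increasing liability cut-points
#'   mapping liability to the ordinal score 0-5.
#' @param pop_shifts per-population mean shift of the liability.
#' @param ld_block_bp haplotype-block length for the admixture block copy.
#' @param hap_pool_size haplotypes per population pool; a small pool induces
#'   haplotype sharing, hence within-block LD and cryptic relatedness.
#' @param missing_rate uniform sporadic missingness rate injected into the
#'   final genotype matrix.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pop_sizes,
                       n_snps = 2000L,
                       n_chroms = 5L,
                       chrom_length_bp = 3e7,
                       fst = 0.03,
                       admixture = NULL,
                       n_families_per_pop = NULL,
                       qtl = data.frame(chrom = integer(), bp = numeric(),
                                        effect = numeric()),
                       h2_poly = 0.3,
                       score_thresholds = c(-0.8, 0.1, 1.0, 1.9, 2.8),
                       pop_shifts = NULL,
                       ld_block_bp = 1e6,
                       hap_pool_size = 24L,
                       missing_rate = 0.01) {
  n_pops <- length(pop_sizes)
  if (n_pops < 1L) stop("need at least one population")
  fst <- rep_len(fst, n_pops)
  if (any(!is.finite(fst)) || any(fst < 0) || any(fst > 1))
    stop("fst must be finite and in [0, 1]")
  if (is.null(admixture)) admixture <- diag(n_pops)
  admixture <- as.matrix(admixture)
  if (!all(dim(admixture) == n_pops))
    stop("admixture must be n_pops x n_pops")
  if (any(abs(rowSums(admixture) - 1) > 1e-12))
    stop("admixture rows must sum to 1")
  if (any(admixture < 0)) stop("admixture proportions must be >= 0")
  if (is.null(n_families_per_pop))
    n_families_per_pop <- pmax(1L, as.integer(pop_sizes / 10))
  n_families_per_pop <- rep_len(as.integer(n_families_per_pop), n_pops)
  if (length(score_thresholds) != 5L || any(diff(score_thresholds) <= 0))
    stop("score_thresholds must be 5 strictly increasing cut-points")
  if (!is.finite(h2_poly) || h2_poly < 0 || h2_poly > 1)
    stop("h2_poly must be in [0, 1]")
  if (is.null(pop_shifts)) pop_shifts <- rep(0, n_pops)
  pop_shifts <- rep_len(pop_shifts, n_pops)
  stopifnot(nrow(qtl) == 0L ||
              all(c("chrom", "bp", "effect") %in% names(qtl)))
  structure(list(
    n_pops = n_pops, pop_sizes = as.integer(pop_sizes),
    n_snps = as.integer(n_snps), n_chroms = as.integer(n_chroms),
    chrom_length_bp = chrom_length_bp, fst = fst, admixture = admixture,
    n_families_per_pop = n_families_per_pop, qtl = qtl, h2_poly = h2_poly,
    score_thresholds = score_thresholds, pop_shifts = pop_shifts,
    ld_block_bp = ld_block_bp, hap_pool_size = as.integer(hap_pool_size),
    missing_rate = missing_rate
  ), class = "sim_config")
}

#' Preset emulating four related salmon breeding populations
#'
#' Geometry: four populations with sizes scaled from 2006/640/2911/2949,
#' ordinal gill-score phenotype with population means ranging from ~1.5 to
#' ~2.4, small between-population genetic distance, admixture-driven cryptic
#' relatedness, family structure and (optionally) one major QTL.
#'
#' @param scale multiplier on the population sizes (desk-scale tests use
#'   scale well below 1).
#' @param n_snps marker count.
#' @param qtl_effect allele substitution effect of the single major QTL on
#'   the liability scale; 0 drops the QTL (null preset).
#' @param admixture `"mixed"` for the default cross-population ancestry
#'   (cryptic relatedness on), `"identity"` for fully separate populations.
#' @param h2_poly polygenic heritability of the residual liability.
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
salmon_preset <- function(scale = 0.1, n_snps = 5000L, qtl_effect = 0.4,
                          admixture = c("mixed", "identity"),
                          h2_poly = 0.5, ...) {
  admixture <- match.arg(admixture)
  pop_sizes <- pmax(8L, as.integer(round(scale * c(2006, 640, 2911, 2949))))
  A <- if (admixture == "mixed") {
    matrix(0.15, 4, 4) + diag(0.4, 4)
  } else {
    diag(4)
  }
  qtl <- if (qtl_effect != 0) {
    data.frame(chrom = 3L, bp = 15e6, effect = qtl_effect)
  } else {
    data.frame(chrom = integer(), bp = numeric(), effect = numeric())
  }
  sim_config(pop_sizes = pop_sizes, n_snps = n_snps, n_chroms = 5L,
             chrom_length_bp = 3e7, fst = 0.03, admixture = A,
             n_families_per_pop = pmax(2L, as.integer(pop_sizes / 8)),
             qtl = qtl, h2_poly = h2_poly,
             score_thresholds = c(-0.95, -0.05, 0.85, 1.75, 2.65),
             pop_shifts = c(0.75, 0.35, 0, 0), ...)
}

snp_map <- function(config) {
  m <- config$n_snps
  per_chrom <- diff(round(seq(0, m, length.out = config$n_chroms + 1)))
  chrom <- rep(seq_len(config$n_chroms), per_chrom)
  bp <- unlist(lapply(per_chrom, function(k) {
    round(seq(1, config$chrom_length_bp, length.out = k + 1L))[-1L]
  }), use.names = FALSE)
  data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chrom = chrom, bp = bp)
}

#' Simulate founder haplotypes for each population
#'
#' Ancestral allele frequencies are uniform on [0.05, 0.95]; population
#' frequencies follow the Balding-Nichols distribution
#' Beta(p(1-F)/F, (1-p)(1-F)/F). Each population carries a finite haplotype
#' pool sampled from its frequencies; founder haplotypes are assembled by
#' copying blocks of `ld_block_bp` from pools chosen according to the
#' admixture matrix, which creates population-specific LD phase and, when
#' admixture is non-identity, cross-population haplotype sharing.
#'
#' @param config a [sim_config()].
#' @return list with the marker map, ancestral and per-population allele
#'   frequencies, the haplotype pools and per-population founder haplotypes
#'   (two matrices per population, one per gamete).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  map <- snp_map(config)
  p_anc <- stats::runif(m, 0.05, 0.95)
  # a major QTL segregates at intermediate frequency in every population;
  # anchor the ancestral frequency of each QTL-designated marker mid-range
  if (nrow(config$qtl)) {
    for (q in seq_len(nrow(config$qtl))) {
      on_ch <- which(map$chrom == config$qtl$chrom[q])
      if (length(on_ch)) {
        j <- on_ch[which.min(abs(map$bp[on_ch] - config$qtl$bp[q]))]
        p_anc[j] <- stats::runif(1, 0.3, 0.7)
      }
    }
  }
  freqs <- matrix(NA_real_, config$n_pops, m)
  for (k in seq_len(config$n_pops)) {
    f <- config$fst[k]
    freqs[k, ] <- if (f == 0) {
      p_anc
    } else {
      stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }
  pools <- lapply(seq_len(config$n_pops), function(k) {
    matrix(stats::rbinom(config$hap_pool_size * m, 1L,
                         rep(freqs[k, ], each = config$hap_pool_size)),
           nrow = config$hap_pool_size, ncol = m)
  })
  block <- (map$chrom - 1) * (config$chrom_length_bp %/% config$ld_block_bp + 2) +
    map$bp %/% config$ld_block_bp
  block_id <- match(block, unique(block))
  n_blocks <- max(block_id)
  cols_by_block <- split(seq_len(m), block_id)
  founders <- lapply(seq_len(config$n_pops), function(k) {
    n_par <- 2L * config$n_families_per_pop[k]
    haps <- lapply(1:2, function(g) {
      h <- matrix(0L, n_par, m)
      for (i in seq_len(n_par)) {
        src_pop <- sample.int(config$n_pops, n_blocks, replace = TRUE,
                              prob = config$admixture[k, ])
        src_hap <- sample.int(config$hap_pool_size, n_blocks, replace = TRUE)
        for (b in seq_len(n_blocks)) {
          cols <- cols_by_block[[b]]
          h[i, cols] <- pools[[src_pop[b]]][src_hap[b], cols]
        }
      }
      h
    })
    list(hap1 = haps[[1]], hap2 = haps[[2]])
  })
  list(map = map, p_anc = p_anc, freqs = freqs, pools = pools,
       founders = founders, block_id = block_id)
}

# one gamete from a parent: Poisson(1) crossovers per chromosome, uniform
# positions, random starting haplotype
make_gamete <- function(hap1, hap2, map) {
  m <- length(hap1)
  out <- integer(m)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]
    n_xo <- stats::rpois(1L, 1)
    cuts <- sort(stats::runif(n_xo, min(bp), max(bp)))
    seg <- findInterval(bp, cuts)
    use1 <- (seg + stats::rbinom(1L, 1L, 0.5)) %% 2L == 0L
    out[idx] <- hap2[idx]
    out[idx[use1]] <- hap1[idx[use1]]
  }
  out
}

#' Simulate full-sib families from founder haplotypes
#'
#' Within each population, founders are paired into distinct parent couples
#' and each couple produces full-sib offspring by meiosis with on average one
#' crossover per chromosome (Poisson, uniform position). Offspring counts
#' per family are split as evenly as possible; a warning is issued when the
#' population size does not divide evenly. Sporadic missingness is injected
#' uniformly at `config$missing_rate`.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return a `genotype_panel`: integer genotype matrix (0/1/2, NA missing,
#'   dosage of allele A2 coded as in 0|AA, 1|AG, 2|GG), marker map, alleles,
#'   sample ids and population labels.
#' @export
simulate_families <- function(founders, config) {
  map <- founders$map
  m <- nrow(map)
  n_total <- sum(config$pop_sizes)
  geno <- matrix(0L, n_total, m)
  pop_lab <- character(n_total)
  sample_id <- character(n_total)
  row <- 0L
  for (k in seq_len(config$n_pops)) {
    nf <- config$n_families_per_pop[k]
    nk <- config$pop_sizes[k]
    per_fam <- diff(round(seq(0, nk, length.out = nf + 1L)))
    if (length(unique(per_fam)) > 1L)
      warning(sprintf("population %d: %d samples split unevenly over %d families",
                      k, nk, nf))
    f1 <- founders$founders[[k]]$hap1
    f2 <- founders$founders[[k]]$hap2
    for (fam in seq_len(nf)) {
      p1 <- 2L * fam - 1L   # parent pair (distinct by construction)
      p2 <- 2L * fam
      for (o in seq_len(per_fam[fam])) {
        row <- row + 1L
        g1 <- make_gamete(f1[p1, ], f2[p1, ], map)
        g2 <- make_gamete(f1[p2, ], f2[p2, ], map)
        geno[row, ] <- g1 + g2
        pop_lab[row] <- sprintf("pop%d", k)
        sample_id[row] <- sprintf("pop%d_fam%d_ind%d", k, fam, o)
      }
    }
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }
  genotype_panel(geno, map$snp_id, map$chrom, map$bp,
                 a1 = rep("A", m), a2 = rep("G", m),
                 sample_id = sample_id, pop = pop_lab)
}

#' Construct a genotype panel
#'
#' @param geno samples x SNPs integer matrix, values 0/1/2 or NA.
#' @param snp_id,chrom,bp,a1,a2 per-SNP map and alleles; positions must be
#'   strictly increasing within chromosome.
#' @param sample_id,pop per-sample identifiers and population labels.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, snp_id, chrom, bp, a1, a2, sample_id, pop) {
  geno <- as.matrix(geno)
  stopifnot(length(snp_id) == ncol(geno), length(sample_id) == nrow(geno),
            length(pop) == nrow(geno))
  rng <- suppressWarnings(range(geno, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("genotypes must be coded 0/1/2 or NA")
  for (ch in unique(chrom)) {
    if (is.unsorted(bp[chrom == ch], strictly = TRUE))
      stop("positions must be strictly increasing within chromosome")
  }
  structure(list(geno = geno, snp_id = as.character(snp_id),
                 chrom = as.integer(chrom), bp = as.numeric(bp),
                 a1 = as.character(a1), a2 = as.character(a2),
                 sample_id = as.character(sample_id),
                 pop = as.character(pop)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs, %d population(s), %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$pop)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

# mean-imputed, NA-free numeric dosage matrix (internal work-horse)
dosage_matrix <- function(panel) {
  X <- panel$geno
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}

#' Simulate the ordinal phenotype on a liability scale
#'
#' Liability = population shift + sum of QTL dosage effects + polygenic term
#' + Gaussian noise. The polygenic term is built from genome-wide genotypes
#' with i.i.d. per-SNP effects shared by all samples, rescaled so that it
#' explains `h2_poly` of the residual (non-QTL) liability variance; the
#' residual liability has unit variance. The ordinal score 0-5 is the number
#' of thresholds the liability exceeds.
#'
#' @param panel a `genotype_panel`.
#' @param config the [sim_config()] (uses qtl, h2_poly, score_thresholds,
#'   pop_shifts).
#' @return data.frame with sample_id, pop, liability and score.
#' @export
simulate_phenotype <- function(panel, config) {
  n <- nrow(panel$geno)
  X <- dosage_matrix(panel)
  qtl_part <- numeric(n)
  if (nrow(config$qtl)) {
    for (q in seq_len(nrow(config$qtl))) {
      j <- which(panel$chrom == config$qtl$chrom[q] &
                   panel$bp == config$qtl$bp[q])
      if (!length(j)) {
        # snap to the nearest marker on that chromosome
        on_ch <- which(panel$chrom == config$qtl$chrom[q])
        if (!length(on_ch)) stop("QTL chromosome absent from map")
        j <- on_ch[which.min(abs(panel$bp[on_ch] - config$qtl$bp[q]))]
      }
      dose <- X[, j[1L]]
      # centered so population score means stay at their calibrated targets
      qtl_part <- qtl_part + (dose - mean(dose)) * config$qtl$effect[q]
    }
  }
  h2 <- config$h2_poly
  if (h2 > 0) {
    a <- stats::rnorm(ncol(X))
    g <- as.vector(scale(X %*% a))
    poly <- g * sqrt(h2)
    e <- stats::rnorm(n, sd = sqrt(1 - h2))
  } else {
    poly <- numeric(n)
    e <- stats::rnorm(n)
  }
  shift <- config$pop_shifts[match(panel$pop, unique(panel$pop))]
  liab <- shift + qtl_part + poly + e
  score <- findInterval(liab, config$score_thresholds)
  data.frame(sample_id = panel$sample_id, pop = panel$pop,
             liability = liab, score = as.integer(score),
             stringsAsFactors = FALSE)
}

#' One-call simulation of a multi-population panel and phenotype
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the same seed yields a bit-identical panel and
#'   phenotype.
#' @return list(panel, pheno, founders, config).
#' @export
simulate_panel <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- simulate_founders(config)
  panel <- simulate_families(founders, config)
  pheno <- simulate_phenotype(panel, config)
  list(panel = panel, pheno = pheno, founders = founders, config = config)
}

#' Extract a single-population sub-panel
#'
#' @param panel a `genotype_panel`.
#' @param pop population label to keep.
#' @return a `genotype_panel` restricted to that population.
#' @export
subset_population <- function(panel, pop) {
  keep <- panel$pop == pop
  if (!any(keep)) stop("unknown population label: ", pop)
  genotype_panel(panel$geno[keep, , drop = FALSE], panel$snp_id, panel$chrom,
                 panel$bp, panel$a1, panel$a2,
                 panel$sample_id[keep], panel$pop[keep])
}

#' Subset a panel to a set of SNP columns
#' @param panel a `genotype_panel`.
#' @param keep logical or integer index over SNPs.
#' @return a `genotype_panel` with the selected SNPs.
#' @export
subset_snps <- function(panel, keep) {
  genotype_panel(panel$geno[, keep, drop = FALSE], panel$snp_id[keep],
                 panel$chrom[keep], panel$bp[keep], panel$a1[keep],
                 panel$a2[keep], panel$sample_id, panel$pop)
}
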