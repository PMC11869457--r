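#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum p_k (1 - p_k)), where column k of W is the dosage of
#' the A2 allele centered by twice its pooled frequency p_k.
#'
#' @param panel a `genotype_panel` without missing genotypes or monomorphic
#'   SNPs (run QC first).
#' @return object of class `grm`: the matrix, sample ids, method tag.
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$geno
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("panel has missing genotypes; run QC first")
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop("monomorphic SNP(s): ", paste(panel$snp_id[mono][1:min(3, sum(mono))],
                                       collapse = ", "))
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  structure(list(mat = G, sample_id = panel$sample_id,
                 method = "vanraden1"), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d x %d, mean diagonal %.3f\n", x$method,
              nrow(x$mat), ncol(x$mat), mean(diag(x$mat))))
  invisible(x)
}

#' Between/within-population relationship means and Nei's genetic distance
#'
#' @param grm a `grm`.
#' @param labels population label per sample.
#' @param panel optionally the `genotype_panel` the GRM came from; when
#'   given, Nei's standard genetic distance between populations is computed
#'   from per-population allele frequencies.
#' @return list(relationship, distance): square matrices indexed by
#'   population. Relationship entries are block means of the GRM (diagonal
#'   blocks exclude the self-relationships).
#' @export
population_summaries <- function(grm, labels, panel = NULL) {
  stopifnot(length(labels) == nrow(grm$mat))
  pops <- unique(labels)
  tab <- table(labels)
  if (any(tab < 2L)) stop("every population needs >= 2 samples")
  K <- length(pops)
  rel <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    ia <- which(labels == pops[a]); ib <- which(labels == pops[b])
    block <- grm$mat[ia, ib, drop = FALSE]
    rel[a, b] <- if (a == b) {
      mean(block[upper.tri(block)])
    } else mean(block)
  }
  dist <- NULL
  if (!is.null(panel)) {
    dist <- matrix(0, K, K, dimnames = list(pops, pops))
    pmat <- vapply(pops, function(k) {
      sub <- panel$geno[panel$pop == k, , drop = FALSE]
      colMeans(sub, na.rm = TRUE) / 2
    }, numeric(ncol(panel$geno)))
    for (a in seq_len(K)) for (b in seq_len(K)) {
      pa <- pmat[, a]; pb <- pmat[, b]
      jab <- sum(pa * pb + (1 - pa) * (1 - pb))
      jaa <- sum(pa^2 + (1 - pa)^2)
      jbb <- sum(pb^2 + (1 - pb)^2)
      dist[a, b] <- -log(jab / sqrt(jaa * jbb))
    }
  }
  list(relationship = rel, distance = dist)
}

#' Eigendecomposition handle of a GRM
#'
#' Adds a small documented jitter to the diagonal for factorization
#' stability, then eigendecomposes once; all REML fits and scans against the
#' same GRM reuse the handle.
#'
#' @param grm a `grm`.
#' @param jitter diagonal jitter (default 1e-6).
#' @return list(U, d, sample_id).
#' @export
grm_eigen <- function(grm, jitter = 1e-6) {
  e <- eigen(grm$mat + diag(jitter, nrow(grm$mat)), symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0), sample_id = grm$sample_id)
}

#' REML variance components under a GRM
#'
#' Fits y = X beta + u + e with u ~ N(0, G sigma_u^2), e ~ N(0, I sigma_e^2)
#' by restricted maximum likelihood. After rotating by the GRM eigenbasis the
#' restricted likelihood is profiled down to a one-dimensional problem in the
#' variance ratio gamma = sigma_u^2 / sigma_e^2, optimized on the log scale;
#' the boundary gamma = 0 is checked explicitly so estimates are constrained
#' nonnegative.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full column rank; intercept included
#'   by the caller). Defaults to an intercept.
#' @param grm a `grm` or a precomputed [grm_eigen()] handle.
#' @return object of class `varcomp`: sigma_u2, sigma_e2, loglik (restricted),
#'   the eigen handle, convergence flag.
#' @export
reml_fit <- function(y, X = NULL, grm) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  eg <- if (inherits(grm, "grm")) grm_eigen(grm) else grm
  stopifnot(length(eg$d) == n)
  ty <- crossprod(eg$U, y)
  tX <- crossprod(eg$U, X)
  p <- ncol(X)

  rll <- function(log_gamma) {
    g <- exp(log_gamma)
    w <- 1 / (g * eg$d + 1)
    XtWX <- crossprod(tX, tX * w)
    XtWy <- crossprod(tX, ty * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- sum(w * (ty - tX %*% beta)^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(g * eg$d + 1)) +
              2 * sum(log(diag(ch))) + (n - p))
  }

  opt <- stats::optimize(rll, interval = c(log(1e-8), log(1e8)),
                         maximum = TRUE, tol = 1e-8)
  # boundary: no genetic variance
  ll0 <- rll(log(1e-12))
  if (ll0 >= opt$objective) {
    gamma <- 0
    ll <- ll0
  } else {
    gamma <- exp(opt$maximum)
    ll <- opt$objective
  }
  w <- 1 / (gamma * eg$d + 1)
  XtWX <- crossprod(tX, tX * w)
  beta <- solve(XtWX, crossprod(tX, ty * w))
  rss <- sum(w * (ty - tX %*% beta)^2)
  sigma_e2 <- rss / (n - p)
  structure(list(sigma_u2 = gamma * sigma_e2, sigma_e2 = sigma_e2,
                 gamma = gamma, loglik = ll, eigen = eg,
                 converged = TRUE, n = n),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp: sigma_u2 = %.4f, sigma_e2 = %.4f (h2 = %.3f), REML logLik %.2f\n",
              x$sigma_u2, x$sigma_e2,
              x$sigma_u2 / (x$sigma_u2 + x$sigma_e2), x$loglik))
  invisible(x)
}

#' Mixed-linear-model association scan
#'
#' Per-SNP generalized least squares of the phenotype on the SNP dosage with
#' V = G sigma_u2 + I sigma_e2 held fixed at the null REML estimates (the
#' candidate SNP is not excluded from the GRM). Wald p-values from
#' chi-square(1) on (b/SE)^2.
#'
#' @param panel QC'd `genotype_panel` (no missing genotypes).
#' @param y phenotype vector aligned with the panel rows.
#' @param vc a `varcomp` from [reml_fit()] fitted under the null with the
#'   same covariates.
#' @param covariates optional matrix of extra fixed effects (no intercept
#'   column; it is added internally).
#' @return data.frame of class `assoc_table`: snp, chr, bp, a1, a2, freq, b,
#'   se, z, p, n. SNPs collinear with the covariates get NA effect rows.
#' @export
mlma_scan <- function(panel, y, vc, covariates = NULL) {
  n <- nrow(panel$geno)
  stopifnot(length(y) == n, inherits(vc, "varcomp"))
  eg <- vc$eigen
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  w <- 1 / (vc$sigma_u2 * eg$d + vc$sigma_e2)
  ty <- drop(crossprod(eg$U, y))
  tC <- crossprod(eg$U, C)
  X <- panel$geno
  storage.mode(X) <- "double"
  tG <- crossprod(eg$U, X)

  A <- solve(crossprod(tC, tC * w))
  # residualize y and every SNP against the covariates under weights w
  ry <- drop(ty - tC %*% (A %*% crossprod(tC, ty * w)))
  M <- crossprod(tC, tG * w)              # p x m
  rG <- tG - tC %*% (A %*% M)
  sww <- colSums(w * rG * rG)
  num <- colSums(rG * (w * ry))

  ok <- sww > 1e-10 * n
  b <- se <- z <- pval <- rep(NA_real_, ncol(X))
  b[ok] <- num[ok] / sww[ok]
  # residual scale estimated per SNP so that b and SE are invariant to
  # rescaling V by a constant; at the null REML optimum the scale is ~1
  ryw2 <- sum(w * ry * ry)
  dof <- n - ncol(C) - 1L
  s2 <- pmax(ryw2 - num[ok]^2 / sww[ok], 1e-12) / dof
  se[ok] <- sqrt(s2 / sww[ok])
  z[ok] <- b[ok] / se[ok]
  pval[ok] <- stats::pchisq(z[ok]^2, df = 1, lower.tail = FALSE)
  freq <- colMeans(X) / 2
  out <- data.frame(snp = panel$snp_id, chr = panel$chrom, bp = panel$bp,
                    a1 = panel$a2, a2 = panel$a1, freq = freq,
                    b = b, se = se, z = z, p = pval, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Mega-analysis scan: pooled panel with a population fixed effect
#'
#' Runs [mlma_scan()] on the pooled panel with population indicator columns
#' appended to the fixed-effect design (first population absorbed by the
#' intercept). REML is refitted under the null with the same design.
#'
#' @param panel pooled QC'd `genotype_panel` spanning >= 1 population.
#' @param y phenotype vector.
#' @param grm pooled `grm` or [grm_eigen()] handle.
#' @param covariates optional extra fixed effects.
#' @return list(assoc, vc): the `assoc_table` and the null `varcomp`.
#' @export
mega_scan <- function(panel, y, grm, covariates = NULL) {
  pops <- unique(panel$pop)
  pop_cols <- NULL
  if (length(pops) > 1L) {
    pop_cols <- sapply(pops[-1L], function(k) as.numeric(panel$pop == k))
    colnames(pop_cols) <- paste0("pop_", pops[-1L])
  }
  Xfix <- if (is.null(covariates) && is.null(pop_cols)) NULL else
    cbind(covariates, pop_cols)
  vc <- reml_fit(y, X = if (is.null(Xfix)) NULL else cbind(1, Xfix),
                 grm = grm)
  assoc <- mlma_scan(panel, y, vc, covariates = Xfix)
  list(assoc = assoc, vc = vc)
}

# deterministic lead pick: smallest p, then largest |b|, then lowest (chr,bp)
pick_lead <- function(assoc, candidates = seq_len(nrow(assoc))) {
  sub <- assoc[candidates, ]
  ord <- order(sub$p, -abs(sub$b), sub$chr, sub$bp)
  candidates[ord[1L]]
}

#' Iterative conditional association analysis
#'
#' Scans, then repeatedly refits with the current lead significant SNP added
#' as a fixed covariate (REML refitted each round against the same GRM
#' eigenbasis) until no SNP passes the threshold. Each round's QTL region is
#' the span of that round's significant SNPs on the lead's chromosome.
#'
#' @param panel,y,grm as in [mega_scan()].
#' @param threshold p-value threshold for significance (e.g. the BH-derived
#'   threshold at FDR < 0.05).
#' @param covariates optional extra fixed effects (e.g. population
#'   indicators for a mega-style conditional analysis).
#' @param max_rounds guard against non-termination.
#' @return list(n_signals, leads, regions, scans): leads in discovery order,
#'   one `qtl_region` row per round, and the per-round association tables.
#' @export
conditional_scan <- function(panel, y, grm, threshold, covariates = NULL,
                             max_rounds = 10L) {
  eg <- if (inherits(grm, "grm")) grm_eigen(grm) else grm
  leads <- character(0)
  regions <- list()
  scans <- list()
  cond <- covariates
  X <- panel$geno
  storage.mode(X) <- "double"
  for (round in seq_len(max_rounds)) {
    vc <- reml_fit(y, X = if (is.null(cond)) NULL else cbind(1, cond),
                   grm = eg)
    assoc <- mlma_scan(panel, y, vc, covariates = cond)
    scans[[round]] <- assoc
    sig <- which(!is.na(assoc$p) & assoc$p <= threshold &
                   !(assoc$snp %in% leads))
    if (!length(sig)) break
    lead <- pick_lead(assoc, sig)
    on_chr <- sig[assoc$chr[sig] == assoc$chr[lead]]
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = assoc$chr[lead],
      start_bp = min(assoc$bp[on_chr]), end_bp = max(assoc$bp[on_chr]),
      interval_bp = max(assoc$bp[on_chr]) - min(assoc$bp[on_chr]),
      lead = assoc$snp[lead], method = "conditional",
      stringsAsFactors = FALSE)
    leads <- c(leads, assoc$snp[lead])
    cond <- cbind(cond, X[, lead])
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
               interval_bp = numeric(), lead = character(),
               method = character(), stringsAsFactors = FALSE)
  list(n_signals = length(leads), leads = leads, regions = regions,
       scans = scans)
}
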