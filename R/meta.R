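#' Harmonize per-population association tables to a shared effect allele
#'
#' SNPs are matched by id across tables and aligned to the first table's
#' effect allele: where a table's alleles are swapped, its b and z are
#' negated and the frequency reflected; SNPs with irreconcilable allele
#' pairs are dropped (counted). SNPs present in fewer tables are carried
#' through with their reduced study count.
#'
#' @param tables list of `assoc_table` data.frames (columns snp, chr, bp,
#'   a1, a2, freq, b, se, z, p, n).
#' @return object of class `harmonized_sumstats`: per-SNP map plus matrices
#'   (SNP x population) of b, se, z, p, n, freq; `n_dropped` counts allele
#'   mismatches.
#' @export
harmonize <- function(tables) {
  stopifnot(length(tables) >= 1L)
  for (t in tables) {
    if (anyDuplicated(t$snp)) stop("duplicate SNP ids within one table")
  }
  ref <- tables[[1L]][, c("snp", "chr", "bp", "a1", "a2")]
  ids <- unique(unlist(lapply(tables, `[[`, "snp")))
  # SNPs absent from the reference table keep their own alleles as reference
  extra <- setdiff(ids, ref$snp)
  if (length(extra)) {
    for (t in tables[-1L]) {
      hit <- t[t$snp %in% extra, c("snp", "chr", "bp", "a1", "a2")]
      ref <- rbind(ref, hit[!duplicated(hit$snp), ])
      extra <- setdiff(extra, hit$snp)
      if (!length(extra)) break
    }
  }
  ref <- ref[match(ids, ref$snp), ]
  N <- length(tables)
  m <- length(ids)
  mk <- function() matrix(NA_real_, m, N, dimnames = list(ids, NULL))
  B <- mk(); SE <- mk(); Z <- mk(); P <- mk(); Nn <- mk(); FR <- mk()
  dropped <- character(0)
  for (j in seq_len(N)) {
    t <- tables[[j]]
    i <- match(t$snp, ids)
    same <- t$a1 == ref$a1[i] & t$a2 == ref$a2[i]
    swap <- t$a1 == ref$a2[i] & t$a2 == ref$a1[i]
    bad <- !(same | swap)
    dropped <- union(dropped, t$snp[bad])
    sgn <- ifelse(swap, -1, 1)
    keep <- !bad
    B[i[keep], j] <- sgn[keep] * t$b[keep]
    SE[i[keep], j] <- t$se[keep]
    Z[i[keep], j] <- sgn[keep] * t$z[keep]
    P[i[keep], j] <- t$p[keep]
    Nn[i[keep], j] <- t$n[keep]
    FR[i[keep], j] <- ifelse(swap[keep], 1 - t$freq[keep], t$freq[keep])
  }
  if (length(dropped)) {
    keep <- !(ids %in% dropped)
    ref <- ref[keep, ]; B <- B[keep, , drop = FALSE]
    SE <- SE[keep, , drop = FALSE]; Z <- Z[keep, , drop = FALSE]
    P <- P[keep, , drop = FALSE]; Nn <- Nn[keep, , drop = FALSE]
    FR <- FR[keep, , drop = FALSE]
  }
  structure(list(map = ref, b = B, se = SE, z = Z, p = P, n = Nn,
                 freq = FR, n_dropped = length(dropped)),
            class = "harmonized_sumstats")
}

#' Sample-size-weighted (Stouffer) Z-score meta-analysis
#'
#' Z_ij = Phi^-1(1 - p_ij / 2) * sign(b_ij); the combined
#' Z = sum(Z_ij * w_ij) / sqrt(sum(w_ij^2)) with w_ij = sqrt(n_ij), and
#' P = 2 Phi(-|Z|). Underflowing p-values are clamped to the smallest
#' positive normal double.
#'
#' @param p,b,n vectors over contributing studies (NA studies are skipped);
#'   `b` supplies the effect direction.
#' @return list(z, p).
#' @export
stouffer_z <- function(p, b, n) {
  ok <- !is.na(p) & !is.na(b) & !is.na(n)
  p <- p[ok]; b <- b[ok]; n <- n[ok]
  if (!length(p)) return(list(z = NA_real_, p = NA_real_))
  if (any(p <= 0)) p[p <= 0] <- .Machine$double.xmin
  zij <- stats::qnorm(p / 2, lower.tail = FALSE) * sign(b)
  w <- sqrt(n)
  z <- sum(zij * w) / sqrt(sum(w^2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Inverse-variance-weighted fixed-effects meta-analysis with heterogeneity
#'
#' beta_j = sum(b w) / sum(w) with w = V^-1, V_j = 1/sum(w); Cochran's
#' Q = sum(w (b - beta_j)^2), I^2 = (Q - (N-1))/Q x 100 truncated to
#' [0, 100] (0 when Q = 0 or N = 1); the test statistic beta_j^2 / V_j is
#' chi-square(1).
#'
#' @param b,se per-study effects and standard errors (NA studies skipped).
#' @return list(beta, v, chisq, p, q, df_q, p_q, i2, n_studies).
#' @export
ivw <- function(b, se) {
  ok <- !is.na(b) & !is.na(se)
  b <- b[ok]; se <- se[ok]
  if (!length(b)) return(list(beta = NA_real_, v = NA_real_, chisq = NA_real_,
                              p = NA_real_, q = NA_real_, df_q = NA_integer_,
                              p_q = NA_real_, i2 = NA_real_, n_studies = 0L))
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  beta <- sum(b * w) / sum(w)
  v <- 1 / sum(w)
  chisq <- beta^2 / v
  q <- sum(w * (b - beta)^2)
  nst <- length(b)
  i2 <- if (q > 0 && nst > 1L) max(0, (q - (nst - 1)) / q * 100) else 0
  list(beta = beta, v = v, chisq = chisq,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       q = q, df_q = nst - 1L,
       p_q = if (nst > 1L) stats::pchisq(q, nst - 1L, lower.tail = FALSE) else NA_real_,
       i2 = i2, n_studies = nst)
}

#' DerSimonian-Laird between-study variance
#'
#' tau^2 = (Q - (N-1)) / (sum w - sum w^2 / sum w), truncated at 0 when
#' Q < N - 1; w = V^-1. With a single study tau^2 is reported as 0.
#'
#' @param b,se per-study effects and standard errors.
#' @param q optionally a precomputed Cochran's Q.
#' @return tau-squared (scalar >= 0).
#' @export
dl_tau2 <- function(b, se, q = NULL) {
  ok <- !is.na(b) & !is.na(se)
  b <- b[ok]; se <- se[ok]
  nst <- length(b)
  if (nst < 2L) return(0)
  w <- 1 / se^2
  if (is.null(q)) {
    beta <- sum(b * w) / sum(w)
    q <- sum(w * (b - beta)^2)
  }
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (q - (nst - 1)) / denom)
}

#' Han-Eskin random-effects statistic and its decomposition
#'
#' S_rand = S_FE + S_Het where S_FE = sum(b^2/V) - sum((b - beta_j)^2/V)
#' (equal to the IVW chi-square) and S_Het collects the heterogeneity
#' likelihood terms evaluated at the DerSimonian-Laird tau^2, with
#' beta_j* the tau^2-reweighted mean. S_Het is truncated at 0. The p-value
#' uses the boundary asymptotic null, an equal mixture of chi-square(1) and
#' chi-square(2).
#'
#' @param b,se per-study effects and standard errors.
#' @param tau2 between-study variance; defaults to [dl_tau2()].
#' @return list(s_fe, s_het, s_rand, beta_star, tau2, p_rand).
#' @export
han_eskin <- function(b, se, tau2 = NULL) {
  ok <- !is.na(b) & !is.na(se)
  b <- b[ok]; se <- se[ok]
  if (!length(b)) return(list(s_fe = NA_real_, s_het = NA_real_,
                              s_rand = NA_real_, beta_star = NA_real_,
                              tau2 = NA_real_, p_rand = NA_real_))
  V <- se^2
  w <- 1 / V
  beta_j <- sum(b * w) / sum(w)
  if (is.null(tau2)) tau2 <- dl_tau2(b, se)
  if (tau2 < 0) stop("tau2 must be pre-truncated at 0")
  ws <- 1 / (V + tau2)
  beta_star <- sum(b * ws) / sum(ws)
  s_fe <- sum(b^2 / V) - sum((b - beta_j)^2 / V)
  s_het <- sum(log(V / (V + tau2))) + sum((b - beta_j)^2 / V) -
    sum((b - beta_star)^2 / (V + tau2))
  s_het <- max(0, s_het)
  s_rand <- s_fe + s_het
  p_rand <- 0.5 * stats::pchisq(s_rand, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(s_rand, 2, lower.tail = FALSE)
  list(s_fe = s_fe, s_het = s_het, s_rand = s_rand,
       beta_star = beta_star, tau2 = tau2, p_rand = p_rand)
}

#' Monte-Carlo null calibration for the random-effects statistic
#'
#' Simulates null per-study effects (common mean zero, stated SEs) and
#' returns the simulated null distribution of S_rand, for calibrating
#' p-values at small study counts where the mixture asymptotics are crude.
#'
#' @param se per-study standard errors.
#' @param n_sim simulated null draws.
#' @param seed RNG seed.
#' @return numeric vector of null S_rand values.
#' @export
han_eskin_null <- function(se, n_sim = 10000L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_sim), function(i) {
    b <- stats::rnorm(length(se), 0, se)
    han_eskin(b, se)$s_rand
  }, numeric(1))
}

#' Convert a z-score to effect and standard error
#'
#' b = z / sqrt(2 p (1-p) (n + z^2)), SE = 1 / sqrt(2 p (1-p) (n + z^2)),
#' so that b/SE = z exactly; used to feed z-only (Stouffer) meta-analysis
#' results into effect-based secondary-signal methods.
#'
#' @param z z-score(s).
#' @param p effect-allele frequency in (0, 1).
#' @param n sample size.
#' @return list(b, se).
#' @export
z_to_beta_se <- function(z, p, n) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency must be in (0, 1)")
  if (any(n < 1)) stop("sample size must be >= 1")
  denom <- sqrt(2 * p * (1 - p) * (n + z^2))
  list(b = z / denom, se = 1 / denom)
}

i2_band <- function(i2) {
  cut(i2, breaks = c(-Inf, 25, 50, 75, Inf),
      labels = c("none", "moderate", "high", "very high"), right = FALSE)
}

#' Meta-analysis over per-population association tables
#'
#' Harmonizes the tables then computes, per SNP over contributing
#' populations: Stouffer Z and its p, IVW beta/SE/p with Cochran's Q
#' (flagged at the 0.10 level) and I-squared (with the 25/50/75 bands),
#' DerSimonian-Laird tau-squared, and the Han-Eskin random-effects
#' decomposition S_rand = S_FE + S_Het.
#'
#' @param tables list of `assoc_table`s (>= 2) or a `harmonized_sumstats`.
#' @param method which p-value is copied into the `p_meta` column:
#'   `"zscore"`, `"ivw"` or `"random"`.
#' @return data.frame with one row per SNP: snp, chr, bp, a1, a2, n_studies,
#'   z, p_z, beta, se, p_ivw, q, df_q, p_q, q_sig10, i2, i2_band, tau2,
#'   beta_re, s_fe, s_het, s_rand, p_rand, directions, p_meta.
#' @export
run_meta <- function(tables, method = c("ivw", "zscore", "random")) {
  method <- match.arg(method)
  h <- if (inherits(tables, "harmonized_sumstats")) tables else harmonize(tables)
  m <- nrow(h$map)
  if (!m) stop("no overlapping SNPs after harmonization")
  out <- h$map
  res <- matrix(NA_real_, m, 18)
  dirs <- character(m)
  for (i in seq_len(m)) {
    b <- h$b[i, ]; se <- h$se[i, ]; p <- h$p[i, ]; n <- h$n[i, ]
    sz <- stouffer_z(p, b, n)
    iv <- ivw(b, se)
    t2 <- dl_tau2(b, se, q = iv$q)
    he <- han_eskin(b, se, tau2 = t2)
    res[i, ] <- c(iv$n_studies, sz$z, sz$p, iv$beta, sqrt(iv$v), iv$p,
                  iv$q, iv$df_q, iv$p_q, iv$i2, t2, he$beta_star,
                  he$s_fe, he$s_het, he$s_rand, he$p_rand,
                  NA, NA)
    dirs[i] <- paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")),
                     collapse = "")
  }
  out$n_studies <- as.integer(res[, 1])
  out$z <- res[, 2]; out$p_z <- res[, 3]
  out$beta <- res[, 4]; out$se <- res[, 5]; out$p_ivw <- res[, 6]
  out$q <- res[, 7]; out$df_q <- as.integer(res[, 8]); out$p_q <- res[, 9]
  out$q_sig10 <- !is.na(out$p_q) & out$p_q < 0.10
  out$i2 <- res[, 10]; out$i2_band <- i2_band(out$i2)
  out$tau2 <- res[, 11]; out$beta_re <- res[, 12]
  out$s_fe <- res[, 13]; out$s_het <- res[, 14]; out$s_rand <- res[, 15]
  out$p_rand <- res[, 16]
  out$directions <- dirs
  out$p_meta <- switch(method, zscore = out$p_z, ivw = out$p_ivw,
                       random = out$p_rand)
  class(out) <- c("meta_table", "data.frame")
  out
}
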