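#' Benjamini-Hochberg step-up FDR control with a derived p-value threshold
#'
#' Ranks p-values ascending, finds the highest rank k with P_(k) <= q k / m,
#' and declares all markers at or below that rank significant. The working
#' p-value threshold (for feeding conditional analysis, COJO and clumping)
#' is the largest significant p-value; NA when nothing is significant.
#'
#' @param p vector of p-values in (0, 1]; NaN rejected.
#' @param q FDR level (default 0.05).
#' @return list(q, m, significant (logical), snp_rank, p_threshold,
#'   adjusted) where `adjusted` are BH-adjusted p-values.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(is.nan(p)) || any(is.na(p))) stop("NA/NaN p-values not allowed")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- ps <= q * seq_len(m) / m
  k <- if (any(pass)) max(which(pass)) else 0L
  sig <- logical(m)
  if (k > 0L) sig[ord[seq_len(k)]] <- TRUE
  list(q = q, m = m, significant = sig,
       n_significant = k,
       p_threshold = if (k > 0L) ps[k] else NA_real_,
       adjusted = stats::p.adjust(p, method = "BH"))
}

#' Bolormaa-style FDR for a candidate p-value threshold (diagnostic)
#'
#' FDR(t) = t (1 - k/m) / ((k/m) (1 - t)) with k the number of tests at or
#' below t; returns the largest observed p-value whose FDR is at most q.
#' Exposed alongside [bh_fdr()] because both derivations circulate for
#' turning an FDR level into a working threshold; the rejection sets agree
#' in practice.
#'
#' @param p p-values.
#' @param q FDR level.
#' @return list(p_threshold, fdr_at_threshold); threshold NA when no
#'   candidate qualifies.
#' @export
bolormaa_threshold <- function(p, q = 0.05) {
  m <- length(p)
  ps <- sort(p)
  k <- seq_len(m)
  fdr <- ps * (1 - k / m) / ((k / m) * (1 - ps))
  # the formula degenerates as k/m -> 1, so take the largest threshold in
  # the leading run where the estimated FDR stays at or below q
  bad <- which(fdr > q)
  i <- if (!length(bad)) m else bad[1L] - 1L
  if (i < 1L) return(list(p_threshold = NA_real_,
                          fdr_at_threshold = NA_real_))
  list(p_threshold = ps[i], fdr_at_threshold = fdr[i])
}

#' Genomic inflation factor
#'
#' lambda = median observed chi-square / median of chi-square(1) (~0.455 at
#' the 3-decimal convention). In `"decomposed"` mode, for random-effects
#' scans, lambda is the sum of the lambdas of the S_FE and S_Het statistic
#' vectors.
#'
#' @param p p-values (converted to chi-square(1) quantiles), or
#' @param chi2 chi-square statistics directly (used when `p` is NULL).
#' @param mode `"plain"` or `"decomposed"`.
#' @param s_fe,s_het component statistic vectors for decomposed mode.
#' @return object of class `lambda_estimate`: lambda, n_tests, mode,
#'   components.
#' @export
genomic_lambda <- function(p = NULL, chi2 = NULL,
                           mode = c("plain", "decomposed"),
                           s_fe = NULL, s_het = NULL) {
  mode <- match.arg(mode)
  m0 <- stats::qchisq(0.5, df = 1)   # 0.4549 (reported as 0.455)
  if (mode == "decomposed") {
    if (is.null(s_fe) || is.null(s_het))
      stop("decomposed mode needs s_fe and s_het")
    comp <- c(fe = stats::median(s_fe) / m0,
              het = stats::median(s_het) / m0)
    lam <- sum(comp)
    n <- length(s_fe)
  } else {
    if (is.null(chi2)) {
      if (is.null(p)) stop("supply p or chi2")
      if (!length(p)) stop("empty input")
      chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
    }
    if (!length(chi2)) stop("empty input")
    n <- length(chi2)
    if (n < 30L) warning("lambda estimated from fewer than 30 tests")
    comp <- NULL
    lam <- stats::median(chi2) / m0
  }
  structure(list(lambda = lam, n_tests = n, mode = mode, components = comp,
                 null_median = m0),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("lambda = %.3f (%s, %d tests, null median %.3f)\n",
              x$lambda, x$mode, x$n_tests, round(x$null_median, 3)))
  invisible(x)
}

#' Flag genomic inflation as evidence of confounding
#'
#' @param estimate a `lambda_estimate` (or bare lambda value).
#' @return `"confounded"` iff lambda > 1.1 (strict), else `"ok"`.
#' @export
lambda_flag <- function(estimate) {
  lam <- if (inherits(estimate, "lambda_estimate")) estimate$lambda else estimate
  if (!is.finite(lam) || lam <= 0) stop("invalid lambda")
  if (lam > 1.1) "confounded" else "ok"
}
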