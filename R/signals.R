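#' COJO configuration
#' @param p_threshold significance threshold (e.g. FDR-derived).
#' @param collinearity_r2 candidates with squared correlation at or above
#'   this with any selected SNP get conditional p forced to 1.
#' @param window_bp SNPs farther apart than this (or on different
#'   chromosomes) are treated as uncorrelated.
#' @param max_iter stepwise iteration cap.
#' @return `cojo_config`.
#' @export
cojo_config <- function(p_threshold, collinearity_r2 = 0.05,
                        window_bp = 1e8, max_iter = 100L) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            collinearity_r2 > 0, collinearity_r2 < 1, window_bp > 0)
  structure(list(p_threshold = p_threshold,
                 collinearity_r2 = collinearity_r2,
                 window_bp = window_bp, max_iter = as.integer(max_iter)),
            class = "cojo_config")
}

#' Clumping configuration
#' @param p1 maximum p-value for clump leads and members.
#' @param r2_min minimum r-squared between a lead and its members.
#' @param kb_max maximum lead-to-member distance in kb (boundary inclusive).
#' @return `clump_config`.
#' @export
clump_config <- function(p1, r2_min = 0.05, kb_max = 5000) {
  stopifnot(p1 > 0, p1 <= 1, r2_min >= 0, r2_min <= 1, kb_max > 0)
  structure(list(p1 = p1, r2_min = r2_min, kb_max = kb_max),
            class = "clump_config")
}

# reference-panel LD state: centered mean-imputed dosages + per-SNP scale
ref_ld_state <- function(reference, snp_ids) {
  idx <- match(snp_ids, reference$snp_id)
  if (anyNA(idx)) stop("reference panel does not cover all SNPs")
  X <- dosage_matrix(reference)[, idx, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  ss <- colSums(Xc^2)
  list(Xc = Xc, ss = ss, n_ref = nrow(Xc),
       chrom = reference$chrom[idx], bp = reference$bp[idx])
}

# r between SNP j and a set of SNPs, with the window rule applied
ref_cor <- function(st, j, k, window_bp) {
  r <- as.vector(crossprod(st$Xc[, j], st$Xc[, k, drop = FALSE])) /
    sqrt(st$ss[j] * st$ss[k])
  r[!is.finite(r)] <- 0
  far <- st$chrom[k] != st$chrom[j] | abs(st$bp[k] - st$bp[j]) > window_bp
  r[far] <- 0
  r
}

#' Approximate conditional and joint (stepwise) selection from summary stats
#'
#' Stepwise model selection on GWAS summary statistics using a reference
#' genotype panel for LD. The X'X blocks are reconstructed from reference
#' correlations and per-SNP variances (D_j = n_j var_ref(x_j)), X'y from
#' D_j b_j, and the phenotypic sum of squares from the median of the
#' per-SNP implied values. Each round: conditional p-values for all
#' non-selected SNPs given the selected set (correlations beyond the window
#' zeroed; candidates violating the collinearity rule get conditional p 1);
#' the best candidate below threshold enters; the joint fit then drops the
#' largest-p non-significant member. Iterates to a fixed point.
#'
#' @param assoc an `assoc_table` (b, se, freq, p, n present; if only z is
#'   available convert first with [z_to_beta_se()]).
#' @param reference a QC'd `genotype_panel` covering the assoc SNPs.
#' @param cfg a [cojo_config()].
#' @return list of class `signal_set`: `snp` (selection order), `joint`
#'   (data.frame snp, chr, bp, b_marginal, b_joint, se_joint, p_joint),
#'   `n_qtl`, `method`.
#' @export
cojo_select <- function(assoc, reference, cfg) {
  stopifnot(inherits(cfg, "cojo_config"))
  ok <- !is.na(assoc$b) & !is.na(assoc$se) & assoc$se > 0
  assoc <- assoc[ok, ]
  m <- nrow(assoc)
  st <- ref_ld_state(reference, assoc$snp)
  st$chrom <- assoc$chr   # the association map is the position authority
  st$bp <- assoc$bp
  v_ref <- st$ss / (st$n_ref - 1)
  D <- assoc$n * v_ref
  rhs <- D * assoc$b
  ypy_each <- D * assoc$b^2 + D * assoc$se^2 * (assoc$n - 2)
  ypy <- stats::median(ypy_each)
  n_eff <- stats::median(assoc$n)

  sel <- integer(0)
  if (!any(assoc$p <= cfg$p_threshold)) {
    return(empty_signal_set("cojo"))
  }
  sel <- pick_lead(assoc, which(assoc$p <= cfg$p_threshold))

  joint_fit <- function(set) {
    q <- length(set)
    A <- matrix(0, q, q)
    for (a in seq_len(q)) {
      r <- ref_cor(st, set[a], set, cfg$window_bp)
      A[a, ] <- r * sqrt(D[set[a]] * D[set])
    }
    diag(A) <- D[set]
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(NULL)
    beta <- Ainv %*% rhs[set]
    rss <- max(ypy - sum(beta * rhs[set]), 1e-12)
    s2 <- rss / (n_eff - q - 1)
    se <- sqrt(pmax(diag(Ainv), 0) * s2)
    pj <- stats::pchisq((beta / se)^2, 1, lower.tail = FALSE)
    list(beta = drop(beta), se = se, p = drop(pj), A = A, Ainv = Ainv,
         rss = rss)
  }

  for (iter in seq_len(cfg$max_iter)) {
    changed <- FALSE
    jf <- joint_fit(sel)
    if (is.null(jf)) break
    # conditional p for every candidate given the selected set
    cand <- setdiff(seq_len(m), sel)
    if (length(cand)) {
      q <- length(sel)
      Rsc <- vapply(cand, function(c0) ref_cor(st, c0, sel, cfg$window_bp),
                    numeric(q))
      Rsc <- matrix(Rsc, nrow = q)
      collinear <- apply(Rsc^2 >= cfg$collinearity_r2, 2, any)
      Asc <- Rsc * sqrt(outer(D[sel], D[cand]))     # q x mc
      AinvAsc <- jf$Ainv %*% Asc
      schur <- D[cand] - colSums(Asc * AinvAsc)
      bc <- (rhs[cand] - colSums(AinvAsc * rhs[sel])) / schur
      rss_j <- pmax(jf$rss - bc^2 * schur, 1e-12)
      s2 <- rss_j / (n_eff - q - 2)
      se_c <- sqrt(pmax(s2 / schur, 0))
      p_c <- stats::pchisq((bc / se_c)^2, 1, lower.tail = FALSE)
      p_c[collinear | schur <= 1e-8 * D[cand]] <- 1
      hit <- which(p_c <= cfg$p_threshold)
      if (length(hit)) {
        sub <- data.frame(p = p_c[hit], b = bc[hit],
                          chr = assoc$chr[cand[hit]],
                          bp = assoc$bp[cand[hit]])
        best <- hit[order(sub$p, -abs(sub$b), sub$chr, sub$bp)[1L]]
        sel <- c(sel, cand[best])
        changed <- TRUE
      }
    }
    # drop the largest-p non-significant member of the joint fit
    jf <- joint_fit(sel)
    if (is.null(jf)) break
    bad <- which(jf$p > cfg$p_threshold)
    if (length(bad) && length(sel) > 1L) {
      worst <- bad[which.max(jf$p[bad])]
      sel <- sel[-worst]
      changed <- TRUE
    }
    if (!changed) break
  }
  jf <- joint_fit(sel)
  joint <- data.frame(snp = assoc$snp[sel], chr = assoc$chr[sel],
                      bp = assoc$bp[sel], freq = assoc$freq[sel],
                      b_marginal = assoc$b[sel],
                      b_joint = jf$beta, se_joint = jf$se, p_joint = jf$p,
                      stringsAsFactors = FALSE)
  structure(list(snp = assoc$snp[sel], joint = joint, members = NULL,
                 n_qtl = length(sel), method = "cojo"),
            class = "signal_set")
}

empty_signal_set <- function(method) {
  structure(list(snp = character(0),
                 joint = data.frame(snp = character(0), chr = integer(0),
                                    bp = numeric(0), freq = numeric(0),
                                    b_marginal = numeric(0),
                                    b_joint = numeric(0),
                                    se_joint = numeric(0),
                                    p_joint = numeric(0),
                                    stringsAsFactors = FALSE),
                 members = if (method == "clump") list() else NULL,
                 n_qtl = 0L, method = method),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal_set (%s): %d independent signal(s)\n", x$method, x$n_qtl))
  if (x$n_qtl) print(utils::head(x$joint, 10))
  invisible(x)
}

#' Greedy LD clumping of significant SNPs
#'
#' The first clump is seeded by the most significant SNP with p <= p1; every
#' unassigned SNP with p <= p1, squared correlation >= r2_min with the lead
#' and distance <= kb_max joins it. Repeat with the most significant
#' unassigned SNP until none remain. Significant SNPs are partitioned across
#' clumps.
#'
#' @param assoc an `assoc_table`.
#' @param reference a QC'd `genotype_panel` covering the assoc SNPs.
#' @param cfg a [clump_config()].
#' @return `signal_set` with `members`: a list (per lead) of member SNP ids
#'   (lead included).
#' @export
clump <- function(assoc, reference, cfg) {
  stopifnot(inherits(cfg, "clump_config"))
  sig <- which(!is.na(assoc$p) & assoc$p <= cfg$p1)
  if (!length(sig)) return(empty_signal_set("clump"))
  st <- ref_ld_state(reference, assoc$snp)
  st$chrom <- assoc$chr
  st$bp <- assoc$bp
  unassigned <- sig
  leads <- integer(0)
  members <- list()
  while (length(unassigned)) {
    lead <- pick_lead(assoc, unassigned)
    others <- setdiff(unassigned, lead)
    memb <- lead
    if (length(others)) {
      r2 <- ref_cor(st, lead, others, window_bp = Inf)^2
      near <- st$chrom[others] == st$chrom[lead] &
        abs(st$bp[others] - st$bp[lead]) <= cfg$kb_max * 1000
      memb <- c(lead, others[r2 >= cfg$r2_min & near])
    }
    leads <- c(leads, lead)
    members[[length(members) + 1L]] <- assoc$snp[memb]
    unassigned <- setdiff(unassigned, memb)
  }
  joint <- data.frame(snp = assoc$snp[leads], chr = assoc$chr[leads],
                      bp = assoc$bp[leads], freq = assoc$freq[leads],
                      b_marginal = assoc$b[leads],
                      b_joint = NA_real_, se_joint = NA_real_,
                      p_joint = NA_real_, stringsAsFactors = FALSE)
  names(members) <- assoc$snp[leads]
  structure(list(snp = assoc$snp[leads], joint = joint, members = members,
                 n_qtl = length(leads), method = "clump"),
            class = "signal_set")
}

#' QTL intervals for a set of independent signals
#'
#' Per lead, the region spans the significant SNPs attributed to that lead:
#' clump members when the signal set carries membership lists, otherwise
#' each significant SNP (p <= threshold) is attributed to the nearest
#' selected lead on its chromosome. A lead without members yields a
#' zero-length region at the lead.
#'
#' @param signals a `signal_set`.
#' @param assoc the `assoc_table` the signals came from.
#' @param threshold significance threshold used for attribution.
#' @return data.frame: chrom, start_bp, end_bp, interval_bp, lead, method.
#' @export
qtl_intervals <- function(signals, assoc, threshold) {
  empty <- data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), interval_bp = numeric(0),
                      lead = character(0), method = character(0),
                      stringsAsFactors = FALSE)
  if (!signals$n_qtl) return(empty)
  leads <- signals$snp
  li <- match(leads, assoc$snp)
  rows <- lapply(seq_along(leads), function(k) {
    if (!is.null(signals$members)) {
      mem <- match(signals$members[[k]], assoc$snp)
    } else {
      sig <- which(!is.na(assoc$p) & assoc$p <= threshold &
                     assoc$chr == assoc$chr[li[k]])
      if (length(sig)) {
        same_chr_leads <- li[assoc$chr[li] == assoc$chr[li[k]]]
        nearest <- vapply(sig, function(s) {
          same_chr_leads[which.min(abs(assoc$bp[same_chr_leads] - assoc$bp[s]))]
        }, integer(1))
        mem <- sig[nearest == li[k]]
      } else mem <- integer(0)
      mem <- union(mem, li[k])
    }
    data.frame(chrom = assoc$chr[li[k]],
               start_bp = min(assoc$bp[mem]), end_bp = max(assoc$bp[mem]),
               interval_bp = max(assoc$bp[mem]) - min(assoc$bp[mem]),
               lead = leads[k], method = signals$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
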