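#' Write a genotype panel as PLINK bed/bim/fam
#'
#' SNP-major bed with the standard 3-byte magic; genotypes are stored as the
#' dosage of the bim A1 allele (panel `a2`, the 2-coded allele), so 2 copies
#' map to the homozygous-A1 code. The fam FID column carries the population
#' label. A phenotype table, when given, is written as `<prefix>.pheno.tsv`
#' (FID, IID, score).
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @param pheno optional phenotype data.frame (sample_id, pop, score).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix, pheno = NULL) {
  n <- nrow(panel$geno); m <- ncol(panel$geno)
  bim <- data.frame(panel$chrom, panel$snp_id, 0, panel$bp,
                    panel$a2, panel$a1)   # A1 = dosage-counted allele
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$pop, panel$sample_id, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # 2-bit codes per sample: 00 hom A1 (dosage 2), 10 het, 11 hom A2, 01 missing
  code <- matrix(3L, n, m)
  code[panel$geno == 2L] <- 0L
  code[panel$geno == 1L] <- 2L
  code[is.na(panel$geno)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bytes_per_snp - n
  for (j in seq_len(m)) {
    v <- c(code[, j], rep(0L, pad))
    dim(v) <- c(4L, bytes_per_snp)
    byte <- v[1, ] + v[2, ] * 4L + v[3, ] * 16L + v[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  if (!is.null(pheno)) {
    utils::write.table(
      data.frame(FID = pheno$pop, IID = pheno$sample_id, score = pheno$score),
      paste0(prefix, ".pheno.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' Inverse of [write_plink()]: genotypes are returned as the dosage of the
#' bim A1 allele; the fam FID column is taken as the population label.
#'
#' @param prefix path prefix of the fileset.
#' @return a `genotype_panel`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "snp", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  ints <- as.integer(raw)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  genotype_panel(geno, bim$snp, bim$chrom, bim$bp,
                 a1 = bim$a2, a2 = bim$a1,
                 sample_id = fam[[2]], pop = fam[[1]])
}

#' Write an association table as GCTA-style TSV
#'
#' Columns SNP CHR BP A1 A2 FREQ B SE P N (mlma-compatible content).
#' @param assoc an `assoc_table`.
#' @param path output file.
#' @export
write_assoc <- function(assoc, path) {
  out <- data.frame(SNP = assoc$snp, CHR = assoc$chr, BP = assoc$bp,
                    A1 = assoc$a1, A2 = assoc$a2, FREQ = assoc$freq,
                    B = assoc$b, SE = assoc$se, P = assoc$p, N = assoc$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association TSV written by [write_assoc()]
#' @param path input file.
#' @return an `assoc_table`.
#' @export
read_assoc <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(snp = x$SNP, chr = x$CHR, bp = x$BP, a1 = x$A1,
                    a2 = x$A2, freq = x$FREQ, b = x$B, se = x$SE,
                    z = x$B / x$SE, p = x$P, n = x$N,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write a GRM as GCTA binary triple and TSV
#'
#' `<prefix>.grm.bin` (float lower triangle including diagonal, row-wise),
#' `<prefix>.grm.N.bin` (pair counts as float), `<prefix>.grm.id`
#' (FID = population optional, IID), plus `<prefix>.grm.tsv`.
#'
#' @param grm a `grm`.
#' @param prefix output prefix.
#' @param n_snps marker count stored in the N file.
#' @export
write_grm <- function(grm, prefix, n_snps = NA_integer_) {
  G <- grm$mat
  n <- nrow(G)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- G[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(vals)), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$sample_id, grm$sample_id),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- as.data.frame(G)
  names(tsv) <- grm$sample_id
  utils::write.table(cbind(id = grm$sample_id, tsv),
                     paste0(prefix, ".grm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
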