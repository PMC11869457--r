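#!/usr/bin/env Rscript
# Meta-analysis of the per-population summary statistics: Stouffer Z-score,
# inverse-variance-weighted and Han-Eskin random-effects estimators with
# Cochran's Q, I-squared and DerSimonian-Laird tau-squared. Compares each
# against the mega-analysis (individual-level pooling).

suppressMessages(library(salmeta))

pops <- sub("^assoc_", "", sub("\\.tsv$", "",
            grep("^assoc_pop", list.files("results"), value = TRUE)))
tabs <- lapply(pops, function(k) read_assoc(sprintf("results/assoc_%s.tsv", k)))
mega <- read_assoc("results/assoc_mega.tsv")

mt <- run_meta(tabs)
write.table(mt, "results/meta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

keep <- mt$n_studies >= 2
cat(sprintf("meta table: %d SNPs (%d in >= 2 populations)\n", nrow(mt), sum(keep)))
cat(sprintf("lambda  z-score: %.3f  IVW: %.3f  random (S_FE+S_Het): %.3f\n",
            genomic_lambda(chi2 = mt$z[keep]^2)$lambda,
            genomic_lambda(chi2 = mt$beta[keep]^2 / mt$se[keep]^2)$lambda,
            genomic_lambda(mode = "decomposed", s_fe = mt$s_fe[keep],
                           s_het = mt$s_het[keep])$lambda))
cat("I2 heterogeneity bands:\n")
print(table(mt$i2_band[keep]))

i <- match(mt$snp, mega$snp)
ok <- !is.na(i) & keep
cat(sprintf("Spearman correlation of -log10 p with the mega-analysis:\n"))
cat(sprintf("  z-score %.3f, IVW %.3f, random %.3f\n",
            cor(-log10(mega$p[i[ok]]), -log10(mt$p_z[ok]), method = "spearman"),
            cor(-log10(mega$p[i[ok]]), -log10(mt$p_ivw[ok]), method = "spearman"),
            cor(-log10(mega$p[i[ok]]), -log10(mt$p_rand[ok]), method = "spearman")))
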