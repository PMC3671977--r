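#!/usr/bin/env Rscript
# Stage 1: reconstruct the 35-protein seminal-plasma count matrix from the
# packaged classification constraints and reproduce the published category
# analysis (significant / low-abundant / common / unique / differentially
# expressed, plus the Venn partition of the DEP set over the NA, OA and ON
# comparisons). Outputs under results/categories/.

suppressPackageStartupMessages(library(specount))

outdir <- "results/categories"
rp <- reproduce_study(seed = 42L, target_library_size = 500L,
                      outdir = outdir)
s <- rp$summary

cat("== category analysis of the reconstructed 35-protein study ==\n")
print(s)
cat("\nThe reconstruction satisfies the packaged classification row-for-row;\n")
cat("documented constraint relaxations (printed annotations that the rule\n")
cat("set cannot produce):\n")
print(rp$relaxations, row.names = FALSE)

write.table(rp$agreement, file.path(outdir, "agreement.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
venn <- data.frame(cell = names(s$venn), proteins = as.integer(s$venn))
write.table(venn, file.path(outdir, "venn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nHeadline counts: total", s$n_total,
    "| low-abundant", s$n_low_abundant,
    "| significant", s$n_significant,
    "| common", s$n_common,
    "| unique", s$n_unique,
    "| DEP", s$n_dep, "\n")
cat("DEP in all three comparisons:", s$venn[["NA+OA+ON"]], "\n")
cat("wrote", outdir, "\n")
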