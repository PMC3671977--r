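#!/usr/bin/env Rscript
# Stage 3: operating characteristics of the NSC-ratio caller on simulated
# negative-binomial counts with planted fold effects (NN = 5 vs NA = 4
# replicates, baseline mean SC 50, dispersion 0.1). The sweep over effect
# prevalence shows the method's compositional limit: NSC normalization
# divides by the per-replicate total, so when a large share of the proteome
# moves in one direction the observed ratios compress toward the total-mass
# ratio and both recall and specificity collapse. At low prevalence --
# the regime the seminal-plasma study operates in, 20 of 35 proteins called
# but most with modest mass -- recovery is essentially perfect.
# Output: results/simulation/recovery.tsv.

suppressPackageStartupMessages(library(specount))

outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

design <- study_design(c(sprintf("n%d", 1:5), sprintf("a%d", 1:4)),
                       c(rep("NN", 5), rep("NA", 4)))
n_proteins <- 200L
rows <- NULL
for (prevalence in c(0.05, 0.10, 0.25, 0.50)) {
  n_planted <- as.integer(prevalence * n_proteins)
  pe <- data.frame(protein = seq_len(n_planted), group = "NA", fold = 4)
  p <- simulation_params(n_proteins, design, baseline_mean_sc = 50,
                         dispersion = 0.1, planted_effects = pe, seed = 1)
  s <- simulate_counts(p)
  rec <- evaluate_recovery(call_dep(quantify(s$matrix)$ratios), s$truth)
  rows <- rbind(rows, data.frame(prevalence = prevalence,
                                 planted = n_planted,
                                 recall = round(rec$recall, 3),
                                 fpr = round(rec$fpr, 3)))
}

cat("== recovery of planted 4-fold effects vs effect prevalence ==\n")
print(rows, row.names = FALSE)
cat("\nRatio compression at high prevalence is expected: with half the\n")
cat("proteome up 4-fold, the NA library grows 2.5x and every NSC ratio\n")
cat("shrinks by that factor (planted effects land near 1.6, nulls near\n")
cat("0.4), so threshold calling fails in both directions.\n")
write.table(rows, file.path(outdir, "recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(outdir, "recovery.tsv"), "\n")
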