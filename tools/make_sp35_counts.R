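# Regenerates inst/extdata/sp35_counts_synthetic.tsv + sp35_design.tsv:
# a deterministic reconstruction (seed 42, library size 500) of a count
# matrix consistent with the packaged 35-protein classification, written in
# the style of the per-replicate identification table -- isoform accessions
# that the unified catalog folds together are emitted as separate rows in
# the replicates where the identification table lists them.
# Run from the repository root: Rscript tools/make_sp35_counts.R
suppressMessages(devtools::load_all("."))

mat <- reconstruct_from_constraints(sp35_constraints(), seed = 42L,
                                    target_library_size = 500L)
counts <- mat$counts

# replicates in which the identification table reports the alias accession
# rather than the primary one
alias_cols <- list(
  "71834855" = list(primary = "4502173",  reps = c("NN1", "OA2")),
  "89033736" = list(primary = "151301154",
                    reps = c("NA1", "NA2", "NA3", "NA4", "OA1", "OA2")),
  "4758236"  = list(primary = "221316614",
                    reps = c("NN5", "NA2", "NA4", "OA1", "OA2")),
  "16933542" = list(primary = "47132551",
                    reps = c("NN2", "NN3", "NN4", "NA1", "NA2", "ON1")))

out <- counts
for (a in names(alias_cols)) {
  info <- alias_cols[[a]]
  row <- integer(ncol(out))
  names(row) <- colnames(out)
  row[info$reps] <- out[info$primary, info$reps]
  out[info$primary, info$reps] <- 0L
  out <- rbind(out, matrix(row, 1, dimnames = list(a, names(row))))
}

hdr <- c(
  "# SYNTHETIC spectral-count matrix for the 35-protein seminal-plasma",
  "# catalog: a deterministic constraint-guided reconstruction (seed 42,",
  "# library size 500) consistent with the packaged classification table.",
  "# The study's raw counts are unpublished; this matrix reproduces their",
  "# printed categorization, not their values. Isoform accessions appear",
  "# as separate rows in the replicates where the identification table",
  "# lists them; resolve_aliases() folds them into the 35-row catalog.")
dest <- "inst/extdata/sp35_counts_synthetic.tsv"
writeLines(hdr, dest)
df <- data.frame(accession = rownames(out), out, check.names = FALSE)
suppressWarnings(write.table(df, dest, sep = "\t", quote = FALSE,
                             row.names = FALSE, col.names = TRUE,
                             append = TRUE))
writeLines(c("replicate_id\tgroup",
             paste(mat$design$replicate_id, mat$design$group, sep = "\t")),
           "inst/extdata/sp35_design.tsv")
cat("wrote", dest, "and inst/extdata/sp35_design.tsv\n")
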