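#!/usr/bin/env Rscript
# Stage 2: functional-distribution profiling of the category protein sets
# using the packaged (synthetic, reconstructed) slim annotation. For each of
# the common / DEP / globally-low-abundant sets and each per-group
# significant set, the percentage of member proteins carrying each
# cellular-component and biological-process term. Outputs under
# results/profiles/.

suppressPackageStartupMessages(library(specount))

outdir <- "results/profiles"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rp <- reproduce_study(seed = 42L)
cls <- rp$pipeline$classification
calls <- rp$pipeline$calls
ann <- sp35_annotations()

selectors <- c("common", "dep", "low_abundant",
               "significant:NN", "significant:NA",
               "significant:OA", "significant:ON")

for (aspect in c("cellular_component", "biological_process")) {
  profs <- lapply(selectors, function(sel)
    profile_set(select_set(cls, calls, sel), ann, aspect, set_name = sel))
  tab <- compare_profiles(profs)
  out <- data.frame(term = rownames(tab), round(tab, 1),
                    check.names = FALSE)
  write.table(out, file.path(outdir, paste0(aspect, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", aspect, "(% of set annotated with term) ==\n")
  print(out, row.names = FALSE)
}

common_cc <- profile_set(select_set(cls, calls, "common"), ann,
                         "cellular_component", "common")
cat(sprintf("\nExtracellular share of the %d ubiquitous proteins: %.1f%%\n",
            common_cc$set_size,
            common_cc$percent_of[["extracellular region"]]))
cat("wrote", outdir, "\n")
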