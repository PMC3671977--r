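# Packaged reference: the published classification of 35 seminal-plasma
# proteins across four semen-parameter groups (NN normal count/normal
# morphology, NA normal/abnormal, ON oligozoospermic/normal, OA
# oligozoospermic/abnormal; 5/4/2/1 pooled replicates).

sp35_path <- function(file) {
  p <- system.file("extdata", file, package = "specount")
  if (!nzchar(p)) {
    # during in-source development (pkgload) inst/ is on the search path root
    p <- system.file("inst", "extdata", file, package = "specount")
  }
  if (!nzchar(p)) stop("packaged file not found: ", file, call. = FALSE)
  p
}

#' The four-group seminal-plasma study design
#'
#' Five NN replicates, four NA, two OA, one ON; baseline NN.
#'
#' @return A [study_design()].
#' @export
sp35_design <- function() {
  study_design(
    replicate_ids = c(paste0("NN", 1:5), paste0("NA", 1:4),
                      paste0("OA", 1:2), "ON1"),
    groups = c(rep("NN", 5), rep("NA", 4), rep("OA", 2), "ON"),
    baseline = "NN",
    group_levels = c("NN", "NA", "OA", "ON"))
}

#' The 35-protein reference catalog
#'
#' Protein records (accession, UniProt id, name, molecular weight, pI) with
#' the alias sets that fold the per-replicate identification table's isoform
#' accessions into the unified 35-row catalog.
#'
#' @return A [protein_catalog()] of 35 records.
#' @export
sp35_catalog <- function() {
  read_catalog(sp35_path("sp35_catalog.tsv"))
}

#' The published 35-protein classification as a constraint table
#'
#' Per-protein presence tallies, per-group abundance classes, and expected
#' differential-expression calls, transcribed from the published
#' classification table. Two cells are deliberately relaxed because the
#' printed annotation is unsatisfiable under the study's own rules (the
#' `relaxation` column documents them): the ankyrin repeat domain 11 row is
#' absent from the baseline so its printed down-calls cannot arise from any
#' ratio (its calls are kept with unconstrained direction), and the serine
#' proteinase inhibitor row's printed OA significance is incompatible with
#' its down-in-OA call given its non-significant baseline (its OA class is
#' encoded as low).
#'
#' @return A `constraint_set` (see [constraint_set()]) for [sp35_design()],
#'   with the raw transcription available as `attr(x, "table")` and the
#'   relaxed cells as `attr(x, "relaxations")`.
#' @export
sp35_constraints <- function() {
  df <- read_tsv_strict(sp35_path("sp35_classification.tsv"),
                        "classification table")
  for (col in c("relaxation", "note", "printed_dep", "printed_sig"))
    df[[col]][is.na(df[[col]])] <- ""
  for (col in grep("^present_|^global_low$", names(df), value = TRUE))
    df[[col]] <- as.integer(df[[col]])
  cs <- constraint_set(df, sp35_design())
  relax <- df[nzchar(df$relaxation), c("accession", "name", "relaxation")]
  attr(cs, "relaxations") <- relax
  attr(cs, "table") <- df
  cs
}

#' Synthetic slim functional annotations for the 35-protein catalog
#'
#' A reconstructed (non-authoritative) multi-label annotation of the catalog
#' with high-level cellular-component and biological-process terms, packaged
#' for exercising the profiling operations.
#'
#' @return An [load_annotations()] table.
#' @export
sp35_annotations <- function() {
  load_annotations(sp35_path("sp35_goslim_synthetic.tsv"))
}

#' Paths to the packaged synthetic count matrix and its design
#'
#' A deterministic constraint-guided reconstruction (seed 42, library size
#' 500) of a count matrix consistent with the packaged classification,
#' written in the per-replicate identification table's style: isoform
#' accessions appear as separate rows in the replicates where that table
#' lists them, so [resolve_aliases()] is needed to reach the unified
#' 35-row catalog. Synthetic data -- the study's raw counts are unpublished.
#'
#' @return Named character vector with elements `counts` and `design`.
#' @export
sp35_counts_paths <- function() {
  c(counts = sp35_path("sp35_counts_synthetic.tsv"),
    design = sp35_path("sp35_design.tsv"))
}

#' Load the full packaged reference fixture
#'
#' @return List with elements `design`, `catalog`, `constraints` (the
#'   expected classification as a constraint set), `annotations`, and
#'   `expected` (the raw transcription table).
#' @export
sp35_fixture <- function() {
  cons <- sp35_constraints()
  list(design = sp35_design(),
       catalog = sp35_catalog(),
       constraints = cons,
       annotations = sp35_annotations(),
       expected = attr(cons, "table"))
}
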