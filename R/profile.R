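#' Load a slim functional-annotation table
#'
#' Reads a TSV with columns `accession`, `aspect`
#' (`cellular_component` or `biological_process`) and `term`, aggregating
#' rows into per-protein term sets (duplicates collapse; a protein may carry
#' zero terms). Terms are opaque slim labels -- no ontology traversal is
#' performed, the table is expected to be pre-slimmed.
#'
#' @param path Path to the annotation TSV.
#' @return List of class `annotation_table` with elements
#'   `cellular_component` and `biological_process`, each a named list of
#'   character term vectors keyed by accession.
#' @export
load_annotations <- function(path) {
  df <- read_tsv_strict(path, "annotation table")
  need <- c("accession", "aspect", "term")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns accession, aspect, term",
         call. = FALSE)
  aspects <- c("cellular_component", "biological_process")
  bad <- setdiff(unique(df$aspect), aspects)
  if (length(bad))
    stop("unknown aspect label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$term)))
    stop("empty term string in annotation table", call. = FALSE)
  out <- lapply(aspects, function(a) {
    sub <- df[df$aspect == a, , drop = FALSE]
    lapply(split(sub$term, sub$accession), unique)
  })
  names(out) <- aspects
  class(out) <- "annotation_table"
  out
}

#' Functional-distribution profile of a protein set
#'
#' For one protein set and one ontology aspect, the percentage of set
#' members annotated with each term. The percentage base is the full set
#' size (unannotated members dilute every term), and because annotations are
#' multi-label the percentages need not sum to 100. Terms carried by no
#' member are omitted.
#'
#' @param set Character vector of accessions (non-empty).
#' @param annotations An [load_annotations()] table.
#' @param aspect `"cellular_component"` or `"biological_process"`.
#' @param set_name Label attached to the profile.
#' @return List of class `distribution_profile`: `set_name`, `aspect`,
#'   `set_size`, and named numeric vector `percent_of` (term percentages in
#'   decreasing order).
#' @export
profile_set <- function(set, annotations, aspect, set_name = "set") {
  if (!length(set)) stop("cannot profile an empty protein set", call. = FALSE)
  if (!aspect %in% names(annotations))
    stop("unknown aspect: ", aspect, call. = FALSE)
  set <- unique(set)
  terms <- annotations[[aspect]][set]
  counts <- table(unlist(terms, use.names = FALSE))
  pct <- 100 * as.numeric(counts) / length(set)
  names(pct) <- names(counts)
  pct <- sort(pct, decreasing = TRUE)
  structure(list(set_name = set_name, aspect = aspect,
                 set_size = length(set), percent_of = pct),
            class = "distribution_profile")
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat("distribution_profile '", x$set_name, "' (", x$aspect, "), n = ",
      x$set_size, "\n", sep = "")
  for (t in names(x$percent_of))
    cat(sprintf("  %-40s %5.1f%%\n", t, x$percent_of[t]))
  invisible(x)
}

#' Side-by-side comparison of distribution profiles
#'
#' Column-wise concatenation of profiles sharing one aspect into a
#' term x set percentage matrix, zero-filled where a term is absent from a
#' set and ranked by the maximum percentage across sets.
#'
#' @param profiles List of [profile_set()] outputs with a common aspect.
#' @return Numeric matrix, terms in rows, set names in columns.
#' @export
compare_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to compare", call. = FALSE)
  aspects <- unique(vapply(profiles, `[[`, "", "aspect"))
  if (length(aspects) != 1)
    stop("profiles mix aspects: ", paste(aspects, collapse = ", "),
         call. = FALSE)
  terms <- unique(unlist(lapply(profiles, function(p) names(p$percent_of))))
  out <- matrix(0, length(terms), length(profiles),
                dimnames = list(terms,
                                vapply(profiles, `[[`, "", "set_name")))
  for (p in profiles) out[names(p$percent_of), p$set_name] <- p$percent_of
  if (nrow(out) > 1)
    out <- out[order(apply(out, 1, max), decreasing = TRUE), , drop = FALSE]
  out
}
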