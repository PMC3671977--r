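#' Study design: replicates mapped to sample groups
#'
#' A study design maps each LC-MS/MS replicate to one sample group and names
#' the baseline group against which differential-expression ratios are taken.
#'
#' @param replicate_ids Character vector of unique replicate identifiers, in
#'   column order of the count matrix.
#' @param groups Character vector (same length) assigning each replicate to a
#'   group label.
#' @param baseline Group label used as the denominator of NSC ratios.
#'   Must occur in `groups`.
#' @param group_levels Optional character vector restricting the admissible
#'   group labels; defaults to the labels present in `groups`.
#' @return An object of class `study_design`: a data frame with columns
#'   `replicate_id` and `group`, plus attributes `baseline` and `groups`
#'   (the group levels).
#' @examples
#' study_design(c("NN1", "NN2", "NA1"), c("NN", "NN", "NA"), baseline = "NN")
#' @export
study_design <- function(replicate_ids, groups, baseline = "NN",
                         group_levels = NULL) {
  replicate_ids <- as.character(replicate_ids)
  groups <- as.character(groups)
  if (length(replicate_ids) != length(groups))
    stop("replicate_ids and groups must have the same length", call. = FALSE)
  if (anyDuplicated(replicate_ids))
    stop("duplicate replicate ids: ",
         paste(unique(replicate_ids[duplicated(replicate_ids)]),
               collapse = ", "), call. = FALSE)
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every replicate must map to a non-empty group label", call. = FALSE)
  if (is.null(group_levels)) group_levels <- unique(groups)
  bad <- setdiff(groups, group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (!baseline %in% groups)
    stop("baseline group '", baseline, "' has no replicates", call. = FALSE)
  out <- data.frame(replicate_id = replicate_ids, group = groups,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "groups") <- group_levels
  class(out) <- c("study_design", "data.frame")
  out
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(factor(x$group, levels = attr(x, "groups")))
  cat("study_design: ", nrow(x), " replicates; baseline ",
      attr(x, "baseline"), "\n", sep = "")
  cat(paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

design_baseline <- function(design) attr(design, "baseline")

design_groups <- function(design) attr(design, "groups")

#' Replicates belonging to one group
#' @param design A `study_design`.
#' @param group A group label.
#' @return Character vector of replicate ids.
#' @keywords internal
group_replicates <- function(design, group) {
  design$replicate_id[design$group == group]
}

#' Spectral-count matrix with its study design
#'
#' Bundles a non-negative integer matrix of spectral counts (proteins in rows,
#' replicates in columns) with the [study_design()] describing its columns.
#'
#' @param counts Integer matrix, proteins x replicates, with rownames
#'   (protein accessions) and colnames (replicate ids).
#' @param design A [study_design()] covering exactly the matrix columns.
#' @return An object of class `sc_matrix`: a list with elements `counts` and
#'   `design`.
#' @examples
#' d <- study_design(c("r1", "r2"), c("NN", "NA"))
#' m <- matrix(c(3L, 0L, 1L, 5L), 2, dimnames = list(c("P1", "P2"), c("r1", "r2")))
#' sc_matrix(m, d)
#' @export
sc_matrix <- function(counts, design) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("count matrix needs protein accessions as rownames", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("count matrix needs replicate ids as colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate protein accession(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  storage <- counts
  if (!is.numeric(storage))
    stop("counts must be numeric integers", call. = FALSE)
  if (anyNA(storage) || any(storage < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(storage != round(storage)))
    stop("counts must be integers", call. = FALSE)
  mode(storage) <- "integer"
  if (!setequal(colnames(storage), design$replicate_id))
    stop("matrix columns and design replicates disagree: matrix has [",
         paste(setdiff(colnames(storage), design$replicate_id), collapse = ","),
         "] not in design; design has [",
         paste(setdiff(design$replicate_id, colnames(storage)), collapse = ","),
         "] not in matrix", call. = FALSE)
  storage <- storage[, design$replicate_id, drop = FALSE]
  out <- list(counts = storage, design = design)
  class(out) <- "sc_matrix"
  out
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat("sc_matrix: ", nrow(x$counts), " proteins x ", ncol(x$counts),
      " replicates\n", sep = "")
  print(x$design)
  invisible(x)
}

#' @export
dim.sc_matrix <- function(x) dim(x$counts)

#' Protein catalog with alias sets
#'
#' Validates a catalog of protein records. The accession (a database index
#' string) is the primary key; `aliases` lists alternate accessions whose
#' count-matrix rows should be folded into the primary record (database
#' entries for isoforms of the same gene product reported under separate
#' indices).
#'
#' @param df Data frame with columns `accession`, `uniprot`, `name`,
#'   `mw_kda`, `pi`, `aliases` (comma-joined string, possibly empty).
#' @return The validated data frame with class `protein_catalog`.
#' @export
protein_catalog <- function(df) {
  need <- c("accession", "uniprot", "name", "mw_kda", "pi", "aliases")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$accession <- as.character(df$accession)
  df$aliases <- ifelse(is.na(df$aliases), "", as.character(df$aliases))
  if (anyDuplicated(df$accession))
    stop("duplicate catalog accession(s)", call. = FALSE)
  ali <- alias_map(df)
  if (anyDuplicated(names(ali)))
    stop("alias accession mapped to more than one primary record",
         call. = FALSE)
  overlap <- intersect(names(ali), df$accession)
  if (length(overlap))
    stop("accession(s) appear both as primary and as alias: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  if (any(!is.na(df$mw_kda) & df$mw_kda <= 0))
    stop("mw_kda must be positive", call. = FALSE)
  if (any(!is.na(df$pi) & (df$pi <= 0 | df$pi >= 14)))
    stop("pI must lie in (0, 14)", call. = FALSE)
  class(df) <- c("protein_catalog", "data.frame")
  df
}

# named vector alias -> primary accession
alias_map <- function(catalog) {
  lists <- strsplit(catalog$aliases, ",", fixed = TRUE)
  lists <- lapply(lists, function(a) trimws(a[nzchar(trimws(a))]))
  n <- lengths(lists)
  stats::setNames(rep(catalog$accession, n), unlist(lists))
}
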