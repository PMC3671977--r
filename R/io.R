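# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines
# ignored, no quoting. Chosen so write -> read round trips are bit-exact.

read_tsv_strict <- function(path, what = "table") {
  if (!file.exists(path))
    stop("cannot read ", what, ": no such file '", path, "'", call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = character(0)),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  df
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a spectral-count matrix and its study design
#'
#' Reads a tab-separated count table (first column `accession`, remaining
#' columns one per replicate, integer cells; missing cells are not allowed --
#' a protein not identified in a replicate carries an explicit 0) together
#' with a design table (columns `replicate_id`, `group`).
#'
#' @param path Path to the counts TSV.
#' @param design_path Path to the design TSV.
#' @param baseline Baseline group label (default `"NN"`).
#' @param group_levels Optional admissible group labels; unknown labels in the
#'   design are rejected.
#' @return An [sc_matrix()].
#' @export
read_count_matrix <- function(path, design_path, baseline = "NN",
                              group_levels = NULL) {
  dsn <- read_tsv_strict(design_path, "design")
  if (!all(c("replicate_id", "group") %in% names(dsn)))
    stop("design TSV must have columns replicate_id and group", call. = FALSE)
  design <- study_design(dsn$replicate_id, dsn$group, baseline = baseline,
                         group_levels = group_levels)

  tab <- read_tsv_strict(path, "count matrix")
  if (ncol(tab) < 1 || names(tab)[1] != "accession")
    stop("count TSV must have 'accession' as its first column", call. = FALSE)
  acc <- tab$accession
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in count matrix: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  reps <- names(tab)[-1]
  missing_from_design <- setdiff(reps, design$replicate_id)
  if (length(missing_from_design))
    stop("replicate(s) in matrix missing from design: ",
         paste(missing_from_design, collapse = ", "), call. = FALSE)
  cells <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(acc, reps)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric count at data line ", bad[1], " (protein ",
         acc[bad[1]], ", replicate ", reps[bad[2]], ")", call. = FALSE)
  }
  if (any(num < 0) || any(num != round(num))) {
    bad <- which(num < 0 | num != round(num), arr.ind = TRUE)[1, ]
    stop("count must be a non-negative integer at protein ", acc[bad[1]],
         ", replicate ", reps[bad[2]], " (value ", num[bad[1], bad[2]], ")",
         call. = FALSE)
  }
  sc_matrix(num, design)
}

#' Write a spectral-count matrix (and optionally its design) to TSV
#'
#' @param mat An [sc_matrix()].
#' @param path Output path for the counts TSV.
#' @param design_path Optional output path for the design TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path, design_path = NULL) {
  df <- data.frame(accession = rownames(mat$counts),
                   mat$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  if (!is.null(design_path))
    write_tsv_strict(data.frame(replicate_id = mat$design$replicate_id,
                                group = mat$design$group,
                                stringsAsFactors = FALSE), design_path)
  invisible(path)
}

#' Read a protein catalog TSV
#'
#' Columns: `accession`, `uniprot`, `name`, `mw_kda`, `pi`, `aliases`
#' (comma-joined alternate accessions, possibly empty).
#'
#' @param path Path to the catalog TSV.
#' @return A [protein_catalog()].
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, "catalog")
  df$mw_kda <- as.numeric(df$mw_kda)
  df$pi <- as.numeric(df$pi)
  protein_catalog(df)
}

#' Fold aliased count-matrix rows into their primary records
#'
#' Rows whose accession appears in a catalog record's alias set are summed
#' into the primary accession's row. Accessions absent from the catalog
#' (neither primary nor alias) are kept verbatim with a warning. Total
#' spectral count per replicate is conserved.
#'
#' @param mat An [sc_matrix()].
#' @param catalog A [protein_catalog()].
#' @return An [sc_matrix()] with one row per primary (or unmapped) accession.
#' @export
resolve_aliases <- function(mat, catalog) {
  ali <- alias_map(catalog)
  acc <- rownames(mat$counts)
  unknown <- setdiff(acc, c(catalog$accession, names(ali)))
  if (length(unknown))
    warning("accession(s) not in catalog kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  primary <- ifelse(acc %in% names(ali), ali[acc], acc)
  # order: first appearance of each primary accession
  keep <- unique(primary)
  merged <- rowsum(mat$counts, group = primary, reorder = FALSE)
  merged <- merged[keep, , drop = FALSE]
  mode(merged) <- "integer"
  sc_matrix(merged, mat$design)
}
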