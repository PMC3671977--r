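#' Classification rule configuration
#'
#' Thresholds behind the abundance/presence/differential-expression rules:
#' a protein is *significant* in a group when its SC reaches `sc_threshold`
#' in at least one of the group's replicates and it is detected in at least
#' half of them (quota `max(1, floor(presence_fraction * n))`; the published
#' classification treats 2 of 5 replicates as meeting "at least 50%", so the
#' quota rounds down); *low-abundant* in a group when detected but never
#' above `sc_threshold` there (and not significant); *globally low-abundant*
#' when that holds across all replicates and it is significant nowhere. A
#' protein is *over-expressed* in a comparison when its NSC ratio exceeds
#' `over_threshold`, *under-expressed* below `under_threshold` (strict
#' inequalities; the default pair 2 and 0.5 is reciprocal).
#'
#' @param sc_threshold Spectral-count cutoff for significance/low abundance
#'   (default 10).
#' @param presence_fraction Fraction of a group's replicates in which a
#'   significant protein must be detected (default 0.5).
#' @param over_threshold NSC ratio above which a protein is called
#'   over-expressed (default 2).
#' @param under_threshold NSC ratio below which a protein is called
#'   under-expressed (default 0.5).
#' @param detection_floor Minimum SC for "present" (default 1).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(sc_threshold = 10L, presence_fraction = 0.5,
                        over_threshold = 2, under_threshold = 0.5,
                        detection_floor = 1L) {
  if (sc_threshold < 1) stop("sc_threshold must be >= 1", call. = FALSE)
  if (presence_fraction <= 0 || presence_fraction > 1)
    stop("presence_fraction must lie in (0, 1]", call. = FALSE)
  if (!(under_threshold < 1 && 1 < over_threshold))
    stop("need under_threshold < 1 < over_threshold", call. = FALSE)
  out <- list(sc_threshold = as.integer(sc_threshold),
              presence_fraction = presence_fraction,
              over_threshold = over_threshold,
              under_threshold = under_threshold,
              detection_floor = as.integer(detection_floor))
  class(out) <- "rule_config"
  out
}

#' Replicate quota implied by the presence fraction
#' @param n Number of replicates in the group.
#' @param fraction Presence fraction from the rule config.
#' @return Integer quota, at least 1.
#' @export
presence_quota <- function(n, fraction = 0.5) {
  q <- pmax(1L, as.integer(floor(fraction * n)))
  names(q) <- names(n)
  q
}

#' Abundance and presence classification
#'
#' Applies the significance / low-abundance rules per group and globally (see
#' [rule_config()]). At the SC boundary value significance dominates: a
#' protein reaching exactly `sc_threshold` with the presence quota met is
#' significant, not low-abundant, keeping the global classes disjoint.
#'
#' @param mat An [sc_matrix()].
#' @param config A [rule_config()].
#' @return List of class `abundance_classification`: matrices
#'   `present_in` (integer replicate tallies, proteins x groups), `max_sc`,
#'   logical matrices `significant_in` and `low_in`, logical vectors
#'   `detected_any`, `global_low`, and the `config`/`design` used.
#' @export
classify_abundance <- function(mat, config = rule_config()) {
  stopifnot(inherits(mat, "sc_matrix"))
  groups <- design_groups(mat$design)
  counts <- mat$counts
  acc <- rownames(counts)
  present <- matrix(0L, nrow(counts), length(groups),
                    dimnames = list(acc, groups))
  maxsc <- present
  for (g in groups) {
    reps <- group_replicates(mat$design, g)
    sub <- counts[, reps, drop = FALSE]
    present[, g] <- as.integer(rowSums(sub >= config$detection_floor))
    maxsc[, g] <- if (ncol(sub)) apply(sub, 1, max) else 0L
  }
  n_rep <- stats::setNames(
    vapply(groups, function(g) length(group_replicates(mat$design, g)), 0L),
    groups)
  quota <- presence_quota(n_rep, config$presence_fraction)
  sig <- (maxsc >= config$sc_threshold) & sweep(present, 2, quota, ">=")
  low <- (present >= 1L) & (maxsc <= config$sc_threshold) & !sig
  detected_any <- rowSums(present) > 0
  global_low <- detected_any &
    apply(maxsc, 1, max) <= config$sc_threshold &
    rowSums(sig) == 0
  structure(list(present_in = present, max_sc = maxsc,
                 significant_in = sig, low_in = low,
                 detected_any = detected_any, global_low = global_low,
                 n_replicates = n_rep, config = config,
                 design = mat$design),
            class = "abundance_classification")
}

#' Differential-expression calls from an NSC ratio table
#'
#' Strict-threshold fold-ratio calling against the baseline group: ratio
#' above `over_threshold` is an up call, below `under_threshold` a down call,
#' anything else (including the boundary values exactly) no call. No call is
#' made when the protein is undetected in the test group (nothing to
#' quantify there) or when the ratio is undefined (undetected on both
#' sides); a protein undetected only in the baseline is callable through the
#' epsilon floor and flagged presence-discordant.
#'
#' @param ratios Ratio table from [nsc_ratio()].
#' @param config A [rule_config()].
#' @return Data frame with one row per (protein, comparison): columns
#'   `accession`, `comparison`, `ratio`, `direction` (`"up"`, `"down"`,
#'   `"none"`), `presence_discordant`.
#' @export
call_dep <- function(ratios, config = rule_config()) {
  if (anyDuplicated(ratios[c("accession", "comparison")]))
    stop("ratio table has duplicate (protein, comparison) rows",
         call. = FALSE)
  dir <- rep("none", nrow(ratios))
  quantifiable <- !ratios$test_zero & !is.na(ratios$ratio)
  # strict thresholds with a 1e-9 relative guard band: a ratio that equals
  # the cutoff up to floating-point rounding of the NSC means is not a call
  tol <- 1e-9
  dir[quantifiable & ratios$ratio > config$over_threshold * (1 + tol)] <- "up"
  dir[quantifiable & ratios$ratio < config$under_threshold * (1 - tol)] <- "down"
  data.frame(accession = ratios$accession,
             comparison = ratios$comparison,
             ratio = ratios$ratio,
             direction = dir,
             presence_discordant = ratios$test_zero | ratios$baseline_zero,
             stringsAsFactors = FALSE)
}

dep_calls_only <- function(calls) calls[calls$direction != "none", ,
                                        drop = FALSE]

#' Category flags and summary over a classified study
#'
#' Combines the abundance classification and DEP calls into the per-protein
#' category flags (common, unique, low-abundant, significant, differentially
#' expressed -- non-exclusive) and the study-level category summary,
#' including the Venn partition of DEP proteins over the test-group
#' comparisons.
#'
#' @param mat The [sc_matrix()] the inputs were computed from.
#' @param classification Output of [classify_abundance()].
#' @param calls Output of [call_dep()].
#' @return List of class `category_summary`: data frame `proteins` (one row
#'   per protein with flags), and counts `n_total`, `n_low_abundant`,
#'   `n_significant`, `n_significant_by_group`, `n_common`, `n_unique`,
#'   `n_dep`, `venn`.
#' @export
categorize <- function(mat, classification, calls) {
  acc <- rownames(mat$counts)
  if (!identical(sort(acc), sort(rownames(classification$present_in))) ||
      !all(calls$accession %in% acc))
    stop("protein sets of matrix, classification and calls disagree",
         call. = FALSE)
  cfg <- classification$config
  common <- rowSums(mat$counts >= cfg$detection_floor) == ncol(mat$counts)
  absent_groups <- classification$present_in == 0L
  uniq <- classification$detected_any & rowSums(absent_groups) > 0
  actual <- dep_calls_only(calls)
  dep_flag <- acc %in% actual$accession
  sig_any <- rowSums(classification$significant_in) > 0

  venn <- venn_partition(calls,
                         comparisons = unique(calls$comparison))
  proteins <- data.frame(
    accession = acc,
    significant_groups = apply(classification$significant_in, 1, function(z)
      paste(colnames(classification$significant_in)[z], collapse = ",")),
    low_groups = apply(classification$low_in, 1, function(z)
      paste(colnames(classification$low_in)[z], collapse = ",")),
    global_low = unname(classification$global_low),
    common = unname(common),
    unique = unname(uniq),
    dep = unname(dep_flag),
    dep_calls = vapply(acc, function(a) {
      rows <- actual[actual$accession == a, , drop = FALSE]
      paste(sprintf("%s:%s", rows$direction, rows$comparison), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    proteins = proteins,
    n_total = length(acc),
    n_low_abundant = sum(classification$global_low),
    n_significant = sum(sig_any),
    n_significant_by_group = colSums(classification$significant_in),
    n_common = sum(common),
    n_unique = sum(uniq),
    n_dep = sum(dep_flag),
    venn = venn), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("category_summary over", x$n_total, "proteins\n")
  cat("  significant (>=1 group):", x$n_significant,
      " | globally low-abundant:", x$n_low_abundant, "\n")
  cat("  common:", x$n_common, " | unique:", x$n_unique,
      " | differentially expressed:", x$n_dep, "\n")
  cat("  venn:", paste(sprintf("%s=%d", names(x$venn), x$venn),
                       collapse = " "), "\n")
  invisible(x)
}

#' Venn partition of DEP proteins over comparisons
#'
#' Assigns each differentially expressed protein to the subset of
#' comparisons in which it carries an up or down call; cell counts sum to
#' the number of DEP proteins.
#'
#' @param calls Output of [call_dep()].
#' @param comparisons Comparison labels defining the universe (order fixes
#'   the cell naming); defaults to those present in `calls`.
#' @return Named integer vector over the non-empty subsets (names like
#'   `"NA"`, `"NA+ON"`, `"NA+ON+OA"`).
#' @export
venn_partition <- function(calls, comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- unique(calls$comparison)
  if (anyDuplicated(calls[c("accession", "comparison")]))
    stop("calls must be deduplicated per (protein, comparison)",
         call. = FALSE)
  subsets <- unlist(lapply(seq_along(comparisons), function(k)
    utils::combn(comparisons, k, paste, collapse = "+", simplify = FALSE)))
  cells <- stats::setNames(integer(length(subsets)), subsets)
  actual <- dep_calls_only(calls)
  if (nrow(actual)) {
    per_prot <- split(actual$comparison, actual$accession)
    keys <- vapply(per_prot, function(cs)
      paste(comparisons[comparisons %in% cs], collapse = "+"), "")
    tab <- table(keys)
    cells[names(tab)] <- as.integer(tab)
  }
  cells
}

#' Select a protein set by category
#'
#' Deterministic, order-stable selection feeding the functional-profiling
#' step. Selectors: `"common"`, `"unique"`, `"low_abundant"` (global),
#' `"dep"`, `"significant:<group>"`, `"dep:<group>:<direction>"` (proteins
#' with that call, possibly among others), and
#' `"dep_only:<group>:<direction>"` (proteins whose *only* call is that
#' one).
#'
#' @param classification Output of [classify_abundance()].
#' @param calls Output of [call_dep()].
#' @param selector Selector string.
#' @return Character vector of accessions in matrix row order.
#' @export
select_set <- function(classification, calls, selector) {
  acc <- rownames(classification$present_in)
  actual <- dep_calls_only(calls)
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  kind <- parts[1]

  if (kind == "common" && length(parts) == 1) {
    # common = detected in every replicate of every group
    full <- sweep(classification$present_in, 2,
                  classification$n_replicates, "==")
    return(acc[rowSums(full) == ncol(full)])
  }
  if (kind == "unique" && length(parts) == 1)
    return(acc[classification$detected_any &
                 rowSums(classification$present_in == 0L) > 0])
  if (kind == "low_abundant" && length(parts) == 1)
    return(acc[classification$global_low])
  if (kind == "dep" && length(parts) == 1)
    return(acc[acc %in% actual$accession])
  if (kind == "significant" && length(parts) == 2) {
    g <- parts[2]
    if (!g %in% colnames(classification$significant_in))
      stop("unknown group in selector: ", selector, call. = FALSE)
    return(acc[classification$significant_in[, g]])
  }
  if (kind %in% c("dep", "dep_only") && length(parts) == 3) {
    g <- parts[2]; dirn <- parts[3]
    if (!dirn %in% c("up", "down"))
      stop("malformed selector: ", selector, call. = FALSE)
    if (!g %in% unique(calls$comparison))
      stop("unknown comparison in selector: ", selector, call. = FALSE)
    hit <- unique(actual$accession[actual$comparison == g &
                                     actual$direction == dirn])
    if (kind == "dep_only") {
      n_calls <- table(actual$accession)
      hit <- hit[n_calls[hit] == 1]
    }
    return(acc[acc %in% hit])
  }
  stop("unknown selector: ", selector, call. = FALSE)
}
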