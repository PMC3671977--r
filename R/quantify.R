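#' Normalized spectral counts
#'
#' Divides each protein's spectral count by the total spectral count of its
#' replicate, so that every replicate column sums to 1. This is the
#' within-sample depth normalization for label-free spectral counting: a
#' protein's NSC is its share of all spectra identified in that run.
#'
#' @param mat An [sc_matrix()].
#' @return Numeric matrix of the same shape as `mat$counts`, values in
#'   `[0, 1]`, with attribute `totals` (the per-replicate library sizes).
#' @examples
#' d <- study_design(c("r1", "r2"), c("NN", "NA"))
#' m <- sc_matrix(matrix(c(3L, 1L, 2L, 2L), 2,
#'                dimnames = list(c("A", "B"), c("r1", "r2"))), d)
#' compute_nsc(m)
#' @export
compute_nsc <- function(mat) {
  stopifnot(inherits(mat, "sc_matrix"))
  totals <- colSums(mat$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("replicate(s) with zero total spectral count: ",
         paste(zero, collapse = ", "), call. = FALSE)
  nsc <- sweep(mat$counts, 2, totals, "/")
  attr(nsc, "totals") <- totals
  nsc
}

#' Group-level NSC summaries
#'
#' For each protein and group, the arithmetic mean of the group's replicate
#' NSC values (zeros included, so each replicate carries equal weight
#' regardless of its depth) and the fraction of the group's replicates in
#' which the protein was detected (SC at or above `detection_floor`).
#'
#' @param nsc NSC matrix from [compute_nsc()].
#' @param design The [study_design()] of the underlying matrix.
#' @param counts Optional raw count matrix used for detection; defaults to
#'   detection wherever `nsc > 0`.
#' @param detection_floor Minimum SC for a protein to count as detected
#'   (default 1).
#' @return List with matrices `mean_nsc` and `detected_fraction`
#'   (proteins x groups), integer matrix `detected` (replicate tallies), and
#'   named vector `n_replicates`.
#' @export
summarize_groups <- function(nsc, design, counts = NULL, detection_floor = 1L) {
  groups <- design_groups(design)
  det_src <- if (is.null(counts)) (nsc > 0) else (counts >= detection_floor)
  mean_nsc <- matrix(0, nrow(nsc), length(groups),
                     dimnames = list(rownames(nsc), groups))
  detf <- mean_nsc
  det <- matrix(0L, nrow(nsc), length(groups),
                dimnames = list(rownames(nsc), groups))
  n_rep <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    reps <- group_replicates(design, g)
    if (!length(reps))
      stop("group '", g, "' has zero replicates", call. = FALSE)
    n_rep[g] <- length(reps)
    mean_nsc[, g] <- rowMeans(nsc[, reps, drop = FALSE])
    det[, g] <- as.integer(rowSums(det_src[, reps, drop = FALSE]))
    detf[, g] <- det[, g] / length(reps)
  }
  list(mean_nsc = mean_nsc, detected_fraction = detf, detected = det,
       n_replicates = n_rep)
}

#' Resolve the epsilon used for one-sided-zero NSC ratios
#'
#' @param summary Output of [summarize_groups()].
#' @param epsilon_policy `"half-min-positive"` (half the smallest positive
#'   group-mean NSC anywhere in the summary) or a single positive number used
#'   as a fixed floor.
#' @return A positive scalar, or `NA` when no positive mean exists.
#' @keywords internal
resolve_epsilon <- function(summary, epsilon_policy = "half-min-positive") {
  if (is.numeric(epsilon_policy)) {
    if (length(epsilon_policy) != 1 || is.na(epsilon_policy) ||
        epsilon_policy <= 0)
      stop("fixed epsilon must be a single positive number", call. = FALSE)
    return(as.numeric(epsilon_policy))
  }
  if (!identical(epsilon_policy, "half-min-positive"))
    stop("unknown epsilon policy: ", epsilon_policy, call. = FALSE)
  pos <- summary$mean_nsc[summary$mean_nsc > 0]
  if (!length(pos)) return(NA_real_)
  min(pos) / 2
}

#' Group-vs-baseline NSC ratio table
#'
#' Ratio of group-mean NSC in each test group to the baseline group. When
#' exactly one side of a comparison is zero, the zero side is replaced by a
#' pseudo-NSC floor epsilon so that a finite ratio exists and the comparison
#' is flagged presence-discordant (`test_zero` / `baseline_zero` record which
#' side was undetected); when both sides are zero the ratio is undefined
#' (`NA`). Swapping test and baseline maps every defined ratio r to 1/r.
#'
#' @param summary Output of [summarize_groups()].
#' @param test_groups Character vector of test group labels; defaults to all
#'   non-baseline groups of `design`.
#' @param baseline Baseline group label.
#' @param epsilon_policy See [resolve_epsilon()].
#' @return Data frame with columns `accession`, `comparison`, `ratio`,
#'   `test_zero`, `baseline_zero`, plus attribute `epsilon_used`.
#' @export
nsc_ratio <- function(summary, test_groups, baseline = "NN",
                      epsilon_policy = "half-min-positive") {
  mn <- summary$mean_nsc
  if (!baseline %in% colnames(mn))
    stop("baseline group '", baseline, "' absent from summary", call. = FALSE)
  missing_g <- setdiff(test_groups, colnames(mn))
  if (length(missing_g))
    stop("test group(s) absent from summary: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  eps <- resolve_epsilon(summary, epsilon_policy)
  base <- mn[, baseline]
  out <- do.call(rbind, lapply(test_groups, function(g) {
    test <- mn[, g]
    tz <- test == 0
    bz <- base == 0
    num <- ifelse(tz, eps, test)
    den <- ifelse(bz, eps, base)
    ratio <- num / den
    ratio[tz & bz] <- NA_real_
    data.frame(accession = rownames(mn), comparison = g, ratio = ratio,
               test_zero = tz, baseline_zero = bz,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "epsilon_used") <- eps
  attr(out, "baseline") <- baseline
  out
}

#' Full quantification pass: NSC, group summary, ratio table
#'
#' Convenience wrapper running [compute_nsc()], [summarize_groups()] and
#' [nsc_ratio()] against every non-baseline group.
#'
#' @param mat An [sc_matrix()].
#' @param epsilon_policy See [resolve_epsilon()].
#' @param detection_floor Minimum SC counting as detection.
#' @return List with `nsc`, `summary`, `ratios`.
#' @export
quantify <- function(mat, epsilon_policy = "half-min-positive",
                     detection_floor = 1L) {
  nsc <- compute_nsc(mat)
  summ <- summarize_groups(nsc, mat$design, counts = mat$counts,
                           detection_floor = detection_floor)
  baseline <- design_baseline(mat$design)
  tests <- setdiff(design_groups(mat$design), baseline)
  ratios <- nsc_ratio(summ, tests, baseline, epsilon_policy)
  list(nsc = nsc, summary = summ, ratios = ratios)
}
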