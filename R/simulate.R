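#' Parameters for spectral-count simulation
#'
#' Counts are drawn per (protein, replicate) from a negative-binomial
#' distribution with mean `baseline_mean_sc * fold(protein, group) *
#' library_factor(replicate)` and overdispersion `dispersion` (variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson counts).
#'
#' @param n_proteins Number of proteins.
#' @param design A [study_design()].
#' @param baseline_mean_sc Baseline expected SC per protein per replicate.
#' @param dispersion Negative-binomial overdispersion (>= 0).
#' @param planted_effects Optional data frame with columns `protein`
#'   (index or accession), `group`, `fold` (positive multiplier) planting
#'   group-specific effects; proteins default to fold 1 everywhere.
#' @param library_size_jitter Half-width of the uniform multiplicative
#'   depth jitter across replicates (default 0).
#' @param seed Integer seed fixing all randomness.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins, design, baseline_mean_sc = 50,
                              dispersion = 0.1, planted_effects = NULL,
                              library_size_jitter = 0, seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  if (baseline_mean_sc <= 0) stop("baseline_mean_sc must be positive",
                                  call. = FALSE)
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  if (library_size_jitter < 0 || library_size_jitter >= 1)
    stop("library_size_jitter must lie in [0, 1)", call. = FALSE)
  acc <- sprintf("P%03d", seq_len(n_proteins))
  folds <- matrix(1, n_proteins, length(design_groups(design)),
                  dimnames = list(acc, design_groups(design)))
  if (!is.null(planted_effects)) {
    if (!all(c("protein", "group", "fold") %in% names(planted_effects)))
      stop("planted_effects needs columns protein, group, fold",
           call. = FALSE)
    if (any(planted_effects$fold <= 0))
      stop("fold multipliers must be positive", call. = FALSE)
    p <- planted_effects$protein
    if (is.numeric(p)) p <- acc[p]
    if (any(!p %in% acc) ||
        any(!planted_effects$group %in% design_groups(design)))
      stop("planted effect refers to unknown protein or group",
           call. = FALSE)
    folds[cbind(p, planted_effects$group)] <- planted_effects$fold
  }
  structure(list(n_proteins = n_proteins, design = design,
                 baseline_mean_sc = baseline_mean_sc,
                 dispersion = dispersion, folds = folds,
                 library_size_jitter = library_size_jitter,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a spectral-count matrix with planted effects
#'
#' @param params A [simulation_params()].
#' @return List with `matrix` (an [sc_matrix()]) and `truth` (data frame
#'   `accession`, `comparison`, `fold`, `direction` of the planted effect
#'   relative to the baseline group; `direction` is `"none"` for null
#'   proteins).
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  design <- params$design
  set.seed(params$seed)
  n_rep <- nrow(design)
  j <- params$library_size_jitter
  libf <- if (j > 0) stats::runif(n_rep, 1 - j, 1 + j) else rep(1, n_rep)
  mu <- params$folds[, design$group, drop = FALSE] *
    params$baseline_mean_sc
  mu <- sweep(mu, 2, libf, "*")
  draw <- if (params$dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
  }
  counts <- matrix(as.integer(draw), nrow(mu), n_rep,
                   dimnames = list(rownames(params$folds),
                                   design$replicate_id))
  baseline <- design_baseline(design)
  tests <- setdiff(design_groups(design), baseline)
  truth <- do.call(rbind, lapply(tests, function(g) {
    rel <- params$folds[, g] / params$folds[, baseline]
    data.frame(accession = rownames(params$folds), comparison = g,
               fold = rel,
               direction = ifelse(rel > 1, "up",
                                  ifelse(rel < 1, "down", "none")),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(matrix = sc_matrix(counts, design), truth = truth)
}

#' Planted-effect recovery of a DEP caller
#'
#' Compares differential-expression calls against simulation truth.
#' Recall is the fraction of planted (protein, comparison) effects recovered
#' with the planted direction; the false-positive rate is the fraction of
#' null (protein, comparison) pairs receiving any call.
#'
#' @param calls Output of [call_dep()].
#' @param truth Truth table from [simulate_counts()].
#' @return List with `recall`, `fpr`, and `confusion` (per-comparison counts
#'   `tp`, `fn`, `fp`, `tn`).
#' @export
evaluate_recovery <- function(calls, truth) {
  key <- function(d) paste(d$accession, d$comparison)
  if (!setequal(key(calls), key(truth)))
    stop("calls and truth cover different (protein, comparison) sets",
         call. = FALSE)
  m <- merge(calls, truth, by = c("accession", "comparison"),
             suffixes = c("_called", "_true"))
  planted <- m$direction_true != "none"
  called <- m$direction_called != "none"
  hit <- planted & m$direction_called == m$direction_true
  conf <- do.call(rbind, lapply(split(m, m$comparison), function(d) {
    p <- d$direction_true != "none"
    c_ <- d$direction_called != "none"
    data.frame(comparison = d$comparison[1],
               tp = sum(p & d$direction_called == d$direction_true),
               fn = sum(p & d$direction_called != d$direction_true),
               fp = sum(!p & c_),
               tn = sum(!p & !c_), row.names = NULL)
  }))
  list(recall = if (any(planted)) sum(hit) / sum(planted) else NA_real_,
       fpr = if (any(!planted)) sum(!planted & called) / sum(!planted)
       else NA_real_,
       confusion = conf)
}
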