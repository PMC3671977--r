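#' Constraint set for count-matrix reconstruction
#'
#' A constraint set specifies, per protein: how many replicates of each group
#' detect it (`present_<G>`), its abundance class per group (`class_<G>`:
#' `significant`, `low` or `absent`), and the expected differential-
#' expression call per non-baseline group (`dep_<G>`: `up`, `down`, `none`,
#' `any` for call-with-free-direction, or `free` for unconstrained).
#' [reconstruct_from_constraints()] builds an integer count matrix that the
#' classification rules map back onto exactly these annotations.
#'
#' @param df Data frame with columns `accession`, `present_<G>` and
#'   `class_<G>` for every group of `design`, and `dep_<G>` for every
#'   non-baseline group.
#' @param design A [study_design()].
#' @param margin Fractional clearance by which target ratios must beat the
#'   call thresholds (default 0.25), so that integer rounding of counts
#'   cannot flip a call.
#' @param config The [rule_config()] the constraints are expressed against.
#' @return The validated data frame with class `constraint_set` and
#'   attributes `design`, `margin`, `config`.
#' @export
constraint_set <- function(df, design, margin = 0.25,
                           config = rule_config()) {
  groups <- design_groups(design)
  baseline <- design_baseline(design)
  tests <- setdiff(groups, baseline)
  need <- c("accession", paste0("present_", groups), paste0("class_", groups),
            paste0("dep_", tests))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("constraint table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$accession))
    stop("duplicate accession in constraint set", call. = FALSE)
  n_rep <- stats::setNames(
    vapply(groups, function(g) length(group_replicates(design, g)), 0L),
    groups)
  for (g in groups) {
    k <- df[[paste0("present_", g)]]
    cl <- df[[paste0("class_", g)]]
    if (any(k < 0 | k > n_rep[g]))
      stop("present_", g, " outside [0, ", n_rep[g], "]", call. = FALSE)
    if (!all(cl %in% c("significant", "low", "absent")))
      stop("class_", g, " must be significant/low/absent", call. = FALSE)
    if (any((cl == "absent") != (k == 0)))
      stop("class_", g, " 'absent' must coincide with present_", g, " = 0",
           call. = FALSE)
    quota <- presence_quota(n_rep[g], config$presence_fraction)
    bad <- cl == "significant" & k < quota
    if (any(bad))
      stop("significant-in-", g, " requires detection in >= ", quota,
           " replicates: ", paste(df$accession[bad], collapse = ", "),
           call. = FALSE)
  }
  for (g in tests) {
    dep <- df[[paste0("dep_", g)]]
    if (!all(dep %in% c("up", "down", "none", "any", "free")))
      stop("dep_", g, " must be up/down/none/any/free", call. = FALSE)
    test_absent <- df[[paste0("present_", g)]] == 0
    bad <- test_absent & dep %in% c("up", "down", "any")
    if (any(bad))
      stop("no call can be made where the test group is undetected (",
           g, "): ", paste(df$accession[bad], collapse = ", "),
           call. = FALSE)
    base_absent <- df[[paste0("present_", baseline)]] == 0
    bad <- base_absent & dep == "down"
    if (any(bad))
      stop("a protein absent from the baseline cannot be called down (",
           g, "): ", paste(df$accession[bad], collapse = ", "),
           call. = FALSE)
  }
  structure(df, class = c("constraint_set", "data.frame"),
            design = design, margin = margin, config = config)
}

#' Check whether a constraint set admits a count matrix
#'
#' Runs the per-protein constructive solver without building the matrix.
#'
#' @param constraints A [constraint_set()].
#' @return Data frame with columns `accession`, `satisfiable`, `reason`
#'   (empty when satisfiable).
#' @export
check_satisfiable <- function(constraints) {
  design <- attr(constraints, "design")
  config <- attr(constraints, "config")
  margin <- attr(constraints, "margin")
  groups <- design_groups(design)
  baseline <- design_baseline(design)
  n_rep <- stats::setNames(
    vapply(groups, function(g) length(group_replicates(design, g)), 0L),
    groups)
  df <- as.data.frame(constraints)
  res <- lapply(seq_len(nrow(df)), function(i) {
    r <- tryCatch(
      { solve_protein_totals(df[i, , drop = FALSE], groups, baseline,
                             n_rep, config, margin); "" },
      error = conditionMessage)
    data.frame(accession = df$accession[i], satisfiable = !nzchar(r),
               reason = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Per-protein solve: choose per-group total counts S_g (expressed through the
# per-replicate weight w_g = S_g / n_g) honoring abundance floors/caps and
# ratio bands. Returns named integer vector of S_g or stops.
solve_protein_totals <- function(row, groups, baseline, n_rep, config,
                                 margin) {
  thr <- config$sc_threshold
  ou <- config$over_threshold + margin      # called ratios clear this
  om <- config$over_threshold - margin      # uncalled ratios stay inside 1/om..om
  k <- vapply(groups, function(g) row[[paste0("present_", g)]], 0L)
  cl <- vapply(groups, function(g) row[[paste0("class_", g)]], "")
  tests <- setdiff(groups, baseline)
  dep <- stats::setNames(
    vapply(tests, function(g) row[[paste0("dep_", g)]], ""), tests)

  quota <- presence_quota(n_rep, config$presence_fraction)
  # per-replicate count cap: none for significant groups; one below the SC
  # threshold where the presence quota is met (so the group cannot turn
  # significant), at the threshold otherwise (low abundance cap only)
  cap <- ifelse(cl == "significant", Inf,
                ifelse(k >= quota, thr - 1L, thr))
  lo <- pmax(n_rep, k, ifelse(cl == "significant", thr + k - 1L, 0L))
  hi <- cap * k
  lo[k == 0] <- 0
  hi[k == 0] <- 0
  bad <- lo > hi
  if (any(bad))
    stop("infeasible abundance constraint for ", row$accession, " in ",
         paste(groups[bad], collapse = ", "), call. = FALSE)
  names(lo) <- names(hi) <- groups

  S <- stats::setNames(integer(length(groups)), groups)

  if (k[baseline] == 0) {
    # baseline-absent protein: uncalled groups must sit exactly at the
    # global minimum positive mean (ratio against the epsilon floor lands on
    # the threshold, excluded by strictness); called groups must clear it
    for (g in tests) {
      if (k[g] == 0) next
      if (dep[g] == "none") {
        if (lo[g] > n_rep[g] || hi[g] < n_rep[g])
          stop("cannot pin ", row$accession, " in ", g,
               " to the boundary mean (uncalled group of a baseline-absent ",
               "protein)", call. = FALSE)
        S[g] <- n_rep[g]
      } else {
        floor_call <- ceiling(n_rep[g] * ou / 2)
        want <- max(lo[g], floor_call)
        if (want > hi[g])
          stop("cannot make ", row$accession, " callable in ", g,
               call. = FALSE)
        S[g] <- as.integer(want)
      }
    }
    return(S)
  }

  # baseline-present: derive bounds on the baseline per-replicate weight w
  nb <- n_rep[baseline]
  wlo <- lo[baseline] / nb
  whi <- hi[baseline] / nb
  for (g in tests) {
    if (k[g] == 0) next   # undetected test group: never called, no bound
    ng <- n_rep[g]
    if (dep[g] %in% c("up", "any")) {
      whi <- min(whi, hi[g] / (ou * ng))
    } else if (dep[g] == "down") {
      wlo <- max(wlo, ou * lo[g] / ng)
    } else if (dep[g] == "none") {
      wlo <- max(wlo, lo[g] / (om * ng))
      whi <- min(whi, om * hi[g] / ng)
    }
  }
  if (wlo > whi + 1e-9)
    stop("jointly infeasible ratio/abundance constraints for ",
         row$accession, call. = FALSE)
  S_b_min <- as.integer(ceiling(wlo * nb - 1e-9))
  S_b_max <- as.integer(floor(min(whi, wlo + 1000) * nb + 1e-9))
  if (S_b_max < S_b_min)
    stop("jointly infeasible ratio/abundance constraints for ",
         row$accession, call. = FALSE)
  for (S_b in S_b_min:min(S_b_max, S_b_min + 500L)) {
    w <- S_b / nb
    ok <- TRUE
    for (g in tests) {
      if (k[g] == 0) { S[g] <- 0L; next }
      ng <- n_rep[g]
      glo <- lo[g]; ghi <- hi[g]
      if (dep[g] %in% c("up", "any")) {
        glo <- max(glo, ceiling(ou * w * ng - 1e-9))
      } else if (dep[g] == "down") {
        ghi <- min(ghi, floor(w * ng / ou + 1e-9))
      } else if (dep[g] == "none") {
        glo <- max(glo, ceiling(w * ng / om - 1e-9))
        ghi <- min(ghi, floor(om * w * ng + 1e-9))
      }
      if (glo > ghi) { ok <- FALSE; break }
      S[g] <- as.integer(switch(dep[g],
                                up = glo, any = glo, down = glo,
                                min(max(round(w * ng), glo), ghi)))
    }
    if (ok) { S[baseline] <- as.integer(S_b); return(S) }
  }
  stop("no integer solution for ", row$accession,
       " within the search bound", call. = FALSE)
}

# Distribute a group total over its detected replicates: significant groups
# concentrate mass in one replicate so the SC threshold is reached; capped
# groups spread counts below the cap.
distribute_counts <- function(S, k, n, cap, significant, thr) {
  if (k == 0) return(integer(n))
  counts <- integer(k)
  if (significant) {
    counts[1] <- S - (k - 1L)
    if (k > 1) counts[2:k] <- 1L
  } else {
    counts[] <- 1L
    left <- S - k
    i <- 1L
    while (left > 0) {
      add <- min(left, cap - counts[i])
      counts[i] <- counts[i] + add
      left <- left - add
      i <- i %% k + 1L
      if (add == 0 && all(counts >= cap)) break
    }
    if (left > 0) stop("cannot place counts under the cap", call. = FALSE)
  }
  c(counts, integer(n - k))
}

#' Reconstruct a count matrix from a classification constraint set
#'
#' Constructive generator: (1) per protein, solve for per-group total counts
#' whose per-replicate mean NSC satisfies every abundance class and every
#' expected call with the configured margin; (2) spread the totals over a
#' seed-chosen subset of replicates honoring the presence pattern,
#' significance floors and low-abundance caps; (3) equalize the library size
#' of every replicate through a depth-filler protein (a ubiquitous,
#' everywhere-significant, uncalled protein -- one of the constrained
#' proteins when the set contains an eligible row, otherwise an appended
#' synthetic row) so that group-mean NSC ratios reduce to count ratios;
#' (4) verify by running the classification pipeline and repair within a
#' bounded loop.
#'
#' @param constraints A [constraint_set()].
#' @param seed Integer seed fixing replicate assignment.
#' @param target_library_size Minimum total SC per replicate (default 500).
#' @param max_iter Repair-loop bound.
#' @return An [sc_matrix()] with attributes `filler` (accession of the depth
#'   filler) and `verified` (`TRUE`).
#' @export
reconstruct_from_constraints <- function(constraints, seed = 42L,
                                         target_library_size = 500L,
                                         max_iter = 30L) {
  design <- attr(constraints, "design")
  config <- attr(constraints, "config")
  margin <- attr(constraints, "margin")
  groups <- design_groups(design)
  baseline <- design_baseline(design)
  tests <- setdiff(groups, baseline)
  n_rep <- stats::setNames(
    vapply(groups, function(g) length(group_replicates(design, g)), 0L),
    groups)
  quota <- presence_quota(n_rep, config$presence_fraction)
  if (target_library_size <= 0)
    stop("target_library_size must be positive", call. = FALSE)

  df <- as.data.frame(constraints)
  acc <- df$accession

  # a filler candidate: present in every replicate, significant everywhere,
  # no expected calls
  eligible <- rep(TRUE, nrow(df))
  for (g in groups) {
    eligible <- eligible & df[[paste0("present_", g)]] == n_rep[g] &
      df[[paste0("class_", g)]] == "significant"
  }
  for (g in tests) eligible <- eligible & df[[paste0("dep_", g)]] == "none"
  filler <- if (any(eligible)) acc[which(eligible)[1]] else "synthetic_filler"

  # Baseline-absent proteins are called through the epsilon floor (half the
  # smallest positive group-mean NSC), so their ratios are 2 * w / w_min in
  # per-replicate count weights. The solver sizes call cells against a
  # global minimum weight of 1; that minimum exists whenever some
  # baseline-absent protein has an uncalled detected group (pinned to
  # weight 1). Otherwise a synthetic anchor protein (weight exactly 1 in
  # the baseline, absent elsewhere, never called) supplies it.
  base_absent <- df[[paste0("present_", baseline)]] == 0
  has_eps_call <- FALSE
  has_pinned <- FALSE
  for (g in tests) {
    dep <- df[[paste0("dep_", g)]]
    k <- df[[paste0("present_", g)]]
    has_eps_call <- has_eps_call || any(base_absent & dep %in% c("up", "any"))
    has_pinned <- has_pinned || any(base_absent & k > 0 & dep == "none")
  }
  anchor <- if (has_eps_call && !has_pinned) "synthetic_anchor" else NULL

  totals <- matrix(0L, nrow(df), length(groups),
                   dimnames = list(acc, groups))
  for (i in seq_len(nrow(df))) {
    if (acc[i] == filler) next   # overwritten by padding
    totals[i, ] <- solve_protein_totals(df[i, , drop = FALSE], groups,
                                        baseline, n_rep, config, margin)
  }

  set.seed(seed)
  rn <- c(acc, setdiff(c(filler, anchor), acc))
  counts <- matrix(0L, length(rn), nrow(design))
  dimnames(counts) <- list(rn, design$replicate_id)
  if (!is.null(anchor))
    counts[anchor, group_replicates(design, baseline)] <- 1L
  for (i in seq_len(nrow(df))) {
    if (acc[i] == filler) next
    for (g in groups) {
      k <- df[[paste0("present_", g)]][i]
      if (k == 0) next
      reps <- group_replicates(design, g)
      chosen <- if (length(reps) == 1) reps else sample(reps, k)
      sig <- df[[paste0("class_", g)]][i] == "significant"
      cap <- if (sig) Inf else if (k >= quota[g])
        config$sc_threshold - 1L else config$sc_threshold
      vals <- distribute_counts(totals[i, g], k, k, cap, sig,
                                config$sc_threshold)
      counts[acc[i], chosen] <- as.integer(vals[seq_len(k)])
    }
  }

  pad_filler <- function(counts) {
    base_depth <- colSums(counts[setdiff(rn, filler), , drop = FALSE])
    depth <- max(target_library_size, ceiling(max(base_depth) / 0.3))
    counts[filler, ] <- as.integer(depth - base_depth)
    counts
  }
  counts <- pad_filler(counts)

  expected_class <- as.matrix(df[paste0("class_", groups)])
  dimnames(expected_class) <- list(acc, groups)
  expected_dep <- as.matrix(df[paste0("dep_", tests)])
  dimnames(expected_dep) <- list(acc, tests)

  for (iter in seq_len(max_iter)) {
    mat <- sc_matrix(counts, design)
    q <- quantify(mat)
    cls <- classify_abundance(mat, config)
    calls <- call_dep(q$ratios, config)
    viol <- character(0)
    for (i in seq_along(acc)) {
      a <- acc[i]
      if (a == filler && !filler %in% df$accession) next
      for (g in groups) {
        want <- expected_class[a, g]
        got <- if (cls$significant_in[a, g]) "significant"
        else if (cls$low_in[a, g]) "low"
        else if (cls$present_in[a, g] == 0) "absent" else "other"
        if (want != got)
          viol <- c(viol, sprintf("%s class in %s: want %s got %s",
                                  a, g, want, got))
        if (cls$present_in[a, g] != df[[paste0("present_", g)]][i])
          viol <- c(viol, sprintf("%s presence in %s: want %d got %d",
                                  a, g, df[[paste0("present_", g)]][i],
                                  cls$present_in[a, g]))
      }
      for (g in tests) {
        want <- expected_dep[a, g]
        if (want == "free") next
        got <- calls$direction[calls$accession == a & calls$comparison == g]
        fine <- switch(want,
                       none = got == "none",
                       any = got != "none",
                       got == want)
        if (!fine) {
          viol <- c(viol, sprintf("%s call in %s: want %s got %s",
                                  a, g, want, got))
          # simple repair moves on the group total
          cur <- counts[a, group_replicates(design, g)]
          kk <- sum(cur > 0)
          if (want %in% c("up", "any") ||
              (want == "none" && got == "down")) {
            bump <- pmax(1L, ceiling(0.1 * cur)) * (cur > 0)
            kk_cap <- if (df[[paste0("class_", g)]][i] == "significant")
              Inf else if (kk >= quota[g]) config$sc_threshold - 1L
            else config$sc_threshold
            counts[a, group_replicates(design, g)] <-
              as.integer(pmin(cur + bump, kk_cap))
          } else if (want == "down" || (want == "none" && got == "up")) {
            shrink <- as.integer(pmax(cur > 0, floor(cur * 0.9)))
            counts[a, group_replicates(design, g)] <- shrink
          }
        }
      }
    }
    if (!length(viol)) {
      out <- sc_matrix(counts, design)
      attr(out, "filler") <- filler
      attr(out, "anchor") <- anchor
      attr(out, "verified") <- TRUE
      attr(out, "library_size") <- unname(colSums(counts)[1])
      return(out)
    }
    counts <- pad_filler(counts)
  }
  stop("reconstruction failed to verify after ", max_iter,
       " repair iterations; remaining violations:\n  ",
       paste(utils::head(viol, 15), collapse = "\n  "), call. = FALSE)
}
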