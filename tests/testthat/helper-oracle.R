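# Independent brute-force re-derivations of the pipeline's quantities,
# written as plain loops over the definitions. These are the reference
# oracles for equivalence tests; they share no code with the package
# internals beyond the public data structures.

oracle_nsc <- function(counts) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    total <- 0
    for (i in seq_len(nrow(counts))) total <- total + counts[i, j]
    for (i in seq_len(nrow(counts))) out[i, j] <- counts[i, j] / total
  }
  out
}

oracle_group_means <- function(counts, design) {
  nsc <- oracle_nsc(counts)
  groups <- unique(design$group)
  out <- matrix(0, nrow(counts), length(groups),
                dimnames = list(rownames(counts), groups))
  for (g in groups) {
    reps <- design$replicate_id[design$group == g]
    for (i in seq_len(nrow(counts))) {
      s <- 0
      for (r in reps) s <- s + nsc[i, r]
      out[i, g] <- s / length(reps)
    }
  }
  out
}

# significance / low-abundance / global class, straight from the rules
oracle_classes <- function(counts, design, thr = 10, frac = 0.5) {
  groups <- unique(design$group)
  sig <- low <- matrix(FALSE, nrow(counts), length(groups),
                       dimnames = list(rownames(counts), groups))
  for (g in groups) {
    reps <- design$replicate_id[design$group == g]
    quota <- max(1, floor(frac * length(reps)))
    for (i in seq_len(nrow(counts))) {
      cc <- counts[i, reps]
      detected <- sum(cc >= 1)
      sig[i, g] <- max(cc) >= thr && detected >= quota
      low[i, g] <- detected >= 1 && max(cc) <= thr && !sig[i, g]
    }
  }
  global_low <- logical(nrow(counts))
  for (i in seq_len(nrow(counts)))
    global_low[i] <- any(counts[i, ] >= 1) && max(counts[i, ]) <= thr &&
      !any(sig[i, ])
  list(sig = sig, low = low, global_low = global_low)
}

# fold-ratio calls vs baseline, with the epsilon floor for baseline-absent
# proteins, no call for test-absent proteins, and the 1e-9 guard band at
# the strict cutoffs
oracle_calls <- function(counts, design, baseline, over = 2, under = 0.5) {
  means <- oracle_group_means(counts, design)
  eps <- {
    pos <- means[means > 0]
    if (length(pos)) min(pos) / 2 else NA_real_
  }
  groups <- setdiff(unique(design$group), baseline)
  out <- NULL
  for (g in groups) {
    for (i in seq_len(nrow(counts))) {
      mt <- means[i, g]; mb <- means[i, baseline]
      dir <- "none"
      if (mt > 0) {
        ratio <- if (mb > 0) mt / mb else mt / eps
        if (ratio > over * (1 + 1e-9)) dir <- "up"
        if (ratio < under * (1 - 1e-9)) dir <- "down"
      }
      out <- rbind(out, data.frame(accession = rownames(counts)[i],
                                   comparison = g, direction = dir,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

oracle_venn <- function(calls, comparisons) {
  actual <- calls[calls$direction != "none", , drop = FALSE]
  subsets <- unlist(lapply(seq_along(comparisons), function(k)
    combn(comparisons, k, paste, collapse = "+", simplify = FALSE)))
  cells <- setNames(integer(length(subsets)), subsets)
  for (a in unique(actual$accession)) {
    inset <- comparisons[comparisons %in%
                           actual$comparison[actual$accession == a]]
    key <- paste(inset, collapse = "+")
    cells[key] <- cells[key] + 1L
  }
  cells
}

# --- random input generators -------------------------------------------------

rand_count_matrix <- function(max_proteins = 8, max_reps = 6,
                              max_count = 20) {
  np <- sample(2:max_proteins, 1)
  nr <- sample(2:max_reps, 1)
  ng <- if (nr == 2) 2 else sample(2:3, 1)
  glabs <- c("NN", "NA", "OA")[seq_len(ng)]
  grp <- c(glabs, sample(glabs, nr - ng, replace = TRUE))
  design <- study_design(sprintf("r%d", seq_len(nr)), grp, baseline = "NN")
  repeat {
    counts <- matrix(sample(0:max_count, np * nr, replace = TRUE,
                            prob = c(0.35, rep(0.65 / max_count,
                                               max_count))),
                     np, nr,
                     dimnames = list(sprintf("P%d", seq_len(np)),
                                     design$replicate_id))
    if (all(colSums(counts) > 0)) break
  }
  sc_matrix(counts, design)
}

# Random satisfiable constraint set over the four-group study design.
# Rows are sampled and kept only when the per-protein solver accepts them;
# satisfiability is then re-verified downstream by the round-trip test
# against the classifier, an independent path.
rand_constraint_set <- function(n_proteins = 6) {
  design <- sp35_design()
  n_rep <- c(NN = 5L, "NA" = 4L, OA = 2L, ON = 1L)
  quota <- presence_quota(n_rep)
  make_row <- function(id) {
    repeat {
      k <- sapply(n_rep, function(n)
        if (runif(1) < 0.2) 0L else sample.int(n, 1))
      if (all(k == 0)) next
      cl <- character(4); names(cl) <- names(n_rep)
      for (g in names(n_rep)) {
        cl[g] <- if (k[g] == 0) "absent"
        else if (k[g] >= quota[g] && runif(1) < 0.5) "significant"
        else "low"
      }
      dep <- c("NA" = "none", OA = "none", ON = "none")
      for (g in names(dep)) {
        if (k[g] == 0) next
        if (k["NN"] == 0) {
          dep[g] <- sample(c("none", "any"), 1)
          if (dep[g] == "none") cl[g] <- "low"
        } else {
          dep[g] <- sample(c("none", "none", "up", "down"), 1)
        }
      }
      row <- data.frame(
        accession = id,
        present_NN = k[["NN"]], present_NA = k[["NA"]],
        present_OA = k[["OA"]], present_ON = k[["ON"]],
        class_NN = cl[["NN"]], class_NA = cl[["NA"]],
        class_OA = cl[["OA"]], class_ON = cl[["ON"]],
        dep_NA = dep[["NA"]], dep_OA = dep[["OA"]], dep_ON = dep[["ON"]],
        stringsAsFactors = FALSE)
      cs <- try(constraint_set(row, design), silent = TRUE)
      if (inherits(cs, "try-error")) next
      if (isTRUE(check_satisfiable(cs)$satisfiable[1])) return(row)
    }
  }
  df <- do.call(rbind, lapply(seq_len(n_proteins), function(i)
    make_row(sprintf("P%d", i))))
  constraint_set(df, design)
}
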