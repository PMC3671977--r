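two_group_design <- function(n_nn = 5, n_na = 4) {
  study_design(c(sprintf("n%d", seq_len(n_nn)), sprintf("a%d", seq_len(n_na))),
               c(rep("NN", n_nn), rep("NA", n_na)))
}

test_that("simulation is reproducible and respects its parameters", {
  p <- simulation_params(20, two_group_design(), baseline_mean_sc = 50,
                         dispersion = 0.1, seed = 5)
  s1 <- simulate_counts(p)
  s2 <- simulate_counts(p)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(dim(s1$matrix$counts), c(20L, 9L))
  expect_error(simulation_params(0, two_group_design()), "n_proteins")
  expect_error(simulation_params(5, two_group_design(), dispersion = -1),
               "dispersion")
  expect_error(
    simulation_params(5, two_group_design(),
                      planted_effects = data.frame(protein = 1, group = "NA",
                                                   fold = -2)),
    "positive")
})

test_that("dispersion zero gives Poisson-like counts at the requested mean", {
  d <- study_design(sprintf("r%d", 1:10), rep(c("NN", "NA"), each = 5))
  p <- simulation_params(100, d, baseline_mean_sc = 50, dispersion = 0,
                         seed = 9)
  s <- simulate_counts(p)
  x <- as.numeric(s$matrix$counts)   # 1000 draws at mean 50
  se <- sqrt(50 / length(x))
  expect_lt(abs(mean(x) - 50), 3 * sqrt(50) / sqrt(length(x)) + 1e-9)
  # variance/mean ratio near 1 within 3 standard errors (~sqrt(2/n))
  expect_lt(abs(var(x) / mean(x) - 1), 3 * sqrt(2 / length(x)))
})

test_that("a null simulation yields (near-)zero differential calls", {
  p <- simulation_params(60, two_group_design(), baseline_mean_sc = 2000,
                         dispersion = 0, seed = 3)
  s <- simulate_counts(p)
  calls <- call_dep(quantify(s$matrix)$ratios)
  expect_lte(sum(calls$direction != "none"), 1)
})

test_that("recovery evaluation computes recall, FPR and confusion exactly", {
  truth <- data.frame(accession = c("A", "B", "C"), comparison = "NA",
                      fold = c(4, 1, 0.25),
                      direction = c("up", "none", "down"),
                      stringsAsFactors = FALSE)
  perfect <- data.frame(accession = c("A", "B", "C"), comparison = "NA",
                        ratio = c(4, 1, 0.25),
                        direction = c("up", "none", "down"),
                        presence_discordant = FALSE,
                        stringsAsFactors = FALSE)
  r <- evaluate_recovery(perfect, truth)
  expect_equal(r$recall, 1)
  expect_equal(r$fpr, 0)
  expect_identical(r$confusion$tp, 2L)
  none <- perfect; none$direction <- "none"
  r0 <- evaluate_recovery(none, truth)
  expect_equal(r0$recall, 0)
  expect_equal(r0$fpr, 0)
  expect_error(evaluate_recovery(perfect[-1, ], truth), "different")
})

test_that("reconstruction satisfies simple constraint sets and its margin", {
  design <- sp35_design()
  # a single ubiquitous protein with no calls verifies as a constant-ish
  # matrix (plus the synthetic depth filler)
  df <- data.frame(accession = "P1",
                   present_NN = 5L, present_NA = 4L, present_OA = 2L,
                   present_ON = 1L,
                   class_NN = "significant", class_NA = "significant",
                   class_OA = "significant", class_ON = "significant",
                   dep_NA = "none", dep_OA = "none", dep_ON = "none",
                   stringsAsFactors = FALSE)
  m <- reconstruct_from_constraints(constraint_set(df, design), seed = 2)
  expect_true(attr(m, "verified"))
  expect_true(all(m$counts["P1", ] >= 1))
  # a planted down-call clears the threshold by the configured margin
  df2 <- df
  df2$accession <- "P2"
  df2$class_NA <- "low"; df2$dep_NA <- "down"
  m2 <- reconstruct_from_constraints(constraint_set(rbind(df, df2), design),
                                     seed = 2)
  q <- quantify(m2)
  r <- q$ratios[q$ratios$accession == "P2" & q$ratios$comparison == "NA", ]
  expect_lt(r$ratio, 0.5 / (1 + 0.25 / 2))
  calls <- call_dep(q$ratios)
  expect_identical(
    calls$direction[calls$accession == "P2" & calls$comparison == "NA"],
    "down")
})

test_that("reconstruction is deterministic given the seed", {
  cs <- sp35_constraints()
  m1 <- reconstruct_from_constraints(cs, seed = 13)
  m2 <- reconstruct_from_constraints(cs, seed = 13)
  m3 <- reconstruct_from_constraints(cs, seed = 14)
  expect_identical(m1$counts, m2$counts)
  expect_false(identical(m1$counts, m3$counts))
})

test_that("classification round-trips random satisfiable constraint sets", {
  set.seed(91)
  for (i in 1:15) {
    cs <- rand_constraint_set(n_proteins = 5)
    m <- reconstruct_from_constraints(cs, seed = i)
    df <- as.data.frame(cs)
    cls <- classify_abundance(m)
    calls <- call_dep(quantify(m)$ratios)
    for (j in seq_len(nrow(df))) {
      a <- df$accession[j]
      for (g in c("NN", "NA", "OA", "ON")) {
        expect_identical(unname(cls$present_in[a, g]),
                         df[[paste0("present_", g)]][j])
        want <- df[[paste0("class_", g)]][j]
        got <- if (cls$significant_in[a, g]) "significant"
        else if (cls$low_in[a, g]) "low" else "absent"
        expect_identical(got, want)
      }
      for (g in c("NA", "OA", "ON")) {
        want <- df[[paste0("dep_", g)]][j]
        got <- calls$direction[calls$accession == a & calls$comparison == g]
        if (want == "any") expect_true(got != "none")
        else if (want != "free") expect_identical(got, want)
      }
    }
  }
})
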