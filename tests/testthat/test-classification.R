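mk_nn5 <- function(nn_counts, other = 20L) {
  d <- study_design(c(paste0("n", 1:5), "x1"), c(rep("NN", 5), "NA"))
  counts <- rbind(P = c(nn_counts, 1L),
                  Q = rep(other, 6))   # keeps every column positive
  colnames(counts) <- d$replicate_id
  sc_matrix(counts, d)
}

test_that("significance needs the SC threshold and the presence quota", {
  cls <- classify_abundance(mk_nn5(c(12L, 11L, 9L, 8L, 7L)))
  expect_true(cls$significant_in["P", "NN"])
  # high count in one replicate only: quota unmet, and max over threshold
  # keeps it out of the low class too
  cls2 <- classify_abundance(mk_nn5(c(12L, 0L, 0L, 0L, 0L)))
  expect_false(cls2$significant_in["P", "NN"])
  expect_false(cls2$low_in["P", "NN"])
  # the boundary count equals the threshold: significance dominates
  cls3 <- classify_abundance(mk_nn5(c(10L, 10L, 10L, 10L, 10L)))
  expect_true(cls3$significant_in["P", "NN"])
  expect_false(cls3$low_in["P", "NN"])
  # detection in two of five replicates meets the half quota
  cls4 <- classify_abundance(mk_nn5(c(11L, 3L, 0L, 0L, 0L)))
  expect_true(cls4$significant_in["P", "NN"])
})

test_that("global low abundance excludes proteins significant anywhere", {
  d <- study_design(c("n1", "n2", "a1"), c("NN", "NN", "NA"))
  counts <- rbind(L = c(4L, 2L, 3L),      # never above threshold
                  S = c(30L, 20L, 25L))
  colnames(counts) <- d$replicate_id
  cls <- classify_abundance(sc_matrix(counts, d))
  expect_true(cls$global_low["L"])
  expect_false(cls$global_low["S"])
  # disjointness: significant somewhere and globally low never co-occur
  expect_false(any(cls$global_low & rowSums(cls$significant_in) > 0))
})

test_that("DEP calling uses strict thresholds and skips undetected test groups", {
  ratios <- data.frame(accession = c("A", "B", "C", "D", "E"),
                       comparison = "NA",
                       ratio = c(1, 2, 2.5, 0.3, 4),
                       test_zero = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                       baseline_zero = FALSE,
                       stringsAsFactors = FALSE)
  calls <- call_dep(ratios)
  expect_identical(calls$direction, c("none", "none", "up", "down", "none"))
  expect_true(calls$presence_discordant[5])
  # boundary under-threshold is not a call either
  r2 <- ratios[1, ]; r2$ratio <- 0.5
  expect_identical(call_dep(r2)$direction, "none")
})

test_that("classes, calls and venn agree with the brute-force oracle", {
  set.seed(51)
  for (i in 1:60) {
    m <- rand_count_matrix()
    cfg <- rule_config()
    cls <- classify_abundance(m, cfg)
    oc <- oracle_classes(m$counts, m$design)
    expect_identical(
      unname(cls$significant_in[, colnames(oc$sig), drop = FALSE]),
      unname(oc$sig))
    expect_identical(unname(cls$low_in[, colnames(oc$low), drop = FALSE]),
                     unname(oc$low))
    expect_identical(unname(cls$global_low), oc$global_low)
    q <- quantify(m)
    calls <- call_dep(q$ratios, cfg)
    ocalls <- oracle_calls(m$counts, m$design, "NN")
    key <- function(d) paste(d$accession, d$comparison)
    expect_identical(calls$direction[order(key(calls))],
                     ocalls$direction[order(key(ocalls))])
    comparisons <- setdiff(design_groups(m$design), "NN")
    expect_identical(venn_partition(calls, comparisons),
                     oracle_venn(calls, comparisons))
  }
})

test_that("venn cells always sum to the number of DEP proteins", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    calls <- expand.grid(accession = sprintf("P%d", 1:n),
                         comparison = c("NA", "OA", "ON"),
                         stringsAsFactors = FALSE)
    calls$ratio <- 1
    calls$direction <- sample(c("up", "down", "none"), nrow(calls),
                              replace = TRUE)
    calls$presence_discordant <- FALSE
    v <- venn_partition(calls, c("NA", "OA", "ON"))
    ndep <- length(unique(calls$accession[calls$direction != "none"]))
    expect_identical(sum(v), ndep)
  }
  # no calls -> all seven cells zero
  none <- data.frame(accession = "P1", comparison = "NA", ratio = 1,
                     direction = "none", presence_discordant = FALSE)
  expect_true(all(venn_partition(none, c("NA", "OA", "ON")) == 0L))
})

test_that("raising thresholds never grows the significant or up-call sets", {
  set.seed(71)
  for (i in 1:20) {
    m <- rand_count_matrix()
    lo <- classify_abundance(m, rule_config(sc_threshold = 5))
    hi <- classify_abundance(m, rule_config(sc_threshold = 9))
    expect_true(all(hi$significant_in <= lo$significant_in))
    q <- quantify(m)
    up_lo <- call_dep(q$ratios, rule_config(over_threshold = 1.5,
                                            under_threshold = 1 / 1.5))
    up_hi <- call_dep(q$ratios, rule_config(over_threshold = 3,
                                            under_threshold = 1 / 3))
    expect_true(all(which(up_hi$direction == "up") %in%
                      which(up_lo$direction == "up")))
  }
})

test_that("set selectors are order-stable and validate their arguments", {
  rp <- reproduce_study()
  cls <- rp$pipeline$classification
  calls <- rp$pipeline$calls
  expect_length(select_set(cls, calls, "common"), 11)
  expect_length(select_set(cls, calls, "low_abundant"), 10)
  expect_length(select_set(cls, calls, "dep"), 20)
  expect_length(select_set(cls, calls, "unique"), 13)
  # the three proteins whose only call is down-in-NA
  only_na_down <- select_set(cls, calls, "dep_only:NA:down")
  expect_setequal(only_na_down, c("151301154", "167857790", "25121982"))
  expect_setequal(select_set(cls, calls, "dep_only:ON:down"), "42716297")
  expect_error(select_set(cls, calls, "significant:ZZ"), "unknown group")
  expect_error(select_set(cls, calls, "nonsense"), "unknown selector")
  # order stability: repeated evaluation gives the same vector
  expect_identical(select_set(cls, calls, "dep"),
                   select_set(cls, calls, "dep"))
})
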