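test_that("catalog validation enforces key, alias and range invariants", {
  base <- data.frame(accession = c("A", "B"), uniprot = c("P1", "P2"),
                     name = c("a", "b"), mw_kda = c(10, 20),
                     pi = c(5, 7), aliases = c("A2", ""),
                     stringsAsFactors = FALSE)
  expect_s3_class(protein_catalog(base), "protein_catalog")
  dup <- base; dup$accession <- c("A", "A")
  expect_error(protein_catalog(dup), "duplicate")
  clash <- base; clash$aliases <- c("B", "")   # alias equals a primary key
  expect_error(protein_catalog(clash), "primary and as alias")
  twice <- base; twice$aliases <- c("X", "X")  # alias in two records
  expect_error(protein_catalog(twice), "more than one")
  badpi <- base; badpi$pi <- c(5, 15)
  expect_error(protein_catalog(badpi), "pI")
})

test_that("alias resolution merges rows additively and conserves totals", {
  d <- study_design(c("r1", "r2"), c("NN", "NA"))
  m <- sc_matrix(matrix(c(3L, 0L, 2L, 4L, 1L, 1L), 3, byrow = TRUE,
                        dimnames = list(c("A", "A2", "B"), c("r1", "r2"))),
                 d)
  cat <- protein_catalog(data.frame(
    accession = c("A", "B"), uniprot = "", name = c("a", "b"),
    mw_kda = 1, pi = 7, aliases = c("A2", ""), stringsAsFactors = FALSE))
  merged <- resolve_aliases(m, cat)
  expect_identical(rownames(merged$counts), c("A", "B"))
  expect_identical(unname(merged$counts["A", ]), c(5L, 4L))
  expect_identical(colSums(merged$counts), colSums(m$counts))
  # no aliased rows -> identity
  m2 <- sc_matrix(m$counts[c("A", "B"), ], d)
  expect_identical(resolve_aliases(m2, cat)$counts, m2$counts)
  # unknown accession kept verbatim with a warning
  m3 <- sc_matrix(matrix(c(1L, 1L), 1,
                         dimnames = list("ZZZ", c("r1", "r2"))), d)
  expect_warning(out <- resolve_aliases(m3, cat), "not in catalog")
  expect_identical(out$counts, m3$counts)
})

test_that("alias resolution conserves per-replicate totals on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    m <- rand_count_matrix()
    acc <- rownames(m$counts)
    primary <- acc[1:max(1, length(acc) %/% 2)]
    aliases <- setdiff(acc, primary)
    owner <- sample(primary, length(aliases), replace = TRUE)
    cat <- protein_catalog(data.frame(
      accession = primary, uniprot = "", name = primary, mw_kda = 1, pi = 7,
      aliases = vapply(primary, function(p)
        paste(aliases[owner == p], collapse = ","), ""),
      stringsAsFactors = FALSE))
    merged <- resolve_aliases(m, cat)
    expect_identical(colSums(merged$counts), colSums(m$counts))
    expect_setequal(rownames(merged$counts), primary)
  }
})

test_that("the packaged catalog and classification table load as published", {
  fx <- sp35_fixture()
  expect_identical(nrow(fx$catalog), 35L)
  tab <- fx$expected
  expect_identical(nrow(tab), 35L)
  # eleven proteins present in every one of the twelve replicates
  full <- tab$present_NN == 5 & tab$present_NA == 4 &
    tab$present_OA == 2 & tab$present_ON == 1
  expect_identical(sum(full), 11L)
  # cystatin S: down in all three comparisons
  cys <- tab[tab$name == "cystatin S precursor", ]
  expect_identical(unname(unlist(cys[c("dep_NA", "dep_OA", "dep_ON")])),
                   c("down", "down", "down"))
  # prolactin-induced protein: ubiquitous, never called
  pip <- tab[tab$name == "prolactin-induced protein", ]
  expect_identical(unname(unlist(
    pip[c("present_NN", "present_NA", "present_OA", "present_ON")])),
    c(5L, 4L, 2L, 1L))
  expect_true(all(pip[c("dep_NA", "dep_OA", "dep_ON")] == "none"))
  # ten globally low-abundant proteins
  expect_identical(sum(tab$global_low), 10L)
  # the two documented relaxations, and only those
  rel <- attr(fx$constraints, "relaxations")
  expect_setequal(rel$relaxation,
                  c("direction_unconstrained", "oa_significant_to_low"))
  # the uncertain CD177 cell carries its note
  expect_match(tab$note[tab$name == "CD177 molecule"], "presumed ON\\(1\\)")
})

test_that("the packaged count fixture matches the design and merges to the catalog", {
  paths <- sp35_counts_paths()
  m <- read_count_matrix(paths["counts"], paths["design"])
  expect_identical(sort(table(m$design$group), method = "radix"),
                   sort(table(c(rep("NN", 5), rep("NA", 4), rep("OA", 2),
                                "ON")), method = "radix"))
  merged <- resolve_aliases(m, sp35_catalog())
  expect_identical(nrow(merged$counts), 35L)
  # the PSA isoform rows fold into one record present in all 12 replicates
  expect_true(all(merged$counts["4502173", ] >= 1))
  expect_identical(colSums(merged$counts), colSums(m$counts))
  # the packaged file is the seed-42 reconstruction, regenerated exactly
  rec <- reconstruct_from_constraints(sp35_constraints(), seed = 42L,
                                      target_library_size = 500L)
  expect_identical(merged$counts[rownames(rec$counts), ], rec$counts)
})

test_that("report writing round trips and handles the empty study", {
  rp <- reproduce_study()
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- write_report(rp$summary, rp$pipeline$classification,
                        rp$pipeline$calls, prefix)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_identical(js$n_total, 35L)
  tab <- utils::read.delim(paste0(prefix, ".tsv"), colClasses = "character",
                           na.strings = character(0))
  expect_identical(nrow(tab), 35L)
  expect_identical(tab$accession, rp$summary$proteins$accession)

  d <- study_design("r1", "NN")
  empty <- run_pipeline(sc_matrix(matrix(integer(0), 0, 1,
                                         dimnames = list(NULL, "r1")), d))
  expect_identical(empty$categories$n_total, 0L)
  p2 <- file.path(withr::local_tempdir(), "empty")
  write_report(empty$categories, NULL, NULL, p2)
  expect_identical(jsonlite::read_json(paste0(p2, ".json"))$n_dep, 0L)
})
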