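mk_entry <- function(pdb_id = "1ABC", ref = c("A2", "C2"), pdb = ref, ...) {
  methods <- list(...)
  benchmark_entry(pdb_id,
                  qs_annotation(ref[1], ref[2], source = "PDB"),
                  qs_annotation(pdb[1], pdb[2], source = "PDB"),
                  methods)
}

test_that("vote collection applies the exclusion rules", {
  e <- mk_entry(
    SC = qs_annotation(source = "SC", status = "not_available"),
    TM = qs_annotation("A2", source = "TM"),
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  expect_length(collect_votes(e), 3L)

  gray <- mk_entry(
    SC = qs_annotation("A2", "C2", source = "SC"),
    TM = qs_annotation("A2", source = "TM"),
    PISA = qs_annotation(source = "PISA", status = "inconclusive"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  expect_length(collect_votes(gray), 3L)
  expect_length(collect_votes(gray, include_inconclusive = TRUE), 4L)

  all_na <- mk_entry(
    SC = qs_annotation(source = "SC", status = "not_available"),
    TM = qs_annotation(source = "TM", status = "not_available")
  )
  expect_length(collect_votes(all_na), 0L)
  expect_length(collect_votes(e, methods = c("SC", "PISA", "EPPIC")), 2L)
})

test_that("majority vote reproduces the monomer-reannotated-as-dimer case", {
  # archive says monomer; all four methods call a dimer (TM by order only)
  e <- mk_entry("1Z77", ref = c("A2", "C2"), pdb = c("A", "C1"),
    SC = qs_annotation("A2", "C2", source = "SC"),
    TM = qs_annotation("A2", source = "TM"),
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  cons <- consensus_predict(collect_votes(e))
  expect_equal(format(cons$stoichiometry), "A2")
  expect_equal(format(cons$symmetry), "C2")
  expect_equal(cons$source, "CONSENSUS")
  expect_equal(classify_outcome(cons, e$reference), "correct")
  # and the deposited monomer annotation is flagged as a possible outlier
  fl <- flag_outliers(list(e))
  expect_true(fl$flags[["1Z77"]])
  expect_equal(fl$fraction, 1)
})

test_that("strict majority: splits are inconclusive, singletons win", {
  split22 <- list(
    qs_annotation("A2", "C2", source = "SC"),
    qs_annotation("A2", "C2", source = "PISA"),
    qs_annotation("A4", "D2", source = "EPPIC"),
    qs_annotation("A4", source = "TM")
  )
  cons <- consensus_predict(split22)
  # the 2-2 stoichiometry split is undecided, but symmetry (2 of 3) stands
  expect_null(cons$stoichiometry)
  expect_equal(format(cons$symmetry), "C2")

  full_split <- consensus_predict(split22[c(1, 3)])
  expect_equal(full_split$status, "inconclusive")

  single <- consensus_predict(list(qs_annotation("A2", "C2", source = "EPPIC")))
  expect_equal(format(single$stoichiometry), "A2")
  expect_equal(format(single$symmetry), "C2")

  expect_equal(consensus_predict(list())$status, "not_available")

  # vote order and method labels do not matter
  votes <- list(
    qs_annotation("A2", "C2", source = "SC"),
    qs_annotation("A2", "C2", source = "PISA"),
    qs_annotation("A4", "D2", source = "EPPIC")
  )
  set.seed(3)
  base <- consensus_predict(votes)
  for (rep in 1:5) {
    p <- consensus_predict(sample(votes))
    expect_equal(format(p$stoichiometry), format(base$stoichiometry))
    expect_equal(format(p$symmetry), format(base$symmetry))
  }

  # removing a dissenting vote never flips a strict-majority winner
  with_dissent <- consensus_predict(votes)
  without <- consensus_predict(votes[1:2])
  expect_equal(format(without$stoichiometry), format(with_dissent$stoichiometry))
  expect_equal(format(without$symmetry), format(with_dissent$symmetry))
})

test_that("a TM order vote backs the matching composition formula", {
  # 1 full-formula vote for the heterodimer + TM order-2 vote beat a monomer vote
  votes <- list(
    qs_annotation("A1B1", "C1", source = "EPPIC"),
    qs_annotation("A2", source = "TM"),
    qs_annotation("A", "C1", source = "PISA")
  )
  cons <- consensus_predict(votes)
  expect_equal(format(cons$stoichiometry), "A1B1")
  # with two distinct order-2 formulas on the table TM cannot choose between
  # them: it abstains and neither formula reaches a strict majority
  amb <- consensus_predict(list(
    qs_annotation("A1B1", "C1", source = "EPPIC"),
    qs_annotation("A2", "C2", source = "PISA"),
    qs_annotation("A2", source = "TM")
  ))
  expect_null(amb$stoichiometry)
})

test_that("outcome classification distinguishes partial from total error", {
  ref <- qs_annotation("A2", "C2", source = "PDB")
  expect_equal(classify_outcome(qs_annotation("A2", "C2", source = "PISA"), ref),
               "correct")
  expect_equal(classify_outcome(qs_annotation("A2", "C1", source = "PISA"), ref),
               "inconclusive")
  expect_equal(classify_outcome(qs_annotation("A", "C1", source = "PISA"), ref),
               "incorrect")
  expect_equal(classify_outcome(qs_annotation("A2", source = "TM"), ref), "correct")
  expect_equal(classify_outcome(qs_annotation(source = "TM", status = "inconclusive"), ref),
               "inconclusive")
  expect_equal(classify_outcome(qs_annotation(source = "SC", status = "not_available"), ref),
               "not_available")
})

test_that("benchmark summaries have full-denominator rows summing to 100", {
  b <- make_benchmark_table(60, seed = 17)
  s <- benchmark_summary(b$entries)
  expect_setequal(s$method, c("SC", "TM", "PISA", "EPPIC", "CONSENSUS"))
  expect_equal(s$pct_correct + s$pct_incorrect + s$pct_inconclusive + s$pct_na,
               rep(100, nrow(s)))
  # an always-right fixture gives a 100%-correct consensus
  perfect <- make_benchmark_table(
    20, profile = matrix(c(rep(1, 4), rep(0, 12)), 4, 4,
                         dimnames = list(c("SC", "TM", "PISA", "EPPIC"),
                                         c("correct", "incorrect", "inconclusive",
                                           "not_available"))),
    seed = 2)
  sp <- benchmark_summary(perfect$entries)
  expect_equal(sp$pct_correct[sp$method == "CONSENSUS"], 100)
  # the three-method consensus is the same engine without TM
  s3 <- benchmark_summary(b$entries, methods = c("SC", "PISA", "EPPIC"))
  expect_setequal(s3$method, c("SC", "PISA", "EPPIC", "CONSENSUS"))
})

test_that("agreement analysis attributes entries to exact method subsets", {
  e_all <- mk_entry("1AAA",
    SC = qs_annotation("A2", "C2", source = "SC"),
    TM = qs_annotation("A2", source = "TM"),
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  e_two_wrong <- mk_entry("1BBB",
    SC = qs_annotation("A2", "C2", source = "SC"),
    TM = qs_annotation("A2", source = "TM"),
    PISA = qs_annotation("A4", "D2", source = "PISA"),
    EPPIC = qs_annotation("A4", "D2", source = "EPPIC")
  )
  ag <- agreement_analysis(list(e_all, e_two_wrong))
  correct_all <- ag[ag$category == "correct" & ag$methods == "SC+TM+PISA+EPPIC", ]
  expect_equal(correct_all$count, 1L)
  wrong_pe <- ag[ag$category == "incorrect" & ag$methods == "PISA+EPPIC", ]
  expect_equal(wrong_pe$count, 1L)
  correct_st <- ag[ag$category == "correct" & ag$methods == "SC+TM", ]
  expect_equal(correct_st$count, 1L)
  # within a category the subset counts sum to the per-method totals
  for (cat in unique(ag$category)) {
    sub <- ag[ag$category == cat, ]
    per_method_total <- sum(vapply(list(e_all, e_two_wrong), function(e) {
      sum(vapply(c("SC", "TM", "PISA", "EPPIC"), function(m) {
        classify_outcome(e$method_results[[m]], e$reference) == cat
      }, logical(1)))
    }, numeric(1)))
    expect_equal(sum(sub$count * (nchar(gsub("[^+]", "", sub$methods)) + 1)),
                 per_method_total)
  }
  expect_equal(nrow(agreement_analysis(list())), 0L)
})

test_that("outliers are conclusive consensus calls contradicting the archive", {
  agree <- mk_entry("2AAA",
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  silent <- mk_entry("2BBB",
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A4", "D2", source = "EPPIC")
  )
  wrong_pdb <- mk_entry("2CCC", ref = c("A2", "C2"), pdb = c("A", "C1"),
    PISA = qs_annotation("A2", "C2", source = "PISA"),
    EPPIC = qs_annotation("A2", "C2", source = "EPPIC")
  )
  fl <- flag_outliers(list(agree, silent, wrong_pdb))
  expect_equal(unname(fl$flags[c("2AAA", "2CCC")]), c(FALSE, TRUE))
  expect_true(is.na(fl$flags[["2BBB"]]))  # inconclusive consensus: no evidence
  expect_equal(fl$fraction, 1 / 2)
})

test_that("annotation and benchmark tables round-trip through CSV", {
  b <- make_benchmark_table(25, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_table(b$entries, path)
  back <- read_benchmark_table(path)
  expect_length(back, 25L)
  expect_identical(benchmark_summary(back), benchmark_summary(b$entries))

  anns <- list(
    X1 = list(PDB = qs_annotation("A2", "C2", source = "PDB"),
              TM = qs_annotation("A2", source = "TM"),
              SC = qs_annotation(source = "SC", status = "not_available"))
  )
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(anns, p2)
  back2 <- read_annotation_csv(p2)
  expect_equal(format(back2$X1$PDB$stoichiometry), "A2")
  expect_equal(back2$X1$SC$status, "not_available")
  expect_null(back2$X1$TM$symmetry)
})
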