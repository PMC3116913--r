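prof <- function(...) marker_profile(...)[1, ]

test_that("early-arrest rules fire in order a, b, c, d", {
  expect_identical(
    is_early_arrest(prof("g", neurons = "MINUS", muscle = "MINUS",
                         gut = "MINUS", hypodermis = "MINUS")),
    "ALL_MARKERS_LOST")
  # the literature annotation overrides marker calls
  expect_identical(
    is_early_arrest(prof("g", neurons = "PLUS", muscle = "PLUS",
                         gut = "PLUS", hypodermis = "PLUS",
                         pre200_arrest = TRUE)),
    "PRE200_ANNOTATION")
  # all lost except the neuron panel, with ASER and bilateral marker lost
  expect_identical(
    is_early_arrest(prof("g", neurons = "PLUS", muscle = "MINUS",
                         gut = "MINUS", hypodermis = "MINUS",
                         aser = "MINUS", ase_bilateral = "MINUS")),
    "ALL_BUT_DOPAMINERGIC")
  # same tissue pattern without clean ASER/bilateral loss is not early arrest
  expect_null(
    is_early_arrest(prof("g", neurons = "PLUS", muscle = "MINUS",
                         gut = "MINUS", hypodermis = "MINUS",
                         aser = "PLUS_MINUS", ase_bilateral = "PLUS_MINUS")))
  expect_identical(
    is_early_arrest(prof("g", neurons = "MINUS", muscle = "MINUS",
                         gut = "PLUS", hypodermis = "MINUS")),
    "NEURONS_AND_MUSCLE_NOT_GUT")
  # blanks satisfy neither "lost" nor "intact"
  expect_null(is_early_arrest(prof("g")))
})

test_that("broad neuronal requires neuron loss with muscle intact", {
  # muscle and gut intact
  expect_true(is_broad_neuronal(
    prof("g", asel = "MINUS", neurons = "MINUS", muscle = "PLUS",
         gut = "PLUS", hypodermis = "MINUS")))
  # gut lost is also permitted
  expect_true(is_broad_neuronal(
    prof("g", asel = "MINUS", neurons = "MINUS", muscle = "PLUS",
         gut = "MINUS", hypodermis = "MINUS")))
  expect_false(is_broad_neuronal(
    prof("g", asel = "MINUS", neurons = "PLUS", muscle = "PLUS",
         gut = "PLUS", hypodermis = "MINUS")))
  # an intact hypodermal marker is inconsistent with ectodermal loss
  expect_false(is_broad_neuronal(
    prof("g", asel = "MINUS", neurons = "MINUS", muscle = "PLUS",
         gut = "MINUS", hypodermis = "PLUS")))
})

test_that("ASE-specific rules reproduce the worked examples", {
  # bilateral fate loss (che-1 pattern)
  r <- classify_ase_specific(prof("g", asel = "MINUS", aser = "MINUS",
                                  ase_bilateral = "MINUS"))
  expect_identical(r$top_class, "ASE_FATE_LOSS")
  # ASER wildtype but no bilateral marker expression (mdt-17 pattern)
  r <- classify_ase_specific(prof("g", asel = "MINUS", aser = "WT",
                                  ase_bilateral = "MINUS"))
  expect_identical(r$top_class, "ASE_FATE_LOSS")
  # ectopic ASEL lineage with extra ASE cells (ref-1 pattern)
  r <- classify_ase_specific(prof("g", asel = "PLUS", aser = "WT",
                                  ase_bilateral = "PLUS", ase_extra = TRUE))
  expect_identical(r$top_class, "ASE_LINEAGE")
  expect_identical(r$subclass, "ECTOPIC_ASEL")
  # one-sided loss with abnormal bilateral complement (lis-1 pattern)
  r <- classify_ase_specific(prof("g", asel = "MINUS", aser = "WT",
                                  ase_bilateral = "PLUS_MINUS"))
  expect_identical(r$top_class, "ASE_LINEAGE")
  expect_identical(r$subclass, "LOSS_ASEL")
  # 2-ASER asymmetry (lim-6 pattern)
  r <- classify_ase_specific(prof("g", asel = "MINUS", aser = "PLUS",
                                  ase_bilateral = "WT"))
  expect_identical(r$subclass, "CLASS_II")
  # mixed asymmetry (klp-16 pattern): ectopic ASEL, ASER unaffected
  r <- classify_ase_specific(prof("g", asel = "PLUS", aser = "WT",
                                  ase_bilateral = "WT"))
  expect_identical(r$subclass, "CLASS_IV")
  # ambiguous bilateral with clear contralateral swap (lsy-22 pattern)
  r <- classify_ase_specific(prof("g", asel = "PLUS", aser = "MINUS",
                                  ase_bilateral = "PLUS_MINUS"))
  expect_identical(r$top_class, "ASYMMETRY")
  expect_identical(r$subclass, "CLASS_I")
  # no usable evidence
  expect_null(classify_ase_specific(prof("g")))
})

test_that("both-ectopic profiles resolve to class II with a trace note", {
  r <- classify_ase_specific(prof("g", asel = "PLUS", aser = "PLUS",
                                  ase_bilateral = "WT"))
  expect_identical(r$subclass, "CLASS_II")
  expect_true("minor_class_I_also_observed" %in% r$notes)
})

test_that("the subclass mode controls the class I / class IV boundary", {
  # ectopic ASEL with ASER lost and bilateral marker unaffected
  p <- prof("g", asel = "PLUS", aser = "MINUS", ase_bilateral = "WT")
  expect_identical(classify_ase_specific(p, "table")$subclass, "CLASS_IV")
  expect_identical(classify_ase_specific(p, "text")$subclass, "CLASS_I")
  # the asymmetry total is unchanged between modes
  expect_identical(classify_ase_specific(p, "table")$top_class, "ASYMMETRY")
  expect_identical(classify_ase_specific(p, "text")$top_class, "ASYMMETRY")
})

test_that("the cascade sets aside mixed-direction clones", {
  cl <- categorize(prof("g", asel = "PLUS_MINUS"), direction = "MIXED")
  expect_identical(cl$top_class, "MIXED_UNRESOLVED")
})

test_that("the cascade orders early arrest before the ASE rules", {
  p <- prof("g", asel = "MINUS", aser = "MINUS", ase_bilateral = "MINUS",
            neurons = "MINUS", muscle = "MINUS", gut = "MINUS",
            hypodermis = "MINUS")
  cl <- categorize(p, "OFF")
  expect_identical(cl$top_class, "EARLY_ARREST")
  expect_identical(cl$subclass, "ALL_MARKERS_LOST")
  # the ectopic branch skips the tissue rules
  cl <- categorize(prof("g", asel = "PLUS", aser = "WT",
                        ase_bilateral = "WT"), "ECTOPIC")
  expect_identical(cl$top_class, "ASYMMETRY")
})

test_that("a profile matching no rule is UNCLASSIFIED with a full trace", {
  cl <- categorize(prof("g", asel = "WT", aser = "WT",
                        ase_bilateral = "WT"), "OFF")
  expect_identical(cl$top_class, "UNCLASSIFIED")
  expect_true(length(cl$rule_trace) >= 3)
})

test_that("every fixture row is assigned the class of its table", {
  for (cls in names(fixture_files)) {
    profiles <- read_marker_profiles(fixture_path(fixture_files[[cls]]))
    out <- categorize_profiles(profiles)
    expect_identical(out$top_class, rep(cls, nrow(profiles)), label = cls)
  }
})

test_that("asymmetry subclasses match the published class labels", {
  profiles <- read_marker_profiles(fixture_path(fixture_files[["ASYMMETRY"]]))
  out <- categorize_profiles(profiles)
  expected <- ifelse(grepl("Class I ", profiles$reported_phenotype),
                     "CLASS_I",
              ifelse(grepl("Class II", profiles$reported_phenotype),
                     "CLASS_II", "CLASS_IV"))
  expect_identical(out$subclass, expected)
  expect_identical(sum(out$subclass == "CLASS_II"), 11L)
})

test_that("per-class counts are invariant under row permutation", {
  profiles <- read_marker_profiles(fixture_path(fixture_files[["ASYMMETRY"]]))
  base <- table(categorize_profiles(profiles)$top_class)
  set.seed(2)
  for (i in 1:5) {
    shuffled <- profiles[sample(nrow(profiles)), , drop = FALSE]
    expect_identical(table(categorize_profiles(shuffled)$top_class), base)
  }
})

test_that("recorded rule traces replay to the same classification", {
  for (cls in names(fixture_files)) {
    profiles <- read_marker_profiles(fixture_path(fixture_files[[cls]]))
    out <- categorize_profiles(profiles)
    dir <- c(MINUS = "OFF", PLUS = "ECTOPIC", PLUS_MINUS = "MIXED",
             WT = "WT", NE = "WT", BLANK = "WT")[profiles$asel]
    for (i in seq_len(nrow(profiles))) {
      expect_true(replay_rule_trace(profiles[i, ], dir[[i]], out[i, ]))
    }
  }
})

test_that("summaries count classes and roll up stage tallies", {
  empty <- summarize_classifications(
    data.frame(gene_id = character(0), top_class = character(0),
               subclass = character(0)))
  expect_true(all(empty$class_counts == 0))

  profiles <- read_marker_profiles(fixture_path(fixture_files[["ASYMMETRY"]]))
  s <- summarize_classifications(
    categorize_profiles(profiles),
    stage_counts = list(
      direction = c(ectopic = 21, loss = 210, mixed = 14),
      early_arrest = c(all_lost = 87, pre200 = 11, all_but_dopaminergic = 8,
                       neurons_muscle_not_gut = 31)))
  expect_identical(unname(s$class_counts["ASYMMETRY"]), 20L)
  expect_identical(sum(s$class_counts), s$n)
  expect_equal(unname(s$stage_totals["direction"]), 245)
  expect_equal(unname(s$stage_totals["early_arrest"]), 137)
})
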