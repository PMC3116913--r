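noise_free <- function(n = 120, seed = 9) {
  simulation_params(
    n_clones = n, penetrance = 1, false_positive_rate = 0,
    class_proportions = c(WT = 0.25, EARLY_ARREST = 0.15,
                          BROAD_NEURONAL = 0.15, ASE_LINEAGE = 0.15,
                          ASE_FATE_LOSS = 0.15, ASYMMETRY = 0.15),
    seed = seed)
}

test_that("parameter validation rejects malformed settings", {
  expect_error(simulation_params(class_proportions = c(WT = 0.5)),
               "sum to 1")
  expect_error(simulation_params(class_proportions = c(BAD = 1)),
               "archetype classes")
  expect_error(simulation_params(penetrance = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(false_positive_rate = -0.1), "\\[0, 1\\]")
})

test_that("an empty screen simulates and scores", {
  scr <- simulate_screen(simulation_params(n_clones = 0))
  expect_length(scr$true_labels, 0)
  expect_identical(nrow(run_pipeline(scr)), 0L)
})

test_that("identical seeds give identical screens", {
  p <- simulation_params(n_clones = 50, seed = 123)
  expect_identical(simulate_screen(p), simulate_screen(p))
  # a different seed gives different well data
  p2 <- simulation_params(n_clones = 50, seed = 124)
  expect_false(identical(simulate_screen(p)$primary,
                         simulate_screen(p2)$primary))
})

test_that("earlier clones are unchanged when n_clones grows", {
  small <- simulate_screen(simulation_params(n_clones = 30, seed = 77))
  big <- simulate_screen(simulation_params(n_clones = 60, seed = 77))
  expect_identical(small$true_labels, big$true_labels[1:30])
  expect_identical(small$primary, big$primary[1:30, ])
})

test_that("noise-free profiles equal their class archetypes", {
  scr <- simulate_screen(noise_free())
  scored <- score_screen(scr)
  arch <- load_class_archetypes()
  rownames(arch) <- arch$top_class
  to_asel <- c(LOSS = "MINUS", ECTOPIC = "PLUS", NONE = "WT")
  for (i in seq_along(scr$true_labels)) {
    cls <- scr$true_labels[[i]]
    expect_identical(scored$profiles$asel[i], unname(to_asel[arch[cls, "primary"]]))
    expect_identical(scored$profiles$muscle[i],
                     if (arch[cls, "muscle"] == "LOST") "MINUS" else "PLUS")
  }
})

test_that("the noise-free pipeline recovers every true label", {
  scr <- simulate_screen(noise_free())
  rep <- recovery_report(scr, run_pipeline(scr))
  expect_equal(rep$accuracy, 1)
  # confusion row sums equal the true class counts
  expect_identical(unname(rowSums(rep$confusion)),
                   as.numeric(table(factor(scr$true_labels,
                                           rownames(rep$confusion)))))
})

test_that("recovery reporting validates the clone universe", {
  scr <- simulate_screen(noise_free(n = 10))
  res <- run_pipeline(scr)
  expect_error(recovery_report(scr, res[-1, ]), "different clone sets")
  # degenerate report: everything called WT
  allwt <- res
  allwt$inferred_class <- "WT"
  rep <- recovery_report(scr, allwt)
  expect_equal(rep$accuracy, mean(scr$true_labels == "WT"))
})

test_that("positive-call probability matches exhaustive enumeration", {
  expect_equal(positive_call_probability(0, 8, 3), 0)
  expect_equal(positive_call_probability(1, 8, 3), 1)
  expect_equal(positive_call_probability(0.5, 8, 3), 219 / 256)
  for (n in c(1, 4, 8, 12)) {
    k <- min(3, n)
    for (p in c(0.1, 0.2, 0.5, 0.8)) {
      expect_equal(positive_call_probability(p, n, k),
                   oracle_positive_probability(p, n, k),
                   tolerance = 1e-12)
    }
  }
  expect_error(positive_call_probability(1.5, 8, 3), "\\[0, 1\\]")
  expect_error(positive_call_probability(0.5, 8, 9), "k must")
})

test_that("positive-call probability is monotone in p and in n", {
  ps <- seq(0, 1, by = 0.05)
  vals <- positive_call_probability(ps, 8, 3)
  expect_true(all(diff(vals) >= 0))
  ns <- 3:12
  vals_n <- vapply(ns, function(n) positive_call_probability(0.3, n, 3),
                   numeric(1))
  expect_true(all(diff(vals_n) >= 0))
})

test_that("the empirical positive rate converges to the analytic rate", {
  p <- 0.3
  params <- simulation_params(
    n_clones = 10000, class_proportions = c(ASE_FATE_LOSS = 1),
    penetrance = p, false_positive_rate = 0, seed = 2024)
  scr <- simulate_screen(params)
  hits <- rowSums(scr$primary != "NONE")
  empirical <- mean(hits / ncol(scr$primary) >= 3 / 8)
  analytic <- positive_call_probability(p, 8, 3)
  se <- sqrt(analytic * (1 - analytic) / 10000)
  expect_lt(abs(empirical - analytic), 3 * se)
})

test_that("mean recovery accuracy is non-decreasing in penetrance", {
  acc <- vapply(c(0.3, 0.65, 1), function(pen) {
    mean(vapply(1:2, function(s) {
      params <- simulation_params(
        n_clones = 250, penetrance = pen, false_positive_rate = 0.02,
        class_proportions = c(WT = 0.4, EARLY_ARREST = 0.12,
                              BROAD_NEURONAL = 0.12, ASE_LINEAGE = 0.12,
                              ASE_FATE_LOSS = 0.12, ASYMMETRY = 0.12),
        seed = 100 + s)
      scr <- simulate_screen(params)
      recovery_report(scr, run_pipeline(scr))$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("well tables export in long format for every assay family", {
  scr <- simulate_screen(simulation_params(n_clones = 5, seed = 1))
  wt <- as_well_tables(scr)
  expect_identical(nrow(wt$primary), 5L * 8L)
  expect_identical(nrow(wt$ase), 5L * 6L * 2L)
  expect_identical(nrow(wt$tissue), 5L * 2L * 4L)
  expect_setequal(unique(wt$tissue$marker),
                  c("neurons", "muscle", "gut", "hypodermis"))
})
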