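demo_interval <- genomic_interval("II", 3e6, 18e6)

test_that("each stringency predicate removes failing records", {
  v <- data.frame(
    chromosome = "II", position = c(5e6, 5.1e6, 5.2e6, 5.3e6),
    ref = "C", alt = "T",
    quality = c(2, 5, 5, 5), multiplicity = c(1, 3, 1, 1),
    depth = c(10, 10, 2, 10), consequence = "protein_coding_change",
    stringsAsFactors = FALSE)
  out <- filter_variants(v, interval = demo_interval)
  expect_identical(out$position, 5.3e6)  # only the all-passing record
})

test_that("background variants are eliminated by exact key", {
  v <- data.frame(
    chromosome = "II", position = c(5e6, 5e6), ref = c("C", "C"),
    alt = c("T", "G"), quality = 9, multiplicity = 1, depth = 12,
    consequence = "protein_coding_change", stringsAsFactors = FALSE)
  bg <- v[1, ]
  out <- filter_variants(v, background = list(bg))
  # allele-aware matching removes only the matching alt
  expect_identical(out$alt, "G")
  # positional matching removes both
  out2 <- filter_variants(v, background = list(bg), positional_only = TRUE)
  expect_identical(nrow(out2), 0L)
})

test_that("the synthetic demonstration data funnels to 4 coding variants", {
  v <- read_variant_table(fixture_path("variants_ot86_synthetic.tsv"))
  bg <- read_variant_table(fixture_path("background_genomes_synthetic.tsv"))
  out <- filter_variants(v, interval = "II:3000000-18000000",
                         background = list(bg),
                         protein_coding_only = TRUE)
  expect_identical(nrow(out), 4L)
  expect_identical(sum(grepl("premature stop", out$annotation)), 1L)
})

test_that("interval endpoints are inclusive and 1-based", {
  v <- data.frame(
    chromosome = "II", position = c(3e6, 18e6, 2999999, 18000001),
    ref = "A", alt = "T", quality = 9, multiplicity = 1, depth = 9,
    consequence = "protein_coding_change", stringsAsFactors = FALSE)
  out <- filter_variants(v, interval = demo_interval)
  expect_identical(out$position, c(3e6, 18e6))
  expect_error(parse_interval("II:badcoords"), "cannot parse")
  expect_error(genomic_interval("II", 10, 5))
})

test_that("the filter is a subset, idempotent and threshold-monotone", {
  for (seed in 1:3) {
    v <- random_variants(80, seed)
    out <- filter_variants(v, interval = demo_interval)
    expect_true(all(rownames(out) %in% rownames(v)))
    expect_identical(filter_variants(out, interval = demo_interval), out)
    # tightening any threshold never grows the output
    for (th in list(filter_thresholds(min_quality = 10),
                    filter_thresholds(max_multiplicity = 0),
                    filter_thresholds(min_depth = 10))) {
      expect_lte(nrow(filter_variants(v, interval = demo_interval,
                                      thresholds = th)),
                 nrow(out))
    }
  }
})

test_that("with no interval and no background only thresholds act", {
  for (seed in 4:6) {
    v <- random_variants(60, seed)
    expect_identical(filter_variants(v), oracle_filter(v))
    expect_identical(
      filter_variants(v, interval = demo_interval,
                      background = list(variant_keys(v[1:5, ])),
                      protein_coding_only = TRUE),
      oracle_filter(v, interval = demo_interval,
                    bg_keys = variant_keys(v[1:5, ]), coding_only = TRUE))
  }
})

test_that("malformed variant rows are reported by address", {
  v <- random_variants(5, 1)
  v$depth[3] <- "many"
  expect_error(validate_variants(v), "row\\(s\\) 3")
  v2 <- random_variants(5, 1)
  v2$consequence[2] <- "bad"
  expect_error(validate_variants(v2), "row\\(s\\) 2")
})

test_that("the pooled z-test matches its closed form and an oracle", {
  r <- two_proportion_ztest(30, 50, 10, 50)
  expect_equal(r$z, 0.4 / sqrt(0.4 * 0.6 * (2 / 50)), tolerance = 1e-12)
  expect_equal(r$z, 4.0825, tolerance = 1e-4)
  # independent oracle: the uncorrected chi-square test statistic is z^2
  pt <- stats::prop.test(c(30, 10), c(50, 50), correct = FALSE)
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, pt$p.value, tolerance = 1e-10)

  same <- two_proportion_ztest(5, 20, 10, 40)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("the z-test is antisymmetric and flags degenerate input", {
  a <- two_proportion_ztest(12, 40, 5, 30)
  b <- two_proportion_ztest(5, 30, 12, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  d <- two_proportion_ztest(0, 50, 0, 50)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  d2 <- two_proportion_ztest(50, 50, 50, 50)
  expect_true(d2$degenerate)
})

test_that("Bonferroni adjustment multiplies and caps at 1", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni_adjust(c(0.5, 0.9)), c(1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.1)), "\\[0, 1\\]")
})
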