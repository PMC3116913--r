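# Independent oracles used across the suite. Each re-derives the expected
# behaviour from the scoring definitions by direct transliteration or
# exhaustive enumeration, without calling the package implementation.

fixture_path <- function(name) {
  system.file("extdata", name, package = "asescreen", mustWork = TRUE)
}

fixture_files <- c(
  BROAD_NEURONAL = "profiles_broad_neuronal.tsv",
  ASE_LINEAGE = "profiles_ase_lineage.tsv",
  ASE_FATE_LOSS = "profiles_ase_fate_loss.tsv",
  ASYMMETRY = "profiles_asymmetry.tsv"
)

# direction of a clone from raw counts, read straight off the scoring
# definitions: sign pattern of the two scores, then the ratio adjustment
# for mixed clones (inclusive at 0.25)
oracle_direction <- function(off_count, ect_count, n_wells) {
  off <- off_count / n_wells
  ect <- ect_count / n_wells
  if (off == 0 && ect == 0) "WT"
  else if (off > 0 && ect == 0) "OFF"
  else if (ect > 0 && off == 0) "ECTOPIC"
  else if (ect / off <= 0.25) "OFF"
  else if (off / ect <= 0.25) "ECTOPIC"
  else "MIXED"
}

# clone-level ASER category truth table
oracle_aser <- function(off, ect, n) {
  if (n == 0) "BLANK"
  else if (off > 0 && ect == 0) "OFF"
  else if (ect > 0 && off == 0) "ECTOPIC"
  else if (off > 0 && ect > 0) "MIXED"
  else "WT"
}

# clone-level bilateral-ASE category truth table; both-off-classes without
# ectopic evidence resolves to the more severe TWO_OFF
oracle_bilateral <- function(off2, off1, ect, mixed, n) {
  if (n == 0) "BLANK"
  else if (mixed > 0 || ((off2 > 0 || off1 > 0) && ect > 0)) "MIXED"
  else if (off2 > 0) "TWO_OFF"
  else if (off1 > 0) "ONE_OFF"
  else if (ect > 0) "ECTOPIC"
  else "WT"
}

# P[at least k of n wells show the phenotype] by exhaustive enumeration of
# all 2^n well outcomes
oracle_positive_probability <- function(p, n, k) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  hits <- rowSums(outcomes)
  weights <- p^hits * (1 - p)^(n - hits)
  sum(weights[hits >= k])
}

# brute-force variant filter: row-by-row predicate evaluation
oracle_filter <- function(variants, interval = NULL, bg_keys = character(0),
                          min_q = 3, max_m = 1, min_d = 3,
                          coding_only = FALSE) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ok <- v$quality >= min_q && v$multiplicity <= max_m && v$depth >= min_d
    if (ok && !is.null(interval)) {
      ok <- v$chromosome == interval$chromosome &&
        v$position >= interval$start && v$position <= interval$end
    }
    if (ok && length(bg_keys) > 0) {
      key <- paste(v$chromosome, v$position, v$ref, v$alt, sep = ":")
      ok <- !(key %in% bg_keys)
    }
    if (ok && coding_only) ok <- v$consequence == "protein_coding_change"
    keep[i] <- ok
  }
  variants[keep, , drop = FALSE]
}

# random variant table for property tests
random_variants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chromosome = sample(c("I", "II", "III"), n, replace = TRUE),
    position = sample(1:5e6, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    quality = sample(0:30, n, replace = TRUE),
    multiplicity = sample(0:3, n, replace = TRUE),
    depth = sample(0:20, n, replace = TRUE),
    consequence = sample(c("protein_coding_change", "non_coding", "other"),
                         n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
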