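# Whole-genome-sequencing candidate-variant filtering for mutant cloning:
# stringency thresholds on quality / loci multiplicity / sequencing depth,
# restriction to the genetic mapping interval, elimination of variants seen
# in background genomes, and (optionally) restriction to protein-coding
# changes. Plus the small proportion-comparison statistics used for rescue
# scoring.

#' Variant-filter stringency thresholds
#'
#' Defaults are the stringency criteria of the mapping pipeline: quality
#' score >= 3, loci multiplicity <= 1 (reads mapping to at most one locus),
#' sequencing depth >= 3 supporting reads. Loci multiplicity is consumed as
#' a provided column of the variant caller's output, never recomputed.
#'
#' @param min_quality minimum quality score (default 3).
#' @param max_multiplicity maximum loci multiplicity (default 1).
#' @param min_depth minimum sequencing depth (default 3).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_quality = 3, max_multiplicity = 1,
                              min_depth = 3) {
  stopifnot(min_quality >= 0, max_multiplicity >= 0, min_depth >= 0)
  structure(list(min_quality = min_quality,
                 max_multiplicity = max_multiplicity,
                 min_depth = min_depth),
            class = "filter_thresholds")
}

#' A genomic mapping interval
#'
#' Coordinates are 1-based and both endpoints are inclusive, matching
#' conventional variant-report coordinates.
#'
#' @param chromosome chromosome name (e.g. `"II"`).
#' @param start,end 1-based inclusive endpoints, `start <= end`.
#' @return list of class `genomic_interval`.
#' @export
genomic_interval <- function(chromosome, start, end) {
  stopifnot(is.character(chromosome), length(chromosome) == 1,
            start >= 1, start <= end)
  structure(list(chromosome = chromosome, start = as.numeric(start),
                 end = as.numeric(end)),
            class = "genomic_interval")
}

#' Parse an interval string of the form `"chrom:start-end"`
#' @param text e.g. `"II:3000000-18000000"`.
#' @return a `genomic_interval`.
#' @export
parse_interval <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4) {
    stop("cannot parse interval ", sQuote(text),
         " (expected chrom:start-end)", call. = FALSE)
  }
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

.variant_cols <- c("chromosome", "position", "ref", "alt", "quality",
                   "multiplicity", "depth", "consequence")
.consequences <- c("protein_coding_change", "non_coding", "other")

#' Read a variant table from a tab-separated file
#'
#' Minimal VCF-like TSV with header columns `chromosome`, `position`, `ref`,
#' `alt`, `quality`, `multiplicity`, `depth`, `consequence` (one of
#' `protein_coding_change`, `non_coding`, `other`) and optionally
#' `annotation`. `#` lines are comments.
#'
#' @param path path to the TSV file.
#' @return validated data frame of variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_variants(df)
}

#' Validate a variant table
#' @param variants data frame of variant records.
#' @return the validated data frame.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("position", "quality", "multiplicity", "depth")) {
    v <- variants[[col]]
    bad <- is.na(suppressWarnings(as.numeric(v)))
    if (any(bad)) {
      stop("non-numeric ", sQuote(col), " in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    if (!is.numeric(v)) variants[[col]] <- as.numeric(v)
  }
  if (any(variants$position < 1)) {
    stop("positions are 1-based; row(s) ",
         paste(which(variants$position < 1), collapse = ", "),
         call. = FALSE)
  }
  if (any(variants$depth < 0)) {
    stop("negative depth in row(s) ",
         paste(which(variants$depth < 0), collapse = ", "), call. = FALSE)
  }
  bad <- !(variants$consequence %in% .consequences)
  if (any(bad)) {
    stop("unknown consequence in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  variants
}

#' Exact variant keys used for background matching
#' @param variants variant data frame.
#' @param positional_only match on (chromosome, position) only, ignoring
#'   alleles (default `FALSE`: exact (chromosome, position, ref, alt) keys).
#' @return character vector of keys.
#' @export
variant_keys <- function(variants, positional_only = FALSE) {
  if (positional_only) {
    paste(variants$chromosome, variants$position, sep = ":")
  } else {
    paste(variants$chromosome, variants$position, variants$ref,
          variants$alt, sep = ":")
  }
}

#' Filter candidate variants for mutant cloning
#'
#' A variant is retained iff it passes all stringency thresholds
#' (quality >= min, multiplicity <= max, depth >= min), lies within the
#' mapping interval on the right chromosome (when an interval is given), is
#' absent from every background genome's variant set (variants also found in
#' other sequenced genomes are considered background and eliminated), and
#' (when requested) is a protein-coding change. Input order is preserved and
#' the output is always a subset of the input.
#'
#' @param variants data frame of variant records (see
#'   [read_variant_table()]).
#' @param interval optional `genomic_interval` (or `"chrom:start-end"`
#'   string); `NULL` skips the interval predicate.
#' @param background list of background variant sets: each element either a
#'   variant data frame or a character vector of keys as produced by
#'   [variant_keys()].
#' @param thresholds a `filter_thresholds` object.
#' @param protein_coding_only keep only `protein_coding_change` records.
#' @param positional_only match background by (chromosome, position) only;
#'   by default matching is allele-aware.
#' @return the retained rows of `variants`.
#' @export
filter_variants <- function(variants, interval = NULL,
                            background = list(),
                            thresholds = filter_thresholds(),
                            protein_coding_only = FALSE,
                            positional_only = FALSE) {
  variants <- validate_variants(variants)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (is.character(interval)) interval <- parse_interval(interval)

  keep <- variants$quality >= thresholds$min_quality &
    variants$multiplicity <= thresholds$max_multiplicity &
    variants$depth >= thresholds$min_depth
  if (!is.null(interval)) {
    stopifnot(inherits(interval, "genomic_interval"))
    keep <- keep & variants$chromosome == interval$chromosome &
      variants$position >= interval$start &
      variants$position <= interval$end
  }
  if (length(background) > 0) {
    bg_keys <- unique(unlist(lapply(background, function(b) {
      if (is.data.frame(b)) variant_keys(b, positional_only) else
        as.character(b)
    })))
    keep <- keep & !(variant_keys(variants, positional_only) %in% bg_keys)
  }
  if (protein_coding_only) {
    keep <- keep & variants$consequence == "protein_coding_change"
  }
  variants[keep, , drop = FALSE]
}

#' Two-proportion z-test with pooled variance
#'
#' Compares two binomial proportions `k1/n1` and `k2/n2` with the pooled
#' z statistic `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p` the pooled
#' proportion, and a two-sided normal p-value. When the pooled proportion is
#' 0 or 1 the variance is zero: the comparison is degenerate (all outcomes
#' identical), reported as `z = 0`, `p = 1` with `degenerate = TRUE`.
#'
#' @param k1,n1,k2,n2 successes and trials of the two groups.
#' @return list with `z`, `p_value`, `estimate` (the two proportions) and
#'   `degenerate`.
#' @export
#' @examples
#' two_proportion_ztest(30, 50, 10, 50)$z  # about 4.082
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(z = 0, p_value = 1, estimate = c(p1 = p1, p2 = p2),
                degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       estimate = c(p1 = p1, p2 = p2), degenerate = FALSE)
}

#' Bonferroni adjustment of a vector of p-values
#'
#' Each p-value is multiplied by the number of comparisons and capped at 1;
#' order is preserved. Backed by [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "bonferroni")
}
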