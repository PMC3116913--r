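# Primary genome-wide ASEL screen: well-level scoring, positive calling and
# direction classification. Clones are scored in duplicate in the primary
# pass and re-screened six additional times when a phenotype is seen, so a
# fully scored clone has 8 wells; scores are always defined over the wells
# actually scored, with no imputation for missing wells.

.ASEL_WELL_CALLS <- c("LOSS", "ECTOPIC", "NONE")

#' Compute ASEL loss and ectopic scores for one clone
#'
#' The loss score is the number of wells showing "loss of ASEL" divided by
#' the total number of wells scored; the ectopic score is the analogous
#' fraction of "ectopic ASEL" wells.
#'
#' @param wells character vector of well-level calls, each one of
#'   `"LOSS"`, `"ECTOPIC"`, `"NONE"`. At least one well is required: no
#'   score is defined over zero wells.
#' @return a list of class `asel_scores` with `off_score`, `ectopic_score`,
#'   `off_count`, `ectopic_count` and `n_wells`.
#' @export
#' @examples
#' compute_asel_scores(c("LOSS", "LOSS", "NONE", "NONE"))$off_score  # 0.5
compute_asel_scores <- function(wells) {
  wells <- as.character(wells)
  if (length(wells) == 0L) {
    stop("at least one scored well is required", call. = FALSE)
  }
  bad <- !(wells %in% .ASEL_WELL_CALLS)
  if (any(bad)) {
    stop("unknown well call(s): ",
         paste(sQuote(unique(wells[bad])), collapse = ", "), call. = FALSE)
  }
  n <- length(wells)
  off <- sum(wells == "LOSS")
  ect <- sum(wells == "ECTOPIC")
  structure(
    list(off_score = off / n, ectopic_score = ect / n,
         off_count = off, ectopic_count = ect, n_wells = n),
    class = "asel_scores"
  )
}

#' Call a clone positive in the primary screen
#'
#' A positive clone has a phenotype (loss or ectopic ASEL) in at least 3 of
#' 8 wells scored. For clones scored in a different number of wells the
#' fraction criterion (phenotype fraction >= 3/8) is the default; a raw
#' count criterion (>= `min_count` phenotype wells) is also available.
#'
#' @param scores an `asel_scores` object from [compute_asel_scores()].
#' @param criterion `"fraction"` (default) or `"count"`.
#' @param min_fraction positivity threshold for the fraction criterion;
#'   default `3/8`.
#' @param min_count positivity threshold for the count criterion; default 3.
#' @return logical scalar.
#' @export
call_positive <- function(scores, criterion = c("fraction", "count"),
                          min_fraction = 3 / 8, min_count = 3L) {
  stopifnot(inherits(scores, "asel_scores"))
  criterion <- match.arg(criterion)
  hits <- scores$off_count + scores$ectopic_count
  if (criterion == "fraction") {
    hits / scores$n_wells >= min_fraction
  } else {
    hits >= min_count
  }
}

#' Classify the direction of a clone's primary ASEL phenotype
#'
#' Directions follow the sign pattern of the two scores: `OFF` when only the
#' loss score is positive, `ECTOPIC` when only the ectopic score is
#' positive, `WT` when both are zero. Clones with both scores positive are
#' `MIXED`, then reclassified by the score ratio: if
#' ectopic/off <= `ratio_cutoff` the clone is moved to `OFF`; if
#' off/ectopic <= `ratio_cutoff` it is moved to `ECTOPIC`. Ties at exactly
#' the cutoff reclassify (the inequality is inclusive).
#'
#' @param scores an `asel_scores` object.
#' @param ratio_cutoff reclassification cutoff for mixed clones; default 0.25.
#' @return one of `"OFF"`, `"ECTOPIC"`, `"MIXED"`, `"WT"`.
#' @export
#' @examples
#' s <- compute_asel_scores(c(rep("LOSS", 4), "ECTOPIC", rep("NONE", 3)))
#' classify_asel_direction(s)  # ratio 0.25 -> moved to OFF
classify_asel_direction <- function(scores, ratio_cutoff = 0.25) {
  stopifnot(inherits(scores, "asel_scores"))
  off <- scores$off_score
  ect <- scores$ectopic_score
  if (off == 0 && ect == 0) return("WT")
  if (off > 0 && ect == 0) return("OFF")
  if (ect > 0 && off == 0) return("ECTOPIC")
  if (ect / off <= ratio_cutoff) return("OFF")
  if (off / ect <= ratio_cutoff) return("ECTOPIC")
  "MIXED"
}

#' Score a table of primary-screen wells, one clone per row of output
#'
#' @param well_table data frame with columns `clone_id` and `well_call`
#'   (one row per scored well, calls as in [compute_asel_scores()]).
#' @return data frame with one row per clone: counts, scores, `positive`
#'   and `direction`.
#' @export
score_primary_table <- function(well_table) {
  stopifnot(is.data.frame(well_table),
            all(c("clone_id", "well_call") %in% names(well_table)))
  clones <- unique(well_table$clone_id)
  rows <- lapply(clones, function(cl) {
    s <- compute_asel_scores(
      well_table$well_call[well_table$clone_id == cl])
    data.frame(clone_id = cl, n_wells = s$n_wells,
               off_count = s$off_count, ectopic_count = s$ectopic_count,
               off_score = s$off_score, ectopic_score = s$ectopic_score,
               positive = call_positive(s),
               direction = classify_asel_direction(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
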