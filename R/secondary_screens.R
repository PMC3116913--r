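# Secondary screens: the 6-well ASE screen (ASER-specific reporter plus a
# bilateral ASE reporter) and the 2-well tissue-marker screen, plus the
# removal rule for clones whose embryonic lethality does not repeat.

#' Classify a clone's ASER phenotype from well counts
#'
#' The ASER reporter is scored per well as "loss of ASER" or "ectopic ASER";
#' clone-level categories follow the sign pattern of the two scores, with at
#' least one scored well required for any call. Zero wells means the assay
#' was not done (`BLANK`).
#'
#' @param off_count,ectopic_count number of wells with loss / ectopic calls.
#' @param n_wells number of wells scored (0 is legal and yields `BLANK`).
#' @return one of `"OFF"`, `"ECTOPIC"`, `"MIXED"`, `"WT"`, `"BLANK"`.
#' @export
classify_aser <- function(off_count, ectopic_count, n_wells) {
  stopifnot(off_count >= 0, ectopic_count >= 0, n_wells >= 0,
            off_count + ectopic_count <= n_wells)
  if (n_wells == 0L) return("BLANK")
  off <- off_count > 0
  ect <- ectopic_count > 0
  if (off && !ect) return("OFF")
  if (ect && !off) return("ECTOPIC")
  if (off && ect) return("MIXED")
  "WT"
}

#' Classify a clone's bilateral-ASE phenotype from well counts
#'
#' Wells of the bilateral reporter are called "off" (both ASEs off; here
#' `off2`), "1-on" (one ASE off; counted as `off1` evidence), "2-on"
#' (wildtype), "ectopic ASEs" or "mixed" (any combination within one well).
#' Clone-level categories: a single-signal category when exactly one score
#' class is positive; `MIXED` when an off class co-occurs with ectopic
#' evidence or when any well was itself called "mixed"; `WT` when all scores
#' are zero; `BLANK` when no wells were scored. When both off classes are
#' positive without ectopic evidence the more severe `TWO_OFF` is reported.
#'
#' @param off2_count wells with both ASE cells off.
#' @param off1_count wells with exactly one ASE cell off ("1-on" wells).
#' @param ectopic_count wells with ectopic ASE cells.
#' @param mixed_count wells called "mixed".
#' @param n_wells number of wells scored.
#' @return one of `"TWO_OFF"`, `"ONE_OFF"`, `"ECTOPIC"`, `"MIXED"`, `"WT"`,
#'   `"BLANK"`.
#' @export
classify_ase_bilateral <- function(off2_count, off1_count, ectopic_count,
                                   mixed_count, n_wells) {
  stopifnot(off2_count >= 0, off1_count >= 0, ectopic_count >= 0,
            mixed_count >= 0, n_wells >= 0,
            off2_count + off1_count + ectopic_count + mixed_count <= n_wells)
  if (n_wells == 0L) return("BLANK")
  any_off <- off2_count > 0 || off1_count > 0
  if (mixed_count > 0 || (any_off && ectopic_count > 0)) return("MIXED")
  if (off2_count > 0) return("TWO_OFF")
  if (off1_count > 0) return("ONE_OFF")
  if (ectopic_count > 0) return("ECTOPIC")
  "WT"
}

.TISSUE_WELL_SCORES <- c(OFF = 0, MIXED = 0.25, ON = 0.5)

#' Score a clone in the tissue-marker screen
#'
#' Each of the (at most two) wells receives a fixed per-well score: tissue
#' OFF 0, tissue Mixed 0.25, tissue ON 0.5. The clone score is the sum of
#' the well scores (range 0 to 1 over two wells) and the clone is "ON" for
#' the tissue iff the score exceeds 0.5; a score of at most 0.5 is "OFF".
#' A clone with a single scored well uses that one score (its range is then
#' 0 to 0.5, so the status can only be OFF); such clones are flagged.
#'
#' @param wells character vector (length 1 or 2) of well calls `"OFF"`,
#'   `"MIXED"`, `"ON"`.
#' @return list of class `tissue_status`: `status` (`"ON"`/`"OFF"`),
#'   `clone_score`, `n_wells`, `single_well` flag.
#' @export
#' @examples
#' score_tissue(c("ON", "ON"))$clone_score   # 1, the attainable maximum
#' score_tissue(c("MIXED", "MIXED"))$status  # "OFF" (score 0.5 is not > 0.5)
score_tissue <- function(wells) {
  wells <- as.character(wells)
  if (length(wells) < 1L || length(wells) > 2L) {
    stop("the tissue screen scores one or two wells per clone",
         call. = FALSE)
  }
  bad <- !(wells %in% names(.TISSUE_WELL_SCORES))
  if (any(bad)) {
    stop("unknown tissue well call(s): ",
         paste(sQuote(unique(wells[bad])), collapse = ", "), call. = FALSE)
  }
  score <- sum(.TISSUE_WELL_SCORES[wells])
  structure(
    list(status = if (score > 0.5) "ON" else "OFF",
         clone_score = unname(score), n_wells = length(wells),
         single_well = length(wells) == 1L),
    class = "tissue_status"
  )
}

#' Remove clones whose embryonic lethality does not repeat
#'
#' A clone flagged "ne" (not embryonic lethal) in 3 or more of the (up to 6)
#' strains screened is taken off the candidate list, on the premise of a
#' non-repeatable embryonic phenotype. The strain panel is supplied by the
#' caller, not hard-coded.
#'
#' @param ne_flags named list: gene id -> logical vector of per-strain "ne"
#'   flags (at most `max_strains` entries each; an empty vector keeps the
#'   gene).
#' @param min_ne number of "ne" strains at which a gene is removed
#'   (default 3).
#' @param max_strains maximum legal number of strain flags (default 6).
#' @return list with character vectors `kept` and `removed`; the two are
#'   disjoint and together exhaust the input genes.
#' @export
apply_ne_filter <- function(ne_flags, min_ne = 3L, max_strains = 6L) {
  stopifnot(is.list(ne_flags))
  if (length(ne_flags) > 0 && is.null(names(ne_flags))) {
    stop("ne_flags must be a named list (gene -> flags)", call. = FALSE)
  }
  too_many <- vapply(ne_flags, length, integer(1)) > max_strains
  if (any(too_many)) {
    stop("more than ", max_strains, " strain flags for gene(s): ",
         paste(names(ne_flags)[too_many], collapse = ", "), call. = FALSE)
  }
  n_ne <- vapply(ne_flags, function(x) sum(as.logical(x)), integer(1))
  removed <- names(ne_flags)[n_ne >= min_ne]
  kept <- setdiff(names(ne_flags), removed)
  list(kept = kept, removed = removed)
}

#' Score an ASE-screen well table into clone-level marker calls
#'
#' Aggregates per-well calls of the ASER reporter (`"LOSS"`, `"ECTOPIC"`,
#' `"NONE"`) and of the bilateral ASE reporter (`"OFF"`, `"ONE_ON"`,
#' `"TWO_ON"`, `"ECTOPIC"`, `"MIXED"`) into the marker-call vocabulary of a
#' profile table. `"1-on"` wells count as one-ASE-off evidence; `"2-on"`
#' wells are wildtype. A clone whose bilateral call is ectopic is flagged
#' as showing extra ASE cells.
#'
#' @param well_table data frame with columns `clone_id`, `marker`
#'   (`"aser"` or `"ase"`) and `well_call`.
#' @return data frame with one row per clone: `aser`, `ase_bilateral`
#'   marker calls and `ase_extra` flag.
#' @export
score_ase_table <- function(well_table) {
  stopifnot(is.data.frame(well_table),
            all(c("clone_id", "marker", "well_call") %in% names(well_table)))
  clones <- unique(well_table$clone_id)
  to_call <- c(OFF = "MINUS", ECTOPIC = "PLUS", MIXED = "PLUS_MINUS",
               WT = "WT", BLANK = "BLANK",
               TWO_OFF = "MINUS", ONE_OFF = "MINUS")
  rows <- lapply(clones, function(cl) {
    sub <- well_table[well_table$clone_id == cl, , drop = FALSE]
    rw <- sub$well_call[sub$marker == "aser"]
    aser_cat <- classify_aser(sum(rw == "LOSS"), sum(rw == "ECTOPIC"),
                              length(rw))
    bw <- sub$well_call[sub$marker == "ase"]
    ase_cat <- classify_ase_bilateral(
      off2_count = sum(bw == "OFF"), off1_count = sum(bw == "ONE_ON"),
      ectopic_count = sum(bw == "ECTOPIC"), mixed_count = sum(bw == "MIXED"),
      n_wells = length(bw))
    data.frame(clone_id = cl,
               aser = to_call[[aser_cat]],
               ase_bilateral = to_call[[ase_cat]],
               ase_extra = ase_cat == "ECTOPIC",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
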