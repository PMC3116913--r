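# The decision cascade that turns a gene's marker profile into one of the
# screen's phenotypic classes. The cascade mirrors the screening sequence:
# a mixed primary direction is set aside; loss-direction genes pass through
# the tissue screen (early arrest, then broad neuronal defects) before the
# ASE-specific rules; ectopic-direction genes go to the ASE rules directly.
#
# Marker-call conventions used throughout: BLANK ("not done") satisfies
# neither a "lost" nor an "intact" requirement; "lost" means MINUS or, where
# noted, PLUS_MINUS (a mixed call contains loss evidence); "intact" means
# PLUS.

.lost <- function(call, strict = FALSE) {
  if (strict) call == "MINUS" else call %in% c("MINUS", "PLUS_MINUS")
}
.intact <- function(call) call == "PLUS"

# ---------------------------------------------------------------------------
# Early arrest
# ---------------------------------------------------------------------------

#' Test a profile against the early-arrest rules
#'
#' A gene is classified as early arrest (arrest before terminal
#' differentiation) by the first matching of four rules:
#' \describe{
#'   \item{a `ALL_MARKERS_LOST`}{knock-down lost all tissue markers tested
#'     (neurons, muscle, gut, hypodermis; a marker not done never counts as
#'     lost).}
#'   \item{b `PRE200_ANNOTATION`}{the gene was previously characterised as
#'     arresting before the 200-cell stage, regardless of marker calls.}
#'   \item{c `ALL_BUT_DOPAMINERGIC`}{all markers lost except the
#'     dopaminergic/cholinergic neuron marker, presumed non-reproducibility
#'     of the RNAi; as these genes also lose the ASER and bilateral ASE
#'     markers, the rule additionally requires both of those lost.}
#'   \item{d `NEURONS_AND_MUSCLE_NOT_GUT`}{neurons and muscle lost but gut
#'     intact (the gut marker is expressed early, before terminal neuronal
#'     differentiation).}
#' }
#'
#' @param profile one row of a `marker_profile` data frame (or a list with
#'   the same fields).
#' @return the matching rule label, or `NULL` if no rule matches.
#' @export
is_early_arrest <- function(profile) {
  p <- as.list(profile)
  tissues_lost <- vapply(c("neurons", "muscle", "gut", "hypodermis"),
                         function(m) .lost(p[[m]], strict = TRUE), logical(1))
  if (all(tissues_lost)) return("ALL_MARKERS_LOST")
  if (isTRUE(p$pre200_arrest)) return("PRE200_ANNOTATION")
  if (!tissues_lost[["neurons"]] && .intact(p$neurons) &&
      tissues_lost[["muscle"]] && tissues_lost[["gut"]] &&
      tissues_lost[["hypodermis"]] &&
      .lost(p$aser, strict = TRUE) &&
      .lost(p$ase_bilateral, strict = TRUE)) {
    return("ALL_BUT_DOPAMINERGIC")
  }
  if (tissues_lost[["neurons"]] && tissues_lost[["muscle"]] &&
      .intact(p$gut)) {
    return("NEURONS_AND_MUSCLE_NOT_GUT")
  }
  NULL
}

# ---------------------------------------------------------------------------
# Broad neuronal defects
# ---------------------------------------------------------------------------

#' Test a profile for a broad neuronal defect
#'
#' In addition to loss of the ASEL marker, the dopaminergic/cholinergic
#' neuron markers are absent while muscle (and possibly gut) is unaffected;
#' consistent with a loss of ectodermal tissue, the hypodermal marker must
#' not be intact. Gut may be intact, lost, unscorable or not done.
#'
#' @param profile one row of a `marker_profile` data frame.
#' @return logical scalar.
#' @export
is_broad_neuronal <- function(profile) {
  p <- as.list(profile)
  .lost(p$asel) &&
    .lost(p$neurons, strict = TRUE) &&
    .intact(p$muscle) &&
    !.intact(p$hypodermis)
}

# ---------------------------------------------------------------------------
# ASE-specific rules
# ---------------------------------------------------------------------------

# ectopic evidence on one side of the ASE pair: a clean ectopic call, or a
# ">2 cells" observation accompanying a mixed call
.ectopic_evidence <- function(call, extra) .intact(call) || isTRUE(extra)

#' Classify a profile within the ASE-specific branch
#'
#' Applied to genes that passed the primary screen and were re-screened with
#' the ASER and bilateral ASE reporters. The rules, in order:
#'
#' 1. *Asymmetry amendment* — when the bilateral-marker result is ambiguous
#'    (`PLUS_MINUS` or `NE`) but the gene clearly shows loss of the ASEL
#'    marker together with ectopic ASER evidence (an ectopic call or an
#'    extra ASER-marker-positive cell), or vice versa, it is an asymmetry
#'    defect. Extra ASE cells on the bilateral marker, or a clean ectopic
#'    call carrying an extra-cell flag on the swapped side, indicate a
#'    lineage defect instead and block the amendment.
#' 2. *Lineage (extra cells)* — any ">2 cells" flag marks an ectopic
#'    ASEL/ASER lineage (ASE fate in general is not lost).
#' 3. *Fate loss* — loss of both the ASEL and ASER cell-fate markers, or
#'    loss of ASEL together with loss of the bilateral ASE marker (covering
#'    the gene wildtype for ASER that nonetheless expressed no bilateral
#'    marker).
#' 4. *Lineage (one-sided loss)* — one side lost with the other unaffected
#'    while the bilateral marker shows an abnormal cell complement.
#' 5. *Asymmetry (bilateral wildtype)* — the bilateral marker is unaffected
#'    but one of the side-specific markers is ectopic.
#'
#' Asymmetry subclasses: ectopic ASER evidence gives `CLASS_II` (2-ASER; a
#' both-ectopic profile is also `CLASS_II`, with the minor 2-ASEL phenotype
#' noted in the rule trace). Ectopic ASEL with ASER lost gives `CLASS_I`
#' (2-ASEL) under `subclass_mode = "text"`; under the default
#' `subclass_mode = "table"` a Class I call additionally requires the
#' ambiguous-bilateral amendment, so an ectopic-ASEL gene with a wildtype
#' bilateral marker is `CLASS_IV` (mixed) even when ASER is lost. Ectopic
#' ASEL with ASER unaffected is `CLASS_IV` in both modes.
#'
#' @param profile one row of a `marker_profile` data frame.
#' @param subclass_mode `"table"` (default) or `"text"`; see above.
#' @return list with `top_class`, `subclass` (or `NA`), `rule` (identifier
#'   of the rule that fired) and `notes` (character vector, possibly empty),
#'   or `NULL` when the profile has no usable ASE-screen evidence.
#' @export
classify_ase_specific <- function(profile,
                                  subclass_mode = c("table", "text")) {
  subclass_mode <- match.arg(subclass_mode)
  p <- as.list(profile)
  if (p$aser == "BLANK" && p$ase_bilateral == "BLANK" &&
      p$asel == "BLANK") {
    return(NULL)
  }

  res <- function(top, sub = NA_character_, rule, notes = character(0)) {
    list(top_class = top, subclass = sub, rule = rule, notes = notes)
  }

  # 1. ambiguous-bilateral asymmetry amendment
  ambiguous <- p$ase_bilateral %in% c("PLUS_MINUS", "NE")
  if (ambiguous && !isTRUE(p$ase_extra)) {
    swap_to_aser <- .lost(p$asel) &&
      .ectopic_evidence(p$aser, p$aser_extra) &&
      !(.intact(p$aser) && isTRUE(p$aser_extra))
    swap_to_asel <- .lost(p$aser) &&
      .ectopic_evidence(p$asel, p$asel_extra) &&
      !(.intact(p$asel) && isTRUE(p$asel_extra))
    if (swap_to_aser) {
      return(res("ASYMMETRY", "CLASS_II", "asymmetry_ambiguous_bilateral"))
    }
    if (swap_to_asel) {
      return(res("ASYMMETRY", "CLASS_I", "asymmetry_ambiguous_bilateral"))
    }
  }

  # 2. lineage defect evidenced by extra marker-positive cells
  if (isTRUE(p$asel_extra) || isTRUE(p$aser_extra) || isTRUE(p$ase_extra)) {
    sub <- if (.intact(p$asel)) "ECTOPIC_ASEL"
      else if (.intact(p$aser)) "ECTOPIC_ASER"
      else if (isTRUE(p$asel_extra)) "ECTOPIC_ASEL"
      else "ECTOPIC_ASER"
    notes <- character(0)
    if (sub == "ECTOPIC_ASEL" && .lost(p$aser)) {
      notes <- "also_loss_of_aser_lineage"
    }
    return(res("ASE_LINEAGE", sub, "lineage_extra_cells", notes))
  }

  # 3. loss of ASE fate
  if (.lost(p$asel) && .lost(p$aser)) {
    return(res("ASE_FATE_LOSS", rule = "fate_loss_both_sides"))
  }
  if (.lost(p$asel) && .lost(p$ase_bilateral, strict = TRUE)) {
    return(res("ASE_FATE_LOSS", rule = "fate_loss_bilateral"))
  }

  # 4. lineage defect: one side lost, bilateral abnormal cell complement
  one_side_lost <- xor(.lost(p$asel), .lost(p$aser))
  if (one_side_lost && p$ase_bilateral == "PLUS_MINUS") {
    sub <- if (.lost(p$asel)) "LOSS_ASEL" else "LOSS_ASER"
    return(res("ASE_LINEAGE", sub, "lineage_one_sided_loss"))
  }

  # 5. asymmetry with an unaffected bilateral marker
  if (p$ase_bilateral == "WT") {
    if (.intact(p$aser)) {
      notes <- if (.intact(p$asel)) "minor_class_I_also_observed"
        else character(0)
      return(res("ASYMMETRY", "CLASS_II", "asymmetry_bilateral_wt", notes))
    }
    if (.intact(p$asel)) {
      if (subclass_mode == "text" && .lost(p$aser, strict = TRUE)) {
        return(res("ASYMMETRY", "CLASS_I", "asymmetry_bilateral_wt"))
      }
      return(res("ASYMMETRY", "CLASS_IV", "asymmetry_bilateral_wt"))
    }
  }

  NULL
}

# ---------------------------------------------------------------------------
# Full cascade
# ---------------------------------------------------------------------------

#' Classify one gene through the full decision cascade
#'
#' @param profile one row of a `marker_profile` data frame.
#' @param direction the gene's primary-screen direction (`"OFF"`,
#'   `"ECTOPIC"`, `"MIXED"` or `"WT"`; see [classify_asel_direction()]). A
#'   mixed direction is set aside as `MIXED_UNRESOLVED` without further
#'   rules; the loss direction passes through early-arrest and
#'   broad-neuronal rules before the ASE-specific rules; the ectopic
#'   direction goes to the ASE-specific rules directly.
#' @param subclass_mode passed to [classify_ase_specific()].
#' @return list of class `gene_classification`: `gene_id`, `top_class`,
#'   `subclass` (`NA` when the class has none), `rule_trace` (character
#'   vector of every rule evaluated, suffixed `:hit`/`:miss`) and `notes`.
#' @export
#' @examples
#' p <- marker_profile("geneA", asel = "MINUS", aser = "PLUS",
#'                     ase_bilateral = "WT")
#' categorize(p[1, ], direction = "OFF")$subclass  # "CLASS_II"
categorize <- function(profile, direction,
                       subclass_mode = c("table", "text")) {
  subclass_mode <- match.arg(subclass_mode)
  stopifnot(direction %in% c("OFF", "ECTOPIC", "MIXED", "WT"))
  p <- as.list(profile)
  trace <- character(0)
  out <- function(top, sub = NA_character_, notes = character(0)) {
    structure(list(gene_id = p$gene_id, top_class = top, subclass = sub,
                   rule_trace = trace, notes = notes),
              class = "gene_classification")
  }

  if (direction == "MIXED") {
    trace <- c(trace, "mixed_direction:hit")
    return(out("MIXED_UNRESOLVED"))
  }
  trace <- c(trace, "mixed_direction:miss")

  if (direction == "OFF") {
    ea <- is_early_arrest(p)
    if (!is.null(ea)) {
      trace <- c(trace, "early_arrest:hit")
      return(out("EARLY_ARREST", ea))
    }
    trace <- c(trace, "early_arrest:miss")
    if (is_broad_neuronal(p)) {
      trace <- c(trace, "broad_neuronal:hit")
      return(out("BROAD_NEURONAL"))
    }
    trace <- c(trace, "broad_neuronal:miss")
  }

  ase <- classify_ase_specific(p, subclass_mode = subclass_mode)
  if (!is.null(ase)) {
    trace <- c(trace, paste0(ase$rule, ":hit"))
    return(out(ase$top_class, ase$subclass, ase$notes))
  }
  trace <- c(trace, "ase_specific:miss")
  out("UNCLASSIFIED")
}

#' Classify every row of a marker-profile table
#'
#' @param profiles a `marker_profile` data frame.
#' @param direction either a single direction applied to all rows, a vector
#'   of per-gene directions, or `NULL` (default) to derive each gene's
#'   direction from its ASEL marker call (`MINUS` -> `OFF`, `PLUS` ->
#'   `ECTOPIC`, `PLUS_MINUS` -> `MIXED`, otherwise `WT`).
#' @param subclass_mode passed to [classify_ase_specific()].
#' @return data frame with columns `gene_id`, `top_class`, `subclass`,
#'   `rule_trace` (rules joined by `;`) and `notes`.
#' @export
categorize_profiles <- function(profiles, direction = NULL,
                                subclass_mode = c("table", "text")) {
  profiles <- validate_marker_profile(profiles)
  subclass_mode <- match.arg(subclass_mode)
  n <- nrow(profiles)
  if (is.null(direction)) {
    direction <- c(MINUS = "OFF", PLUS = "ECTOPIC", PLUS_MINUS = "MIXED",
                   WT = "WT", NE = "WT", BLANK = "WT")[profiles$asel]
  } else {
    direction <- rep_len(direction, n)
  }
  rows <- lapply(seq_len(n), function(i) {
    cl <- categorize(profiles[i, ], direction[[i]],
                     subclass_mode = subclass_mode)
    data.frame(gene_id = cl$gene_id, top_class = cl$top_class,
               subclass = cl$subclass,
               rule_trace = paste(cl$rule_trace, collapse = ";"),
               notes = paste(cl$notes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replay a recorded rule trace
#'
#' Re-evaluates the cascade for a profile and checks that the recorded rule
#' trace and resulting classification are reproduced; used for auditing.
#'
#' @param profile one row of a `marker_profile` data frame.
#' @param direction the direction used for the original classification.
#' @param classification a row of the output of [categorize_profiles()].
#' @param subclass_mode passed through to [categorize()].
#' @return `TRUE` if the replay reproduces top class, subclass and trace.
#' @export
replay_rule_trace <- function(profile, direction, classification,
                              subclass_mode = c("table", "text")) {
  redo <- categorize(profile, direction, subclass_mode = match.arg(subclass_mode))
  identical(redo$top_class, classification$top_class) &&
    identical(paste(redo$rule_trace, collapse = ";"),
              classification$rule_trace) &&
    (identical(redo$subclass, classification$subclass) ||
       (is.na(redo$subclass) && is.na(classification$subclass)))
}

# ---------------------------------------------------------------------------
# Summaries
# ---------------------------------------------------------------------------

#' Summarise classifications and roll up printed stage tallies
#'
#' Counts genes per top class and per subclass. When stage tallies are
#' supplied (named numeric vectors of printed per-category counts, e.g. the
#' per-direction counts of the primary screen or the per-rule early-arrest
#' counts), their arithmetic roll-ups (sums) are computed as well.
#'
#' @param classifications data frame from [categorize_profiles()] (may have
#'   zero rows).
#' @param stage_counts optional named list of named numeric vectors; each
#'   element is rolled up to its total.
#' @return list of class `counts_summary`: `n`, `class_counts` (named
#'   integer vector over all top classes), `subclass_counts`, and
#'   `stage_totals` (named numeric, one total per supplied tally).
#' @export
#' @examples
#' summarize_classifications(
#'   data.frame(gene_id = character(0), top_class = character(0),
#'              subclass = character(0)),
#'   stage_counts = list(direction = c(ectopic = 21, loss = 210, mixed = 14))
#' )$stage_totals
summarize_classifications <- function(classifications, stage_counts = NULL) {
  stopifnot(is.data.frame(classifications))
  class_counts <- vapply(
    TOP_CLASSES,
    function(cl) sum(classifications$top_class == cl), integer(1))
  sub <- classifications$subclass
  sub <- sub[!is.na(sub) & sub != ""]
  subclass_counts <- if (length(sub) > 0) {
    tab <- table(sub)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  stage_totals <- if (!is.null(stage_counts)) {
    vapply(stage_counts, sum, numeric(1))
  } else {
    numeric(0)
  }
  structure(
    list(n = nrow(classifications), class_counts = class_counts,
         subclass_counts = subclass_counts, stage_totals = stage_totals),
    class = "counts_summary"
  )
}

#' @export
print.counts_summary <- function(x, ...) {
  cat("Classification summary over", x$n, "genes\n")
  nz <- x$class_counts[x$class_counts > 0]
  if (length(nz)) {
    for (cl in names(nz)) cat("  ", cl, ": ", nz[[cl]], "\n", sep = "")
  }
  if (length(x$subclass_counts)) {
    cat("subclasses:\n")
    for (s in names(x$subclass_counts)) {
      cat("  ", s, ": ", x$subclass_counts[[s]], "\n", sep = "")
    }
  }
  if (length(x$stage_totals)) {
    cat("stage-tally totals:\n")
    for (s in names(x$stage_totals)) {
      cat("  ", s, ": ", x$stage_totals[[s]], "\n", sep = "")
    }
  }
  invisible(x)
}
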