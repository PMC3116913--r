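#' asescreen: scoring and classification for RNAi screens of ASE neuron fate
#'
#' The package covers every computational stage of a genome-wide RNAi screen
#' for the development of the left/right asymmetric ASE gustatory neuron pair
#' in *Caenorhabditis elegans*: well-level scoring of the primary ASEL
#' reporter screen ([compute_asel_scores()], [call_positive()],
#' [classify_asel_direction()]), the secondary ASER / bilateral-ASE and
#' tissue-marker screens ([classify_aser()], [classify_ase_bilateral()],
#' [score_tissue()], [apply_ne_filter()]), the rule cascade that assigns each
#' gene to a phenotypic class ([categorize()], [summarize_classifications()]),
#' a synthetic screen generator with known ground truth ([simulate_screen()],
#' [score_screen()], [recovery_report()]), cross-screen comparison of visible
#' phenotypes ([call_visible_phenotypes()], [overlap_fraction()],
#' [severity_shift_table()]) and the whole-genome-sequencing candidate-variant
#' filter used for mutant cloning ([filter_variants()]).
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Controlled vocabularies
# ---------------------------------------------------------------------------

#' Marker call vocabulary
#'
#' A categorical marker readout takes exactly one of six states. `"BLANK"`
#' means the marker was not assayed for that gene ("not done") and is
#' deliberately distinct from `"WT"` (assayed, found wildtype): missing
#' evidence must never be imputed to wildtype, and `"BLANK"` satisfies
#' neither a "marker lost" nor a "marker intact" requirement in the
#' classification rules.
#'
#' @format Character vector of the six legal states:
#'   `PLUS` (ectopic / `+`), `MINUS` (lost / `-`), `PLUS_MINUS` (mixed,
#'   `+/-`), `WT` (wildtype), `NE` (clone not embryonic lethal, so the
#'   marker could not be scored in the embryonic assay), `BLANK` (not done).
#' @export
MARKER_CALLS <- c("PLUS", "MINUS", "PLUS_MINUS", "WT", "NE", "BLANK")

#' Top-level phenotypic classes assigned by the categorizer
#' @format Character vector of class labels.
#' @seealso [categorize()]
#' @export
TOP_CLASSES <- c("EARLY_ARREST", "BROAD_NEURONAL", "ASE_LINEAGE",
                 "ASE_FATE_LOSS", "ASYMMETRY", "MIXED_UNRESOLVED",
                 "UNCLASSIFIED")

# token <-> state mapping used by the TSV fixtures (tokens as printed in the
# gene-by-gene marker tables)
.marker_tokens <- stats::setNames(
  c("PLUS", "MINUS", "PLUS_MINUS", "WT", "NE", "BLANK"),
  c("+", "-", "+/-", "wt", "ne", ""))

#' Convert a printed marker token to a marker call
#'
#' Tokens are the cell vocabulary of the published marker tables: `"+"`,
#' `"-"`, `"+/-"` (a unicode minus in `"+/−"` is also accepted),
#' `"wt"`, `"ne"` and the empty string (blank cell, not done).
#'
#' @param token character vector of table tokens.
#' @return character vector of marker calls (see [MARKER_CALLS]).
#' @export
#' @examples
#' marker_call_from_token(c("+", "-", "+/-", "wt", "ne", ""))
marker_call_from_token <- function(token) {
  token <- trimws(as.character(token))
  token[is.na(token)] <- ""
  # normalise the typographic minus that the printed tables use
  token <- gsub("−", "-", token)
  idx <- match(token, names(.marker_tokens))
  if (anyNA(idx)) {
    stop("unknown marker token(s): ",
         paste(sQuote(unique(token[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  }
  unname(.marker_tokens[idx])
}

#' Convert a marker call back to its printed token
#' @param call character vector of marker calls.
#' @return character vector of table tokens.
#' @export
marker_token_from_call <- function(call) {
  call <- as.character(call)
  bad <- !(call %in% MARKER_CALLS)
  if (any(bad)) {
    stop("unknown marker call(s): ",
         paste(sQuote(unique(call[bad])), collapse = ", "), call. = FALSE)
  }
  tokens <- names(.marker_tokens)
  unname(tokens[match(call, .marker_tokens)])
}

# ---------------------------------------------------------------------------
# MarkerProfile
# ---------------------------------------------------------------------------

.profile_marker_cols <- c("asel", "aser", "ase_bilateral", "neurons",
                          "muscle", "gut", "hypodermis")
.profile_extra_cols <- c("asel_extra", "aser_extra", "ase_extra")

#' Construct a table of marker profiles
#'
#' A marker profile is one gene's categorical readout across the reporter
#' panel: the ASEL, ASER and bilateral ASE reporters (each with an optional
#' "more than two cells observed" flag), the dopaminergic/cholinergic neuron
#' panel, and the muscle, gut and hypodermis tissue markers.
#'
#' @param gene_id character, unique non-empty gene identifiers.
#' @param functional_category character, free-text functional annotation.
#' @param asel,aser,ase_bilateral,neurons,muscle,gut,hypodermis marker calls
#'   (see [MARKER_CALLS]); default `"BLANK"` (not done).
#' @param asel_extra,aser_extra,ase_extra logical, `TRUE` when more than the
#'   normal complement of marker-positive cells was observed (the ">2"
#'   columns of the published tables). Only legal when the corresponding
#'   marker call is `PLUS` or `PLUS_MINUS`.
#' @param viable logical, clone viable (not embryonic lethal overall).
#' @param pre200_arrest logical, gene previously characterised as arresting
#'   before the 200-cell stage (external literature annotation).
#' @return data frame of class `marker_profile` with one row per gene.
#' @export
marker_profile <- function(gene_id,
                           functional_category = NA_character_,
                           asel = "BLANK", asel_extra = FALSE,
                           aser = "BLANK", aser_extra = FALSE,
                           ase_bilateral = "BLANK", ase_extra = FALSE,
                           neurons = "BLANK", muscle = "BLANK",
                           gut = "BLANK", hypodermis = "BLANK",
                           viable = FALSE, pre200_arrest = FALSE) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  df <- data.frame(
    gene_id = gene_id,
    functional_category = rep_len(as.character(functional_category), n),
    asel = rep_len(asel, n), asel_extra = rep_len(as.logical(asel_extra), n),
    aser = rep_len(aser, n), aser_extra = rep_len(as.logical(aser_extra), n),
    ase_bilateral = rep_len(ase_bilateral, n),
    ase_extra = rep_len(as.logical(ase_extra), n),
    neurons = rep_len(neurons, n), muscle = rep_len(muscle, n),
    gut = rep_len(gut, n), hypodermis = rep_len(hypodermis, n),
    viable = rep_len(as.logical(viable), n),
    pre200_arrest = rep_len(as.logical(pre200_arrest), n),
    stringsAsFactors = FALSE
  )
  validate_marker_profile(df)
}

#' Validate a marker profile table
#'
#' Checks the invariants of the profile type: gene ids non-empty and unique,
#' marker calls in the closed vocabulary, and ">2 cells" flags set only where
#' the corresponding marker call is `PLUS` or `PLUS_MINUS`.
#'
#' @param profiles data frame as built by [marker_profile()] or
#'   [read_marker_profiles()].
#' @return the validated data frame, invisibly classed `marker_profile`.
#' @export
validate_marker_profile <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  missing_cols <- setdiff(
    c("gene_id", .profile_marker_cols, .profile_extra_cols,
      "viable", "pre200_arrest"),
    names(profiles)
  )
  if (length(missing_cols) > 0) {
    stop("marker profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(profiles$gene_id) | profiles$gene_id == "")) {
    stop("gene_id must be non-empty", call. = FALSE)
  }
  dup <- duplicated(profiles$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id: ",
         paste(unique(profiles$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (col in .profile_marker_cols) {
    bad <- !(profiles[[col]] %in% MARKER_CALLS)
    if (any(bad)) {
      stop("column ", sQuote(col), " contains illegal call(s) in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  extra_of <- c(asel_extra = "asel", aser_extra = "aser",
                ase_extra = "ase_bilateral")
  for (flag in names(extra_of)) {
    call <- profiles[[extra_of[[flag]]]]
    bad <- profiles[[flag]] & !(call %in% c("PLUS", "PLUS_MINUS"))
    if (any(bad)) {
      stop(sQuote(flag), " set but ", sQuote(extra_of[[flag]]),
           " is not PLUS/PLUS_MINUS in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  class(profiles) <- unique(c("marker_profile", class(profiles)))
  profiles
}

#' Read a marker-profile fixture table
#'
#' Reads the tab-separated fixture format used to transport gene-by-gene
#' marker tables. The file is UTF-8 TSV with a header, `#` comment lines,
#' and the printed cell tokens `+`, `-`, `+/-`, `wt`, `ne` and blank; the
#' ">2 cells" companion columns hold `yes` or blank. All columns are
#' addressed by header name, never by position. Extra columns (for example
#' a free-text phenotype annotation) are carried through untouched.
#'
#' @param path path to the TSV file.
#' @return a validated `marker_profile` data frame (zero rows for a file
#'   with only a header).
#' @export
#' @examples
#' path <- system.file("extdata", "profiles_asymmetry.tsv",
#'                     package = "asescreen")
#' profiles <- read_marker_profiles(path)
#' nrow(profiles)
read_marker_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "",
                           fileEncoding = "UTF-8")
  token_cols <- intersect(.profile_marker_cols, names(raw))
  for (col in token_cols) {
    calls <- tryCatch(marker_call_from_token(raw[[col]]), error = function(e) {
      bad <- !(gsub("−", "-", trimws(raw[[col]])) %in%
                 names(.marker_tokens))
      stop("column ", sQuote(col), ", row(s) ",
           paste(which(bad), collapse = ", "), ": ", conditionMessage(e),
           call. = FALSE)
    })
    raw[[col]] <- calls
  }
  yes_no <- function(x) tolower(trimws(x)) %in% c("yes", "true", "1")
  for (col in intersect(c(.profile_extra_cols, "viable", "pre200_arrest"),
                        names(raw))) {
    raw[[col]] <- yes_no(raw[[col]])
  }
  defaults <- marker_profile(gene_id = "x")[0, ]
  for (col in setdiff(names(defaults), names(raw))) {
    raw[[col]] <- if (is.logical(defaults[[col]])) FALSE else
      if (col %in% .profile_marker_cols) "BLANK" else NA_character_
  }
  validate_marker_profile(raw)
}

#' Write a marker-profile table in the fixture format
#'
#' Inverse of [read_marker_profiles()]: marker calls are written back as the
#' printed tokens, logical flags as `yes`/blank.
#'
#' @param profiles a `marker_profile` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_profiles <- function(profiles, path) {
  profiles <- validate_marker_profile(profiles)
  out <- as.data.frame(profiles)
  for (col in .profile_marker_cols) {
    out[[col]] <- marker_token_from_call(out[[col]])
  }
  for (col in c(.profile_extra_cols, "viable", "pre200_arrest")) {
    out[[col]] <- ifelse(out[[col]], "yes", "")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneClassification I/O
# ---------------------------------------------------------------------------

#' Write gene classifications to a TSV file
#'
#' Columns: `gene_id`, `top_class`, `subclass` (blank when the class has no
#' subclasses) and `rule_trace` (rule identifiers joined by `;`).
#' Re-reading with [read_classifications()] reproduces the table exactly.
#'
#' @param classifications data frame as returned by [categorize_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  stopifnot(is.data.frame(classifications))
  need <- c("gene_id", "top_class", "subclass", "rule_trace")
  missing_cols <- setdiff(need, names(classifications))
  if (length(missing_cols) > 0) {
    stop("classification table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- classifications[, need, drop = FALSE]
  out$subclass[is.na(out$subclass)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene classifications written by [write_classifications()]
#' @param path path to the TSV file.
#' @return data frame with columns `gene_id`, `top_class`, `subclass`
#'   (`NA` when absent), `rule_trace`.
#' @export
read_classifications <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  df$subclass[df$subclass == ""] <- NA_character_
  bad <- !(df$top_class %in% TOP_CLASSES)
  if (any(bad)) {
    stop("unknown top_class in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  df
}

# ---------------------------------------------------------------------------
# Lineage-name utilities (Sulston nomenclature)
# ---------------------------------------------------------------------------

.lineage_founders <- c("AB", "MS", "E", "C", "D", "P0", "P1", "P2", "P3",
                       "P4", "Z2", "Z3")
.lineage_letters <- c("a", "p", "l", "r", "d", "v")

#' Parse a Sulston lineage name
#'
#' Embryonic cells are named by a founder blastomere (e.g. `AB`, `MS`, `E`,
#' `C`, `P3`) followed by one lowercase letter per division giving the
#' daughter's position (a/p anterior/posterior, l/r left/right, d/v
#' dorsal/ventral). `"ABalppp"` is the AB descendant reached by the
#' divisions a, l, p, p, p, at division depth 5.
#'
#' @param name a single lineage name, e.g. `"ABalppp"`.
#' @return a `lineage_address` list with elements `founder` (character) and
#'   `sublineage` (character vector of division letters; length 0 for a
#'   founder itself).
#' @export
#' @examples
#' addr <- parse_lineage_name("ABalppp")
#' addr$founder
#' length(addr$sublineage)  # division depth
parse_lineage_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  founders <- .lineage_founders[order(nchar(.lineage_founders),
                                      decreasing = TRUE)]
  founder <- NULL
  for (f in founders) {
    if (startsWith(name, f)) { founder <- f; break }
  }
  if (is.null(founder)) {
    stop("no known founder blastomere prefix in ", sQuote(name),
         call. = FALSE)
  }
  rest <- substring(name, nchar(founder) + 1L)
  sub <- if (nzchar(rest)) strsplit(rest, "", fixed = TRUE)[[1]] else
    character(0)
  bad <- !(sub %in% .lineage_letters)
  if (any(bad)) {
    stop("illegal division letter(s) ",
         paste(sQuote(unique(sub[bad])), collapse = ", "), " in ",
         sQuote(name), call. = FALSE)
  }
  structure(list(founder = founder, sublineage = sub),
            class = "lineage_address")
}

#' Format a lineage address back to its name
#' @param address a `lineage_address` from [parse_lineage_name()].
#' @return the textual lineage name.
#' @export
format_lineage_name <- function(address) {
  stopifnot(inherits(address, "lineage_address"))
  paste0(address$founder, paste(address$sublineage, collapse = ""))
}

#' @export
format.lineage_address <- function(x, ...) format_lineage_name(x)

#' @export
print.lineage_address <- function(x, ...) {
  cat("<lineage> ", format_lineage_name(x), " (founder ", x$founder,
      ", depth ", length(x$sublineage), ")\n", sep = "")
  invisible(x)
}

#' Is one cell a lineal descendant of another?
#'
#' `TRUE` iff the ancestor's name is a (proper or equal) prefix of the
#' child's name. By this convention every cell is its own descendant.
#'
#' @param child,ancestor lineage names (character) or `lineage_address`
#'   objects.
#' @return logical scalar.
#' @export
#' @examples
#' is_descendant("ABalppp", "ABa")  # TRUE
#' is_descendant("ABalppp", "ABp")  # FALSE
is_descendant <- function(child, ancestor) {
  if (is.character(child)) child <- parse_lineage_name(child)
  if (is.character(ancestor)) ancestor <- parse_lineage_name(ancestor)
  if (child$founder != ancestor$founder) return(FALSE)
  na <- length(ancestor$sublineage)
  if (na > length(child$sublineage)) return(FALSE)
  identical(child$sublineage[seq_len(na)], ancestor$sublineage)
}
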