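# Cross-screen comparison of visible RNAi phenotypes: calling phenotypes
# from observation fractions, directional overlap of positive clone sets,
# and severity-shift tabulation against a reference screen.

#' The closed vocabulary of visible worm phenotype codes
#' @format Character vector: Emb (embryonic lethal), P0Ste (P0 sterile),
#'   Stp (sterile progeny), Brd (low brood size), Gro (slow postembryonic
#'   growth), Lva (larval arrest), Let (larval lethal), Adl (adult lethal),
#'   Bli, Bmd, Clr, Dpy, Egl, Lon, Mlt, Muv, Prz, Pvl, Rol, Rup, Sck, Unc.
#' @export
VISIBLE_PHENOTYPES <- c("Emb", "P0Ste", "Stp", "Brd", "Gro", "Lva", "Let",
                        "Adl", "Bli", "Bmd", "Clr", "Dpy", "Egl", "Lon",
                        "Mlt", "Muv", "Prz", "Pvl", "Rol", "Rup", "Sck",
                        "Unc")

#' The non-viable phenotype group
#' @format Character vector: the phenotypes grouped as nonV.
#' @export
NONVIABLE_PHENOTYPES <- c("P0Ste", "Emb", "Stp", "Let")

#' Default severity scale for visible phenotypes
#'
#' A total preorder as integer ranks, higher = more severe. Only the split
#' between the non-viable group (top rank, shared by all nonV members) and
#' viable phenotypes is fixed by the scoring definitions; the ordering of
#' viable ranks (larval arrest above slow growth above morphology/behaviour)
#' is a documented default and [severity_shift_table()] accepts any
#' user-supplied scale.
#'
#' @return named integer vector of ranks over [VISIBLE_PHENOTYPES].
#' @export
default_severity_scale <- function() {
  ranks <- stats::setNames(rep(1L, length(VISIBLE_PHENOTYPES)),
                           VISIBLE_PHENOTYPES)
  ranks["Gro"] <- 2L
  ranks["Lva"] <- 3L
  ranks[NONVIABLE_PHENOTYPES] <- 4L
  ranks
}

#' Call visible phenotypes from per-clone observation fractions
#'
#' Emb is called iff the dead-embryo fraction strictly exceeds 30%; every
#' other phenotype is called iff present among at least 10% of the analysed
#' worms (inclusive).
#'
#' @param fractions named numeric vector in \[0, 1\]: observed fraction per
#'   phenotype code (for `Emb`, the fraction of dead embryos).
#' @param emb_cutoff strict lower cutoff for Emb (default 0.30).
#' @param presence_cutoff inclusive cutoff for all other phenotypes
#'   (default 0.10).
#' @return character vector of called phenotype codes (possibly empty).
#' @export
#' @examples
#' call_visible_phenotypes(c(Emb = 0.31, Unc = 0.10, Gro = 0.05))
call_visible_phenotypes <- function(fractions, emb_cutoff = 0.30,
                                    presence_cutoff = 0.10) {
  if (length(fractions) == 0) return(character(0))
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% VISIBLE_PHENOTYPES)) {
    stop("fractions must be named with visible phenotype codes",
         call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  called <- ifelse(names(fractions) == "Emb",
                   fractions > emb_cutoff,
                   fractions >= presence_cutoff)
  names(fractions)[called]
}

#' Directional overlap fraction of two positive sets
#'
#' The fraction of the first screen's positives that are also positive in
#' the second: `|A intersect B| / |A|`. The overlap is directional; report
#' both directions when the denominator choice matters.
#'
#' @param a,b character vectors of positive clone (or gene) identifiers.
#' @return fraction in \[0, 1\]; `NA_real_` with a warning when `a` is
#'   empty (the fraction is undefined).
#' @export
#' @examples
#' overlap_fraction(c("1", "2", "3", "4", "5"),
#'                  c("1", "2", "3", "4", "9", "10"))  # 0.8
overlap_fraction <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0) {
    warning("overlap fraction undefined over an empty reference set")
    return(NA_real_)
  }
  length(intersect(a, b)) / length(a)
}

#' Both directional overlap fractions at once
#' @param a,b character vectors of positive identifiers.
#' @return named numeric vector `c(a_in_b = , b_in_a = )`.
#' @export
overlap_fractions <- function(a, b) {
  c(a_in_b = overlap_fraction(a, b), b_in_a = overlap_fraction(b, a))
}

# most severe rank among a clone's phenotypes, NA when none
.max_severity <- function(phenotypes, scale) {
  phenotypes <- phenotypes[!is.na(phenotypes)]
  if (length(phenotypes) == 0) return(NA_integer_)
  max(scale[phenotypes])
}

#' Tabulate severity shifts between two screens for one focus phenotype
#'
#' For every clone carrying the focus phenotype in the reference screen, the
#' query screen's call is classified against the severity scale: `same` when
#' the query's most severe phenotype has the focus phenotype's rank,
#' `more_severe` / `less_severe` when it ranks above / below, and `absent`
#' when the query reports no phenotype for the clone. Multi-phenotype clones
#' are ranked by their most severe phenotype.
#'
#' @param reference,query named lists: clone id -> character vector of
#'   visible phenotype codes.
#' @param focus the focus phenotype code (e.g. `"Gro"`).
#' @param scale named integer severity ranks over the phenotype vocabulary;
#'   default [default_severity_scale()].
#' @return list with `counts` (named integer vector over
#'   same/more_severe/less_severe/absent, partitioning the reference focus
#'   set), `fractions`, and `n_focus`.
#' @export
severity_shift_table <- function(reference, query, focus,
                                 scale = default_severity_scale()) {
  stopifnot(is.list(reference), is.list(query))
  if (!(focus %in% names(scale))) {
    stop("focus phenotype ", sQuote(focus), " is not on the severity scale",
         call. = FALSE)
  }
  bad <- setdiff(unique(unlist(c(reference, query))), names(scale))
  if (length(bad) > 0) {
    stop("phenotype(s) not on the severity scale: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  focus_clones <- names(reference)[vapply(reference,
                                          function(p) focus %in% p,
                                          logical(1))]
  focus_rank <- scale[[focus]]
  shifts <- vapply(focus_clones, function(cl) {
    q <- if (cl %in% names(query)) query[[cl]] else character(0)
    rank <- .max_severity(q, scale)
    if (is.na(rank)) return("absent")
    if (rank > focus_rank) return("more_severe")
    if (rank < focus_rank) return("less_severe")
    "same"
  }, character(1))
  levels <- c("same", "more_severe", "less_severe", "absent")
  counts <- vapply(levels, function(l) sum(shifts == l), integer(1))
  n <- length(focus_clones)
  list(counts = counts,
       fractions = if (n > 0) counts / n else counts * NA_real_,
       n_focus = n)
}
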