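# Synthetic screens with known ground truth. Each clone draws a true
# phenotypic class; the class's canonical marker archetype then determines
# which assays show a phenotype, and each well is an independent Bernoulli
# detection event (probability = per-class penetrance for phenotype wells,
# or the per-well false-positive rate for no-phenotype clones). Per-clone
# random streams are derived deterministically from one master seed, so
# changing n_clones does not reshuffle earlier clones.

#' Load the canonical marker archetypes of the phenotypic classes
#'
#' One row per class: the phenotype each assay shows for a fully penetrant
#' clone of that class. Shipped as a versioned data file so simulations and
#' tests share one source of truth. Archetypes follow the published
#' gene-by-gene patterns: an early-arrest clone loses every marker; a
#' broad-neuronal clone loses ASEL, the neuronal panel and hypodermis but
#' keeps muscle and gut; a fate-loss clone loses ASEL, ASER and the
#' bilateral marker with all tissues intact; a lineage clone shows ectopic
#' ASEL and ectopic bilateral ASE cells; an asymmetry clone (2-ASER
#' archetype) loses ASEL and gains ectopic ASER with the bilateral marker
#' unaffected.
#'
#' @return data frame with columns `top_class`, `primary`, `aser`, `ase`,
#'   `neurons`, `muscle`, `gut`, `hypodermis`.
#' @export
load_class_archetypes <- function() {
  path <- system.file("extdata", "class_archetypes.tsv",
                      package = "asescreen")
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    colClasses = "character", fileEncoding = "UTF-8")
}

#' Construct and validate simulation parameters
#'
#' @param n_clones number of clones to simulate.
#' @param class_proportions named numeric vector of true-class probabilities
#'   over the archetype classes (including the no-phenotype class `"WT"`);
#'   must sum to 1 (tolerance 1e-9).
#' @param penetrance named numeric vector: per-well detection probability of
#'   a phenotype well, per class. A single unnamed value is recycled to all
#'   phenotype classes.
#' @param false_positive_rate per-well probability that a no-phenotype clone
#'   shows a spurious call.
#' @param wells_primary,wells_ase,wells_tissue wells per assay (defaults 8,
#'   6 and 2: a duplicate primary pass pooled with six re-screen wells, a
#'   six-well ASE screen, and a two-well tissue screen).
#' @param seed master integer seed.
#' @param clone_effect_sd standard deviation of an optional clone-level
#'   normal random effect on the logit of penetrance (0 = off, the default;
#'   wells within a clone then stay independent Bernoulli draws).
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_clones = 1000,
                              class_proportions = c(
                                WT = 0.95, EARLY_ARREST = 0.02,
                                BROAD_NEURONAL = 0.005, ASE_LINEAGE = 0.005,
                                ASE_FATE_LOSS = 0.01, ASYMMETRY = 0.01),
                              penetrance = 0.7,
                              false_positive_rate = 0.02,
                              wells_primary = 8L, wells_ase = 6L,
                              wells_tissue = 2L, seed = 1L,
                              clone_effect_sd = 0) {
  archetypes <- load_class_archetypes()
  known <- archetypes$top_class
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% known)) {
    stop("class_proportions must be named with archetype classes: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (any(class_proportions < 0)) {
    stop("class_proportions must be non-negative", call. = FALSE)
  }
  pheno_classes <- setdiff(names(class_proportions), "WT")
  if (is.null(names(penetrance))) {
    if (length(penetrance) != 1L) {
      stop("unnamed penetrance must be a single value", call. = FALSE)
    }
    penetrance <- stats::setNames(rep(penetrance, length(pheno_classes)),
                                  pheno_classes)
  }
  missing_pen <- setdiff(pheno_classes, names(penetrance))
  if (length(missing_pen) > 0) {
    stop("penetrance missing for class(es): ",
         paste(missing_pen, collapse = ", "), call. = FALSE)
  }
  probs <- c(penetrance, false_positive_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("penetrance and false_positive_rate must lie in [0, 1]",
         call. = FALSE)
  }
  stopifnot(n_clones >= 0, wells_primary >= 1, wells_ase >= 1,
            wells_tissue >= 1, wells_tissue <= 2, clone_effect_sd >= 0)
  structure(
    list(n_clones = as.integer(n_clones),
         class_proportions = class_proportions,
         penetrance = penetrance,
         false_positive_rate = false_positive_rate,
         wells_primary = as.integer(wells_primary),
         wells_ase = as.integer(wells_ase),
         wells_tissue = as.integer(wells_tissue),
         seed = as.integer(seed),
         clone_effect_sd = clone_effect_sd,
         archetypes = archetypes),
    class = "simulation_params"
  )
}

# deterministic per-clone stream: one substream per (master seed, clone)
.clone_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483629)
}

#' Simulate a synthetic screen with known ground truth
#'
#' @param params a `simulation_params` object.
#' @return list of class `synthetic_screen`: `true_labels` (named character
#'   vector, clone -> class), well matrices `primary` (clones x wells),
#'   `aser`, `ase`, `tissue` (list of four clones-x-wells matrices, one per
#'   tissue marker) and the `params` used. Identical parameters (including
#'   seed) give identical output.
#' @export
#' @examples
#' scr <- simulate_screen(simulation_params(n_clones = 20, seed = 42))
#' table(scr$true_labels)
simulate_screen <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_clones
  arch <- params$archetypes
  rownames(arch) <- arch$top_class
  tissues <- c("neurons", "muscle", "gut", "hypodermis")
  clone_ids <- sprintf("clone_%05d", seq_len(max(n, 0)))

  primary <- matrix("NONE", n, params$wells_primary)
  aser <- matrix("NONE", n, params$wells_ase)
  ase <- matrix("TWO_ON", n, params$wells_ase)
  tissue <- lapply(tissues, function(t) matrix("ON", n, params$wells_tissue))
  names(tissue) <- tissues
  labels <- character(n)

  classes <- names(params$class_proportions)
  cum <- cumsum(params$class_proportions)

  for (i in seq_len(n)) {
    set.seed(.clone_seed(params$seed, i))
    labels[i] <- classes[findInterval(stats::runif(1), cum,
                                      left.open = TRUE) + 1L]
    a <- arch[labels[i], ]
    pen <- if (labels[i] == "WT") 0 else params$penetrance[[labels[i]]]
    if (params$clone_effect_sd > 0 && pen > 0 && pen < 1) {
      pen <- stats::plogis(stats::qlogis(pen) +
                             stats::rnorm(1, 0, params$clone_effect_sd))
    }
    fpr <- params$false_positive_rate

    # primary ASEL assay
    if (a$primary != "NONE") {
      hit <- stats::runif(params$wells_primary) < pen
      primary[i, hit] <- a$primary
    } else {
      fp <- stats::runif(params$wells_primary) < fpr
      primary[i, fp] <- ifelse(stats::runif(sum(fp)) < 0.5,
                               "LOSS", "ECTOPIC")[seq_len(sum(fp))]
    }

    # ASER reporter
    if (a$aser != "NONE") {
      hit <- stats::runif(params$wells_ase) < pen
      aser[i, hit] <- a$aser
    } else {
      fp <- stats::runif(params$wells_ase) < fpr
      aser[i, fp] <- ifelse(stats::runif(sum(fp)) < 0.5,
                            "LOSS", "ECTOPIC")[seq_len(sum(fp))]
    }

    # bilateral ASE reporter
    if (a$ase != "NONE") {
      hit <- stats::runif(params$wells_ase) < pen
      ase[i, hit] <- a$ase
    } else {
      fp <- stats::runif(params$wells_ase) < fpr
      ase[i, fp] <- ifelse(stats::runif(sum(fp)) < 0.5,
                           "OFF", "ECTOPIC")[seq_len(sum(fp))]
    }

    # tissue markers
    for (t in tissues) {
      if (a[[t]] == "LOST") {
        hit <- stats::runif(params$wells_tissue) < pen
        tissue[[t]][i, hit] <- "OFF"
      } else {
        fp <- stats::runif(params$wells_tissue) < fpr
        tissue[[t]][i, fp] <- "OFF"
      }
    }
  }

  rownames(primary) <- rownames(aser) <- rownames(ase) <- clone_ids
  for (t in tissues) rownames(tissue[[t]]) <- clone_ids
  structure(
    list(true_labels = stats::setNames(labels, clone_ids),
         primary = primary, aser = aser, ase = ase, tissue = tissue,
         params = params),
    class = "synthetic_screen"
  )
}

#' Export a synthetic screen as long-format well tables
#'
#' @param screen a `synthetic_screen` object.
#' @return list of data frames `primary` (`clone_id`, `well`, `well_call`),
#'   `ase` (`clone_id`, `marker`, `well`, `well_call`) and `tissue`
#'   (`clone_id`, `marker`, `well`, `well_call`).
#' @export
as_well_tables <- function(screen) {
  stopifnot(inherits(screen, "synthetic_screen"))
  melt <- function(m, marker = NULL) {
    df <- data.frame(
      clone_id = rep(rownames(m), ncol(m)),
      well = rep(seq_len(ncol(m)), each = nrow(m)),
      well_call = as.vector(m), stringsAsFactors = FALSE)
    if (!is.null(marker)) df$marker <- marker
    df[order(df$clone_id, df$well), , drop = FALSE]
  }
  ase_long <- rbind(melt(screen$aser, "aser"), melt(screen$ase, "ase"))
  tissue_long <- do.call(rbind, lapply(names(screen$tissue), function(t) {
    melt(screen$tissue[[t]], t)
  }))
  list(primary = melt(screen$primary),
       ase = ase_long[order(ase_long$clone_id, ase_long$marker,
                            ase_long$well), , drop = FALSE],
       tissue = tissue_long[order(tissue_long$clone_id, tissue_long$marker,
                                  tissue_long$well), , drop = FALSE])
}

#' Score a synthetic screen into derived marker profiles
#'
#' Runs the scoring stages over the screen's well data: primary scores,
#' positive calling and direction; ASER / bilateral clone categories; tissue
#' statuses. Clone categories are mapped to the marker-call vocabulary
#' (loss -> `MINUS`, ectopic -> `PLUS`, mixed -> `PLUS_MINUS`, tissue ON ->
#' `PLUS`, tissue OFF -> `MINUS`); an ectopic bilateral category sets the
#' extra-ASE-cells flag.
#'
#' @param screen a `synthetic_screen` object.
#' @return list with `primary` (per-clone score table, see
#'   [score_primary_table()]) and `profiles` (a `marker_profile` data frame
#'   for all clones).
#' @export
score_screen <- function(screen) {
  stopifnot(inherits(screen, "synthetic_screen"))
  clone_ids <- rownames(screen$primary)
  n <- length(clone_ids)

  off <- unname(rowSums(screen$primary == "LOSS"))
  ect <- unname(rowSums(screen$primary == "ECTOPIC"))
  nw <- ncol(screen$primary)
  primary <- data.frame(
    clone_id = clone_ids, n_wells = rep(nw, n),
    off_count = off, ectopic_count = ect,
    off_score = off / nw, ectopic_score = ect / nw,
    stringsAsFactors = FALSE, row.names = NULL)
  per <- lapply(seq_len(n), function(i) {
    s <- structure(list(off_score = primary$off_score[i],
                        ectopic_score = primary$ectopic_score[i],
                        off_count = off[i], ectopic_count = ect[i],
                        n_wells = nw), class = "asel_scores")
    c(positive = call_positive(s), direction = classify_asel_direction(s))
  })
  primary$positive <- vapply(per, function(x) as.logical(x[["positive"]]),
                             logical(1))
  primary$direction <- vapply(per, function(x) x[["direction"]],
                              character(1))

  dir_to_call <- c(OFF = "MINUS", ECTOPIC = "PLUS", MIXED = "PLUS_MINUS",
                   WT = "WT")
  to_call <- c(OFF = "MINUS", ECTOPIC = "PLUS", MIXED = "PLUS_MINUS",
               WT = "WT", BLANK = "BLANK", TWO_OFF = "MINUS",
               ONE_OFF = "MINUS")

  aser_call <- character(n); ase_call <- character(n)
  ase_extra <- logical(n)
  tissue_call <- matrix("BLANK", n, 4,
                        dimnames = list(NULL, names(screen$tissue)))
  for (i in seq_len(n)) {
    rw <- screen$aser[i, ]
    aser_call[i] <- to_call[[classify_aser(sum(rw == "LOSS"),
                                           sum(rw == "ECTOPIC"),
                                           length(rw))]]
    bw <- screen$ase[i, ]
    cat_b <- classify_ase_bilateral(sum(bw == "OFF"), sum(bw == "ONE_ON"),
                                    sum(bw == "ECTOPIC"), sum(bw == "MIXED"),
                                    length(bw))
    ase_call[i] <- to_call[[cat_b]]
    ase_extra[i] <- cat_b == "ECTOPIC"
    for (t in names(screen$tissue)) {
      st <- score_tissue(screen$tissue[[t]][i, ])
      tissue_call[i, t] <- if (st$status == "ON") "PLUS" else "MINUS"
    }
  }

  profiles <- marker_profile(
    gene_id = clone_ids,
    asel = unname(dir_to_call[primary$direction]),
    aser = aser_call, ase_bilateral = ase_call, ase_extra = ase_extra,
    neurons = tissue_call[, "neurons"], muscle = tissue_call[, "muscle"],
    gut = tissue_call[, "gut"], hypodermis = tissue_call[, "hypodermis"])

  list(primary = primary, profiles = profiles)
}

#' Run the full scoring and classification pipeline on a synthetic screen
#'
#' Clones not called positive in the primary screen are reported as `"WT"`;
#' positive clones are classified through the cascade with the direction
#' derived from the primary scores.
#'
#' @param screen a `synthetic_screen` object.
#' @param subclass_mode passed to [categorize_profiles()].
#' @return data frame with `clone_id`, `true_class` and `inferred_class`.
#' @export
run_pipeline <- function(screen, subclass_mode = c("table", "text")) {
  subclass_mode <- match.arg(subclass_mode)
  scored <- score_screen(screen)
  inferred <- rep("WT", nrow(scored$primary))
  pos <- scored$primary$positive
  if (any(pos)) {
    cls <- categorize_profiles(scored$profiles[pos, , drop = FALSE],
                               direction = scored$primary$direction[pos],
                               subclass_mode = subclass_mode)
    inferred[pos] <- cls$top_class
  }
  data.frame(clone_id = scored$primary$clone_id,
             true_class = unname(screen$true_labels),
             inferred_class = inferred, stringsAsFactors = FALSE)
}

#' Analytic probability that a clone is called positive
#'
#' Upper-tail binomial probability that at least `k` of `n` independent
#' wells show the phenotype when each well detects it with probability `p`
#' (the operating characteristic of the at-least-3-of-8 positive rule).
#'
#' @param p per-well detection probability, in \[0, 1\].
#' @param n number of wells (>= 1).
#' @param k minimum number of phenotype wells (1 <= k <= n).
#' @return `P[X >= k]` for `X ~ Binomial(n, p)`.
#' @export
#' @examples
#' positive_call_probability(0.5, 8, 3)  # 219/256
positive_call_probability <- function(p, n = 8L, k = 3L) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Confusion summary of pipeline recovery against the simulated truth
#'
#' @param truth named character vector of true classes (clone -> class), or
#'   a `synthetic_screen` object.
#' @param inferred data frame with `clone_id` and `inferred_class` (as from
#'   [run_pipeline()]), or a named character vector.
#' @return list of class `confusion_summary`: `confusion` (true classes in
#'   rows, inferred in columns; row sums equal true-class counts) and
#'   `accuracy`.
#' @export
recovery_report <- function(truth, inferred) {
  if (inherits(truth, "synthetic_screen")) truth <- truth$true_labels
  if (is.data.frame(inferred)) {
    inferred <- stats::setNames(inferred$inferred_class, inferred$clone_id)
  }
  if (!setequal(names(truth), names(inferred))) {
    stop("truth and inferred cover different clone sets", call. = FALSE)
  }
  inferred <- inferred[names(truth)]
  levels <- sort(unique(c(truth, inferred)))
  confusion <- table(true = factor(truth, levels),
                     inferred = factor(inferred, levels))
  structure(
    list(confusion = confusion,
         accuracy = mean(truth == inferred)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Recovery accuracy:", format(x$accuracy, digits = 4), "\n")
  print(x$confusion)
  invisible(x)
}
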