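# asescreen

Scoring, hit calling and multi-tier phenotype classification for
genome-wide RNAi screens of ASE neuron fate in *Caenorhabditis elegans*.

## The problem

The two gustatory neurons ASEL and ASER form a bilaterally symmetric but
functionally lateralized pair: they arise from distinct embryonic lineages
(ABa and ABp descendants), converge on a shared ASE fate, and then
diverge again into left- and right-specific gene expression programs. A
genome-wide RNAi screen against an ASEL-specific reporter
(*lim-6::gfp*) in an RNAi-hypersensitive background (*nre-1 lin-15b*) can
ask, for nearly every gene in the genome, whether its knock-down prevents
the neuron from being generated, converts its fate, or creates ectopic
ASEL-fated cells. Turning the raw well-level observations of such a screen
into interpretable gene classes requires a fixed, auditable scoring and
decision procedure — that procedure is what this package implements, for
screeners and analysts who need to score plates, call hits and place genes
into phenotypic classes reproducibly.

## The method

**Primary screen scoring.** Each clone is scored in duplicate and, when a
phenotype is seen, re-screened six more times. With `n` wells scored, the
loss score is `#("loss of ASEL" wells) / n` and the ectopic score is
`#("ectopic ASEL" wells) / n`. A clone is *positive* iff it shows a
phenotype in at least 3 of 8 wells (fraction ≥ 3/8). Direction follows the
sign pattern of the two scores (off / ectopic / mixed / wildtype), with
mixed clones reclassified when one score dominates: if
`ectopic/off ≤ 0.25` the clone moves to *off*, if `off/ectopic ≤ 0.25` to
*ectopic*. The operating characteristic of the positive rule is the
binomial upper tail `P[X ≥ k]`, `X ~ Bin(n, p)`, exposed as
`positive_call_probability()`.

**Secondary screens.** The ASE screen scores six wells with an
ASER-specific reporter and a bilateral ASE reporter; clone-level categories
(off, ectopic, mixed, wildtype, blank = not done) follow the sign patterns
of the well counts. The tissue screen scores two wells per marker
(dopaminergic/cholinergic neurons, muscle, gut, hypodermis) at 0 / 0.25 /
0.5 per well; the clone is ON for a tissue iff the summed score exceeds
0.5. Clones that are "not embryonic lethal" in 3 or more of 6 strains are
removed as non-repeatable (`apply_ne_filter()`).

**Classification cascade.** `categorize()` assigns each positive gene
exactly one class, in screening order: mixed-direction clones are set
aside; loss-direction clones are tested for *early arrest* (four rules:
all tissue markers lost; prior annotation of pre-200-cell arrest; all
markers lost except the dopaminergic panel; neurons and muscle lost but
gut intact) and then *broad neuronal defects* (neurons and hypodermis lost,
muscle intact); the remaining genes pass to the ASE-specific rules —
*loss of ASE fate* (both side markers lost, or ASEL plus the bilateral
marker lost), *ASE lineage defects* (extra marker-positive cells, or a
one-sided loss with an abnormal bilateral complement), and *asymmetry
defects* (bilateral marker unaffected with ectopic ASEL or ASER, classes
I "2-ASEL" / II "2-ASER" / IV "mixed"; an ambiguous bilateral call routes
to asymmetry only when a clear contralateral swap is seen). Every decision
is recorded in a replayable rule trace.

**Synthetic screens.** `simulate_screen()` generates screens with known
ground truth (per-class canonical marker archetypes, per-well Bernoulli
detection with configurable penetrance and false-positive rate,
deterministic per-clone seed streams), so that every stage of the pipeline
is testable end to end without the unreleased raw screen data.

**Screen comparison and mutant cloning.** `call_visible_phenotypes()`
(Emb iff > 30% dead embryos; any other phenotype iff present in ≥ 10% of
worms), `overlap_fraction()` and `severity_shift_table()` compare positive
sets across screens; `filter_variants()` implements the
whole-genome-sequencing candidate filter (quality ≥ 3, loci multiplicity
≤ 1, depth ≥ 3, mapping-interval restriction, elimination of variants seen
in background genomes, optional protein-coding restriction) with
`two_proportion_ztest()` / `bonferroni_adjust()` for rescue comparisons.

## Worked example

Classify the packaged asymmetry-defect marker profiles:

```r
library(asescreen)

profiles <- read_marker_profiles(
  system.file("extdata", "profiles_asymmetry.tsv", package = "asescreen"))
cls <- categorize_profiles(profiles)
head(cls[, c("gene_id", "top_class", "subclass")], 5)
#>    gene_id top_class subclass
#> 1   klp-16 ASYMMETRY CLASS_IV
#> 2 F21H12.1 ASYMMETRY CLASS_II
#> 3   lin-49 ASYMMETRY CLASS_II
#> 4    ash-2 ASYMMETRY CLASS_II
#> 5   dpy-30 ASYMMETRY CLASS_II

summarize_classifications(cls)
#> Classification summary over 20 genes
#>   ASYMMETRY: 20
#> subclasses:
#>   CLASS_I: 2
#>   CLASS_II: 11
#>   CLASS_IV: 7
```

All 20 genes are asymmetry-class: 11 are Class II (both neurons adopt
ASER fate, e.g. the COMPASS-complex genes *ash-2*, *dpy-30*, *F21H12.1*),
2 are Class I (2-ASEL) and 7 are Class IV (ectopic ASEL marker with ASER
fate unaffected).

Score one clone of the primary screen (4 loss wells, 1 ectopic well of 8):

```r
s <- compute_asel_scores(c("LOSS", "LOSS", "LOSS", "LOSS",
                           "ECTOPIC", "NONE", "NONE", "NONE"))
call_positive(s)             # TRUE  (5/8 >= 3/8)
classify_asel_direction(s)   # "OFF" (ectopic/off = 0.25, moved to off)
positive_call_probability(0.5, n = 8, k = 3)
#> 0.8554688                  # chance a 50%-penetrant clone is called positive
```

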