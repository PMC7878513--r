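---
title: "Methods and design choices in beecaste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in beecaste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beecaste` implements the statistics used to compare nurse and forager
worker subcastes across eusocial bee species: annotation-based overlap of
differentially expressed (DE) gene sets under a resampling null,
rule-based taxonomic-conservation classification of orthogroups, and
context-resolved gene-body DNA methylation analysis coupled to expression.
This vignette explains the models, the tunable parameters and the design
decisions, in that order of importance; the README shows the worked
examples.

## Cross-species overlap of DE gene sets

Species without curated one-to-one orthology are compared through the
free-text protein annotations of their DE genes. `normalize_terms()`
lowercases, collapses whitespace, deduplicates, and removes empty entries
and anything containing "uncharacterized protein": such annotations carry
no information that could match across species, so keeping them would
inflate both set sizes without adding matchable content. Matching is exact
string equality after normalisation — no fuzzy matching. Instead,
obviously over-generic matches ("transporter"-level annotations) are
handled by an explicit, configurable curation pattern list
(`curate_terms()`), applied **only** to the reported shared-term list;
the test statistic always uses the uncurated computational overlap, so
manual judgement can never manufacture significance.

`overlap_random_test()` draws, in each of `reps` replicates, `|A|` terms
without replacement from species A's annotated-term universe and `|B|`
from B's, and records the intersection size. The one-sided empirical
p-value is `(m + 1) / (reps + 1)`, never zero; with `reps = 10000`
(default) the smallest reportable p is about `1e-4`, which is the
resolution appropriate to the smallest p-values such comparisons
realistically support. A published analysis of this kind may print
`p = 0`; our convention reports the floor instead, which we consider the
defensible reading of an empirical tail.

Two universe conventions are possible and the choice is not innocuous.
The default, `universe_mode = "per-species"`, draws each set from its own
species' annotated transcriptome, because that is the sampling frame the
DE sets actually came from. `"shared"` mode draws both sets from the
union, making the null exactly the convolution of hypergeometrics; it
exists because it admits closed-form moments
(`mean = n_A n_B / N`) used by the oracle tests. The universes are the
*annotated* term sets only: normalisation removes unannotated entries
before the universe is formed, which is stated here because the
alternative (counting unannotated transcripts in the frame) would shrink
the null mean.

`stratified_overlap()` runs the test for the full sets and for the
nurse- and forager-biased strata. The per-stratum seeds are derived
deterministically from the given seed so the three results are
individually reproducible.

## Taxonomic-conservation classification

Orthogroup presence over an 11-dataset panel (two honeybees, two
bumblebee proteomes plus the focal bumblebee transcriptome, two orchid
bees, two stingless-bee proteomes plus the focal stingless-bee
transcriptome, one outgroup) is classified by `classify_orthogroup()`
with a priority-ordered rule list evaluated first-match-wins and closed
by a catch-all `other`, so classification is total and deterministic.

Several category boundaries are genuinely ambiguous in prose, and we
fixed interpretations rather than leave them implicit; all are editable
via YAML rule files (`read_category_rules()`) without code changes:

* **apinae** ("present in all species") requires presence in at least one
  dataset *per species*, not in all 11 datasets: the two datasets of the
  focal species are alternative observations of the same gene catalogue,
  and requiring both would reclassify genes merely missed by one assembly.
* **corbiculates** requires at least one member of each of the four
  corbiculate clades and absence from the outgroup (otherwise the pattern
  would be apinae, which has priority anyway).
* **stingless_bees_F** (all three stingless datasets) is evaluated before
  **stingless_bees** (which ignores the *F. varia* state), so the more
  complete pattern takes the more specific label.
* **bterrestris_G** vs **species_specific**: we take `bterrestris_G` to be
  presence in *both* focal-bumblebee datasets (transcriptome and
  proteome) and nowhere else — i.e. genome-supported but bumblebee-clade
  restricted only to that species — while `species_specific` is presence
  in exactly one focal transcriptome dataset. These two wordings overlap
  in the source prose; the shipped rules make them disjoint and the
  interpretation is ours, documented, not asserted as the original
  authors' intent.

`exclude_unassigned()` drops focal genes that orthology inference left
unassigned, on the argument that genes without support from any related
sequence are more likely assembly or annotation artefacts than real
novelties; the audit records both fractions so the decision is visible.
`category_proportions()` then reports the transcriptome ring and the
focal (DE) ring, each closing to 1 within 1e-12.

## Methylation statistics

Sites below 10× coverage (default `min_cov = 10`) are removed before any
statistic; at lower coverage a site-level methylation fraction is too
quantised to be meaningful.

**What counts as a methylated cytosine** is not standardised. The default
rule is `mc_count >= 1` after the coverage filter — the simplest reading
of "methylated cytosines reported". A binomial alternative
(`rule = "binomial"`) calls a site only if the one-sided tail probability
of its methylated-read count under a per-read error rate `error_rate`
(default 0.005, a typical bisulfite non-conversion rate) is below 0.01.
Both are shipped because the choice changes the composition denominators;
the default is the more inclusive rule and is stated in every report.

**Per-transcript mean mC** is the unweighted arithmetic mean of site-level
fractions (×100). The coverage-weighted alternative
(total mC reads / total reads) is computed alongside in
`transcript_mc()`: the two differ exactly when coverage is uneven across
sites (a 0.8-level site at 10× plus a 0-level site at 90× has mean 40%
but weighted 8%), and reporting both makes the convention auditable.

**The context census** counts both strands: a plus-strand G is a
minus-strand cytosine whose following base is the complement of the base
preceding the G. Sites at sequence ends or adjacent to an ambiguity
letter have undefined context and are excluded from the denominator (they
are counted in an `undefined` bucket). A consequence worth knowing: CpG
sites always occur in strand pairs, because a plus-strand `CG` implies
the complementary minus-strand `CG`.

**CG enrichment** compares the CG fraction of methylated sites against
the availability census by resampling context labels; since only the
CG/non-CG split enters the statistic, the draw is a binomial with the
census CG proportion — the exact binomial tail is the oracle the tests
check against.

**The gene-set z-test** treats the global per-transcript mean-mC
distribution as the reference population with known mean and SD, and
tests a subset mean one-tailed. The default tail (`"auto"`) follows the
sign of the observed difference, matching how "significantly different
from the transcriptomic mean" is used in practice; note that this
doubles the nominal null rejection rate relative to a fixed tail, so the
calibration experiments (below) fix `tail = "greater"`. A degenerate
population (zero SD) is an error, not a silent NaN.

**Methylation–expression coupling** uses Spearman correlation with
average-rank ties, computed separately for CG- and CW-context transcript
means, over the full transcriptome or a designated subset. Expression is
whatever normalized count the caller supplies; the package performs no
internal normalization.

## The synthetic generators

The generators define the study conditions the tests run under; they are
fixed defaults, not tuning knobs.

`simulate_methylome()` emulates a nurse whole-bisulfite profile mapped to
a transcriptome: 500 transcripts of mean length 1500 bp, a both-strand
C-site census with CG fraction 0.2314 (bumblebee-like; 0.1544 for the
stingless-bee-like profile), per-context methylation probabilities
CG 0.02 / CW 0.004 / CC 0.002 (giving a transcriptome mean mC in the
0.6–0.7% range and a mostly-CG methylated-site composition), Beta(5,1)
levels at methylated sites (gene-body mC in insects is high-or-absent),
and negative-binomial coverage (mean 30, dispersion 0.3) chosen so the
10× filter removes a consequential ~7–10% of sites. Sequences are built
on an A/T background with planted context motifs (palindromic `CG`
pairs; `CA`/`CT`; `CCN` so that exactly one defined CC site results), so
the realized census is a multinomial draw from the context mix by
construction. Expression is log-normal with its log-mean coupled to the
transcript's CG methylation propensity (coupling 1.2) and not to CW,
planting the sign pattern (CG positive, CW null) that the correlation
estimator must recover. What this generator does **not** emulate: real
sequence composition (the background contains no unplanted C/G), read-
level bisulfite errors, fragment-level coverage autocorrelation along a
transcript, and differential methylation between samples. Passing tests
therefore demonstrate estimator correctness under the declared sampling
model, not robustness to alignment artefacts.

`simulate_de_pair()` plants an exact normalised-term overlap `k` with a
concordant direction split; defaults (universes 4000/4500 sharing 2500
terms, DE sets 400/120, k = 15 with 7 nurse- and 2 forager-concordant)
give a chance expectation near 7 shared terms, the regime of a
bumblebee-vs-stingless-bee comparison. Annotation case is jittered so
normalisation does real work. Batch structure in the underlying counts is
out of scope: DE tables are simulated at the results level.

`simulate_orthogroup_matrix()` emits presence patterns constructed to
satisfy each requested category under the shipped rules and verifies each
with the classifier at generation time, so recovery is exact by
construction — the value of the test is that it stays exact under rule
refactoring. `simulate_ontology()` builds a rooted tree (default depth 4,
branching 3) and plants one enriched level-3 term via weighted,
without-replacement study-set sampling at a stated odds ratio.

## Numerical and calibration choices

* CGmap levels are stored to two decimals (consistency tolerance 0.005
  against `mc_count / coverage`), matching the upstream caller's print
  format.
* Ontology depth counts the root as level 1 and uses shortest `is_a`
  paths by default (`mode = "longest"` available): with multiple
  inheritance the shortest path is the conventional reading of "level".
  Only `is_a` edges are traversed.
* Fisher enrichment uses the exact hypergeometric upper tail with no
  multiplicity correction by default, mirroring raw `p < 0.01` reporting;
  a Benjamini–Hochberg column is available behind a flag.
* Empirical p-values use `(m + 1)/(reps + 1)` throughout.
* The p-value calibration experiment runs the overlap test at universe
  8000 with set sizes 2000/2000 and 500 replicates per run, 500 runs.
  The sizes are chosen so the null overlap distribution has SD ≈ 17 and
  the p-value support is near-continuous; a Kolmogorov–Smirnov
  uniformity check is meaningless at Table-scale set sizes, where the
  observed overlap takes a handful of values and the empirical p is
  intrinsically discrete. The z-test size check uses 1000 subsets of 50
  transcripts from a 300-transcript simulated methylome, with the fixed
  `greater` tail for the reason above.
* Default problem sizes throughout (500-transcript methylomes,
  10000-replicate resampling) keep any single check in the seconds-to-
  a-couple-of-minutes range; they are stated in the tests and the
  acceptance script, and all scale up linearly if heavier runs are
  wanted.

## Limitations

The package consumes DE tables and orthogroup tables as inputs; it does
not run read QC, assembly, quantification, DE fitting, orthology
inference or bisulfite alignment. Annotation-based matching is
deliberately conservative: paralogous genes sharing an annotation string
are counted as a single term, and differently-worded annotations of the
same gene do not match. The one-nurse-methylome-per-species design the
methylation statistics mirror means between-sample variance is not
estimable; the z-test quantifies deviation from the transcriptome
profile of the same sample, nothing more. The semantic-similarity
reduction of enriched-term networks and weighted (decorrelating) Fisher
variants are intentionally out of scope; reports based on classic Fisher
should not be compared numerically against weighted-variant results.
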