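---
title: "Methods: consensus-based pre-miRNA hairpin detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-based pre-miRNA hairpin detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premirna)
```

## The detection problem and the model

A pre-miRNA is a ~60–180 nt RNA whose secondary structure is a stem-loop: a
mostly base-paired helix closed by an unpaired terminal loop. Genomes fold
into vast numbers of such stem-loops, almost all of which are not miRNA
precursors, so ab initio detection is a heavily imbalanced binary
classification problem over hairpin-shaped candidates. No single published
feature set or learner dominates; this package therefore implements a
*comparative* design: many per-study classifiers trained under one identical
protocol, then fused into consensus predictors.

The pipeline is: fold → extract → parameterize → classify → combine.

### Folding backend

Structures come from a pluggable backend. The default is a Nussinov-style
maximum base-pairing dynamic program over {AU, UA, GC, CG, GU, UG} with a
minimum terminal loop of 3 nt — the smallest loop sterically possible in RNA.
Its recurrence maximizes the pair count; the reported "energy" is the
surrogate score $E = -n_{bp}$ and is flagged as such in every downstream
record (`energy_is_surrogate`), so thermodynamic features computed from it
are explicitly backend-dependent. Traceback is deterministic: the outermost
pair is placed at the smallest opening index and the smallest admissible
closing partner, so folding is idempotent.

A maximum-pairing model is not a thermodynamic model: it has no stacking
energies, so its structures are pairing-maximal rather than
energy-minimal. It is, however, fully self-contained, deterministic and
testable against exhaustive enumeration, and it preserves what the
downstream steps need — stems, loops, and their counts. An `RNAfold` wrapper
(`backend = "vienna"`) supplies true minimum-free-energy structures in
kcal/mol when the binary is on the PATH; suboptimal enumeration then
delegates to `RNAsubopt`.

Under the fallback, suboptimal structures are generated by re-running the
dynamic program once per optimal base pair with that pair forbidden. Each
run yields the best structure lacking that pair; after deduplication these
are ordered by surrogate energy. This costs $O(n_{bp} \cdot n^3)$ and works
at real hairpin lengths, where exhaustively enumerating all structures (the
testing oracle, guarded to 14 nt) would be combinatorially impossible.
Probability-based (partition function) features are declared in the registry
but capability-gated: neither built-in backend provides base-pair
probabilities, and requesting such a feature is an explicit error rather
than a silent NA.

### Features

The registry holds 73 features in four families:

* **SEQ (22)** — mononucleotide frequencies, overlapping dinucleotide
  frequencies (denominator $L-1$), GC fraction, length. The mono and
  dinucleotide blocks each sum to 1.
* **TRIPLET (32)** — for every interior position, the paired/unpaired status
  of the three surrounding positions combined with the center nucleotide
  ($8 \times 4$ bins, both bracket characters mapped to "paired" before
  windowing), normalized by $L-2$.
* **STRUCT (13)** — base-pair count, paired fraction $2 n_{bp}/L$, pairing
  density $dP = n_{bp}/L$, terminal loop length, longest stacked-pair run,
  stem count, loop count, and AU/GC/GU pair counts and fractions.
* **THERMO (6)** — the folding energy and the MFE-index family:
  $dG = \mathrm{MFE}/L$, $\mathrm{MFEI1} = dG/\mathrm{GC\%}$,
  $\mathrm{MFEI2} = dG/n_{stems}$, $\mathrm{MFEI3} = dG/n_{loops}$,
  $\mathrm{MFEI4} = \mathrm{MFE}/n_{bp}$.

Conventions that silently differ across the literature are fixed here and
recorded in the schema: GC enters MFEI1 *as a percentage* (50.0, not 0.5); a
*stem* is a maximal run of ≥ 3 stacked pairs, the same rule the extraction
step uses; a *loop* is a maximal unpaired run; the terminal loop length of a
multi-hairpin structure is its largest hairpin loop. Any feature whose
denominator is zero is defined as 0, with the guard noted in its
description — degenerate hairpins thus produce finite vectors, never
NaN/Inf.

The 13 study profiles reconstruct the published studies' feature selections
from this registry, in a fixed group-priority order per study, and each
carries the study's declared feature count as metadata. Where the original
count cannot be met from the registry (for example the 99-feature study) the
profile holds the closest reconstruction and `count_matches = FALSE`; the
profiles are documented approximations, not claims of fidelity to
unpublished feature code.

### Training protocol

Training uses balanced Monte Carlo cross-validation (default 1000
iterations, 70/30 split). Per iteration, `floor(0.7 n_{pos})` positives and
the same number of negatives (sampled without replacement) form the training
set; the remaining positives plus an equal number of fresh negatives form
the test set, so both sides are always 1:1 balanced and disjoint. Crucially,
the split stream depends only on (master seed, iteration), never on the
profile or learner, so every (profile, classifier) pair sees byte-identical
splits — the fair-comparison guarantee. Per-iteration substream seeds are
derived arithmetically from the master seed, so any iteration is
reproducible in isolation.

Learners are the standard R fits: `rpart` decision trees, `e1071` naive
Bayes and SVM, with their package-default hyperparameters recorded in
provenance rather than tuned — the comparison is between feature sets under
one common protocol, not a hyperparameter search. Eight measures are stored
per iteration; the best model per pair is selected by test accuracy, ties
broken by F-measure and then by the earlier iteration. Selection by
F-measure or Youden's J is exposed as an option. All three learners,
including the SVM, persist through the JSON model envelope.

### Consensus schemes

Per-study scores in $[0,1]$ are combined six ways: majority vote over the 13
studies (≥ 7 positive votes ⇒ miRNA) separately for DT and NB; the score
averages with the 0.5 boundary (a mean of exactly 0.5 is miRNA — the
boundary is only strict on the negative side); the three-way rule (either
average **>** 0.89 ⇒ miRNA, else either **<** 0.5 ⇒ negative, else
*candidate*); and an MLP meta-classifier trained on the score matrix under
the same MCCV procedure (one hidden layer as wide as the input, weight decay
$10^{-3}$, selection by accuracy then F-measure). Two deliberate
disambiguations: when one average exceeds 0.89 while the other is below 0.5
the miRNA clause wins (clause order), and the case is flagged
`rule_conflict`; and a vote vector with a missing study is an error — the
vote is never renormalized over fewer studies.

Model ranking across data sets uses average ranks under ties (minimum-rank
is an option), summed across data sets with equal weight; with $M$ models
and $D$ data sets the total ranges from $D$ (best everywhere) to $MD$ (worst
everywhere, no ties). ROC curves sweep the distinct score values with ties
grouped; the trapezoidal area equals the Mann–Whitney pair-concordance
statistic, which the tests verify directly and against an independent ROC
implementation. Genome-scan confidence thresholds are the lower quartile of
ensemble scores on positive controls, using the same linear-interpolation
(type 7) quantile estimator as the dataset constructors — one estimator
everywhere, since quartile conventions differ across software.

### Data-set constructors

Three synthetic constructions mirror the evaluation sets used in this
field. *Shuffled*: seeded Fisher–Yates permutation of each hairpin's
residues (exact multiset preservation); a dinucleotide-preserving mode
(random Eulerian walk over the transition multigraph) is available because
plain shuffling destroys stacking statistics, but the simple permutation is
the default reading of "shuffling sequences". *NotBestFold*: the same
sequences paired with their best suboptimal structure; sequences admitting
no alternative are skipped and logged. *FR/BQ/AM feature-space sets*
(default 5000 rows): each feature drawn independently and uniformly within
its per-feature min–max range, interquartile range, or 40–60 percentile
band. Independence across features is implied by the per-feature
construction; the quantile nesting AM ⊆ BQ ⊆ FR holds per feature by
construction. Every constructor records operation, parameters and seed, so
a synthetic set regenerates bit-identically from its provenance.

### Genome scanning

Chromosomes are cut into 500 nt windows every 250 nt (0-based half-open
coordinates; BED convention). Window starts run at every multiple of the
step while they precede the chromosome end, and a trailing window shorter
than 500 nt is kept when it is at least the minimum hairpin length —
dropping it would blind the scanner to chromosome ends; interior positions
are covered twice. Both strands are folded (T→U; reverse complement for the
template strand). Hairpin elements are every terminal loop of ≥ 3 nt
extended outward through the enclosing nested stem — across bulges and
internal loops — until the structure branches or ends, kept when the stem
contains ≥ 3 consecutive stacked pairs. Candidates are length-filtered to
36–180 nt (the span of human precursor lengths), deduplicated genome-wide by
sequence (first locus kept in (chrom, start, strand) order, duplicate loci
listed in a sidecar — duplicate *sequences* are redundant for training but
multiple *loci* remain biologically meaningful), parameterized, scored by
every stored model, labeled by the consensus schemes, and thresholded on
the averaged score.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| minimum terminal loop | 3 | nt | steric minimum for an RNA hairpin loop |
| stem rule | ≥ 3 stacked pairs | pairs | extraction definition, shared with `n_stems` |
| hairpin length bounds | 36–180 | nt | span of human precursor lengths |
| window / step | 500 / 250 | nt | every position seen in two frames |
| train fraction | 0.7 | — | 70/30 protocol; higher ratios overestimate performance |
| iterations | 1000 | — | full protocol (tests and examples use 3–10) |
| vote threshold | 7 of 13 | votes | majority of the studies |
| rule boundaries | 0.89, 0.5 | score | the consensus rule's constants |
| feature-space rows | 5000 | rows | construction size of FR/BQ/AM sets |
| control threshold | lower quartile | score | confidence cutoff from positive controls |
| fixture stem / loop | 20 / 6 | nt / nt | 46 nt designed hairpins, inside the length filter |

## What the synthetic fixtures do and do not show

The generators define the package's study conditions. Designed stem-loops
(random arm + loop + perfect complement, GC-biased arms) guarantee
extractable hairpins; shuffled copies provide matched negatives. Separable
Gaussian feature clouds (class means `separation` pooled SDs apart; the
separation-4 setting is near-perfectly separable, separation 0 is the null)
exercise the train→predict→evaluate path with a known answer. The planted
genome (uniform background, five perfect-stem hairpins at non-overlapping
loci on random strands in 10 kb) validates coordinate arithmetic and
recovery.

These fixtures establish that the machinery is correct: splits balanced,
schemas enforced, coordinates exact, classifiers able to recover planted
signal, rules at their stated boundaries. They do not establish biological
performance. Real pre-miRNA discrimination is far harder than separation-4
clouds; real negatives (coding-region pseudo-hairpins) are not shuffles; a
uniform background under a maximum-pairing folder yields many more incidental
stem-loops than a thermodynamic folder on real genomic sequence. Claims
about sensitivity/specificity on miRBase-scale data require the real
external data sets, which users can supply as plain FASTA through the same
loaders.

## Numerical choices and degenerate inputs

Frequency-block normalization is exact up to 1e-9 in the tests. All
zero-denominator features and metrics are defined as 0 and flagged, never
NaN. Quantiles are type 7 everywhere. Ranking ties get average ranks by
default. Ambiguity codes abort sequence normalization unless the explicit
N→A mapping policy is requested (with a warning), because silent coercion
corrupts composition features. Empty inputs propagate as empty outputs
(empty genome → zero-count summary; empty record list → 0-row matrix with a
full header); structurally invalid inputs (unbalanced brackets, mismatched
lengths, missing RPM metadata, unknown features) are structured errors
naming the offender. Model schemas are matched strictly at prediction time —
names and order — and a mismatch is an error before any folding work.

Problem sizes in the shipped tests and acceptance script are scaled to the
package's own fixtures: 220 sequences for the folding oracle, 1000 hairpins
for the shuffle invariant, 120 hairpins behind the feature-space sets, 1200
points and 6 iterations for the separable-recovery runs, 50 inspected
splits of the 1000-positive MCCV contract, and one 10 kb planted
chromosome. The full 1000-iteration protocol is the default for real use.

## Known limitations

* The fallback folder's surrogate energies make THERMO features
  backend-dependent; models trained under one backend must be applied under
  the same backend (the schema records it).
* Study profiles are reconstructions from the registry, not the original
  studies' code; declared counts are preserved as metadata where the lists
  cannot be.
* No partition-function features, no pseudoknots, no weighted consensus
  (all studies enter with equal weight; the hook exists), no
  similarity-based clustering of scan output, and no mature-miRNA
  localization — the scanner stops at scored precursor candidates.
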