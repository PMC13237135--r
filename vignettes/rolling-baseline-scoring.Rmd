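---
title: "Scoring deep mutational scans against a rolling silent baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring deep mutational scans against a rolling silent baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollscreen)
library(dplyr)
```

## The problem

A saturation-mutagenesis proliferation screen introduces every programmed
variant of a gene into cells as a pool, lets selection act over several
population doublings, and sequences the pool at the start and end of the
experiment. For a tumor-suppressor such as SMARCB1 re-expressed in a
SMARCB1-deficient line, the functional (wild-type-like) protein suppresses
proliferation, so loss-of-function (LOF) variants *enrich* during the
experiment and functional ones deplete. The raw signal is each variant's log2
fold-change (L2FC) in read abundance between the two timepoints.

Raw L2FC values are not directly comparable along the gene: tiled library
construction and amplification leave regional technical artifacts in which
variants across a stretch of codons share a systematic L2FC offset. The
scoring model in this package removes those artifacts by standardizing every
variant against the *silent* (synonymous) variants in its own codon
neighborhood, under the assumption that silent changes are functionally
neutral:

$$ z = \frac{\mathrm{L2FC}_{variant} - \overline{\mathrm{L2FC}}_{silent,w}}{\mathrm{SD}(\mathrm{L2FC}_{silent,w})} $$

where $w$ is the window of codons within ±2 positions of the variant's codon
(a 5-codon window, truncated at the gene ends). Because any additive artifact
that is constant across a window cancels in both the numerator and the
(shift-invariant) SD, z-scores are exactly invariant to block-constant L2FC
shifts and to global positive affine transformations of the L2FC scale; both
invariances are asserted exactly in the test suite.

Per-replicate z-scores are averaged into the final functional z-score, with
the across-replicate SD retained as a consistency measure. Downstream calls
use strict thresholds: a variant is LOF when its mean z exceeds 2, and a
residue is intolerant when its mean z over observed missense substitutions
exceeds the mean + 2 SD of residue averages.

## The parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pseudocount` | 1 | reads | keeps zero counts finite in L2FC |
| `normalize` | TRUE | — | convert counts to library proportions |
| `window_radius` | 2 | codons | half-width of the silent window |
| `min_silent` | 2 | variants | floor before symmetric window expansion |
| `sd_floor` | 1e-6 | log2 | guard against zero-SD windows (flagged) |
| `lof_threshold` | 2 | z units | strict LOF cutoff on mean z |
| `k_sd` | 2 | SDs | residue intolerance cutoff above the mean |

The L2FC mechanics (pseudocount, library-size normalization) are a package
choice — the screen convention only fixes the z-score construction — and are
therefore exposed in full. The affine invariance of z means the LOF calls do
not depend on them in well-covered regions.

Two fallbacks handle degenerate windows. A window holding fewer than
`min_silent` silent variants expands symmetrically one codon at a time until
the minimum is met (logged and flagged), so baselines remain local where
possible but are always defined when the gene has any silent variant at all.
A window whose silent L2FCs are numerically identical would give an infinite
z; instead `sd_floor` is substituted and the score flagged, never silently.
Variants with no defined baseline, or scored in fewer than `min_replicates`
replicates, are reported as missing (`NA`) rather than guessed.

Boundary conventions are strict and deliberate: LOF requires `mean_z > 2`
(a variant at exactly 2 is not called), residue intolerance requires strictly
exceeding the cutoff, and all SDs are sample SDs (n − 1) because windows are
small. Predictor thresholds go the other way — CADD PHRED ≥ 20, REVEL ≥ 0.75,
AlphaMissense ≥ 0.564 are non-strict, as published by each tool.

## What the synthetic screen emulates

`simulate_library()` emits 22 records per codon — 19 missense, 1 nonsense,
1 frameshift, 1 silent — so a 385-codon gene yields 8470 variants,
approximating the scale of a real SMARCB1 tile (8418 programmed alterations).
A silent record at every codon guarantees a defined rolling baseline
everywhere; sparse-silent behavior is exercised separately through the
window-expansion fallback.

`simulate_screen()` draws start counts from a multinomial over uniform
proportions at the configured depth, then end counts from proportions scaled
by $2^{g\,s + a}$, with $g$ the number of doublings, $s$ the variant's true
per-doubling selection coefficient and $a$ any regional artifact shift. The
defaults are the study conditions: depth $10^6$ reads per sample, 3
replicates (emulating three cell-line contexts), 6 doublings (the middle of
the experimental 4–8 range), LOF effect 1 log2 per doubling, and 5% of
missense variants planted as LOF. Nonsense and frameshift variants are LOF by
construction; an optional `terminal_escape_start` attenuates truncations near
the C terminus (factor 0.5), emulating late truncations that retain partial
function. Each replicate draws from its own child RNG stream derived from the
master seed, so output is bit-identical for a fixed seed.

The generator does *not* emulate read-level errors, lentiviral template
switching, cloning bias, or variant dropout; passing recovery tests therefore
demonstrates correctness of the scoring machinery under multinomial
sequencing noise with planted regional artifacts, not robustness to every
failure mode of a wet screen.

## Null behavior of the rolling z-score

With one silent variant per codon the 5-codon window holds 5 silent L2FCs,
so under a fully neutral screen the per-replicate z is distributed as
$\sqrt{1 + 1/5}\; t_4$ — noticeably heavier-tailed than standard normal (SD
≈ 1.55) because the baseline SD is estimated from only 4 degrees of freedom.
Averaging across 3 replicates pulls the final mean z in (theoretical SD
$\sqrt{1.2 \cdot 2 / 3} \approx 0.894$; the empirical SD fluctuates around
that value because the fourth moment of $t_4$ diverges). The practical
consequence, verified by simulation in the acceptance suite at 200 codons,
depth $10^6$ and 3 replicates, is that the *fraction of null variants called
LOF at mean z > 2 is about 0.011–0.019*, comfortably below the 0.0455
two-sided normal tail nominally associated with the threshold: replicate
averaging more than compensates for the heavy per-replicate tails. Users
scoring screens with fewer replicates or sparser silent coverage should
expect anti-conservative tails and may wish to raise the threshold.

## Downstream statistics

The remaining modules re-implement the study's bespoke downstream
computations in testable form.

**Interval algebra** (0-based half-open BED coordinates throughout):
`merge_intervals()` unions intervals with gap ≤ distance (a gap of exactly
the merge distance merges, matching `bedtools merge -d`);
`reproducible_peaks()` keeps intervals of one replicate overlapping the
other by ≥ 1 bp; `partition_consensus()` labels consensus peaks
gained/lost/persistent with gained-before-lost priority for the rare
double-overlap (the labels always partition the input). `spikein_factor()`
is the exogenous-genome normalization `1/((ecoli/human)·100)`.
`quadrant_concordance()` tabulates the signs of paired accessibility and
expression fold-changes; the default test is a two-sided Fisher exact test
on the signed 2×2 table, with an observed-vs-expected 50/50 construction
available (`method = "observed_expected"`) since the verbal description of
the original analysis admits both readings. Zero fold-changes are excluded
(upstream |L2FC| filters normally preclude them); the odds ratio is
reported as `Inf` under complete concordance, where formal testing is
uninformative.

**MD trajectory statistics**: `contact_frequency()` counts frames in which
any heavy-atom pair of two residues lies strictly within 4.0 Å (hydrogens
identified by element, with a leading-letter fallback for inputs lacking
element columns). Energy differences follow a mutant-minus-wild-type
convention (positive = destabilizing); contact differences follow
wild-type-minus-mutant (positive = contact lost in the mutant). The two
opposite conventions are preserved deliberately as printed in the original
formulations and documented on each function. `ddelta()` subtracts a control
variant's per-replicate differences (matched by replicate identifier, since
runs are paired); `one_sample_significance()` combines a two-tailed
one-sample t test against zero with an effect-magnitude criterion (0.5
kcal/mol for van der Waals, 1.0 for electrostatics), and
`contact_diff_map()` retains residue pairs with mean normalized contact loss
above 0.20, reporting gains separately. Whether the 20% filter applies to
the control-normalized or raw loss is ambiguous in the source description;
the control-normalized reading is the default with `on = "df"` as the
alternative.

**Proteomics**: `ms_preprocess()` log2-transforms LFQ intensities and drops
proteins missing in more than 3 samples (counted across all samples, the
literal reading; exactly 3 is retained). `ms_impute()` draws missing values
from a normal centred `downshift` sample-SDs below the sample mean with
width 0.3 sample-SDs — the Perseus column-wise convention; the stated width
and shift are ambiguous between SD multiples and absolute log2 units, so
`mode = "absolute"` provides the latter. `ms_differential()` uses the
pooled-variance Student t test (the Perseus default; Welch behind a flag)
with dual significance criteria |L2FC| > 1.5 and p < 0.05, deliberately
uncorrected for multiple testing to match the original procedure.

## A worked example

```{r example}
lib <- simulate_library(n_codons = 120, seed = 7)
model <- effect_model(
  lof_effect = 1, lof_fraction_missense = 0.06, doublings = 6,
  depth = 1e6, n_replicates = 3, seed = 7
)
sim <- simulate_screen(lib, model)
scores <- dms_score(sim$counts)

joined <- inner_join(as_tibble(scores), sim$truth, by = "variant_id")
joined |>
  group_by(true_class) |>
  summarise(n = n(), called_lof = sum(lof, na.rm = TRUE))

prof <- residue_profile(scores)
sum(prof$intolerant)
```

## Design choices and numerical notes

- A silent variant contributes to its own codon's baseline. Excluding it
  would leave single-silent windows undefined; the chosen convention matches
  "all silent codons within the window" and is pinned by the brute-force
  oracle tests.
- Windows truncate at the gene termini; there is no wraparound.
- The residue-intolerance cutoff is computed over all residues with at least
  `min_subs` scored substitutions by default. Restricting to
  positive-average residues (`positive_only = TRUE`) reproduces rank-plot
  style analyses that drop depleted residues; with heavy left tails the two
  modes give different cutoffs, and the all-residues mode is the less
  data-dependent default.
- The mean-z > 2 threshold is one-sided while the 0.0455 tail often quoted
  for it is two-sided; the package documents the threshold as strict
  one-sided and leaves the nominal tail probability as a description, not a
  guarantee.
- Replicates are equally weighted in the final score; no precision weighting
  is attempted because window SDs are estimated from very few silents.
- Problem sizes in the test and acceptance suites — 200-codon genes at depth
  $10^6$ with 3 replicates for calibration and recovery, ≤ 500 intervals,
  ≤ 200 atoms and ≤ 40-count tables for oracle equivalence — were chosen so
  every stochastic check has comfortable Monte-Carlo margins while the whole
  suite completes in about a minute.

## Known limitations

- The simulator plants binary effects (neutral vs one LOF effect size); it
  does not emulate the continuum of intermediate effects visible in real
  screens.
- Scores for variants in silent-poor regions lean on expanded windows and
  are less local; the `expanded` flag in the baseline table marks them.
- The concordance join is on `variant_id`; nucleotide-level resolution of a
  protein variant across multiple SNVs is supported only insofar as the
  caller supplies SNV-level identifiers on both sides.
- `contact_frequency()` is a plain R implementation intended for
  post-processed, already-aligned coordinate tables at analysis scale
  (hundreds of atoms, thousands of frames), not a trajectory engine.
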