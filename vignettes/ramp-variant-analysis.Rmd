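---
title: "Methods: ramp-sequence detection and variant effect analysis"
author: "rampvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ramp-sequence detection and variant effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampvar)
```

## The model

A *ramp sequence* is a stretch of slowly translated codons at the 5' end of a
coding sequence.  By slowing the first ribosome, it evenly spaces the ribosomes
that follow, reducing downstream collisions and the mRNA/protein degradation
triggered by ribosome-associated quality control.  Whether a codon is "slow"
depends on the tRNA pool of the tissue or cell type at hand, so the same gene
can have a ramp in one context and none in another — and a single synonymous
variant can destroy a ramp without touching the protein sequence.

`rampvar` operationalizes this as follows.  Each context is an *efficiency
table*: a strictly positive weight for each of the 61 sense codons,
normalized so the best codon is 1 (*relative codon adaptiveness*).  For a
coding sequence $c_1 \dots c_n$ with per-codon efficiencies $x_i$, translation
speed over a ribosome-sized window of $w$ codons starting at codon $i$ is the
harmonic mean

$$ H_i = \frac{w}{\sum_{j=i}^{i+w-1} 1/x_j }, $$

which is dominated by the slowest codons in the window — exactly the property
wanted for bottleneck detection.  The gene-wide speed $G$ is the harmonic mean
over all profiled codons.

A ramp is called in five steps:

1. compute $G$;
2. compute the sliding-window profile $H_1, H_2, \dots$ (stride one codon,
   matching a ribosome advancing one codon at a time);
3. take the maximal run of consecutive windows, **starting at window 1**,
   with $H_i < G$ — a slow region preceded by a fast first window is not a
   ramp, because ramps are a 5'-end phenomenon;
4. the run is a ramp iff it contains at least `min_ramp_windows` windows that
   are *low outliers* of the gene's full window-speed distribution;
5. the ramp extent is the last codon covered by the last outlier window.

Ties at $H_i = G$ break toward "not below": only strictly slow windows count.

### The initiation codon

The start codon is excluded from the speed profile used for detection.  Its
decoding is kinetically a different process — governed by initiation factors
and the initiator tRNA — and elongation-efficiency tables say nothing about
it.  Operationally this matters: the table value attached to ATG is an
elongation weight for *internal* methionines, and letting it stand at
position 1 puts an arbitrary weight inside every window of the candidate ramp
region.  In simulations with planted ramp-free controls this single codon was
the dominant source of spurious 5' "bottlenecks".  Window $i$ therefore
covers codons $i+1$ through $i+w$, and all reported ramp extents are in
original codon coordinates.  `codon_speed_profile()` retains the full
per-codon contract (`exclude_start = FALSE` by default); `detect_ramp()`
always profiles elongation codons only.  The terminal stop codon is likewise
excluded from all speed and pairing metrics (it is not decoded by elongation)
but retained for GC content, which is a nucleotide-level property.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` | 9 codons | ribosome footprint; the averaging window |
| `outlier_rule` | `"IQR"` | low-outlier definition over the window-speed distribution |
| `outlier_k` | 1.5 (IQR), 2.0 (SD) | fence multiplier |
| `min_ramp_windows` | 1 | outlier windows required in the 5' run |

The outlier rule is the one genuinely open design choice in the detector: the
notion of a "true outlier region" admits more than one formalization.  The
default is the Tukey fence $Q_1 - k \cdot \mathrm{IQR}$, which is robust for
the short, skewed window-speed distributions of single genes; a
standard-deviation alternative ($\bar H - k \cdot s_H$) is exposed behind
`outlier_rule = "SD"`.  Both are validated the same way — by planted-ramp
recovery on synthetic data — rather than by claimed equivalence to any
particular existing implementation.

A consequence of the fence-based rule worth knowing: on short genes whose
window distribution is dominated by transition windows (e.g. a 60-codon gene
with a 15-codon slow prefix), the IQR itself inflates and the fence can drop
below every window, so no ramp is called.  The fence is meaningful when the
fast body dominates the distribution — roughly, when candidate ramp windows
are fewer than a quarter of all windows.  This is why the synthetic default
CDS length is 200 codons (see below).

Normalization of efficiency tables divides by the *global* maximum
(tAI-style).  Only relative order and ratios enter the harmonic means, so any
global rescaling of a raw table leaves every profile and every ramp call
unchanged (this scale invariance is property-tested).  A per-amino-acid-family
normalization (CAI-style, `style = "cai"`) is available for sensitivity
analysis.  Zero efficiencies are rejected rather than floored: a zero makes
the harmonic mean undefined, and silently flooring would manufacture
bottlenecks.

## Variant effects

A single-nucleotide variant is applied to each isoform it maps onto
(coordinates are 1-based CDS positions; genomic positions are projected
through an exon map, with minus-strand allele complementing done by the
reader layer so the projection itself stays pure).  Its consequence —
synonymous, missense, nonsense — is derived from the standard genetic code;
a nonsense mutant is allowed to carry the premature stop it creates, while
FASTA input is strictly validated.

The wildtype and mutant sequences are then swept over every context
(2 × isoforms × contexts ramp calls, all counted in the run manifest).  Each
context yields a pairwise outcome — `LOSS`, `GAIN`, `SIZE_CHANGE`,
`UNCHANGED`, `NEITHER` — and the variant's category is the most severe
outcome under the ordering

`LOSS_OF_RAMP > GAIN_OF_RAMP > RAMP_SIZE > GENE_WITH_RAMP > NONE`.

`GENE_WITH_RAMP` marks a variant that changes no ramp but sits in a gene
carrying one in at least one context; `NONE` renders as `"N/A"`.
`GAIN_OF_RAMP` completes the state space (a variant can in principle create
a ramp) and ranks below loss.  Aggregation is order-invariant in contexts and
isoforms, and each variant is applied singly — multi-variant haplotypes are
out of scope.

## Expression statistics

The qPCR stage implements the standard ΔΔCt workflow.  Per well,
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{housekeeping}}$ and relative
expression is $2^{-\Delta C_t}$.  Tukey outlier removal (k = 1.5, per group,
on relative expression; skipped with a warning below four values) precedes
aggregation.  The fold change is computed from group means:

$$ \Delta\Delta C_t = 2^{-(\overline{\Delta C_t}_{\text{mut}} -
   \overline{\Delta C_t}_{\text{ctrl}})} , \qquad
   \text{ratio}_{\text{wt/mut}} = 2^{+(\overline{\Delta C_t}_{\text{mut}} -
   \overline{\Delta C_t}_{\text{ctrl}})} . $$

Both orientations are always reported and multiply to 1: when the mutant is
the lower-expressed group, the first is a small number and the second is the
"x-fold higher in the wildtype" figure.  Group comparison defaults to a Welch
two-sample t-test on the per-well values (unequal-variance-safe at this
design size), with a Mann–Whitney alternative (`test = "wilcoxon"`) and an
option to average within biological replicate first (`average_bio = TRUE`).
Per-well analysis treats wells as exchangeable; with a strong shared
biological-replicate effect that assumption understates the standard error,
which is exactly when `average_bio = TRUE` is the right choice.  ELISA values
are normalized to total protein (a scale-invariant ratio) and compared the
same way.

## The synthetic-data generator

Every input class has a generator, each a pure function of
`(seed, parameters)` — byte-identical output at a fixed seed, with the
caller's RNG state left untouched.  Defaults encode the study conditions the
package is validated under:

* **Efficiency tables**: 61 log-normal weights (`sdlog` =
  `efficiency_dispersion`, default 1), max-normalized.  Log-normality gives
  strictly positive, right-skewed weights with one dispersion knob;
  dispersion 0 degenerates to the uniform table.
* **Planted-ramp CDSs** (`gen_cds_with_planted_ramp`): 200 codons by default
  (a realistic CDS length — the motivating receptor transcript is ~300
  codons — and long enough that ramp windows stay under a quarter of the
  window distribution, keeping the Tukey fence meaningful); a slow prefix of
  `ramp_length` (default 15) drawn from the slowest codon quartile at a
  slow/fast mean ratio of at most 0.2, body from the fastest quartile, ATG
  start, terminal stop, no internal stops.  Quartile pools maximize contrast
  so the planted truth is unambiguous; they make no attempt to respect
  synonymous-family structure (the variant generator exercises that
  separately).
* **Fragile-ramp CDSs** (`gen_cds_fragile_ramp`): the entire bottleneck
  concentrated in one 5' codon chosen to admit a large synonymous
  single-nucleotide speedup.  This mirrors the situation a ramp-destroying
  synonymous variant exploits in practice — a broad 14-codon slow prefix is
  robust to any single swap, so "loss of ramp" demonstrations need a ramp
  that one codon carries.
* **Synonymous variants** (`gen_synonymous_variant`): exhaustive enumeration
  of synonymous single-nucleotide swaps in the first window;
  `RAMP_DESTROYING` takes the largest strict efficiency increase, `NEUTRAL`
  an equal-efficiency swap.
* **qPCR data**: 3 biological × 8 technical replicates per group.
  Housekeeping Ct ~ Normal(20, 0.2); the true ΔCt is a wildtype baseline
  (5 cycles) plus the planted `qpcr_log2fc` (default 7, the scale of a
  ~130-fold knockdown) for the mutant; technical noise SD 0.3 cycles on the
  target Ct, so per-well ΔCt noise equals the technical SD exactly.  The
  biological-replicate baseline shift defaults to SD 0 — wells exchangeable,
  matching the default per-well analysis and making its α calibration exact;
  `qpcr_bio_sd > 0` produces clustered data for exercising `average_bio`.
* **ELISA data**: log-normal replicates around a planted wildtype/mutant
  ratio (default 1.1635) with 8% CV, total protein around 200 µg/mL.

What the generator deliberately does **not** emulate: real tissue-specific
tRNA biology (true efficiency tables are correlated across tissues and
structured within synonymous families), sequence evolution, amplification
efficiency differences between qPCR targets, or plate/batch effects.  Passing
the planted-truth recoveries therefore shows the *pipeline machinery* is
correct and calibrated — not that any particular biological gene has or loses
a ramp.  Claims about a real transcript require its real CDS and real
per-context adaptiveness tables as inputs.

## Validation

The test suite checks, among other properties: exact agreement of
`detect_ramp` with an independently coded brute-force oracle on hundreds of
random sequence/table pairs; sensitivity and specificity of planted-ramp
recovery; protein invariance of every generated synonymous variant under
exhaustive SNV fuzzing; sweep bookkeeping (2 × isoforms × contexts logged
calls); recovery of a planted 7-cycle log2 fold change and the type-I error
rate of the default test under the null; and byte-identity of repeated
pipeline runs at a fixed seed.  `scripts/acceptance.R` recomputes all of
these from scratch at the problem sizes stated there (500 oracle pairs up to
200 codons, 100 + 100 planted/control seeds, 500 recovery and 2000 null
replicates) and writes them as JSON.

## Numerical and edge-case choices

* Quartiles use `stats::quantile`'s default (type 7) everywhere.
* Sequences with fewer than `window_size` profiled codons yield a flagged
  `present = FALSE` no-call, never an exception, so sweeps cannot abort on a
  short isoform.
* Uniform tables produce flat profiles; no window is strictly below the gene
  speed, so no ramp is ever called — the degenerate case is exact.
* `remove_outliers` on an all-equal group removes nothing (the fences collapse
  onto the data); a clean group can in rare cases lose more than a quarter of
  its values when the sample IQR collapses by chance, which the tests bound
  as a rare event rather than excluding.
* Ambiguity codes (N) are rejected, not imputed: one N makes codon speed
  undefined.
* Ties in `codon_family_rank` share the smaller rank (`ties.method = "min"`).

## Known limitations

* The detector is a calibrated reimplementation of the windowed
  harmonic-mean/outlier idea, not a clone of any specific tool; its outlier
  rule is declared and configurable precisely because published descriptions
  of such tools underdetermine it.
* Only single-nucleotide substitutions are supported — no indels, MNVs, or
  splice effects.
* Efficiency values are treated as opaque positive weights; the package does
  not compute tRNA adaptation indices from tRNA gene copy numbers or model
  wobble pairing.
* The qPCR stage assumes equal amplification efficiency between target and
  housekeeping gene (no Pfaffl correction, no standard curves).
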