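---
title: "Methods: pooled-plaque mutation calling and clonality correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-plaque mutation calling and clonality correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmut)
```

## The measurement problem

Transgenic rodent mutation reporter assays (Muta™Mouse and relatives) recover
a neutral reporter transgene — here the 3.1-kb bacterial *lacZ* gene — from
animal tissue, package it into phage, and select plaques whose *lacZ* copy is
inactivated. The classical endpoint is the *mutant frequency*: mutant
plaque-forming units over total plaque-forming units. Sequencing the mutants
adds three things the plaque count cannot give: the *mutation spectrum* (which
base changes the exposure induces), *hotspots* (which sites are targeted), and
a correction for *clonal expansion* — a single mutation amplified through cell
division inflates the mutant frequency without representing independent
mutational events.

Sanger sequencing of individual 3-kb mutants does not scale, so the design
analysed here pools all mutant plaques from one animal, amplifies the pool in
**two separate PCR reactions** (technical replicates), barcodes, and deep
sequences (~9×10⁴× per library). A mutation carried by one plaque of an
*n*-plaque pool is expected in ~1/*n* of the reads. Everything in this package
flows from that expectation.

## Calling model

For each library, reads are reduced to a position × event count table
(`read_pileup()` / `read_count_tsv()`), where an event is a substitution
(alternative base), an insertion (inserted sequence, anchored at the preceding
base), or a deletion (length, anchored at the first deleted base), with
strands collapsed because the transgene has a fixed orientation.

1. **Background ("false mutation proportion").** PCR and semiconductor
   sequencing artefacts recur at characteristic sites and rates that are
   consistent across libraries. `estimate_noise()` estimates the background of
   every (position, event) as the **median** of its read proportion across all
   libraries in the run, with libraries lacking the event contributing zero.
   The median is robust to the minority of libraries in which the event is a
   real mutation (at most the two replicates of one pool). The run should
   include every library sequenced together — both exposure groups and the
   wild-type negative-control pool — since the artefact field is a property of
   the platform and target, not of the treatment. A leave-one-out mode
   (`exclude=`) is provided for small experiments in which a sample's own
   libraries would otherwise be a sizeable fraction of the median.
2. **Subtraction.** `subtract_noise()` computes the *true mutation proportion*
   `max(0, total − background)` per event.
3. **Indel cap.** Indel error at homopolymers can dwarf substitution error.
   Indel events whose background exceeds the largest substitution background
   (`indel_cap()`) are masked from calling entirely (`indel_mask()`); the cap
   is the strictly-greater boundary, so an indel exactly at the cap survives.
4. **Thresholds.** `calling_threshold(n_plaques, stringency)` is
   `stringency / n_plaques` with stringency 1.0, 0.75 or 0.5. The stringent
   threshold is the default: relaxed thresholds call more events but the
   extra calls are dominated by replicate-discordant artefacts (the package
   reports the sweep via `filter_log`).
5. **Replicate concordance.** An event is called only if its true proportion
   reaches the threshold in **both** technical replicates
   (`call_mutations()`). Replicate-specific PCR errors fail this filter.
   Comparison is inclusive (`>=`); at these magnitudes ties are measure-zero,
   but the rule is fixed for determinism.
6. **Copy number.** The replicate-averaged true proportion divided by the
   expected single-copy proportion `1/n_plaques`, rounded half-up with floor
   1, estimates how many pooled plaques carried the event (`raw_count`). The
   stringent denominator is used regardless of calling stringency so counts
   always mean "copies among the pooled plaques".

Within an animal, each distinct event is one **independent** mutation; copies
beyond the first are **recurrent** (clonal). Spectra (`build_spectrum()`) use
independent mutations only; positional mutation-load plots may weight by
copies.

## Clonality calibration (LOD/linear model)

Pooled sequencing overestimates low copy numbers, and below a limit of
detection (LOD) copy number cannot be quantified at all. `fit_lod_linear()`
fits calibration mixtures (known copies per mutation) with a changepoint
model: candidates `L` are scanned over `[0, max(expected)]` by a coarse grid
plus step-halving refinement under a fixed budget of objective evaluations
(default 1000); for each candidate, points with `expected > L` get an OLS fit
of observed on expected and points at or below `L` are fit flat (their mean);
total squared error decides, with ties going to the smallest LOD, reported as
the integer it implies (floor). A lack-of-fit test against the saturated
per-level means is reported for the linear segment when expected values
replicate; it is informational, not a gate.

Applying the model (`adjust_count()`) follows the published convention:
observed counts at or below the LOD collapse to one copy; above it,
`(observed − intercept)/slope`, rounded half-up, floor 1. With the published
parameters (LOD 4, slope 1.1363, intercept 0.3123) an observed 3 adjusts to 1
and an observed 50 to 44 — note round-half-up is required for the latter,
truncation would give 43. When no calibration mixtures are supplied,
`run_pipeline()` defaults to those published parameters
(`clonality_model()`).

One deliberate design choice: the *fit* partitions calibration points by
**expected** copies (a changepoint in the covariate), while the *application*
collapses by **observed** count. An objective that partitions the fit by
observed count and scores below-LOD points against a constant 1 cannot
recover a positive LOD from realistic calibration data — near-line points
always score better inside the regression — so the changepoint form is used.

Per sample, clonality is `(total_adjusted − independent)/total_adjusted`
(`clonality()`, zero for empty samples) and the clonality-corrected *mutation
frequency* is `mutant_pfu/total_pfu × (1 − clonality)`
(`corrected_mutation_frequency()`). Group fold induction is the ratio of
group means of the per-animal corrected frequencies.

## Group statistics

* Spectra are compared by Pearson's chi-squared test of independence on the
  class × group count table (`compare_spectra()`); when any expected cell is
  below 5 the p-value is Monte-Carlo (default 10⁵ draws, fixed seed
  `20151019`, so reports are reproducible). Per-class 2×2 comparisons with
  Holm correction (configurable, since no single convention dominates) are in
  `compare_spectra_by_class()`.
* Mutant frequencies are compared by Poisson regression of mutant pfu with a
  `log(total pfu)` offset (`compare_mutant_frequency()`); a group with no
  mutants at all triggers an exact rate-ratio fallback, flagged in the output.
* `find_hotspots()` counts per-sample-distinct events per position, summed
  across samples, and keeps positions strictly above `min_independent`
  (default 4, i.e. "more than four independent mutations").
* `power_simulation()` subsamples k mutants without replacement from an
  animal's full mutation list and scores each subsample against the full-list
  spectrum with a chi-squared goodness-of-fit (Monte-Carlo p); power is the
  fraction of draws not significantly different at α. The comparison metric
  is a strategy argument because the original procedure is not fully
  specified; the goodness-of-fit default asks "would this subsample have led
  me to the same spectrum?".

## Reference annotation

`load_reference()` reads a single-record FASTA and applies optional
colony-correction variants (position, expected base, replacement), verifying
the expected base. The packaged reference (`lacz_fasta_path()`) is the
authentic 3075-bp *E. coli* lacZ coding sequence. The archival gene record
adds ~21 bp of flanking sequence (quoted gene length 3096 bp) that is not
part of the CDS; homopolymer/CpG censuses computed here therefore sit 2–3
runs (≈9 bp) below flank-inclusive published counts, and colony-specific
variants (not public as a printed list) may shift censuses by a further ±1–2.
The default variant list is empty.

`find_homopolymers()` returns maximal mononucleotide runs (length ≥ 2 by
default). "CpG stretches" have no standard operational definition; this
package uses maximal strictly-alternating C/G tracts of length ≥ 5
(`find_cpg_stretches()`, configurable minimum), which reproduces the order of
magnitude of published censuses but is a declared choice, not a community
standard. Protein impact (`classify_impact()`) translates the affected codon
through the standard genetic code — silent / missense / nonsense for
substitutions, frameshift vs in-frame for indels — with each event classified
independently against the reference codon.

## The synthetic generator

`simulate_pools()` generates data the pipeline can be tested against without
any sequencing: each of `n_plaques` plaques carries one phenotype-driving
mutation (type from `class_probs`, site hotspot-weighted, with site-collision
retries that keep the class mix intact so recurrence within a sample is
attributable to clonal duplication only); with probability `clonal_fraction`
a plaque duplicates an earlier plaque's mutation. Optional silent
"hitchhiker" co-mutations (`hitchhiker_rate`) emulate multi-mutation plaques.
Each replicate library then draws, per event, a binomial read count at the
configured depth with success probability *copies/n_plaques* (+ per-plaque
weight effects when `plaque_weight_cv > 0`) plus a positional background rate
plus replicate-specific PCR artefacts. `simulate_study()` composes the full
assay design — treated and control groups plus a wild-type pool sharing one
background field, as libraries on one chip do.

Generator defaults state the study conditions being emulated:

| parameter | default | rationale |
|---|---|---|
| `depth` | 9×10⁴ | mean per-library coverage of the assay emulated |
| `sub_noise_range` | 1.7×10⁻⁵–2.15×10⁻² | published background range for substitutions, log-uniform per event |
| `indel_noise_multiplier` | ×50 at homopolymers ≥ 4 bp (±1 bp), capped 0.464 | published indel background reaches 4.64×10⁻¹, ~21× the substitution maximum; semiconductor indel error concentrates at longer homopolymers |
| `clonal_fraction` | 0.3 | published adjusted clonality 31–43 % |
| `n_plaques` | 500 | exposed-group pool scale (~3000 mutants / 6 animals) |
| `class_probs` | `class_probs_bap()` / `class_probs_control()` | published grouped proportions (0.14/0.61/0.25 and 0.35/0.49/0.16), allocated within groups by the published class shape, insertion:deletion ≈ 1:4 |
| `pcr_n_events` | 10/library, proportions 10⁻³–2×10⁻² | gives the concordance filter true negatives to reject |

What the generator does **not** emulate: read-level errors (counts are drawn
directly, so alignment artefacts and soft-clipping pathologies are absent),
flowgram-specific homopolymer signal beyond a rate multiplier, depth
variation along the gene, barcode cross-talk, and complex multi-nucleotide
mutations. A passing test suite therefore shows the *analysis* is correct
under the stated error model, not that the error model captures every failure
mode of a real instrument.

A structural property worth knowing: a single-copy mutation sits exactly at
the stringent threshold (expected proportion = threshold), so its
per-replicate recall is ~50 % and its both-replicate recall ~25 % at any
depth. Recovery of *total* mutations is much higher because clonal copies sit
at multiples of the threshold; this is why published recoveries of ~67–69 %
of pooled mutants are copies-weighted, and the package's end-to-end tests
measure recovery the same way.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive on the coding strand.
* Rounding of copy estimates is round-half-up (`floor(x + 0.5)`), never
  banker's rounding.
* Medians over an even library count average the two central order
  statistics; events never observed anywhere get background 0 (no
  pseudocount) — subtraction then preserves raw signal and the threshold is
  the guard.
* Zero-depth positions are kept (proportion 0, flagged) so medians stay
  positionally aligned.
* Empty call sets tabulate to zeros; clonality of an empty sample is 0;
  `total_pfu = 0` and `n_plaques = 0` are hard errors.
* All Monte-Carlo p-values and every simulation take explicit seeds; reports
  rerun bit-identically.

## Problem sizes used by the test suite

Unit and property tests run on 150–600-bp toy genes at depths 10³–5×10⁴ so
the suite completes in well under a minute. The acceptance-level checks run
one full-scale study — 6 + 6 pools on the complete lacZ sequence at 9×10⁴×
depth (~15,000-event background field × 26 libraries) — which takes a few
seconds; these sizes are the package's chosen trade-off between fidelity to
the emulated assay and a suite that a maintainer will actually run.

## Known limitations

* The background model is the empirical median — no positional context
  regression, no quality recalibration; sites whose artefact rate drifts
  *between* runs are not corrected.
* Multi-nucleotide and complex haplotype calls are out of scope; deletions
  of ≥ 2 bp are a single event keyed by length.
* The CpG-stretch census and the power-simulation metric are declared
  conventions (see above), so cross-study comparisons of those outputs should
  state them.
* With few samples, the all-samples median can absorb part of a mutation
  shared by many samples (a strong hotspot present in most animals); the
  wild-type library and the second exposure group in the run mitigate this,
  and the leave-one-out mode exists for small designs.
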