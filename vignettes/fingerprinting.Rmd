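---
title: "Peak-list fingerprinting of 1H-NMR mixtures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-list fingerprinting of 1H-NMR mixtures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmatch)
```

## The problem and the model

A 1D ¹H-NMR spectrum of a biological mixture is, to a good approximation, a
superposition of the spectra of its component metabolites.  When a curated
library of single-metabolite peak lists measured under comparable conditions
is available, assignment reduces to a combinatorial matching problem: which
library records best explain the sample's peak coordinates?

`specmatch` works entirely on peak coordinates.  All chemical shifts live on
a canonical 0.01 ppm grid (the precision at which curated reference peak
lists are commonly distributed), and a library metabolite with `t` peaks of
which `m` are found in the sample receives the significance score

$$S = \frac{m}{t + 1}.$$

The `+1` is deliberate: under the plain fraction `m/t`, a record whose
peaks are a subset of another's ties with it whenever both match fully,
and single-peak records reach the maximal score far too easily.  With the
`+1` denominator, equal match fractions rank the peak-richer record
strictly higher, and `S < 1` always.  A record is reported when `S ≥ r`
(inclusive) and at least one of its peaks matched.

Assumptions worth stating explicitly:

* the sample spectrum is already processed (FT, phasing, baseline); the
  package does no FID handling, apodization, binning, or 2D support;
* peak *heights* carry no evidence — library heights are stored as given
  and never compared across records, because reference collections do not
  guarantee cross-metabolite normalization.  Heights are used only to
  threshold the query against noise and for display;
* no concentration estimation or spectral deconvolution is attempted.

## The three search strategies

**MH1 (exact)** scores every record (after metadata filtering) with
tolerance 0 — a library peak matches only an identical canonical
coordinate.  Appropriate when sample and library were acquired under the
same conditions.

**MH2 (shift-tolerant)** counts a library peak at `q` as matched when some
sample peak lies in the inclusive window `[q − τ, q + τ]`.  Each library
peak contributes at most once regardless of how many sample peaks fall in
its window, so `m ≤ t` and the score stays well defined.  With `τ = 0`,
MH2 is bit-identical to MH1 (a tested invariant).

**MH3 (greedy, mutually exclusive)** repeatedly scores all remaining
candidates against the *remaining* sample peaks, emits the best one if its
current score reaches `r`, and removes the sample coordinates it matched.
Selection ties go to the record with more peaks, then the
lexicographically smaller id.  Output order is selection order.  Because
early winners consume shared coordinates, overlapping metabolites suppress
each other — fewer false positives, more false negatives.  Two guards make
the iteration total: every emitted record must remove at least one sample
peak (so iterations are bounded by the sample size), and the loop stops as
soon as the best remaining candidate falls below `r` or matches nothing —
residual peaks that no record explains are returned as `unassigned` rather
than looping forever.  With nonzero tolerance the removal step takes every
remaining sample peak inside a matched library peak's window; since that
coupling of window matching with coordinate consumption is easy to
misread, it is gated behind `experimental_drift = TRUE`.

## Tunable parameters

| parameter | units | default | notes |
|---|---|---|---|
| `eta` | intensity | 0 | noise threshold; sample peaks with height `< eta` are discarded before matching (inclusive keep at `eta`) |
| `r` | score, in [0, 1] | 0.5 | confidence threshold; comparison is `S ≥ r` at full precision — the two-decimal score is display only |
| `tolerance` | ppm | 0 | MH2/MH3 window half-width; MH1 requires 0 |
| `max_results` | count | 100 | output cap after ranking |
| `score_fn` | — | `"f2"` | `"f2"` is `m/(t+1)`; `"f1"` (`m/t`) exists for scoring-function comparisons |

Ranked output (MH1/MH2) sorts by descending full-precision score, breaking
ties by more matched peaks, then id.  MH3's *selection* tie-break uses the
record's total peak count instead, matching the greedy rule's intent of
preferring peak-rich explanations; the two rules are intentionally
distinct.

## Numerical choices

* **Rounding.** Canonicalization rounds half away from zero
  (`1.005 → 1.01`), not IEEE half-even, so results are identical across
  platforms and compiler settings; the implementation guards against the
  binary representation of exact halves.  Canonicalization is idempotent
  and duplicates created by it collapse to one peak keeping the larger
  height (matching is coordinate-based; duplicates would double-count).
* **Window comparisons** run on an integer centi-ppm grid with an inclusive
  bound and a representation guard, so `tolerance = 0.01` covers exactly
  one grid step on both sides.
* **Peak picking** is threshold-then-local-maxima: points below `eta` are
  removed, runs of equal consecutive intensity are collapsed, and a run
  higher than both neighbours is a peak at the run's central ppm (so a
  flat plateau yields one centred peak).  The picker is invariant to input
  point order and anti-monotone in `eta`, both property-tested.
* **Degenerate inputs.** An empty sample (or one emptied by `eta`) is an
  error for searches; an `eta` above the spectrum's maximum yields an
  empty peak list, not an error; an empty post-filter library is a
  configuration error; `r = 1` legitimately returns nothing since `S < 1`.
* **AUC** uses the trapezoidal rule over the cut-off sweep `N = 1…max`,
  anchored at (0, 0) and extended horizontally to (1, last sensitivity);
  the accuracy-optimal cut-off resolves ties toward the smallest `N`.
  When zero mixture members are identified within the list cap, the
  average rank is reported as the cap itself — a miss is "as bad as the
  bottom of the reported list".

## What the synthetic generator emulates — and what it does not

`generate_library()` emulates the *shape* of curated reference libraries:
per-record peak counts drawn uniformly from a range (default 1–181, the
span HMDB-like collections show; MMCD-like collections span roughly 1–66),
coordinates on the 0.01 ppm grid over 0–10 ppm, and cross-metabolite peak
sharing controlled by `overlap_rate` (default 0.25, giving the substantial
coordinate sharing real libraries exhibit; `0` yields pairwise-disjoint
records, useful as an analytically tractable regime).  Metadata (type, pH
in 3–10, solvent, 400/500/600 MHz) is sampled from the controlled
vocabularies.  Fresh coordinates are globally unique by construction;
exhausting the grid raises an error rather than silently reusing
coordinates.

`make_mixture()` pools `n` records sampled without replacement;
`apply_noise()` implements the two benchmark noise channels — deleting
`floor(f·count)` peaks uniformly at random with `f ≤ 0.5` (floor keeps
single-peak records alive at the maximal fraction) and shifting every
survivor by `±magnitude ∈ {0.01, …, 0.05}` ppm with per-peak independent
random signs (the sign convention is a package choice; a per-metabolite
coherent drift would be equally defensible and is not currently
implemented).  `render_spectrum()` sums Lorentzian lines — the natural NMR
lineshape — with Gaussian baseline noise on a uniform grid, mainly so the
peak picker can be exercised end to end.

What passing tests on these synthetics do **not** show: real spectra have
J-coupling multiplets, pH-dependent coherent shift drift, baseline roll
and intensity distortions that the generator does not model, and real
libraries have strongly non-uniform peak-count and overlap distributions.
The synthetic experiments validate definitions, invariants and *trends*
(degradation under noise, window rescue by MH2, mutual-exclusion
behaviour of MH3), not absolute identification percentages on any real
collection.

## Experiment drivers and problem sizes

`recovery_experiment()` sweeps mixture sizes (default `n = 1:10`) with 25
runs per size; the "ALL" metric counts a member found at any rank with no
score threshold by default (`all_unthresholded = TRUE`), since "found
anywhere in the list" and "found above `r`" are both defensible readings —
the flag selects the thresholded variant.  `noise_experiment()` offers the
single-metabolite protocol (each record noised and re-searched, 5
repetitions by default) and the pooled protocol (50-member mixtures, 50
repetitions, success = reported within the first 50 results).  The test
suite runs these at desk scale — libraries of 25–100 records with 3–8
peaks, 2–25 repetitions — sizes chosen so the deterministic regimes
(disjoint libraries, exact matching) make the expected outcomes provable
while the full protocol remains available through the arguments.

`scoring_comparison()` self-queries every record under `f1` and `f2`; on a
duplicate-free library `f2` ranks each record strictly first among its
perfect-fraction competitors, which is the designed advantage of the `+1`
denominator.

## Known limitations

* Matching is purely positional; relative intensities, multiplet structure
  and peak widths are ignored, so metabolites whose peak sets are subsets
  of others are intrinsically hard for MH1/MH2 and deliberately suppressed
  by MH3.
* The shift tolerance is a single global window; real drift is
  non-uniform across the ppm axis (pH-sensitive resonances drift more).
* MH3's windowed removal (nonzero tolerance) is experimental and its
  false-negative behaviour under heavy overlap is not characterised.
* The peak picker is intentionally simple (no smoothing, no shoulder
  resolution); heavily overlapped lines separated by less than the
  linewidth merge into one picked peak.
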