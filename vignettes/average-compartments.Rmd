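---
title: "Average chromatin compartments and compartment strength from Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average chromatin compartments and compartment strength from Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicpentad)
```

## The problem

At the megabase scale, interphase chromatin segregates into two classes of
genomic regions — the transcriptionally active A compartment and the
repressed B compartment — visible in Hi-C contact maps as a plaid
(checkerboard) pattern: regions of the same class touch each other more
often than expected, regions of different classes less often. The standard
summary of this pattern, the saddle plot, averages contacts over bins
ordered by compartment signal but discards where along the genome, and at
what genomic distance, those contacts occur. Yet short- and long-range
within-compartment contacts respond very differently to perturbations of
the loop-extrusion machinery, to mitotic exit, or to embryonic genome
activation.

`hicpentad` addresses this with a pile-up ("average compartment") analysis
that keeps the short/long-range distinction. It consumes two inputs only: a
binned contact matrix in the cooler (HDF5) standard and a compartment
signal in bedGraph format at the same bin size. The signal is typically the
first principal component (PC1) of the Hi-C correlation map; computing it
is deliberately out of scope — any per-bin signed track whose sign encodes
A (positive) versus B (negative) works.

## The procedure

1. **Observed over expected.** Each cis matrix is divided by its expected
   value at each genomic separation; the expected at offset $d$ is the
   arithmetic mean of all finite matrix entries on diagonal $d$ of the same
   chromosome (no pooling across chromosomes, no smoothing — the simplest
   estimator consistent with per-chromosome strength values). Trans
   matrices are divided by the scalar mean of the chromosome-pair matrix,
   which has no distance structure. Means ignore missing entries; division
   by an expected value of exactly 0 yields a missing value, never
   infinity.

2. **Segmentation.** Maximal runs of constant signal sign become
   compartment intervals. A value of exactly 0 has no sign and therefore no
   compartment call: it breaks runs, as do missing bins. No minimum
   interval length is imposed here — tiny intervals are removed later by
   the area-dimension filter, so all filtering lives in one place.

3. **Area enumeration.** For $n$ intervals on a chromosome, every
   on-diagonal square (short-range A or B) and every upper-triangle
   interval pair (long-range A–A, B–B, or the mixed A–B) defines a
   rectangular area of the O/E map: $n + n(n-1)/2$ candidates. In trans,
   the full cross product of two chromosomes' intervals is used and types
   collapse to A–A, B–B, A–B. Each cis area carries an anchor distance: the
   midpoint-to-midpoint separation of its two intervals in bp. Midpoints
   (rather than interval edges) are used because edge-to-edge distances
   would make long intervals look systematically closer.

4. **Filtering.** An area is kept iff (i) its smaller dimension is at least
   `min_dimension` bins (small areas are noise-dominated), (ii) at most
   `max_zero_fraction` of its entries are missing *or zero* (both indicate
   poor coverage: balancing masks bins to missing, dropout leaves zeros),
   and (iii) its anchor distance does not exceed the optional cutoff.
   Rejections are attributed to the first failing rule, in that order.

5. **Rescale and stack.** Surviving areas are rescaled to a common
   $S \times S$ square by bilinear interpolation and averaged per pixel
   with the *median*, which is robust to the occasional extreme area. A
   rescaled pixel is missing iff any source sample contributing to it with
   positive weight is missing — missingness propagates, contact values are
   never imputed; the median simply ignores missing contributors. Areas
   from all chromosomes enter a single genome-wide stack per panel type.

The result is the pentad: five panels (short A, short B, long A–A, long
B–B, A–B) in cis; three in trans; and, in by-distance mode, one column of
long-range/A–B panels per distance stratum next to the (unstratified)
short-range panels. Short-range areas sit on the diagonal — their anchor
distance is 0 by definition — so only long-range and A–B areas are
stratified.

## Compartment strength

For each chromosome, panels are built from that chromosome's areas alone
and summarised as

$$\mathrm{strength}(t) \;=\;
  \frac{\overline{\mathrm{O/E}}\,[\text{panel } t]}
       {\overline{\mathrm{O/E}}\,[\text{cropped A–B panel}]},$$

for each within type $t$; the A–B (denominator) panel is first cropped by
`crop_fraction` of $S$ per side, because pixels near its edges still carry
residual within-compartment signal and would bias the denominator upward.
The `combined` strength pools the finite pixels of all four within panels
over the same denominator, so panels weigh in proportion to their data
rather than each contributing one vote. A single shared denominator keeps
the four types comparable within a chromosome. A structureless map gives
strength 1 for every type; the ratio is invariant to any global rescaling
of the matrix.

Per-chromosome values allow paired comparisons between conditions with the
two-sided Wilcoxon signed-rank test. Zero differences are dropped before
ranking (the classical treatment). For fewer than 26 zero-free pairs the
exact permutation null is enumerated by dynamic programming over doubled
ranks — doubling makes average ranks integral, so the exact route also
covers tied differences, where the reference implementation in base R
silently switches to an approximation; beyond that, the normal
approximation with tie and continuity corrections is used. Reports carry
the conventional significance tiers (`**` $p \le 0.01$, `***`
$p \le 0.001$, `****` $p \le 0.0001$; plus `*` at $0.05$ and `ns`).

## Tunable parameters

| Parameter | Default | Unit | Why this default |
|---|---|---|---|
| `rescale_size` (S) | 33 | pixels | odd, so a centre pixel exists; typical pile-up size |
| `min_dimension` | 3 | bins | areas thinner than 3 bins are noise-dominated |
| `max_zero_fraction` | 0.5 | — | tolerate sparse matrices without keeping empty areas |
| `max_distance` | none | bp | cis cutoff disabled unless asked for |
| `crop_fraction` | 0.25 | of S per side | removes the contaminated A–B panel margin (33 → 17 centre) |
| `distance_bins` | 10, 25, 50, 100 | Mb | brackets the short/long transition at mammalian chromosome scales |

The method itself prescribes the three filters and the crop, but not their
thresholds; all of the above are exposed as CLI flags and
`pentad_settings()` arguments. Balanced matrix values are used by default
whenever balancing weights are stored (O/E analysis conventionally runs on
balanced maps); raw counts are a logged fallback or an explicit choice.
Chromosome names are matched by exact string equality — no silent "chr"
prefix normalisation — and multi-resolution containers require an explicit
`resolution`, so a run is always reproducible from its recorded
configuration.

## The synthetic world

`synthetic_spec()` / `generate_genome()` produce seeded genomes with
planted structure:

* cis entry $(i,j) = \mathrm{depth} \cdot (|i-j|+1)^{-\alpha} \cdot m(i,j)$
  with $m = f$ when bins $i,j$ share a label and $1/f$ otherwise;
  trans entry $= \mathrm{depth}_{trans} \cdot m(i,j)$;
* defaults: 4 chromosomes of 50 Mb at 100 kb bins, alternating A/B
  intervals of 5–15 bins, $\alpha = 1$ (a typical Hi-C decay slope at
  compartment scales), depth 1000 (expected diagonal count per 100 kb bin
  pair, a mid-coverage experiment), trans depth 10, Poisson count noise,
  2% of bins blanked to missing (mimicking bins masked during balancing);
* the signal track is $+1$ on A bins and $-1$ on B bins; blanked bins keep
  their track value but have missing matrix rows/columns and an `NA`
  balancing weight, so balanced reads reproduce the missing mask exactly.

One subtlety is worth spelling out. Relative to the generator's *known*
decay profile ($\mathrm{depth}\cdot(d+1)^{-\alpha}$, available as
`true_expected_cis()`), the planted O/E is exactly $f$ within and $1/f$
between compartments, and the combined strength of a noise-free genome is
exactly $f^2$ — the analytic recovery target used by the tests. The
*empirical* per-diagonal expected, by contrast, absorbs part of the planted
contrast: at offset 0 every bin pair shares a label, so the empirical O/E
diagonal is exactly 1 whatever $f$ is, and short offsets are biased toward
1 in proportion to how label-pure they are. This is a property of the
method on any data (the expected curve of a strongly compartmentalised
genome contains compartment signal), not a generator artefact. Recovery
and calibration tests therefore plant and measure contrast against the
known profile (`synthetic_oe(genome, "true")`), while the file-based CLI
uses the empirical expected like any real analysis. For the null case
$f = 1$ the two coincide, which is what makes the null calibration a clean
end-to-end test of the actual pipeline.

What the generator does *not* emulate: TADs, loops, chromosome-arm
structure, replicate variability, balancing artefacts beyond a uniform
missing mask. A green test establishes that the machinery computes what it
claims on block-enriched decaying matrices — not that biological
compartments behave like blocks.

## Numerical choices and degenerate inputs

* Bilinear rescaling maps target pixel centres onto the source sample grid
  (`(p + 0.5)/S \cdot L - 0.5`, clamped to the grid); a constant input is
  reproduced exactly at any size, and rescaling is positively homogeneous,
  so a global O/E scale factor passes through every panel untouched and
  cancels from every strength ratio.
* Only the upper triangle is enumerated in cis; panels are not
  re-symmetrised afterwards.
* An area type with zero surviving areas yields an all-missing panel and a
  logged warning, never an error; an all-missing A–B panel makes the
  chromosome's strengths `NA` (as does a cropped A–B mean of exactly 0,
  with a warning).
* A comparison of a table with itself (all differences zero) reports
  $p = 1$.
* `floor(crop_fraction * S)` pixels are cropped per side; any
  `crop_fraction < 0.5` leaves at least one pixel.
* Intervals at chromosome ends may cover a partial last bin; bedGraph
  records ending at the chromosome length are accepted as bin-aligned.

## Implementation notes

Cooler containers are HDF5 files; since the package's R dependency set has
no HDF5 bindings, a small bundled Python helper (numpy + h5py, found via
`PATH` or `options(hicpentad.python=)`) performs the byte-level reads and
writes. Everything analytical is R. The pentad JSON document written by
the compute step carries every panel grid, count, stratum bound and the
full settings, and is the sole interchange format between the compute,
strength, and plot subcommands; every CLI run also records its complete
configuration as `<prefix>.config.json`, and re-running with the recorded
configuration reproduces the outputs bit for bit.

## Known limitations

* Compartment annotation (PC1) is an input, not a product; mis-signed or
  mis-scaled signals propagate silently into the segmentation.
* The empirical expected absorbs compartment contrast at short range (see
  above), so absolute strength values are conservative; comparisons
  between conditions computed the same way remain meaningful.
* Two-state segmentation only; no sub-compartments.
* Median aggregation is robust but not unbiased for skewed pixel
  distributions at low coverage; counts per panel are reported so users
  can judge support.
* Trans mode enumerates all chromosome pairs of the shared set; for large
  genomes this is the slow path.
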