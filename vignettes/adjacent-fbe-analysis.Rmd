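---
title: "Adjacent FBF binding elements: scanning, binding models, and germline profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacent FBF binding elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbepair)
```

## The biological question

PUF-family RNA-binding proteins such as *C. elegans* FBF-2 recognize short
single-stranded elements (FBF binding elements, FBEs) in target mRNAs,
most prominently in 3'UTRs, and repress or activate those targets in the
germline stem cell region. A partner protein, LST-1, carries two PUF
interacting motifs in an intrinsically disordered region and can bridge
two FBF-2 molecules, which predicts that some targets are controlled
through *pairs* of closely spaced FBEs rather than single sites. The
*gld-1* 3'UTR provides the canonical case: the well-known FBEa element is
followed a few nucleotides downstream by a weaker, noncanonical element
(FBEa*), and the two act together in repression and activation.

`fbepair` packages the quantitative workflows around that biology:

1. **Element scanning** -- exact degenerate-consensus matching of four FBE
   classes over CLIP peak sequences.
2. **Adjacency analysis** -- pairing of elements under a spacing
   constraint and peak/gene/region bookkeeping.
3. **Peak statistics** -- occupancy (peak height) comparisons and
   partnership-dependence categories.
4. **Binding models** -- a one-set-of-sites calorimetry (ITC) isotherm for
   simulation and fitting, EMSA fraction-bound fits, FRET efficiency and
   thermodynamic conversions.
5. **Germline profiles** -- intensity along the distal-proximal gonad
   axis: means, confidence bands, wild-type normalization and pooled
   window tests.
6. **Synthetic data** -- generators with known ground truth so that every
   stage can be exercised and validated at desk scale.

## Element grammar and matching semantics

Four consensus classes are scanned, written over the symbols
`A, C, G, U, R (= A/G), Y (= C/U), n (= any base)`:

| class     | consensus    | length | role |
|-----------|--------------|--------|------|
| `FBE9`    | `UGURnnAUn`  | 9      | canonical FBE |
| `CFBE8`   | `UGURnAUn`   | 8      | compact FBE |
| `ASTAR9`  | `UGUYRnAUn`  | 9      | FBEa*-like |
| `ASTAR10` | `UGUnRnnAUn` | 10     | FBEa*-like |

Matching is **exact**: a position matches only if the base is in the
symbol's allowed set. Consequences worth spelling out:

* Input is normalized with `normalize_sequence()`: uppercased, `T` mapped
  to `U`, so DNA-alphabet FASTA works unchanged. Any other character is
  rejected with its position.
* The ambiguous base `N` matches *nothing* by default -- not even the `n`
  symbol. An exact-match search should not award credit for uncertainty;
  `match_positions(..., n_matches_ambiguous = TRUE)` relaxes this for
  users who want it.
* Matching is single-strand, in the given 5'-to-3' orientation. CLIP peak
  sequences are transcript-sense, so no reverse-complement search is
  performed.
* Overlapping matches are all reported, and matches of two classes at the
  same start are kept as distinct records. Whether a published search
  would have merged same-start multi-class hits is not documented
  anywhere we know of; keeping both is the lossless choice, and
  peak-level results are unaffected because pairs are deduplicated at the
  unordered-pair level and peaks are counted once.

Coordinates are 1-based inclusive throughout, both internally and in
output tables. (A 0-based internal convention was considered and
rejected: every container in R is 1-based, and the spacing formula below
depends only on position *differences*, so nothing is gained by carrying
two conventions.)

```{r scan-example}
gld1 <- "AUCAUGUGCCAUACAUCAUGUUGCCAUUU"  # the 29-nt FBEa-FBEa* region
scan_all(gld1)
```

## Adjacency: what counts as a pair

`find_pairs()` emits every unordered pair of element matches in one
sequence such that

* at least one member is canonical (`FBE9`) -- the second element may be
  any of the four classes, including another canonical FBE, and may lie
  upstream or downstream;
* the gap, computed from start positions as
  `downstream_start - upstream_start - upstream_length`, lies in
  `[min_gap, max_gap]`, default `[1, 20]`, read as inclusive.

Overlapping or abutting elements (gap <= 0) therefore never qualify; no
separate overlap rule is needed.

**Two gap conventions coexist for the *gld-1* pair** and both are
reproducible with `element_gap()`. The consensus cores (9-nt FBEa core at
position 5, 10-nt FBEa*-like match at position 19 of the 29-mer) are 5 nt
apart -- this is what the scanner reports. The flank-inclusive elements
usually drawn in figures (11-nt `CAUGUGCCAUA`, 12-nt `CAUGUUGCCAUU`) are
3 nt apart. The package treats the core-element convention as primary
because it is the one the scan definitions operate on, and exposes the
flank-inclusive arithmetic through the same `element_gap()` utility.

```{r gap-example}
find_pairs(scan_all(gld1))$gap   # core convention
element_gap(3, 11, 17)           # flank-inclusive convention
```

Peaks are counted once no matter how many pairs they contain; genes are
counted by the `gene_id` column of the annotation as given (peaks are not
re-deduplicated across transcripts), and region labels are trusted as-is.

## Peak-height statistics

Heights (FPKM) of peaks with adjacent elements are compared against all
scanned peaks with an unpaired, equal-variance, two-sided t-test
(`pooled_t_test()`), the convention used for occupancy comparisons in
this field. Degenerate inputs are handled by convention: zero pooled
variance with equal means gives `t = 0, p = 1`; with unequal means it is
an error rather than an infinite statistic.

One calibration note: on strongly skewed lognormal heights with only ~10
values per group, the pooled t-test is conservative (empirical type-I
error near 0.025 at nominal 0.05). This is a property of the test on
skewed data, not of the implementation; the package's calibration tests
use 50 values per group, where the nominal level holds.

Partnership dependence (`categorize_y479()`) classifies each peak as
`lower`, `higher` or `unchanged` by a 1.5-fold default threshold between
wild-type and partnership-defective heights. Deposited peak sets carry
their own precomputed category labels; when a `category` column is
present it takes precedence and the fold rule is bypassed -- the rule
exists so synthetic data can exercise the categorized comparison.

## The one-set-of-sites ITC model

For a titration of `X` (syringe, total `Xt`) into `M` (cell, total `Mt`,
`N` sites per molecule, association constant `K = 1/Kd`), the cumulative
heat after each injection is

$$ Q = \frac{N M_t \Delta H V_0}{2}\left[ 1 + \frac{X_t}{N M_t} +
\frac{1}{N K M_t} - \sqrt{\left(1 + \frac{X_t}{N M_t} +
\frac{1}{N K M_t}\right)^2 - \frac{4 X_t}{N M_t}} \right] $$

The observed heat of injection *i* is the difference of successive `Q`
values plus the half-displaced-volume correction
`(dV_i / V0) (Q_i + Q_{i-1}) / 2`.

**Dilution convention.** Perfusion-cell instruments displace liquid as
they inject, and vendor packages differ in the exact bookkeeping. With
`v` = cumulative injected volume / cell volume, this package uses

```
Mt = M0 (1 - v/2) / (1 + v/2),      Xt = Xs v / (1 + v/2)
```

for both simulation and fitting. Users comparing parameter values against
vendor software output should be aware of this dialect; because generator
and fitter share it, round-trip recovery is exact.

`fit_itc()` estimates `(N, Kd, dH)` by Levenberg-Marquardt least squares
(`minpack.lm`), with `N` and `Kd` on the log scale to keep them positive.
Initialization is `N = 1`, `dH` from the first retained injection
converted to kJ per mole of injectant, and a small grid of `Kd` starting
values spanning 0.01-10x the cell concentration; the converged start with
the lowest residual wins. The first injection is discarded by default
(syringe-tip diffusion during equilibration, standard practice);
`discard_first = FALSE` disables this. Standard errors come from the
least-squares covariance (delta method for the log-scale parameters) --
the error model of vendor fits is not public, so these are labeled for
what they are. All-zero heats and other degenerate series are flagged,
not fitted.

Verification is two-route: the closed-form isotherm is checked against an
independent numeric equilibrium solver (per-injection mass-action root
finding), and generate-and-refit round trips recover `N`, `Kd` and `dH`
to better than 1% on noise-free data across `N` in `[0.3, 2]` and `Kd` in
`[0.1, 50]` uM.

A design note on noise studies: the published instrument setup for the
stoichiometry experiments (19 x 2-uL injections of ~300 uM titrant into
~20 uM cell material) saturates a 2:1 complex within the first few
injections -- fine for reading off `N`, poor for constraining `Kd` from
noisy data. The package's noise-robustness checks therefore use a
schedule with equivalence near mid-titration (150 uM into 30 uM); with
Gaussian noise at 2% of the largest heat, the median recovered `Kd` over
200 replicates stays within 10% of truth.

Thermodynamic conversions are `delta_g(kd) = R T ln(Kd)` (kJ/mol,
`T = 293.15 K` default, matching the 20 C experiments) and
`minus_t_delta_s(dG, dH) = dG - dH`.

## EMSA and FRET

EMSA band intensities give the fraction of RNA bound,
`bound / (bound + unbound)`, which is fit with the one-site specific
binding curve `Bmax x / (Kd + x)`. The RNA is trace (5 nM against
nanomolar-to-micromolar protein), so free protein is approximated by
total protein; `fit_emsa(..., exact = TRUE)` instead solves the depletion
quadratic for users titrating near the RNA concentration. A fitted `Kd`
above the highest tested concentration is reported as a censored lower
bound (printed `"> <max> nM"`), the convention used for out-of-range
affinities. Replicate affinities are summarized as mean +/- SEM
(`replicate_summary()`), and `fold_change()` expresses affinity gains as
`Kd_reference / Kd_test`.

Relative FRET efficiency is the acceptor fraction of total emission,
`I668 / (I668 + I564)`, for Cy3 (donor, 564 nm) / Cy5 (acceptor, 668 nm)
pairs.

## Germline intensity profiles

Input is long-format per-gonad intensity versus distance from the distal
end of the gonad (um). `mean_profile()` resamples each gonad onto a
common grid (default 0-100 um at 1-um steps) by linear interpolation --
pixel-level line profiles from the original images are not reproducible
without the images, so a physical grid is the stand-in -- and reports the
pointwise mean with a 95% t-interval. `normalize_to_wt_max()` rescales
every genotype by the wild-type mean's maximum over the distal 100 um, so
the wild-type maximum is exactly 1; the operation is idempotent and
invariant to rescaling raw intensities.

`window_compare()` implements the pooled regional tests (defaults 0-10,
70-80 and 90-100 um): each gonad contributes its *trapezoidal average*
over the window, and the two genotypes' per-gonad averages are compared
with the pooled t-test. The trapezoidal average integrates the gonad's
piecewise-linear profile, so the result is exactly invariant to how
finely the profile was sampled -- a plain mean over grid points is not.
Significance labels follow `*** p < 0.001, ** p < 0.01, * p < 0.05, ns`,
with no multiple-testing correction across windows (per-window p-values
are reported as such).

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed.

* `gen_background()` draws i.i.d. sequence from a base composition
  (uniform default; `utr3_composition()` is a U-rich preset, A 0.30 /
  U 0.40 / C 0.15 / G 0.15, emulating 3'UTR composition).
* `realize_element()` draws a concrete element from a consensus class,
  uniformly over the degenerate positions.
* `plant_pair()` overwrites (never inserts) two elements into a
  background at an exact gap, keeping peak length controlled. Accidental
  background matches are allowed to remain -- real sequence has them too
  -- and validation recounts with a brute-force oracle rather than
  assuming the plant is the only signal.
* `gen_peakset()` produces a FASTA-ready named sequence vector, an
  annotation table and a ground-truth record. Planted peaks draw heights
  lognormal(`logmean + log(adjacent_multiplier)`, `logsd`); background
  peaks omit the multiplier. Defaults -- median height 400 FPKM,
  `logsd = 1`, multiplier 4, ~90% 3'UTR labels -- give a long-tailed
  height distribution and an adjacent-element effect of the magnitude
  seen in occupancy data (mean heights a few-fold apart).
* `gen_itc()`, `gen_emsa()`, `gen_fret()`, `gen_profiles()` add Gaussian
  noise to the corresponding forward models and attach the generating
  truth.

What the generators do **not** emulate: read-level CLIP artifacts
(crosslink bias, PCR duplicates, peak-calling uncertainty), genome
context, transcript isoform structure, correlated measurement error in
titrations, or image-domain effects in gonad profiles (line width,
projection, segmentation). Tests passing on synthetic data therefore
demonstrate correctness of the analysis given its inputs, not robustness
to upstream artifacts.

The analytic false-positive theory used in validation:
`expected_match_probability(pattern, composition)` is the product over
pattern positions of the composition mass of each symbol's allowed set
(e.g. `2^-11` for the canonical element on uniform background), and the
expected match count in a length-`L` sequence is `(L - m + 1)` times
that. Empirical counts over thousands of element-free peaks sit inside
99% bands around these values.

## Numerical and testing choices

* Nonlinear fits: `minpack.lm::nls.lm`, tolerances `1e-14`, max 500
  iterations; positivity via log-parameterization; multi-start on `Kd`
  for the ITC fit. Non-convergence is reported, never silently replaced.
* Degenerate inputs: all-zero ITC heats and flat-zero EMSA curves are
  flagged; both-zero intensity pairs are errors; zero-variance t-tests
  follow the conventions above.
* Test problem sizes (chosen to make the stochastic checks sharp but
  quick): 200-seed noise studies for ITC and EMSA, 500-replicate CI
  coverage for profiles, 200-replicate power checks for window tests,
  1000-2000 simulated sequences for match-rate calibration, 100-1000
  simulated datasets for t-test calibration. The whole suite runs in
  about two minutes on one core.
* Reproducing the accession-scale scan (thousands of deposited peaks)
  requires the deposited peak sequences and annotation; the package does
  not download them. Place them as `inst/extdata/gse233561/peaks.fa` and
  `peaks.tsv` and the dedicated test recomputes the published counts.
  Note that exact reproduction may depend on how same-start multi-class
  matches were deduplicated in the original analysis (see above); both
  behaviors are reachable by filtering the match table before
  `find_pairs()`.

## Known limitations

* The scanner is exact-match by design; there is no position-weight
  scoring, no mismatch tolerance, and no modeling of the
  affinity-enhancing cytosine directly upstream of core elements -- that
  flank is outside the search definitions, which is also why the flanked
  and core gap conventions differ.
* The ITC model covers one set of identical sites only. Two-site or
  sequential models are out of scope (fitting them to uniphasic curves is
  ill-posed without external constraints).
* EMSA fitting assumes equilibrium and a clean bound/unbound partition;
  supershifts and nonspecific intermediate bands must be resolved during
  quantitation, upstream of this package.
* Gonad profiles are taken as given; image processing, segmentation and
  projection are out of scope.
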