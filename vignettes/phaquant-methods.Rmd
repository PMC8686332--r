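---
title: "Methods: PhaC profiling, FT-IR PHA quantification and growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PhaC profiling, FT-IR PHA quantification and growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaquant)
```

phaquant bundles the desk computations used when characterizing bacterial
polyhydroxyalkanoate (PHA) producers: physicochemical profiling of PhaC
polymerase candidates, a semi-quantitative FT-IR statistic for intracellular
PHA, growth-rate estimation from OD600 time series, and titer arithmetic
from cell dry weight (CDW) and monomer fractions. A seeded synthetic-data
module generates inputs with known ground truth so that every stage is
testable without instrument or sequence downloads. This vignette records the
models, the tunable parameters and the design decisions behind each stage.

## Protein profiling

### Charge model and isoelectric point

The net charge of a protein at a given pH is the sum of
Henderson–Hasselbalch terms: the N-terminus and the side chains of H, K and
R contribute $+1/(1+10^{\,\mathrm{pH}-pK_a})$ each, while the C-terminus and
the side chains of D, E, C and Y contribute $-1/(1+10^{\,pK_a-\mathrm{pH}})$.
The default constants are the Bjellqvist set used by the Expasy Compute
pI/MW tool: N-terminus 7.5 (generic), C-terminus 3.55, side chains D 4.05,
E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0. All constants live in
`pka_set()` so an alternative set (EMBOSS is shipped) can be swapped in one
place. Residue-specific N-terminal pKa values (A 7.59, M 7.00, S 6.93,
P 8.36, T 6.82, V 7.44, E 7.70) are available behind
`nterm_residue_specific = TRUE` but default to off; they move typical pI
values by at most a few hundredths of a pH unit.

Because every term is strictly decreasing in pH, the net charge is strictly
decreasing and the isoelectric point — the unique root — is found by
bisection on $[0, 14]$ down to a net-charge magnitude below `tol` (default
$10^{-4}$). The test suite checks the bisection result against an
independently written dense-grid scan (step $10^{-4}$ pH) and against a
separately authored implementation of the same published constants; both
agree to well under 0.01 pH units.

Molecular weight is the sum of average (isotope-weighted) residue masses
plus one water (18.01524 Da), the Expasy convention; summaries print it in
kDa to one decimal. Non-canonical residue letters (B, Z, X, U, O, ...) are
accepted by the FASTA parser but are hard errors in the MW/pI computations:
no imputation, so a profile is either computed from the real sequence or not
at all.

### Segmented profiles

`segment_profile()` splits a candidate at a boundary (default residue 613,
matching the catalytic region of class I PhaC polymerases) and reports the
pI of the N-terminal segment and of the C-terminal extension separately,
along with full-sequence MW, motif annotations and a variant call.
Coordinates are 1-based inclusive throughout, so a 993-residue protein with
boundary 613 has a 380-residue C-terminus spanning residues 614–993.
Sequences no longer than the boundary yield a catalytic-only profile
(`pi_c_segment = NA`) rather than an error.

### Motif scans

The PhaC box — the catalytic motif around the active-site cysteine — is
written as a 6-position pattern `(G/S)XCX(G/A)G`, yet the motifs reported
for Cobetia and Halomonas polymerases are 5-residue strings (SYCIG, GYCLG,
SYCVG). `scan_phac_box()` therefore scans both patterns, reports each hit
with its pattern provenance, and suppresses the 5-mer hit at a position
where the 6-mer also matches (the 5-mer is its prefix). Overlapping matches
at different starts are all reported. The AAKP tetrapeptide count
(`count_aakp()`) uses a sliding window, so overlapping occurrences would be
counted — the conservative superset, although AAKP cannot in fact overlap
itself.

`classify_phac()` encodes the size logic: a PhaC box plus MW ≥ 90 kDa is
called `phac2_extended` (the extended variant runs 93.6–106.4 kDa); a box
with MW in 55–80 kDa is `phac1_like`; anything else is `unclassified`. Both
thresholds are arguments.

## FT-IR quantification

### The C:A 1 ratio

The carbonyl-ester stretch of PHA gives a characteristic band near
1724 cm⁻¹, while the amide band I from cellular protein sits near
1650 cm⁻¹. The C:A 1 ratio is the area of the carbonyl-ester region
(1705–1763 cm⁻¹) divided by the area of the amide band I region
(1580–1705 cm⁻¹); it is a semi-quantitative proxy for PHA content, linear
only below about 44% PHA of CDW, which is why `calibrate_ratio_to_pha()`
requires user-supplied calibration coefficients and flags results above that
bound rather than defaulting to invented ones.

Integration is trapezoidal on the instrument grid with linear interpolation
at region boundaries that fall between grid points. The two default regions
share the 1705 cm⁻¹ boundary as touching closed intervals; the single
shared ordinate is a set of measure zero under the trapezoid rule, so
adjacent-region areas are exactly additive. Ratios are computed from raw
spectra by default; offset or linear baseline correction (over a
1500–1800 cm⁻¹ window) is opt-in, mirroring practice where only spectra of
cells scraped from agar plates need negative-absorbance removal.

A spectrum is called PHA-positive when the absorbance maximum inside the
carbonyl window sits at 1724 ± 2 cm⁻¹ and rises more than a prominence
threshold (default 0.01 absorbance) above the window minimum. The
prominence value is a reporting convention, not an instrument constant, and
is an argument.

### Per-hour normalization

Putative PHA production is normalized to production per hour after the
culture reaches stationary phase. Because "ratio per hour" admits two
readings, `ratio_rate()` computes both: the primary definition (the ratio at
the first measurement at or after the stationary onset, divided by that
elapsed time) and a slope definition (Δratio/Δt over the last two points).
Neither is asserted as canonical; both are always reported.

## Growth kinetics and titers

The specific growth rate over one sampling interval is
$k = \ln(\mathrm{OD}_2/\mathrm{OD}_1)/(T_2 - T_1)$, invariant to OD
rescaling. `max_growth_rate()` estimates the exponential-phase maximum
either as the maximum pairwise $k$ over consecutive points or as the
maximum slope of $\ln(\mathrm{OD})$ in a sliding regression window (default
4 points, mirroring 2-h sampling of the exponential phase), reported with
its $r^2$. Stationary onset is the first time OD reaches 95% of the curve
maximum; the fraction is configurable since no standard threshold exists.

PHA titer is $\mathrm{CDW} \times (\sum \text{monomer fractions})/100$ g/L.
Reported titers are rounded half away from zero at one decimal — the
spreadsheet convention that reproduces printed values such as 2.108 → 2.1
and 0.65 → 0.7, where base R's round-half-to-even would not — with the
unrounded value retained in an attribute. Dispersion statistics use the
population (divide-by-$n$) standard deviation, matching the spreadsheet
`STDEV.P` convention used for the published replicate summaries, even
though sample SD would be the textbook choice; the CV is SD/mean.

`run_productivity()` treats published productivity tables as fixed inputs:
it recomputes each titer from the printed CDW and fractions and *flags*
disagreements rather than adjusting anything. On the bundled
`cobetia_productivity()` table, eight of ten rows reproduce exactly; the two
flagged rows (computed 2.4 vs printed 2.5) are consistent with the original
arithmetic having used unrounded CDW/fraction values that the printed table
no longer carries.

## Synthetic data: what it emulates and what it does not

`gen_protein()` builds a two-segment protein: a catalytic segment with one
planted PhaC box and a low-complexity C-terminal extension with a target
K+R fraction (default 0.20) and a planted number of AAKP motifs (default
5, the largest count observed among natural extended C-termini). Background
residues are drawn uniformly from the canonical alphabet *minus cysteine
and proline*: a PhaC box needs a central C and AAKP needs a P, so this
exclusion makes the planted motifs provably the only matches and exact
recovery a meaningful test. The residue following a planted 5-mer box is
forced non-G so the hit is not promoted to a 6-mer. The catalytic background
is mildly D/E-enriched (default D+E fraction 0.15) because real PhaC
catalytic domains are acidic (published segment pI values 4.6–5.4); without
this the N-segment pI of a balanced random sequence is unstable across
seeds, swinging anywhere between ~4.5 and ~10. The realized K+R fraction
and all planted positions are returned as ground truth.

`gen_spectrum()` sums Gaussian bands on a 650–4000 cm⁻¹ grid (step
1.9 cm⁻¹): carbonyl-ester 1724/σ10 with amplitude `2.5 × pha_fraction`,
amide I 1650/σ18/1.0, amide II 1540/σ15/0.6 and minor CH-stretch bands at
2850–2960 cm⁻¹, plus a linear baseline and iid Gaussian noise (default sd
0.002). The amplitude slope 2.5 is an arbitrary recorded convention — no
published calibration exists — so tests assert only monotonicity of the
ratio in `pha_fraction`, never absolute values. Gaussian (rather than
Lorentzian/Voigt) band shapes are the simplest adequate for validating
integration and ratio logic; they do not emulate ATR artefacts, water-vapor
lines or detector drift, so passing tests validate the *computation*, not
instrument realism.

`gen_growth_curve()` produces a logistic OD600 curve with a lag (defaults:
start OD 0.05, intrinsic rate 0.4 h⁻¹, capacity OD 15, 2-h sampling over
32 h — shake-flask-like conditions) under multiplicative log-normal noise
(default sd 0.02). The analytic 95%-of-capacity crossing time is part of
the truth. The logistic's early-phase curvature means even noiseless
regression estimates sit ~1–3% below the intrinsic rate; the recovery
tests budget 5% (noiseless) and 10% mean bias (noisy, 100 curves)
accordingly.

## Numerical choices and degenerate inputs

* Bisection runs to a net-charge tolerance of $10^{-4}$ with the bracket
  narrowed below $10^{-6}$ pH; results are deterministic.
* Trapezoid integration on the native grid is effectively exact for the
  smooth Gaussian bands used in testing (closed-form agreement well under
  0.1%); no resampling is performed.
* Empty FASTA files, duplicate record ids, one-point spectra, non-numeric
  spectral rows, non-positive ODs, negative CDW/fractions and empty value
  vectors are all hard errors with named messages; `run_productivity()`
  alone degrades row-wise (an error column) so one bad row does not abort a
  table.
* Flat growth curves give a zero rate and an onset at the first time point;
  a descending curve gives a negative rate, not an error.
* Rounding uses a $10^{-9}$ guard before the half-away-from-zero floor so
  binary representation error in products like $2.5 \times 26/100$ cannot
  flip a titer's last digit.

## Problem sizes used in validation

The shipped validation suite uses 200 random sequences for the pI
grid-scan comparison, 100 seeded proteins for exact motif recovery, 50
seeded spectra for ratio monotonicity (8-point sweep of the PHA fraction
over [0, 0.44]) and carbonyl-peak localization, and 100 noisy logistic
curves for rate recovery. These sizes give stable pass/fail behavior for
the properties tested while keeping a full run in the tens of seconds.

## Known limitations

* The pI model ignores charged-residue interactions, cysteine oxidation
  state and post-translational modification; agreement with tool-computed
  values is expected to the first decimal, with the second decimal
  sensitive to the N-terminal pKa convention.
* The C:A 1 ratio is semi-quantitative: absolute PHA content requires an
  external calibration, and the 44%-of-CDW linearity bound is inherited
  from the underlying mixed-culture model.
* No homology search, conserved-domain detection or secondary-structure
  prediction is performed; variant calls rest solely on motif presence and
  size.
* The accession-based reference checks need the one-off
  `scripts/fetch_phac2.R` download; without it those checks report the
  sequence as unavailable.
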