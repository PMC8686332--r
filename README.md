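# phaquant

Desk computations for characterizing bacterial polyhydroxyalkanoate (PHA)
producers, built for microbiologists screening strains such as *Cobetia* and
*Halomonas* for bioplastic production. The package covers four stages that
normally live in separate ad-hoc spreadsheets and web tools:

1. **PhaC polymerase profiling** — average molecular weight (Expasy
   convention), Bjellqvist isoelectric points computed for the full sequence
   and for N-/C-terminal segments split at a configurable boundary (default
   residue 613, the class I catalytic region), PhaC-box scanning with the
   catalytic motif `(G/S)XCX(G/A)G` (plus its reported 5-residue forms such
   as SYCIG/GYCLG), AAKP motif counting in the C-terminal extension, and a
   size-based variant call (`phac1_like` ≈ 55–80 kDa vs `phac2_extended`
   ≥ 90 kDa with an extended, basic C-terminus).
2. **FT-IR quantification** — the semi-quantitative **C:A 1 ratio**: the
   area of the carbonyl-ester region (1705–1763 cm⁻¹) divided by the area
   of the amide band I region (1580–1705 cm⁻¹), with trapezoidal
   integration, optional offset/linear baseline correction, carbonyl-peak
   detection at 1724 ± 2 cm⁻¹, and per-hour normalization after stationary
   onset.
3. **Growth kinetics and titers** — the specific growth rate
   `k = ln(OD₂/OD₁)/(T₂ − T₁)` per hour, pairwise and sliding-window
   regression estimators of the exponential-phase maximum, stationary-phase
   onset, population-SD dispersion statistics, and PHA titer arithmetic
   `CDW × Σ(monomer %)/100` g/L with spreadsheet-style rounding.
4. **Synthetic data** — seeded generators for proteins with planted motifs,
   Gaussian-band FT-IR spectra whose carbonyl amplitude scales with a known
   PHA fraction, and logistic growth curves with known rate, each returning
   its ground truth.

## Worked example

```r
library(phaquant)

# a synthetic PhaC_2-like protein: 613-residue catalytic segment with a
# planted SYCIG box, 380-residue K/R-rich C-terminus with 5 AAKP motifs
g <- gen_protein(seed = 42)
segment_profile(g$record)
#> <phac_profile> synthetic_phac_42
#>   length        993 aa (N-segment 613, C-terminus 380)
#>   MW            119.4 kDa
#>   pI            full 8.75 | N-segment 4.99 | C-terminus 10.50
#>   PhaC box      SYCIG@310
#>   AAKP (C-term) 5
#>   variant       phac2_extended

# FT-IR of a culture simulated at 30% PHA of CDW
sp <- gen_spectrum(seed = 42, pha_fraction = 0.30)
ca1_ratio(sp$spectrum)
#> <ca1_result> C:A 1 ratio 0.4080 (carbonyl 20.6934 / amide 50.7138)
#>   carbonyl peak 1723.5 cm-1 (height 0.7468) -> PHA positive

# growth kinetics of a simulated shake-flask culture
gr <- gen_growth_curve(seed = 42)        # true intrinsic rate 0.4 /h
max_growth_rate(gr$curve, method = "regression")
#> <rate_estimate> k = 0.3978 /h (regression, window 2.0-8.0 h, r2 = 1.000)
stationary_onset(gr$curve)
#> [1] 26

# titer from a printed productivity row: CDW 3.4 g/L, 48% 3HB + 14% 3HV
pha_titer(3.4, c(`3HB` = 48, `3HV` = 14))
#> [1] 2.1
```

The profile reads: a 993-residue polymerase at 119.4 kDa whose catalytic
segment is acidic (pI 4.99) while the extended C-terminus is strongly basic
(pI 10.50) — the signature of the extended PhaC_2 variant, consistent with
a DNA-binding role; the planted catalytic box and all five AAKP motifs are
recovered. The spectrum shows a carbonyl-ester peak on the grid point
nearest 1724 cm⁻¹ and a C:A 1 ratio of 0.41, and the regression estimator
recovers the simulated growth rate to within 1%.

`run_profile()` and `run_productivity()` assemble the same computations into
per-record TSV/JSON reports; `run_productivity(cobetia_productivity())`
recomputes every titer of the bundled two-strain productivity table and
flags the two rows whose printed titer cannot be reproduced from the
printed (rounded) inputs.

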