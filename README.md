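# osteokin

Multi-evidence identity testing for ancient skeletal remains.

Excavated skeletons are often incomplete, and isolated elements (a mandible
found outside a burial, say) may or may not belong to an individual buried
nearby. `osteokin` implements the computational chain used to answer "one
individual or two?" from low-coverage ancient-DNA data, radiocarbon dates and
collagen stable isotopes — together with a synthetic-data generator so every
analysis can be run and tested with known ground truth and no downloads.

## The statistics at the core

**Pairwise mismatch rate (PMR).** Low-coverage ancient samples are genotyped
in *pseudo-haploid* form: at each SNP one sequenced allele is drawn at random
(base quality ≥ 30, read ends trimmed by 2 bp). For two pseudo-haploid
observations of the *same* diploid genome the expected mismatch rate is
H/2 — half the heterozygosity — because disagreement is only possible at
heterozygous sites and occurs there half the time. Two unrelated individuals
mismatch at rate ≈ H. Hence the identity rule: a pair whose PMR is half the
unrelated-pair baseline is the same individual or identical twins
(`pmr()`, `pmr_baseline()`, `classify_pair()`).

**Outgroup f3.** `f3(O; A, B) = E[(o − a)(o − b)]` over SNP allele
frequencies measures the drift shared by A and B relative to an outgroup O,
with standard errors from a weighted delete-one-block jackknife
(`f3_outgroup()`, blocks of 5 Mb by default). Two observations of one
individual show far more "shared drift" than any cross pair, and values well
above 0.5 additionally indicate low population heterozygosity (small
effective population size).

**Radiocarbon.** Conventional ages relate to fraction modern carbon by
`t = −8033 · ln(F14C)`. Calibration against a curve `μ(θ), σ_curve(θ)` gives
a posterior on the calendar grid with 68.3%/95.4% highest-density ranges and
a median (`calibrate()`). Ward–Wilson chi-square testing decides whether
dates of one object can be pooled (`ward_wilson_combine()`). Contamination
mixes linearly in F14C, so the contaminant fraction needed to explain an
observed shift is `c = (F_obs − F_true)/(F_cont − F_true)`
(`required_contamination()`) — a percent or two of modern carbon is enough
to pull a terminal-Pleistocene date centuries younger.

**Damage & sex.** Terminal C→T (5') / G→A (3') deamination is profiled
(`damage_profile()`) and used to filter for authentic ancient reads
(`pmd_filter()`); genetic sex comes from X and Y coverage normalized by the
autosomes (`determine_sex()`).

**Collagen QC and diet.** Collagen is accepted when the C:N atomic ratio is
in 2.9–3.6 with %C > 8 and %N > 3 (`qc_collagen()`). Consumer–prey shifts
beyond the terrestrial trophic expectation (~1‰ δ13C, 3–5‰ δ15N) flag
aquatic resource use (`trophic_shift()`); `element_difference()` checks
whether two skeletal elements are isotopically consistent with one
individual.

## Worked example

```r
library(osteokin)
fx <- write_demo_fixtures(file.path(tempdir(), "demo"), seed = 1)
report <- run_case(fx$config)
report
```

```
case report: same_individual_or_twin 
  - PMR ratio 0.513 < 0.625 (half-baseline identity rule) 
  - sex calls concordant: XY 
  - pair f3 0.271 vs unrelated baseline mean 0.184 
annotations:
  * dates are not statistically combinable; treating LAB-0001 as the true age,
    modern-carbon contamination of 1.5% (LAB-0002), 0.6% (LAB-0003) would
    explain the younger dates 
  * isotope offset femur_vs_molar exceeds same-individual bounds; dentine
    records childhood diet while bone remodels through life, so a life-stage
    dietary change is a candidate explanation 
  * elevated d15N trophic shift flags aquatic resource consumption; a
    freshwater reservoir effect would bias 14C dates older, not younger 
```

The fixture was generated with ground truth "same individual": the PMR ratio
lands near 0.5 (the half-baseline law), the two focal samples' coverage
profiles both call XY, and the injected 1.4%/0.7% modern-carbon
contamination is recovered (1.5%/0.6% under measurement noise) as the
explanation for the deliberately non-combinable dates. Drill-down objects
print their own summaries:

```r
report$genetic$classification
#> PMR ratio 0.513 (pmr 0.1884 / baseline 0.3672) -> identical_or_twin [bands 0.625, 0.875]
report$chronology$combination
#> pooled 13723 +/- 25 14C BP; chi2 = 55.00 (df 2, crit 5.99) -> NOT combinable
report$chronology$calibrated[[1]]
#> LAB-0001: median 13934 cal BP
#>   68.3%: 13990-13880
#>   95.4%: 14030-13830
```

A command-line surface mirrors the R API
(`inst/exec/osteokin <subcommand>`): `fixtures`, `call`, `damage`, `sex`,
`pmr`, `f3`, `calibrate`, `combine`, `contamination`, `isotopes`, `report`.

## Scope notes

Headline statistics from the motivating application (PMR 0.116 vs baseline
0.212; f3 0.571 ± 0.006; 8.1% terminal C→T) require external sequence
archives and comparative genotype panels; they are documented reference
points, not desk-scale tests. Published calibration curves are not bundled:
`read_calibration_curve()` reads the standard dialect if you supply one, and
all tests run against a synthetic identity curve with closed-form
expectations.
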