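---
title: "Methods: identity testing for ancient skeletal remains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identity testing for ancient skeletal remains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteokin)
```

# The problem

Palaeolithic skeletal collections frequently contain isolated elements whose
attribution is uncertain: a mandible recovered from disturbed deposits may or
may not belong to a nearby burial preserving only the postcranium. `osteokin`
combines three independent lines of biomolecular evidence — nuclear DNA
relatedness, radiocarbon chronology, and collagen stable isotopes — into a
single reproducible decision, and ships a synthetic-data generator so the
whole chain can be exercised with known ground truth.

# Genetic identity

## Pseudo-haploid calling

Low-coverage ancient samples cannot be genotyped diploid. Instead, at each
panel SNP one sequenced base is drawn uniformly at random among bases with
Phred quality ≥ 30 that match the panel's ref or alt allele, after excluding
bases within 2 bp of a read end (where post-mortem deamination concentrates).
There is deliberately *no* majority rule: the uniform draw is what gives the
PMR identity law below its clean expectation. Tri-allelic observations are
discarded before the draw; a site with no qualifying base is missing, which
is a value, not an error.

## The half-baseline PMR law

Let a locus have alt-allele frequency $p$ and let $H = \mathrm{E}[2p(1-p)]$
be the population heterozygosity. Two pseudo-haploid observations of the
*same* diploid genome disagree only at heterozygous sites, and there with
probability 1/2, so $\mathrm{E}[\mathrm{PMR}] = H/2$. Two unrelated
individuals disagree with probability $2p(1-p)$ per locus, i.e.
$\mathrm{E}[\mathrm{PMR}] = H$. First-degree relatives, sharing one allele
identical-by-descent per locus, sit at $3H/4$. `classify_pair()` therefore
reports the ratio of the pair's PMR to the mean PMR of the target against
putatively unrelated reference individuals, with class bands at the midpoints
0.625 and 0.875 between the expected ratios 0.5 / 0.75 / 1.0. The bands are a
package convention (the published argument only needs the identity case);
they are configurable and always reported next to the raw ratio. The
low-overlap warning threshold is 500 SNPs, low enough not to reject
damage-filtered datasets of a few thousand SNPs.

Pseudo-haploid data cannot separate "same individual" from "identical twins"
— that distinction requires non-genetic evidence — so the pipeline's top
verdict is deliberately capped at `same_individual_or_twin`.

## Outgroup f3 and the jackknife

For allele frequencies $o, a, b$, the outgroup statistic is
$f_3(O; A, B) = \mathrm{E}[(o-a)(o-b)]$, computed over sites non-missing in
all three populations (dropped triple-wise, not panel-wise), with no
heterozygosity normalization or inbreeding correction (outgroup mode).
Single pseudo-haploid samples contribute 0/1 "frequencies". Standard errors
use a weighted delete-one-block jackknife over contiguous 5-Mb blocks
(per-chromosome fallback; block length is a free parameter large relative to
linkage disequilibrium). With block weights equal to SNP counts, the
per-block pseudo-values reduce algebraically to the block means, so their
weighted average recombines to the point estimate exactly — a property the
test suite asserts with no tolerance slack.

Why can $f_3$ between two observations of one individual exceed 0.5? Writing
$g$ for the individual's allele dosage/2, $f_3 = \mathrm{E}[(o-g)^2]$, which
grows both with outgroup–target divergence and with low heterozygosity
(small $\mathrm{Var}(g)$ around extreme $p$). For *independent* symmetric
frequency laws this expression is capped at 0.5; values above 0.5 require
divergently ascertained SNPs — panels chosen to be polymorphic/divergent
between the outgroup and target lineages, as genome-capture panels are. The
test suite emulates this with anti-correlated mean frequencies (target law
centered at 0.8, outgroup at 0.2) and verifies the monotone trend of $f_3$
against heterozygosity, crossing 0.5 in the low-heterozygosity regime.

## Damage and sex

`damage_profile()` reports, per terminal position, C→T mismatches (5') and
G→A mismatches (3') over reference-C/-G opportunities; zero-opportunity
positions are undefined (`NA`), never 0. `pmd_filter()` retains reads with at
least one deamination-consistent mismatch within 3 bp of either terminus.
Two conventions exist in print for which substitution belongs to which end;
the package defaults to the canonical orientation (C→T near 5', G→A near 3')
and offers `orientation = "literal"` for the inverted wording. The window
rule is a documented simplification of per-read likelihood scores used by
dedicated damage tools; those scores, and mtDNA/X-heterozygosity
contamination estimators, are out of scope and treated as external inputs.

Genetic sex uses X and Y coverage normalized by autosomal coverage, with
screening bands XY: both rates in [0.3, 0.7]; XX: X in [0.8, 1.2] and
Y < 0.05; anything else indeterminate. No published threshold set exists for
this screening heuristic; the bands follow common practice and are
configurable.

# Chronology

Conventional age and fraction modern carbon are linked by
$t = -8033 \ln F$ (Libby mean-life, defined in exactly one place in the
code). Calibration interpolates the curve onto a 1-yr calendar grid and
normalizes the Gaussian likelihood
$\exp\!\big(-(t - \mu(\theta))^2 / 2(\sigma^2 + \sigma_{curve}(\theta)^2)\big)$
— Gaussian on the 14C-age scale, standard for this age range. Ranges are
highest-posterior-density sets at 68.3%/95.4% (possibly multi-interval on
curve wiggles), endpoints rounded *outward* to 10 yr to match the printed
convention; a central-interval mode exists because the exact range
construction of common calibration software is not published in detail.
Published curves are not bundled (they are large and externally licensed);
`read_calibration_curve()` accepts the standard comma/whitespace dialect,
and all closed-form tests use `synthetic_identity_curve()`, for which the
posterior is exactly Gaussian.

Ward–Wilson combinability pools dates by inverse variance and compares
$\chi^2 = \sum_i ((t_i - \bar t)/\sigma_i)^2$ with the 95% critical value at
$n-1$ degrees of freedom.

Contamination mixes linearly in F14C:
$F_{obs} = (1-c) F_{true} + c\,F_{cont}$, inverted by
`required_contamination()`. The default contaminant is modern,
$F_{cont} = 1.0$; post-bomb values > 1 are allowed, and the choice matters:
for a ~14 14C-kyr-old sample and offsets of 600/280 14C yr, $F_{cont} = 1.0$
yields required fractions near 1.7%/0.8%, while a post-bomb
$F_{cont} \approx 1.15$ yields ~1.4%/0.7%. Which value a given laboratory
assumed is rarely stated; the package keeps 1.0 as the neutral default and
exposes the parameter. Directionality is a theorem of the model: a
contaminant with $F_{cont} > F_{true}$ always biases the date younger, a
reservoir-depleted one ($F_{cont} < F_{true}$) older — which is why an
aquatic diet (reservoir effect) cannot explain a date that is too *young*.

# Diet

Collagen QC: pass iff C:N atomic ratio (masses 12.011/14.007) lies in
[2.9, 3.6] — both bounds inclusive — and %C > 8, %N > 3, both strict; all
violated rules are listed. Trophic shifts are consumer minus the arithmetic
mean of the prey group (the aggregation is a package choice); the
terrestrial expectation is ~1‰ δ13C and 3–5‰ δ15N per trophic level, and a
δ15N shift above 5‰ raises the aquatic flag. Marine versus freshwater
attribution is deliberately left open. Two skeletal elements of one
individual are expected to agree within 0.5‰ (δ13C) and 0.9‰ (δ15N), treated
as inclusive verdict thresholds. Herbivore baselines are split into two
groups by the largest gap on sorted δ15N — a transparent 1-D rule standing in
for groupings usually made by inspection (e.g., high- vs low-elevation
guilds).

# The synthetic world

The generator states one fixed world rather than tunable difficulty:

* allele-frequency law Uniform(0.05, 0.95) by default (heterozygosity
  0.365), avoiding monomorphic loci so PMR ratios are defined; the source
  population's real heterozygosity is unknown, so it is a free parameter,
  never an asserted value;
* genotype contamination draws from an independent frequency vector,
  mimicking modern human contamination (which pushes same-individual PMR
  upward — asserted as a monotonicity test);
* terminal damage decays exponentially with constant 2.5 positions from a
  5'-terminal rate of 8.1% in the demo fixtures (the published real-data
  terminal rate serves as the simulation's rate, not as a recomputed value);
* the demo chronology uses a true age of 13,950 14C yr BP with modern-carbon
  fractions 1.4% and 0.7% injected into two of three dates and measurement
  errors of 35–55 yr, so the pipeline's contamination solver must recover
  the injected values under noise;
* isotope fixtures place the consumer at (−18.5‰, +13.5‰) over herbivore
  groups spanning +1.2–2.5‰ and +4.2–5.8‰ δ15N.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent, so jackknife blocks are i.i.d. by construction), reference
bias, mapping artefacts, indel damage, curve wiggles of real calibration
curves, or inter-laboratory offsets. A green test therefore establishes the
correctness of the estimators under their own model assumptions, not
robustness to those real-data complications.

All generators take explicit integer seeds and restore the caller's RNG
state; derived child seeds stay below $2^{31}$.

# Numerical choices and degenerate inputs

* Posterior mass is normalized on the grid; conservation is asserted to
  1e-9, HPD interval mass to 0.5% of nominal on a 1-yr grid.
* A calibration whose likelihood peaks at the grid edge is an error (curve
  too narrow), not a silently truncated posterior.
* Ties in pseudo-haploid calling are resolved by the uniform draw only.
* Reads shorter than twice the trim width are fully masked and flagged.
* `required_contamination` with an inverted sign (observed older than truth
  under a modern contaminant) is flagged inconsistent rather than clipped.
* Zero-overlap PMR and empty prey groups are errors; all-missing frequency
  sites are `NA` and dropped triple-wise in f3.

# Known limitations

Likelihood-based kinship beyond the ratio rule, f4/D statistics and
admixture modelling, full Bayesian sequence calibration, marine reservoir
curves, and isotope mixing models are all out of scope. The decision rule
weighs genetics above chronology and isotopes by design: dates and diets of
one individual can legitimately disagree (contamination, life-stage diet
changes), so those discrepancies annotate rather than veto.
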