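---
title: "Models and methods behind retrosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosim)
```

`retrosim` models a directed-evolution experiment in which a passenger gene
is mutagenized by the error-prone reverse transcriptase of HIV-1-derived
vectors over successive transduction cycles, then screened for variants that
change a cellular phenotype. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The mutation-accumulation model

Each "generation" is one reverse-transcription cycle: the genome is copied
once, and every site can acquire a substitution during the copy. The
process is Bernoulli per site per cycle rather than Poisson per genome:
at the rates of interest (≤ 10⁻³ per nt per cycle) the two are numerically
indistinguishable, and the Bernoulli formulation handles back-mutation
naturally — a site that reverts to the reference base simply stops counting
as mutated. A clone's "mutated positions" are defined as the positions at
which its sequence differs from the reference *at observation time*,
exactly as Sanger sequencing of an amplicon would score them.

Under this model the per-clone count of mutated positions after $G$ cycles
on a gene of $n$ nt at rate $m$ is Binomial$(nG, m)$ to first order, i.e.
effectively Poisson$(mnG)$; `dispersion_test()` checks observed per-clone
counts against this neutral expectation via the index of dispersion.

### The substitution spectrum and G>A hypermutation

Reverse-transcriptase errors are dominated by G→A transitions. The spectrum
is configured as a *joint* distribution over the 12 ordered substitution
types; the default puts 62.3% of the total substitution mass on G→A and
spreads the remainder uniformly over the other 11 types.

A joint spectrum cannot be realized on a concrete sequence by resolving
substitutions only after a site has been hit: a G→A event can only happen at
a G, so with base-independent site rates the realized G→A fraction is
bounded by the gene's G content (~25%). The package therefore derives
per-base site weights from the spectrum and the reference's base
composition $f_b$:

$$ w_b = \frac{\text{row mass}_b}{f_b}, \qquad
   \Pr(\text{site with base } b \text{ mutates}) = m \, w_b . $$

Because $\sum_b f_b w_b = 1$ exactly, the composition-weighted *average*
per-site rate equals the configured `mutation_rate`, while realized
event-type frequencies converge to the configured joint mass. This is the
standard biological picture of hypermutation — G sites are hit more often,
not merely resolved differently once hit — and it is what makes the
realized G→A fraction match the configured 62.3% regardless of the gene's
composition. The weights are fixed from the reference composition at
configuration time; at the rates simulated, composition drift over a run is
negligible. One consequence worth knowing: under a G>A-dominated spectrum
mutated positions are uniform only *within* each base class, so positional
uniformity of the whole process holds exactly only under a uniform
spectrum (that is how the uniformity property is tested).

### Recombination and the cis-lethal mask

Copy-choice recombination is modeled per heterozygous virion: copying
starts on a uniformly chosen parent and switches template at each position
independently with probability `recombination_switch_rate`. The fraction of
genomes co-packaged with a distinct partner is a direct parameter
(`heterozygous_virion_fraction`) rather than being derived from MOI,
because no quantitative link is established experimentally; its default is
0 and both recombination parameters are placeholders to be set by the
user.

Selection is limited to a lethal/neutral dichotomy: any substitution inside
`cis_lethal_mask` (standing in for packaging/RT/integration signals)
removes the genome, which is replaced by resampling survivors. Positive
selection — such as the fixation of promoter variants in the vector LTR
that is observed experimentally — is deliberately out of scope: no fitness
function is available to parameterize it, and modelling it would suggest a
precision the data cannot support.

### Generation labels

Label $F_k$ corresponds to $k+1$ reverse-transcription cycles: producing
the parental vector stock from transfected plasmid is itself the first
copying step. This convention is adopted because it uniquely reproduces
both printed per-cycle rates of the motivating clone sets from their printed
counts (14 mutations / 16 clones at F8 → 1.2×10⁻⁴ only with $G=9$;
61 / 40 at F16 → 1.14×10⁻⁴ only with $G=17$). A `generations = 0`
population is labelled `plasmid`. Note one printed-precision quirk: the
benchmark F16 rate 1.14×10⁻⁴ is a truncation of 1.1457×10⁻⁴ (rounding
would give 1.15×10⁻⁴), while the F8 per-clone average 0.88 is a rounding of
0.875; `estimate_rate()` therefore exposes full precision plus both
rendering conventions.

## Rate estimation

`estimate_rate()` treats $C \cdot L \cdot G$ site-cycles as a Poisson
exposure for the observed count $M$ and reports $\hat m = M/(CLG)$ with an
exact Poisson (Garwood) 95% interval via gamma quantiles — chosen over the
normal approximation because realistic sequenced clone sets yield tens of
events, where the normal interval undercovers. For $M = 0$ the one-sided
construction yields the familiar upper bound $3.689/(CLG)$. Mutated
positions are summed over clones without deduplicating positions shared
between clones, matching how per-clone averages are computed in practice
($14/16 = 0.875 \to 0.88$).

Coverage of the interval, the root-$n$ shrinkage of its width with clone
count, and dispersion of simulated per-clone counts are verified by
simulation in the test suite (100 seeded replicates at $C=40$, $L=783$,
$G=17$ for rates 3.4×10⁻⁵ and 1×10⁻⁴).

## Library planning and MOI statistics

The planning formula is linear: `cycles_required()` returns $p/(mn)$ cycles
for $p$ desired mutations per copy. `expected_mutations()` returns both the
linear expectation $mnG$ and the exact binomial complement
$n(1-(1-m)^G)$; they agree within 1% whenever $mG \le 0.01$, and the linear
form is the default because it is the convention in which such plans are
stated. At $m = 1.2\times 10^{-4}$, $n = 783$, 16 cycles, the linear model
gives 1.5 mutated positions per gene copy — the complexity at which a
library of this kind is typically screened.

Proviral copies per cell are modeled as Poisson(MOI), the standard
single-hit model for VSV-G pseudotyped transduction. The quantity that
matters for screening design is the fraction of transduced cells carrying
more than one provirus,
$P(N\ge 2 \mid N \ge 1) = (1-e^{-\lambda}-\lambda e^{-\lambda})/(1-e^{-\lambda})$,
computed via `ppois()` for numerical stability (it behaves as $\lambda/2$
as $\lambda \to 0$). `recommend_moi()` inverts it by monotone
root-finding; a 1.5% doublet tolerance gives λ ≈ 0.030, which is why
screens are run at MOI ≈ 0.03, while the evolution phase at MOI > 100 makes
multiple integration — and hence heterozygous virions and recombination —
essentially certain.

## The screening model

Viability readouts emulate an MTT/OD570 assay: each clone follows a
log-logistic dose-response $v(c) = 1/(1+(c/\mathrm{IC50})^h)$, scaled by a
baseline signal, with additive Gaussian noise truncated at zero. Death
rate is defined explicitly as $1 - $ (readout at concentration $c$ /
readout at concentration 0), clamped to $[0,1]$ with clamping counted —
the complement of the living fraction, which resolves the ambiguity between
"death rate" and "survival" phrasings that plague assay descriptions.

### Generator defaults (the screening scenario)

The hit-calling scenario fixes, once, a parameterization consistent with
the anchors of the motivating screen:

* untransduced cells IC50 14 nM, Hill slope 2 — the untransduced line is
  already sensitive near the 10 nM screening concentration through its
  endogenous kinase, and >80% of cells die at 35 and 70 nM, which is what
  disqualifies those concentrations for screening;
* wild-type-transgene control IC50 12 nM — an extra wild-type copy adds a
  modest sensitization, making this control the effective bar in the
  "exceeds **both** controls" hit rule;
* non-sensitizer library clones behave like untransduced cells (most
  variants are neutral or inactivating);
* sensitizer clones have the baseline IC50 divided by `sensitizer_fold`
  (60 in the screening scenario);
* readout noise sd 0.01 on a baseline signal of 1.

With these defaults the separation between a fold-60 sensitizer and the
controls at 10 nM is tens of noise standard deviations, while a
non-sensitizer clone must beat the wt control by ~5σ of readout noise to
false-positive — so a 76-clone screen recovers all implanted sensitizers
with at most a couple of false positives, which the end-to-end test pins
down under fixed seeds. The dose-response scenario uses a separate,
wider-range parameterization (untransduced IC50 22,500 nM; wild-type
4,500 nM; strong sensitizer 75 nM) so that the 60-fold and 300-fold IC50
reductions are exact generator truths that the fitting stage must recover.

### Dose-response fitting

`fit_dose_response()` fits the 4-parameter log-logistic
$v(c) = \text{bottom} + (\text{top}-\text{bottom})/(1+(c/\mathrm{IC50})^h)$
by Levenberg–Marquardt with box constraints ($h > 0$, IC50 within a wide
window around the measured range) and a multi-start grid (5 log-spaced IC50
starts × 4 Hill starts), keeping the best residual sum of squares. The top
is left free because normalized viability of transduced populations need
not be 1 at concentration 0. The reported IC50 is the inflection
(relative) IC50; the absolute 50%-viability crossing is reported separately
when the fitted curve crosses 0.5. Flat responses (range < 0.05) and fits
with vanishing amplitude or an inflection far outside the measured window
are flagged `converged = FALSE` with `ic50 = NA` — never a silent arbitrary
number. Fold-changes come with a seeded percentile bootstrap over
resampled residuals.

### Hypothesis tests

`compare_populations()` uses the Welch unequal-variance two-sample t-test:
where only "a two-sample t-test" is specified, Welch is the safer default
and coincides with the classical test under equal variances. Degenerate
inputs (zero variance in both groups) return $p = 1$ for equal means and
$p = 0$ for exactly separated constants, flagged and logged. Per-
concentration tests are reported unadjusted, matching the convention of
small screening studies; users comparing many concentrations can apply
`p.adjust()` downstream.

## Determinism and problem sizes

Every stochastic entry point requires an explicit integer seed — a missing
seed is an error, not a silent default — and identical seeds produce
byte-identical outputs (`withr::with_seed` scopes the RNG, so user session
state is untouched). The test suite and acceptance script run at the study
scale that the quantities refer to: 10,000 lineages × 783 nt × 16–17 cycles
for simulator means and dispersion, 100 seeded replicates for CI coverage
and noisy IC50 recovery, 4×10⁶ Poisson draws for the MOI Monte-Carlo
cross-checks, and a 76-clone × 3-experiment screen. These sizes keep every
Monte-Carlo standard error far below the tolerance being asserted.

## What the generator does not emulate

The synthetic data reproduce the *statistical structure* the analysis
stages assume, not the biology: there is no fitness landscape (the
lethal/neutral mask is the only selection), no insertion-site effects
(polyclonal-population averaging is represented by independent noise
draws), no indels or hypermutation runs, no plate-position or batch
effects, and the heterozygosity/recombination frequencies are placeholders.
Passing tests therefore demonstrate that the estimators and the screening
pipeline recover known truths under the stated stochastic model — not that
any particular biological value is correct. The bundled 783-nt reference is
a seeded synthetic CDS-like sequence (ATG start, no internal stops), not
the natural dCK coding sequence.
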