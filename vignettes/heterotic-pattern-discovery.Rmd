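---
title: "Genome-based discovery of heterotic patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based discovery of heterotic patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteropattern)
```

## The problem

Hybrid breeding exploits heterosis: crosses between inbred lines from
complementary, genetically distinct *heterotic groups* out-yield the
lines themselves, and a pair of such groups whose inter-group crosses
are consistently high-yielding is a *heterotic pattern*. In crops such
as hybrid rice, where breeding programs are organized around a
cytoplasmic male sterility (CMS) system into maintainer (female) and
restorer (male) lines, historical pool boundaries were set by the
seed-production system, not by combining ability — so the pools in use
need not be the best heterotic pattern available in the germplasm.

`heteropattern` implements a three-step, genome-based procedure to find
better patterns:

1. **Predict** the grain-yield performance of *every* possible single
   cross among the parental lines, from SNP marker data and the
   adjusted means of a sparse set of field-tested hybrids.
2. **Search** the predicted full matrix for two disjoint, equal-size
   groups maximizing the mean inter-group prediction, by simulated
   annealing.
3. **Evaluate** candidate patterns for short-term success (the pattern
   score itself) and long-term success (theoretical selection limit
   under reciprocal recurrent selection, and genetic
   representativeness), as a function of group size.

Because commercial breeding data are proprietary, the package ships a
synthetic breeding-program generator that reproduces the statistical
structure this analysis assumes; all tests and examples run on it.

## Trial model and variance components

Plot yields from augmented multi-location trials are modelled as

$$y_{jkmn} = \mu + m_j + g_j + l_k + t_{km} + b_{kmn} + (gl)_{jk} +
\varepsilon_{jkmn}$$

with fixed intercept and maturity class $m_j$ and random genotype
$g_j$, location $l_k$, trial-within-location $t_{km}$,
block-within-trial $b_{kmn}$, genotype-by-location $(gl)_{jk}$ and
residual. Entries (hybrids) are unreplicated; the replicated check
varieties identify the residual variance within locations, which in
turn separates $\sigma^2_{G\times L}$ from $\sigma^2_\varepsilon$.
`fitTrialModel()` fits this model by REML through `lme4`; at least two
locations are required, otherwise $G\times L$ and error are
inseparable. Perfectly noiseless records (a degenerate case that
arises in simulation) make the REML surface singular in the
genotype-to-error variance ratio, so they are detected and the
components evaluated analytically instead.

`decomposeGcaSca()` refits the model replacing the hybrid genotype
effect with female GCA + male GCA + SCA (female-by-male) effects and
their three interactions with location; checks keep a genotypic term of
their own via indicator weighting, so the GCA/SCA structure applies to
hybrids only. The likelihood-ratio test for a variance component uses
the boundary-corrected null (an equal mixture of a point mass at zero
and $\chi^2_1$); when testing $\sigma^2_{SCA}$, the SCA-by-location
term is retained in both models so the test isolates the cross-specific
main effect.

Broad-sense heritability on an entry-mean basis is

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times L}/n_{loc} +
\sigma^2_\varepsilon/(n_{loc}\,n_{rep})}$$

with $n_{rep} = 1$ for unreplicated entries. `computeBlues()` refits
the model with fixed genotype effects; the reported adjusted mean is
the intercept-plus-effect under equal weighting of the maturity
classes. When every genotype carries exactly one maturity class —
the usual field situation — maturity is aliased with genotype and the
maturity effect is absorbed into the genotype's own mean, which is the
estimable quantity. Commercial heterosis is the percent advantage of a
hybrid's adjusted mean over the best check's.

## Marker data and hybrid coding

Parental lines are (essentially) homozygous inbreds; dosages are 0/2
with 1 reserved for flagged impure lines. QC removes markers with
minor-allele frequency below 5% by default, computed on the configured
line set. Rogers' distance between lines reduces, for homozygous
biallelic data, to the fraction of mismatching loci (missing calls are
handled pairwise-complete); the additive relationship between lines is
$A = 1 - RD$. LD is summarized by the squared dosage correlation $r^2$
(equivalent to haplotype $r^2$ for inbreds) for same-chromosome pairs
within a physical window, and population structure by classical metric
scaling of the Rogers' matrix (`runPcoa()`, which reports rather than
drops negative eigenvalues).

Hybrids are coded under the F$_\infty$ metric: at each marker, parents
sharing the reference homozygote give $z_A = +1$, sharing the
alternative $-1$, and discordant homozygotes give $z_A = 0$ with
dominance indicator $z_D = 1$. Missing parental calls yield missing
covariates, imputed with the marker mean over the coded hybrids —
imputation is restricted to the prediction covariates; distances and
$r^2$ stay pairwise-complete so they remain unbiased.

## RR-BLUP with additive and dominance effects

The prediction model is $Y = 1_n\mu + Z_A a + Z_D d + e$ with
$a \sim N(0, \sigma^2_a I)$, $d \sim N(0, \sigma^2_d I)$, solved via
Henderson's mixed-model equations with shrinkage ratios
$\lambda_a = \sigma^2_e/\sigma^2_a$, $\lambda_d =
\sigma^2_e/\sigma^2_d$. Covariates are centred by training means; the
intercept is re-expressed on the raw-code scale afterwards so
predictions are literally $\mu + z_A a + z_D d$. When $\lambda$s are
not supplied they are estimated by REML on the equivalent two-kernel
model ($K_A = Z_A Z_A'/m$, $K_D = Z_D Z_D'/m$), using a coarse
log-scale grid followed by a Nelder–Mead polish of the profiled
restricted likelihood; we chose a 2-d simplex polish over 1-d
golden-section passes because the two ratios are strongly coupled.
Estimated variance ratios are bounded in $[10^{-8}, 10^8]$, and if the
dense MME is still near machine-singular (tiny shrinkage plus
monomorphic-in-sample markers) the solver falls back to the exactly
equivalent $n \times n$ kernel form, which is bounded below by the
identity and always well conditioned.

One subtlety of the F$_\infty$ dominance covariate deserves emphasis:
$z_D = p_f + p_m - 2p_fp_m$ (in parental allele frequencies) carries
additive margins, so "dominance variance" at the covariate level is
*not* pure SCA variance — a large part of it surfaces as parental GCA.
The synthetic generator's calibration accounts for this (below).

### Chess-board cross-validation

Prediction ability is evaluated over three relatedness scenarios. Per
run, 80% of the females and 80% of the males are sampled; phenotyped
crosses among the sampled parents form a block of which a configurable
fraction (default 20%) is held out as **T2** and the rest is the
estimation set. Crosses with exactly one parent represented in the
estimation set form **T1**, crosses with neither parent **T0**.
Scenario membership is determined by the parents *actually present* in
the estimation crosses, which guarantees the T2/T1/T0 definitions
hold exactly. Ability is the Pearson correlation of observed and
predicted values per scenario; accuracy divides ability by
$\sqrt{h^2}$. Runs with an empty scenario are redrawn (capped). The
T2 hold-out fraction exists because the estimation block would
otherwise exhaust all crosses among sampled parents, leaving T2 empty.

## Pattern search

`patternScore()` is the mean predicted performance over all $s^2$
inter-group crosses. `annealSearch()` maximizes it over two disjoint
size-$s$ groups with a single-swap neighbourhood (replace one member
of one group by a non-member, including members of the opposite
group), Metropolis acceptance $\min(1, e^{\Delta/T})$, geometric
cooling $T \leftarrow 0.995\,T$ from a starting temperature calibrated
to accept about 80% of score-decreasing moves, $200\,n\,s$ steps per
restart and 5 restarts. Each restart ends with a steepest-ascent
polish over the same neighbourhood, so the returned pattern is always
a local optimum of the move set; across the tested instance sizes this
combination matches exhaustive enumeration exactly.
`bruteForceSearch()` provides that exact oracle up to a configurable
evaluation cap. By default the candidate pool ignores pool membership
(restorer conversion is treated as feasible); a `pool` argument
restricts the search to, say, one sex for CMS-practical variants.
`sizeSweep()` repeats the search over sizes (classically 2–20) and
reports the Jaccard overlap of selected lines between consecutive
sizes plus the fraction of female lines selected.

## Short- and long-term success

The **theoretical selection limit** is the performance of the best
hybrid reachable by reciprocal recurrent selection within the two
groups, assuming no migration, mutation or epistasis: per marker, an
allele is fixable in a group if at least one member carries it, and
the limit sums the per-marker maximum of $+a$ (both groups fix the
reference allele), $-a$ (both the alternative) or $d$ (opposite
fixation, i.e. a permanently heterozygous hybrid), plus the intercept.
It therefore never falls below the predicted score of any realized
inter-group cross, and never decreases when groups grow.

**Genetic representativeness** measures how much of the population's
genome the selected lines cover. The published sources name its
ingredients (within-group relationship, population-to-group
relationship, genome proportion) without printing the algebra, so the
package fixes a declared stand-in index:

$$R = 2\,\bar a(P, G) - \bar a(G, G)$$

where $G$ is the union of both groups, $\bar a(P,G)$ averages each
population line's mean additive relationship to the group (self
excluded) and $\bar a(G,G)$ is the mean over unordered within-group
pairs. The first term rewards coverage, the second penalizes
redundancy: duplicating a selected line cannot increase $R$, and
selecting the whole population returns its mean off-diagonal kinship.
Values are clamped to $[0,1]$ with a flag. This index is our design
choice, not a reconstruction of the original reference's formula.

`compareToPools()` contrasts the top-$k$ (default 256) predicted
female-by-male crosses of the existing pools with the pattern's
inter-group crosses, reporting the percent advantage of the means.
`detectPlateau()` reads the plateau of the long-term curves as the
smallest size at which both reach 95% of their maximum over the sweep;
this mirrors judging saturation off a plotted curve and, like any
relative-to-max rule, saturates early for curves whose offset is large
against their dynamic range.

## The synthetic breeding program

`simConfig()`/`simulateProgram()` generate: two parental pools whose
allele frequencies follow a Balding–Nichols model around ancestral
frequencies $U(0.1, 0.9)$, with one divergence parameter
(F\\(_{st}\\)-like, default 0.3, which reproduces the clear pool
separation on PCoA axis 1 that motivates pattern search);
an unbalanced factorial of crosses with gamma-distributed male usage
weights; marker effects at a random QTL subset rescaled so realized
additive and dominance variances over the full factorial hit their
targets exactly; and augmented trials (every hybrid once per location,
every check once per block, blocks nested in trials in locations) with
the configured location, trial, block, G-by-L and error variances,
plus a three-level fixed maturity class.

Defaults mirror a medium-grain hybrid rice segment scaled down about
4-fold for test speed: 48 males by 8 females, 234 phenotyped crosses
(about 61% of the factorial, matching the observed fill rate), two
locations, 500 markers on 12 chromosomes, 5 checks per block, 20
entries per block, and variances (Mg/ha)$^2$ of the magnitudes
reported for such trials: $\sigma^2_{G\times L} = 2.10$,
$\sigma^2_\varepsilon = 0.97$. The genetic targets are calibrated
through the covariate geometry: `varAdditive = 0.17`,
`varDominance = 0.36` yield realized GCA variance $\approx 0.40$ and
realized SCA (interaction) variance $\approx 0.13$ over the full
factorial — the decomposition magnitudes of the emulated segment —
because roughly two thirds of the dominance-covariate variance
surfaces in the GCA margins. Checks are drawn 1 Mg/ha below the hybrid
mean (inbred lines yield well below hybrids), giving realistic
commercial-heterosis figures.

What the generator does *not* emulate: linkage maps and recombination
(markers are exchangeable), epistasis, multi-year structure, genotyping
error, and selection history shaping allele frequencies. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimation machinery under the assumed model, not robustness to the
full messiness of real breeding data.

## Numerical choices and test design

* REML fits go through `lme4` with singular fits permitted (variance
  components at zero are reported and flagged as boundary estimates).
* The parameter-recovery suite (100 seeds at the default scale)
  compares mean estimates against per-seed realized truths: the
  genotype variance against the realized variance of simulated
  genotypic values, G-by-L and error against their drawn counterparts,
  and trial/block against the *within*-location / within-trial spread
  of the drawn effects, because the between-group part of those
  effects is absorbed by the enclosing stratum and is not estimable.
* The GCA/SCA split itself is estimated with substantial sampling
  noise under two-location, high-G$\times$L conditions; the SCA
  component in particular is subject to boundary-truncation bias
  (estimates cannot go negative), so recovery is asserted for the
  genetic total while the split's behaviour is exercised through the
  size of the SCA likelihood-ratio test under an additive-only null.
* Oracle comparisons use independent routes: a hand-coded dense
  EM-REML iteration for the trial model, closed-form ridge and kernel
  (GBLUP) algebra for the MME, exhaustive enumeration for annealing
  and for the per-locus selection limit.
* Problem sizes in the test suite (e.g. 100-seed recovery at the
  4-fold scaled segment, the full 95-by-16 dimensions for the
  cross-validation ordering, 20-marker instances for selection-limit
  enumeration) were chosen as the smallest sizes at which the checked
  properties are stable.
* All stochastic stages derive their streams from one master seed;
  pipelines re-run bit-identically, which the manifest checksums
  verify.

## Known limitations

* The representativeness algebra is a declared stand-in (above).
* BLUE standard errors, and with them per-hybrid significance tests
  against checks, are not computed.
* The trial model ignores spatial row-column structure within blocks.
* With a single location the G-by-L component is inseparable from
  error and the trial model refuses to fit rather than silently
  confounding the two.
* Annealing is exact on all instances we can enumerate, but carries no
  global-optimality guarantee at production sizes; restarts and the
  stability report across the size sweep are the practical safeguards.
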