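---
title: "Quantifying technical variation in 16S rRNA amplicon profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying technical variation in 16S rRNA amplicon profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampvar)
```

## The problem

Targeted 16S rRNA gene sequencing estimates the composition of a microbial
community, but every estimate carries technical noise: run-to-run batch
effects, replicate-to-replicate scatter within a run, reagent
contamination, and the stochastic amplification of small amounts of
template DNA. Clinical and longitudinal studies need to know how large
this noise floor is, because a biological difference is only
interpretable when it exceeds it. `ampvar` implements a complete
quality-control and variance-quantification workflow built around three
kinds of control material that a sequencing core accumulates naturally:

* a **mock community** (a defined mixture of bacterial strains) sequenced
  repeatedly across runs,
* **negative controls** (template-free extractions) that capture the
  reagent "kitome",
* a **dilution series** of the mock community with absolute biomass
  measured by 16S qPCR.

## Contaminant scoring

For each sequence variant (SV) $i$, the contaminant score is

$$S_i = \frac{\sum_{j \in \text{negatives}} c_{ij}}{\sum_j c_{ij}},$$

the fraction of the SV's reads that occur in negative controls. $S_i = 0$
for SVs never seen in a negative and $S_i = 1$ for SVs seen only there.
SVs with $S_i > 0.1$ are removed ("exceeds 10%" is read strictly, so a
score exactly at the threshold survives). The score is deliberately an
aggregate-count statistic, not a frequency/prevalence classifier: it asks
where the reads are, pooled over the whole study, which makes it robust
to individual low-depth negatives but means it should always be computed
on the **full** study — scoring a dilution run in isolation dilutes the
negative signal against heavily contaminated low-biomass libraries.

After removal, a read-depth threshold is chosen. The operational
definition implemented here is: the smallest per-sample total among
non-negative samples such that at most `max_negatives_retained` (default
2) negative controls reach it. This turns "an inflection point above
which almost no negatives remain" into a reproducible rule; a manual
override is first-class for analysts who prefer to fix the depth (e.g.
at a conventional 10,942 reads). Samples below the threshold are dropped;
the retained table is rarefied (a single seeded multivariate
hypergeometric draw) for alpha diversity and converted to relative
abundances for everything else.

## Variability metrics

**CV.** For a taxon within a stratum, the coefficient of variation is
$100 \cdot \mathrm{SD}/\mathrm{mean}$ of relative abundances (sample SD,
$n-1$). Stratifying by run gives intra-assay CVs; pooling all samples
gives the inter-assay CV. The per-taxon "mean intra-assay CV" is the
unweighted mean over run strata — runs have unequal sizes and weighting
is a reporting choice, so the simplest summary is used. A taxon absent
from a stratum has an *undefined* CV, carried as `NA`, never as 0.

**ICC.** Reproducibility across runs is summarized by the one-way
random-effects, single-measure intraclass correlation computed per taxon
from ANOVA mean squares,

$$\mathrm{ICC} = \frac{MS_B - MS_W}{MS_B + (n_0 - 1) MS_W},
\qquad n_0 = \frac{N - \sum_j n_j^2 / N}{J - 1},$$

with runs as groups, tolerating unbalanced and singleton groups. The
per-rank summary is the unweighted mean over taxa with a defined ICC.
Note the grouping convention: with runs as groups the statistic measures
the fraction of a taxon's variance attributable to run membership, so it
rises with the batch effect. The alternative convention — taxa as
subjects and samples as raters — yields values near 1 whenever the
community structure dwarfs replicate noise; both are "one-way ICCs" and
published values rarely state which was used. This package implements
the per-taxon/run-grouping form because it is the one that decomposes
technical variance, which is the quantity of interest here.

**Levey-Jennings.** Clinical-lab control charting: per taxon, samples
more than $k$ SDs (default 2) from the all-sample mean are flagged, in
run order. The mean and SD are computed over all samples rather than
leave-one-run-out; with dozens of runs the difference is negligible and
the all-sample form is the standard chart construction.

## Community distances

Bray-Curtis ($\sum|x-y| / \sum(x+y)$), unweighted Jaccard on
presence/absence, and the Jensen-Shannon *distance* — the square root of
the JS divergence with base-2 logarithms, so its range is $[0,1]$ and it
is a metric. PCoA is classical metric scaling (Gower centering of
$-D^2/2$); negative eigenvalues are reported, not corrected, and
variance explained is relative to the positive eigenvalues only.

PERMANOVA is the standard distance-based one-way partition:
$R^2 = 1 - SS_W / SS_T$ on squared distances, pseudo-F from the usual
mean squares, and a permutation p-value with the $+1$ correction
$p = (1 + \#\{F^\ast \ge F\}) / (1 + P)$, which can never be exactly
zero (999 permutations bound p below at 0.001). Multiple factors are
tested *marginally*, one PERMANOVA each — reporting two $R^2$ values
without a joint model is reproducible and avoids order-dependence; joint
partitioning is out of scope. For tiny designs an exhaustive mode
enumerates every distinct label arrangement except the observed one
(the 2+2 complete-separation instance yields exactly $p = 1/3$).

Distances among repeat stool samples are partitioned into intra-run /
same-specimen, inter-run / same-specimen, and different-specimen
(biological) sets; both means and medians are reported since either may
be quoted in the literature.

## Biomass and the variation model

The qPCR standard curve is least squares of Ct on $\log_{10}$(copies per
reaction) over the nonzero standards ($0, 10^2, \dots, 10^7$ copies per
5 µL are the conventional plate; zero-copy wells serve only as
no-template checks). Efficiency is $10^{-1/\text{slope}} - 1$.
Quantification inverts the curve at the mean Ct of a sample's determined
wells and divides by the 5 µL template volume; all-undetermined samples
get 0 copies with a flag.

Expected concentrations along a dilution series come in two flavours:
naive ($\text{stock}/\text{factor}$) and sequential, which propagates
the *measured* parent concentration down the chain
($E_k = M_{k-1} \cdot f_{k-1} / f_k$) because each dilution is prepared
from the previous tube. A consistent over-dilution at each step makes
measured values fall below the naive line everywhere while the
sequential recalibration tracks them.

The variation model is ordinary least squares of

$$\log_{10}(\mathrm{CV}) \sim \log_{10}(\text{copies}/\mu L)
  + \log_{10}(\text{mean relative abundance}),$$

fitted to one row per taxon × dilution level. Rows enter only if the
taxon's mean relative abundance is at least 0.1%, it was detected in at
least 3 of the level's replicates, and the CV is defined and positive —
all three variables are logged, so zeros cannot enter; these defaults
are this package's choice of a minimal publishable inclusion rule.
Biomass per row is the level's mean qPCR measurement (measured, not
theoretical, since the model's purpose is prediction from a measurable
quantity). Mean relative abundance enters in **percent** by default and
the unit convention is stored on the model object, so `predict_variation()`
cannot silently mix units; an SD response is available behind a flag for
comparison with plots drawn on the SD scale. Predictions back-transform
the linear predictor, and `prediction_grid()` evaluates the standard
low/medium/high-biomass (10, 10³, 10⁵ copies/µL) × 1–50% abundance
table. Published prediction tables of this kind are not always exactly
the back-transform of the published coefficients; this implementation
follows the fitted formula verbatim.

## The synthetic study generator

No suitable public dataset pairs repeated mock controls, negatives and a
qPCR-calibrated dilution series, so the package ships a generator whose
defaults define the study conditions used throughout the tests:

* **Layout** (`default_study_design()`): 19 runs, 218 mock libraries
  (108 undiluted across 18 runs + a dilution run of 11 levels × 10
  replicates, 10 of them undiluted), 29 stool libraries from 3 specimens
  across 3 runs, 222 negative controls — 469 libraries.
* **Mock community**: 33 synthetic strains across 12 genera, uniform
  true proportions (membership is what defines such controls; measured
  compositions are rarely published), stock at 7,520 16S copies/µL so
  that the 1:80 dilution sits near 94 copies/µL, the neighbourhood where
  contamination takes over.
* **Noise cascade** per sample: a log-normal run batch effect
  (`run_effect_sd = 0.2`) shared within a run; Dirichlet replicate noise
  (concentration 1000 × run composition), the standard overdispersed
  composition model; a **finite-template bottleneck** — the composition
  is resampled multinomially at $n = \text{copies}/\mu L \times 5\,\mu L$
  molecules — which is the mechanistic source of the biomass–variance
  relationship (noise $\propto 1/\sqrt{n p}$, hence negative log-log
  slopes on both biomass and abundance); constant-load contamination
  with $w = L/(L + c)$, $L = 10$ copies/µL-equivalents over five kitome
  SVs (Pseudomonas, Moraxella, Ralstonia, Sphingomonas,
  Bradyrhizobium); multinomial read sampling at log-normal depths
  (median 40,000 reads; negatives at a median of 1,500 so the depth
  filter removes essentially all of them); a 5% per-step over-dilution
  bias; and 10% log-normal qPCR error with 0.1-cycle well noise.
* Stool specimens are drawn from a heavy-tailed 60-taxon base community
  perturbed per specimen (`specimen_effect_sd = 0.8`), so biological
  distances exceed inter-run distances, which exceed intra-run scatter.

The calibration above was fixed once, by matching the qualitative
structure the workflow is meant to detect (distance ordering, inter >
intra CV, contamination dominance at low biomass) at magnitudes typical
of published mock-community monitoring; it was then frozen. Everything
is a deterministic function of one integer seed, drawn from a single
sequential RNG stream in fixed generation order (per-sample sub-streams
would only matter for parallel generation, which the study sizes here do
not warrant).

What the generator does **not** emulate: sequencing error and chimeras
(denoising is upstream of the feature table), taxon-specific PCR
efficiency or copy-number bias (the mock's observed composition equals
its input composition on average, which real mocks routinely violate),
cross-contamination between wells, and any time model for the stool
specimens. Tests passing on this generator therefore demonstrate that
the statistical machinery recovers the structure it targets — not that
real data will show the same magnitudes.

## Numerical choices and degenerate inputs

* Rarefaction drops samples below depth rather than resampling upward.
* SVs with zero total count score 0 (flagged) and are dropped silently.
* Taxa unassigned at a collapse rank group under
  `unclassified_<parent>`, conserving reads.
* CV of an undetected taxon, and the ICC when $MS_B = MS_W = 0$, are
  `NA` with flags, never coerced to 0.
* A constant regression response returns zero slopes and $R^2 = 0$
  rather than `NaN`.
* Spearman correlations use average ranks; a constant CV vector returns
  `rho = 0` with a tie flag.
* Permutation p-values always carry the $+1$ correction.

## Problem sizes used in the packaged checks

The test-suite simulations use the default 469-library study (20 seeds
for the stochastic properties), 200 null simulations at 999 permutations
for permutation-test calibration, 100 simulated fits at $n = 126$ rows
and residual SD 0.5 for regression parameter recovery, and brute-force
oracle comparisons on random tables up to 50 × 50. These sizes give
Monte-Carlo error comfortably below every asserted margin while keeping
a full run in the low minutes on one CPU.

## Known limitations

* The contaminant score cannot separate a genuine community member that
  also contaminates reagents; it removes it wholesale.
* Marginal PERMANOVA $R^2$ values over correlated factors do not sum to
  an interpretable total.
* The per-taxon ICC convention differs from the taxa-as-subjects
  convention (see above); values from the two are not comparable.
* The variation model is a global log-log plane; taxon-specific slopes
  (random-slope or per-rank refits) are supported only by refitting at
  another rank.
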