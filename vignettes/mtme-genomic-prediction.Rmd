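---
title: "Multi-trait multi-environment genomic prediction: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait multi-environment genomic prediction: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmegp)
```

This vignette is the package's own account of the science it implements:
the statistical models and their assumptions, the priors and tunable
parameters, what the synthetic-trial generator does and does not emulate,
and the numerical and design decisions taken where the methodology left
room. Nothing stated here as an empirical result goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The two-stage analysis

Replicated field trials are analysed in two stages, the standard practice
for multi-environment breeding data.

**Stage one** (`compute_blues()`, `adjust_phenotypes()`) fits, per trait and
environment, the plot-level mixed model

$$ y_{sjr} = \mu + \mathrm{Gen}_s + \mathrm{Rep}_j +
             \mathrm{Block}_{r(j)} + \varepsilon_{sjr}, $$

with genotype fixed and replication and block-within-replication random,
by REML (via lme4). The fixed-genotype fit, in cell-mean coding, yields the
per-line adjusted means (BLUEs) directly on the trait scale together with
their standard errors. A companion refit with genotype random — the same
model otherwise — supplies the variance components and the entry-mean
broad-sense heritability

$$ h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon / r}, $$

with \(r\) the harmonic mean of per-line replicate counts. The dual
fixed/random treatment resolves an ambiguity common in methods write-ups
that call the genotype term fixed while also assigning it a variance: BLUEs
need the fixed fit, \(\sigma^2_g\) needs the random one. Whether reported
heritabilities in any given study are plot-basis or entry-mean is often
unstated; both are available (`estimate_h2(basis =)`, including a
Cullis-style generalised heritability), entry-mean is the default because it
is the repeatability of exactly the quantity passed downstream — the
genotype mean.

Degenerate designs (one replicate, one block) make the mixed model singular;
the function then returns plain line means with a warning rather than
failing.

**Stage two** treats the line × environment × trait array of BLUEs as the
response for genomic prediction.

## 2. Relationship kernels

`vanraden_g()` implements the genome-wide kernel
\(G = ZZ' / (2\sum_i p_i(1-p_i))\) with \(Z\) the dosage matrix centred at
twice the observed allele frequency of each marker. Missing dosages are
mean-imputed before centring (the de-facto standard before GRM
construction); markers are dropped when monomorphic, below a MAF threshold
(default 0.01) or with missing fraction above 0.2 — both configurable.
Allele frequencies are always estimated from the data at hand; no external
reference frequencies are assumed.

`target_gene_g2()` builds the complementary kernel from allele calls at a
small set of characterised loci (vernalization, photoperiod, dwarfing). The
construction is the package's main open design point, since published
descriptions of such kernels rarely state a formula. The choice here: each
gene's allele classes are one-hot encoded as homozygous diploid allele
counts (0/2 — the material is inbred), and the same VanRaden centring and
scaling is applied to the indicator matrix. This route was chosen because it
has a checkable consequence: for a biallelic gene it coincides *exactly*
with the genome-wide formula applied to the equivalent 0/2 dosage recoding,
which the test suite asserts. A joint-combination variant (one indicator per
observed multi-gene allele combination, `encoding = "combination"`) is
provided because it is the other defensible reading of "allelic
combinations"; per-gene encoding is the default as the less parameter-hungry
of the two.

`validate_kernel()` enforces symmetry (to 1e-10) and positive
semidefiniteness, adding the smallest diagonal jitter from
\(\{10^{-8}, 10^{-6}, 10^{-4}\}\) that restores PSD and recording it in the
object. Exact zero eigenvalues (duplicated lines) are accepted without
jitter.

## 3. The GBLUP family and its Gibbs samplers

Four nested models are fitted by Gibbs sampling (`fit_se()`, `fit_mt()`,
`fit_me()`, `fit_mtme()`; see the README table for their equations). Points
worth making explicit:

* **Data augmentation.** Missing and deliberately masked cells are sampled
  each sweep from their conditional normal given the observed cells of the
  same line (for MT/MTME, a rowwise conditional through the residual
  covariance \(R\)). This keeps every full conditional balanced and is the
  mechanism by which CV2 borrows secondary-trait and other-environment
  information. Predictions are posterior means of the *linear predictor*
  (fitted cell values), not of the noisy augmented draws, so masked-cell
  predictions are Rao-Blackwellised.
* **Computation.** All matrix-normal conditionals are evaluated in the
  eigenbasis of the kernel (and, for the G×E block of MTME, of
  \(\Sigma_E\), re-eigendecomposed each sweep). After rotation the rows of
  each effect matrix are conditionally independent with posterior precision
  \(\Sigma^{-1}/d_i + P_{\mathrm{lik}}\), identical across rows up to the
  scalar \(d_i\); one simultaneous diagonalisation per sweep therefore
  serves every row at once and no Kronecker matrix is ever formed. This is
  what makes 200 cross-validation refits per acceptance run affordable.
* **The ME line effect.** The multi-environment model carries both an IID
  line effect \(L_j\) and the genomic effect \(g_j\) (the reaction-norm
  convention); \(L_j\) captures line variance not explained by the markers.
  The two compete for the line main effect, which is expected and harmless
  for prediction; `drop_line_effect = TRUE` removes \(L_j\).
* **Shared trait covariance in MTME.** As written in the model, the main
  genetic block \(b_1\) and the G×E block \(b_2\) share one \(\Sigma_t\);
  `separate_sigma_t = TRUE` gives \(b_2\) its own trait covariance. The
  residual covariance is unstructured across traits and shared across
  environments; a heterogeneous-by-environment residual is out of scope.

### Priors

Chain settings and hyperpriors are rarely reported in applied
genomic-prediction papers (fits are typically delegated to a Bayesian
regression package's defaults), so they are declared assumptions here,
mirroring the weakly-informative conventions of standard Bayesian GBLUP
software:

* scalar variances: scaled-inverse-chi-square, 5 df, scale set so the prior
  mode assigns half the phenotypic variance to the component. In the ME
  model the genetic half is further partitioned equally across the random
  terms (line, genomic, G×E) — the equal-split default of standard software —
  without which the prior alone props up a spurious interaction variance;
* \(\Sigma_t\), \(\Sigma_E\), \(R\): inverse-Wishart with
  \(\dim + 3\) df and scale half the diagonal phenotypic (co)variance
  (\(0.5\,I\) for the unit-scaled \(\Sigma_E\));
* MCMC defaults: 12,000 iterations, 2,000 burn-in, thinning 5 —
  configurable, and deliberately reduced in tests where only predictions
  (which mix fast) are compared.

Effective sample sizes of all scalar variance components are computed by a
Geyer initial-positive-sequence estimator on the thinned chain and reported
in every fit; a warning is raised when any falls below 100. The
\(\Sigma_E\) diagonal mixes slowest (its scale trades off against the
shared \(\Sigma_t\)), and is the component that triggers the warning first
at reduced settings.

## 4. Cross-validation

`make_folds()` draws, per cycle, an independent uniform partition into
\(k\) folds differing in size by at most one (remainder lines assigned one
per fold at random); the default regime is 10 cycles of 5-fold CV.
`build_mask()` turns folds into cell-level masking plans: **CV1** hides
every cell of a test line within the model's scope (the unphenotyped-
candidate scenario); **CV2** hides only the target-trait cells in the
target environments, keeping secondary traits and other environments
observed (the sparse-testing scenario). For a single-environment,
single-trait scope the two coincide, so SE is run under CV1 only.

Prediction ability is the Pearson correlation between predicted and
observed BLUEs of masked cells, computed per environment (and trait) per
cycle by pooling that cycle's five folds, then averaged over cycles with
the SD taken across cycle-level abilities. SDs could equally be taken
across all 50 fold-fits; cycle-level pooling is implemented because the
per-cycle correlation uses every line exactly once, making cycles the
natural exchangeable unit. Degenerate cases (constant predictions, fewer
than three scored cells) yield a missing ability with a warning rather than
a crash, and a failed fold fit is recorded as missing for its cycle without
aborting the run. `rank_models()` sorts by mean ability, breaking ties by
smaller SD then label, truncated to a Top-N table; labels follow the
`MODEL_SCHEME[_G2]` grammar (`MTME_CV2`, `ME_CV1_G2`, `SE_G2`, ...).

Leakage safety is asserted by construction in the test suite: for every
scheme × model-scope combination, the masked cells are shown to be absent
from the tensor handed to the sampler and every unmasked cell to be intact.

## 5. SREG / GGE biplots

For one trait, the line × environment BLUE table is column-centred
(removing environment main effects, leaving G+GE) and decomposed by SVD.
The variance fraction of the first two components,
\((\lambda_1^2+\lambda_2^2)/\sum_k\lambda_k^2\), measures how much of the
genotype-plus-interaction structure a two-dimensional biplot captures.
Genotype-focused scaling (singular values on genotype scores) is the
default, with symmetric scaling behind a flag; environment standardisation
is off by default. The sign of each component is fixed by making its
largest-magnitude environment loading positive.

Missing cells are completed before decomposition by iterative low-rank
(default rank 2) SVD completion initialised at column means — chosen for
coherence with the two-component biplot, since published SREG workflows
based on imputed tables rarely state their imputation algorithm. Column-mean
single-shot filling is available as a fallback. Fully missing rows or
columns are an error, named.

## 6. The synthetic world

`sim_config()` declares a generative world patterned on a Mediterranean
durum panel: 186 inbred lines; eight sowing-by-season environments (three
sowing dates across three seasons, `"<sowing>_<season>"` labels); seven
spike and phenology traits (GN, GW, NS, SL, SW, HD, PH); 2,000 biallelic
SNPs in Hardy-Weinberg proportions with allele frequencies uniform on
[0.05, 0.5]; and four target genes with 2-3 allele classes each. Effects
are drawn exactly under the MTME generative model: polygenic values
matrix-normal with row covariance the realised kernel and column covariance
\(\Sigma_t\); G×E deviations with row covariance \(\Sigma_E \otimes G\).
Plot values add environment-trait means, replication and block-within-rep
effects and residual noise.

Values the underlying study design leaves unstated were chosen once, for
realism, and are not tuned:

* per-trait entry-mean heritabilities inside the reported bands —
  GN 0.45, GW 0.42, NS 0.70, SL 0.70, SW 0.50, HD 0.90, PH 0.85;
* genetic correlations 0.6 among the five yield components (they share
  sink-source physiology), 0.2 between yield components and HD/PH, 0.3
  HD-PH; per-trait genetic SDs on the trait scale (e.g. 6 grains, 0.3 g);
* G×E variance half the main genetic variance with 0.25 correlation across
  environments;
* two replications with two incomplete blocks each, rep and block variances
  each 5% of the total genetic variance (replication counts are not given
  in the source design; these are declared defaults, overridable).

The residual variance is back-calculated from the heritability target via
\(\sigma^2_\varepsilon = r\,\sigma^2_{g,\mathrm{tot}}(1-h^2)/h^2\) on the
entry-mean basis, where \(\sigma^2_{g,\mathrm{tot}}\) is the total
per-environment genetic variance (main plus G×E) implied by the
configuration. Heritability 1 is allowed and gives exactly noise-free
genotype means — a useful degenerate test case; heritability 0 is a
configuration error.

One master seed drives everything; each stochastic stage (genotypes, gene
calls, effects, trials, folds, samplers) derives its own sub-stream, so
stages rerun reproducibly in isolation and whole studies are bit-identical
under a fixed configuration.

**What the generator does not emulate** — and hence what a green test does
not establish: linkage disequilibrium and genetic map structure, selection
history or pedigree relatedness, weather-driven environment differentiation,
spatial field trends, non-additive (dominance/epistatic) gene action, and
phenology measured in growing-degree-days. Tests against this world verify
the statistical machinery (estimation, masking, ranking, decomposition),
not the biology of any particular panel.

## 7. Numerical choices

* Kernel eigenvalues are floored at 1e-10 after validation so rotated
  precisions never overflow; \(\Sigma_E\) eigenvalues at 1e-12.
* Inverse-Wishart draws go through the Wishart of the inverted scale with
  explicit symmetrisation at every step to stop asymmetry drift across
  thousands of sweeps.
* REML fits use lme4 with singular-fit checks silenced (small blocks make
  near-zero block variance common and benign) and tightened convergence
  tolerances.
* The rowwise augmentation covariance gets a 1e-12 ridge before Cholesky.
* Ties in ranking resolve deterministically (SD, then label) so rankings
  are invariant to input order.

## 8. Known limitations

* Marker-effect models (Bayes A/B/Cπ, LASSO) and REML/EM fits of the same
  models are out of scope; the samplers are the implementation.
* The residual covariance is homogeneous across environments in MT/MTME.
* Prediction targets must be lines present in the kernel; there is no
  pedigree fallback for ungenotyped lines.
* \(\Sigma_E\) mixes slowly when the trait covariance is shared between the
  main and interaction blocks; long chains or `separate_sigma_t = TRUE`
  help when the interaction structure itself is of interest.
* The Kronecker prior-predictive check in the acceptance suite tests ~136
  covariance entries against a hard 3-Monte-Carlo-SE band; with that many
  simultaneous comparisons an occasional near-3σ excursion is expected
  under a correct sampler, so the check is sensitive to the fixed seed by
  construction.
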