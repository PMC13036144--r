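---
title: "Models and methods behind polyGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyGS implements a complete quantitative-genetics workflow for a single
continuous trait measured on a genotyped panel: heritability estimation,
mixed-model association, regional heritability mapping, and genomic
prediction, together with a simulator that generates data with exactly the
statistical structure these methods assume. This vignette records the
models, the defaults and why they were chosen, the numerical decisions,
and what the accompanying tests do and do not demonstrate.

## The mixed model and REML

Everything genetic in the package is a variance component of the linear
mixed model

$$y = Xb + \sum_i u_i + e, \qquad
  u_i \sim N(0, \sigma^2_{g_i} G_i), \qquad e \sim N(0, \sigma^2_e I),$$

with $X$ an intercept by default (covariates are opt-in; the default
analysis deliberately fits intercept-only fixed effects, since replicate
averaging happens upstream in the phenotype module). The relationship
matrices $G_i$ are VanRaden method-1 GRMs: dosages centered by twice the
in-sample allele frequency, $G = WW^\top / \sum_j 2p_j(1-p_j)$. A
GCTA-style per-marker-standardized flavor is available
(`computeGRM(..., method = "gcta")`), but VanRaden is the default because
the rrBLUP–GBLUP equivalence, which the test suite asserts to $10^{-6}$,
is cleanest under a single declared scaling shared by the kinship and
marker-effect code paths.

`fitREML()` maximizes the restricted likelihood

$$\ell_R = -\tfrac12\!\left[(n-p)\log 2\pi + \log|V| +
  \log|X^\top V^{-1}X| + y^\top P y\right]$$

by average-information (AI) updates. Numerical decisions, in order of how
often they matter:

* **Initialization.** Every component starts at
  $\widehat{\mathrm{var}}(y - X\hat b)/(k+1)$ — symmetric across
  components and scale-aware, so the fit is equivariant under rescaling of
  $y$ (asserted to $10^{-8}$ in the tests).
* **Step safeguarding.** An AI step that would leave the parameter space
  is clamped at a small floor ($10^{-6}$ of the phenotypic variance); if
  the AI system is singular the update falls back to the EM-REML step.
  Every accepted step must not decrease $\ell_R$; violations trigger
  step-halving (up to 12 halvings) — AI-REML without this safeguard
  oscillates near the zero boundary.
* **Zero boundary.** A component that finishes at the floor is reported as
  exactly zero with a `boundary` flag, and the *remaining* components are
  re-optimized in the reduced model. This makes nested-model comparisons
  exact: the full model's likelihood can never fall below the null's, so
  likelihood-ratio statistics are never spuriously negative.
* **Convergence.** Both the scaled parameter change and the
  log-likelihood change must fall below `tol` (default $10^{-6}$, at most
  100 iterations). Non-convergence is reported through a flag on the fit,
  never silently.
* **Single-component shortcut.** With one GRM the model is rotated by the
  GRM's eigenvectors so $V$ is diagonal and each iteration costs $O(n)$;
  multi-component fits (regional scans, multi-kernel RKHS) use the dense
  Cholesky path.

Standard errors come from the inverse AI matrix; the heritability
$h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$ carries a delta-method SE.
The likelihood-ratio test for a genetic component uses
$\chi^2_1$ with the statistic clamped at zero. Because the null hypothesis
sits on the boundary of the parameter space this reference distribution is
conservative; the type-I error simulation in the test suite checks the
rejection rate from above, not for equality.

## Association scan

`runMLMA()` estimates variance components once on the no-SNP null model
and then tests every SNP by generalized least squares under
$\hat V = \hat\sigma^2_g G + \hat\sigma^2_e I$ (the
population-parameters-previously-determined approximation — no per-SNP
REML, which is standard practice and orders of magnitude faster). The
tested SNP remains in the background GRM by default; a
leave-one-chromosome-out scan is available via `loco = TRUE`. Per-SNP
variance explained is defined as $r^2 = \beta^2\,\mathrm{var}(s)/
\mathrm{var}(y)$ from the mixed-model effect — the definition is a package
decision, since several conventions circulate. The genome-wide threshold
follows the $1/N$ convention (not $0.05/N$). When the genetic component
sits at the zero boundary the scan collapses exactly to ordinary least
squares, which the tests assert to $10^{-8}$.

## Regional heritability mapping

Windows are built per chromosome on the lattice $1, 1+s, 1+2s, \dots$
(width 2 Mb, step 500 kb by default; the printed boundaries of a lead
window such as `12,000,001–14,000,000` pin this start-at-1 convention).
Trailing windows are truncated at the chromosome end and kept if they hold
at least `minMarkers` markers (default 10 — windows below that are
unstable in REML; the floor is a package decision).

Each window is fitted as a three-component model: local GRM (window
markers), background GRM (all markers *except the window's chromosome*,
the LOCO strategy), and residual. The background for a chromosome and its
null fit are computed once and cached; consecutive windows warm-start from
their neighbor's estimates. The df = 1 LRT compares against the
background-only model.

Two semantics deserve emphasis:

* **The share** `VG1/(VG1+VG2)` is model-internal: it compares the focal
  window with the *rest of the genome excluding the window's chromosome*.
  Because the LOCO background omits the focal chromosome entirely, a
  window on a chromosome that carries polygenic signal will absorb part of
  that chromosome-wide signal. The correct null for the local component is
  therefore a chromosome without causal variants, and that is how the
  calibration test is constructed.
* **ΣVG1 summaries** are fractions of the summed local components over
  converged windows, ranked by VG1 (ties broken by chromosome then start).
  Overlapping windows preclude any additive decomposition of genome
  heritability, so the package never adds VG1 across windows into an
  h²-like quantity. Using converged windows only is a package decision;
  non-converged windows are flagged in the scan output rather than
  dropped, so the choice is visible.

## Genomic prediction models

All twelve models train through `trainModel()` and predict through
`predict()`:

| family | models | machinery |
|---|---|---|
| kinship REML | rrBLUP, GBLUP | REML + BLUP; rrBLUP solves the ridge system in marker space via the kinship identity, GBLUP back-solves in individual space — algebraically identical, verified to $10^{-6}$ |
| penalized | RR, LASSO, EN | glmnet coordinate descent on standardized markers; penalty chosen by inner 5-fold CV over a 50-point path; elastic-net mixing fixed at 0.5 |
| Bayesian alphabet | Bayes A, Bayes B, Bayes C, BRR, BL | compiled Gibbs samplers (Rcpp) |
| kernel | RKHS, MKRKHS | Gaussian kernel $K = \exp(-h D^2/\mathrm{median}(D^2))$; single kernel $h = 1$, multi-kernel averaging over $h \in \{0.25, 1, 4\}$ with per-kernel variance components |

Markers for penalized and Bayesian models are centered by $2p$ and scaled
by $\sqrt{2p(1-p)}$; rrBLUP/GBLUP use the kinship module's centering-only
scaling so that the equivalence identity holds exactly. A center-only
coding (`standardize = FALSE`) exists so that BRR with fixed variances can
be compared against the rrBLUP solution on the same scale — the test suite
uses it to confirm the sampler converges to the REML ridge solution
(correlation ≥ 0.995 at 30,000 iterations).

MCMC defaults are pinned rather than inherited from any package version:
12,000 iterations, 2,000 burn-in, thinning 5; scaled-inverse-chi-square
priors with 5 df whose scales split the phenotypic variance half genetic,
half residual (divided by the expected number of nonzero effects for the
spike-slab models); Bayes B inclusion probability fixed at 0.05; Bayes C
inclusion estimated under a Beta(1, 9) prior; Bayesian-LASSO rate
parameter $\lambda^2 \sim$ Gamma(1, 0.1). Reproducibility is bitwise under
a fixed seed because the samplers draw from R's RNG. Each fit records the
effective sample size of the residual-variance chain as a convergence
diagnostic. The RKHS bandwidths are package decisions (they are rarely
reported in applied work); `h` and the bandwidth grid are exposed in the
training config.

Off-the-shelf machine learners (SVM, random forests, boosting, neural
networks) are deliberately outside the model set: they are generic
regressors, not genetic models, and on dense polygenic architectures they
are dominated by rrBLUP-type shrinkage.

## Cross-validation and external validation

`kfoldCV()` draws one seeded partition with fold sizes differing by at
most one (436 individuals and k = 5 give 88/87/87/87/87) and shares it
across all models. Accuracy is the Pearson correlation between predicted
GEBVs and observed phenotypes. Because "accuracy across folds" is
ambiguous, the report carries both the pooled correlation over
concatenated out-of-fold predictions (the headline, stable under a single
partition) and the per-fold mean ± sd. Folds with constant predictions —
which genuinely happen when the genetic component hits the zero boundary
on a training split — yield a missing per-fold r with a warning while the
pooled r is still computed. `externalValidate()` applies a fitted model to
an independent panel and refuses correlations on fewer than three
samples. `benchmarkModels()` resamples individuals with replacement to
larger population sizes and records wall time and memory; these numbers
are informational only and are never asserted, being hardware-dependent.

## The simulator: what it emulates, and what it does not

`simulateGenotypes()` uses a founder-haplotype mosaic: per chromosome, a
small founder set with allele frequencies from a Beta(0.5, 0.5) spectrum
truncated at the MAF floor, and per-gamete crossovers at a Poisson rate.
This produces block-wise LD, a realistic U-shaped frequency spectrum, and
pedigree-like relatedness — the three features the GRM-based methods
actually consume — while remaining seedable and fast. It is *not* a
coalescent: it has no mutation/drift equilibrium, no population splits (a
single exchangeable population; GRM-PCA on it shows no structure), and no
selection, dominance or epistasis.

Defaults describe a desk-scale diversity panel of a narrow-base selfing
crop: 436 individuals, 24 chromosomes of 60 Mb, ~210 markers per
chromosome at a MAF floor of 0.03, 10 founder haplotypes, and 15
crossovers per chromosome per gamete (haplotype blocks of roughly 4 Mb).
The founder count and crossover rate were calibrated once so that the
panel's information content for heritability matches published precision
for such panels — the model-based SE of ĥ² at n = 500 is about 0.10 — and
are not revisited; cultivated tobacco, the motivating crop, is famously
narrow-based. Markers whose realized MAF falls below the floor are
dropped, so the floor holds exactly in every output panel.

`simulateTrait()` is strictly additive: QTLs sampled uniformly among
markers, Normal effects, jointly rescaled so the realized genetic variance
hits the target $h^2$ within the finite-sample draw. The total phenotypic
variance is a config field (default 64, i.e. an sd of 8 mg/cigarette on
the tar scale, consistent with a trait ranging over roughly 8–60
mg/cigarette around a mean near 30); it exists so that the degenerate
$h^2 = 0$ case is well defined. With a focal window, effects are rescaled
so the frequency-weighted variance contribution of focal-window QTLs
equals `focalFraction` *exactly* (the tests assert this to $10^{-10}$),
and at least one QTL is guaranteed inside the window.
`degradeGenotypes()` adds compound site/individual missingness and
Gamma-distributed per-site depths for exercising the QC filters.

Consequently, passing tests demonstrate correctness of the estimators and
algorithms *under the additive, single-population model* — they say
nothing about robustness to population structure, genotype-by-environment
interaction, non-additive architecture, or imputation error on real GBS
data.

## QC and data-handling decisions

* Filter boundaries are read literally: depth strictly greater than 2,
  MAF strictly above 0.03, missingness removed at ≥ 0.5. Removed markers
  are attributed to the first failing rule in the fixed order depth → MAF
  → site missingness, then individuals are removed; because sample removal
  changes per-marker statistics, the rules iterate to a fixed point, which
  makes filtering idempotent (asserted on degraded panels).
* When no depth metadata exists (plain GT-only VCF), the depth rule is
  skipped with a warning rather than silently passing everything.
* MAF is computed from non-missing calls before imputation; imputation is
  a deliberately simple per-site mean (fractional dosages allowed
  downstream) or mode (ties toward the smaller dosage); haplotype-aware
  imputation is out of scope.
* Coordinates are 1-based inclusive everywhere (VCF convention). Genotype
  concordance compares jointly non-missing cells matched by id and
  position.
* Phenotype/genotype joining is by exact sample id, with unmatched ids
  reported, never dropped silently. Replicate averaging is the plain
  arithmetic mean; no block/replicate adjustment is applied before
  genetic analysis (a documented default, since designs vary).

## Problem sizes in the test suite

The statistical tests run at sizes chosen to finish in minutes while
keeping each property identifiable: parameter recovery at n = 400–500 with
1,200–5,000 markers; the REML grid oracle at n ≤ 60 against an 11 × 11
grid evaluated by an independently coded likelihood; regional-enrichment
recovery at n = 400 with two 12-Mb chromosomes of 1,000 markers; MLMA
calibration at n = 300 with 2,000 markers over 20 seeds; model ordering at
n = 436 with 2,000 markers over 20 seeds. Where a property is stochastic
the acceptance thresholds allow the binomial slack stated alongside each
test.

## Known limitations

* Single trait, single environment; no multi-trait or GxE modeling.
* GRM-structured random effects only; no pedigree, dominance or epistatic
  kinships.
* The regional scan reports raw p-values plus a Bonferroni-by-window-count
  reference; sliding windows overlap, so these p-values are correlated and
  any genome-wide regional threshold is approximate.
* Mean/mode imputation understates genotype uncertainty relative to
  haplotype-based methods; concordance checking exists precisely to
  quantify call-set quality before relying on it.
* The Bayesian samplers use single-chain posterior means; no formal
  multi-chain convergence diagnostics beyond the residual-variance ESS.
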