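---
title: "Reaction-norm kernel models for multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm kernel models for multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant breeding programs evaluate hundreds of candidate lines in a handful of
field sites. Genotype-by-environment interaction (G×E) changes line rankings
from site to site, and most lines are observed in few plots or none at all in
a given site. `metGP` implements the kernel ("reaction-norm") approach to
this setting: every source of resemblance between plot records — shared site,
shared environmental conditions, marker similarity, pedigree relatedness, and
their interactions — enters as a covariance structure, and prediction for
unobserved line-site combinations flows through those covariances.

## The model

A plot record $y_{ijk}$ (line $j$, site $i$, replicate $k$) is modelled as

$$y_{ijk} = \mu + E_i + w_{ij} + g_j + a_j + gE_{ij} + aE_{ij} +
\varepsilon_{ijk},$$

where each term is a zero-mean Gaussian vector with its own variance
component and kernel:

* $E_i$: IID site main effects (site-indicator kernel);
* $w_{ij}$: a random regression on $Q$ site-level environmental covariables
  with IID coefficients, equivalent to a site kernel
  $\Omega = W_sW_s'/Q$ built from the (standardized) covariable table —
  sites with similar climate get similar effects;
* $g_j = \sum_m x_{jm}b_m$: genomic values with IID marker effects,
  equivalent to the genomic relationship kernel $G = X_cX_c'/p$
  ($X_c$ column-centered codes, $p$ markers);
* $a_j$: pedigree additive effects with the numerator relationship matrix
  $A$ (recursive tabular method);
* $gE_{ij}$, $aE_{ij}$: interactions whose observation-level covariance is
  the Hadamard (cell-by-cell) product of the expanded genetic kernel and the
  site-indicator structure — genetic covariance applies within a site,
  nothing is shared across sites;
* $\varepsilon$: IID plot error.

Eight named sub-models are supported (`rnm_models()`), from the `E+L`
baseline (IID line effects, no markers) through the full
`E+W+G+A+GE+AE`. A model with an IID line term `L` but no `G`/`A` cannot
say anything about lines never observed anywhere — that is the point of
including it as a negative control.

## Fitting: Gibbs sampling in the kernel factor basis

Each term $u_t \sim N(0, \sigma^2_t K_t)$ is reparameterized through a
factorization $K_t = \Phi_t\Phi_t'$ with coordinates
$b_t \sim N(0, \sigma^2_t I)$. For the structured kernels the factors are
assembled directly from level-wise eigendecompositions (site-level for
$\Omega$, line-level for $G$ and $A$, site-blocked for the interactions), so
no observation-level eigendecomposition is needed and held-out records
simply have their rows of $\Phi_t$ excluded from the likelihood. The sampler
(C++ core) is:

* conjugate single-site normal updates for each coordinate of each $b_t$;
* a flat-prior update for $\mu$;
* scaled-inverse-$\chi^2$ updates for every variance component;
* one generalized-Gibbs *scale move* per term and iteration, which proposes
  $(b_t, \sigma^2_t) \to (\alpha b_t, \alpha^2\sigma^2_t)$ with $\alpha$
  drawn by slice sampling from the exact invariant density. Single-site
  updates mix very slowly along this scale direction when many coordinates
  sit in low-eigenvalue directions (always the case for marker kernels);
  the move restores useful effective sample sizes (in internal checks,
  roughly two orders of magnitude for the genomic variance).

Posterior summaries are accumulated from post-burn-in thinned draws. Fitted
and predicted values reconstruct exactly as $\hat\mu + \sum_t \bar u_t$.
Coordinates with zero training-row support are dropped: they are
data-independent, and their posterior-mean contribution to predictions is
exactly zero. One visible consequence: for a fully held-out site the
interaction terms contribute *exactly* zero to its predictions —
leave-one-site-out information flows only through $W$, $g$ and $a$, which is
the scientific content of predicting untested environments.

### Priors and defaults

Every variance has a scaled-inverse-$\chi^2$ prior with `df = 5` and scale
set so the prior mode equals the phenotypic variance times an $R^2$ share:
0.5 for the residual, the rest split equally among terms. We deliberately do
*not* rescale prior modes by mean kernel diagonals: with presence/absence
marker coding the genomic kernel diagonal is far below 1 and the rescaled
prior (a common default elsewhere) inflates weakly identified interaction
variances by a factor of about two in our recovery checks (verified against
an exact eigenbasis ML oracle).

MCMC defaults are 12,000 iterations, 2,000 burn-in, thinning 5 — ample for
the posterior means used here at the scales this package targets
(hundreds of lines, a handful of sites). The examples and tests use shorter
chains where the quantity examined is insensitive to chain length.
Eigenvalues below $10^{-10}\lambda_{max}$ are truncated (presence/absence
coded G is rank-deficient); kernels must satisfy
$\lambda_{min} \ge -10^{-8}\lambda_{max}$.

In the prediction models $\mu$ is the only fixed effect and sites are
random; the stage-one combined phenotypic analysis instead treats sites as
fixed (see below), matching the usual two-stage practice.

## Stage-one phenotypic analysis

`fit_single_site()` fits, per site, a REML mixed model (via `lme4`) with
random accessions and blocks and a fixed entry-group separating the repeated
checks from accessions. Broad-sense line-mean heritability uses the p-rep
aware effective replication: $H^2 = \sigma^2_L/(\sigma^2_L +
\sigma^2_\varepsilon/\bar r)$ with $\bar r$ the mean replication of
accessions.

`fit_factor_analytic()` models genotype-within-site effects with covariance
$(\Lambda\Lambda' + \Psi)\otimes G$: a two-factor loading matrix plus
site-specific variances, with genetic relationship $G$ between lines. It
works on line-by-site cell means with site means fixed (removed) and the
cell-mean residual variance plugged in from within-cell replicate variance —
EM then estimates only the genetic parameters. Transforming to the
eigenbasis of $G$ makes lines independent with a line-specific scale, so the
E- and M-steps are exact closed forms and the log-likelihood is
non-decreasing (asserted). Between-site genetic correlations come from
$\Sigma = \Lambda\Lambda' + \Psi$; biplot coordinates use the principal-axis
rotation of $\Lambda$ (singular value orientation), the standard FA biplot —
the cosine between site vectors approximates their genetic correlation and
vector length tracks the site's genetic variance, i.e. its power to
discriminate genotypes.

Design choices worth noting, where the design was genuinely open:

* *Estimation algorithm for the FA model*: EM with fixed plug-in residual
  variances rather than a full joint REML — it is exactly monotone, has no
  tuning constants, and the plug-in matches how two-stage MET analyses are
  run in practice.
* *Biplot rotation*: principal axes; any rotation gives the same $\Sigma$,
  so this is presentation only.
* *Pairwise option*: between-site correlations can also be read from
  two-site fits; the FA fit is the default because it borrows strength
  across all sites at once.

## The four prediction problems

`make_cv_plan()` + `run_scheme()` implement:

* **CV1** — 80/20 at the line level: all records of a test line are masked
  everywhere (can a never-tested line be predicted?);
* **CV2** — 80/20 at the plot level: lines are typically observed in some
  sites and masked in others (sparse testing);
* **pairwise** — train on exactly one site's records, predict another site;
* **leave-one-site-out** — mask one entire site; its covariable row stays
  in $W$, so prediction uses only climate similarity plus genetics.

Checks never enter test sets and are excluded from accuracy computation:
they are design infrastructure, estimated separately. Accuracy is the
per-site Pearson correlation between observed and predicted test values,
computed on raw plot records by default (`observed = "line_mean"` averages
replicates first); sites with fewer than three test records report `NA`
rather than a fabricated value. A correlation is also `NA` when the
predictions are constant — notably under CV1 for models without `G` or
`A`, whose posterior-mean prediction for every untested line in a site is
identical; scientifically that is zero ranking ability, and comparisons in
the acceptance checks treat it as such. CV replicates default to 50 random
partitions; single-pass schemes (pairwise, leave-one-site-out) report no SD.

## The synthetic trial generator

`simulate_met()` emulates the multi-environment trial the models assume:

* a crossing pedigree whose most recent individuals are the trial lines;
* a marker panel *gene-dropped along that pedigree*: founders draw alleles
  with uniform frequencies and descendants inherit them, so relatives share
  marker codes and the genomic kernel carries family information to
  untested lines — without this, CV1 accuracy would be zero by construction
  for any marker model, since unrelated lines are unpredictable.
  Presence/absence coding by default (a DArTseq-like panel; dosage
  available), monomorphic columns redropped
  (`simulate_markers()` also provides an independent-lines panel for
  kernel-level testing);
* five temperature-like site covariables (means drawn in 8–30 °C,
  3 °C between-site spread);
* a p-rep augmented design — 81% of accessions once, 15% twice, 4% three
  times per site, with 3 checks in every block filling about 6% of plots;
* phenotypes from the full generative model above, with all realized
  effects, marker effects and variance components recorded as ground truth.

Default variance components (`E = 2, w = 0.5, g = 0.8, a = 0.4, gE = 0.45,
aE = 0.2, eps = 1` on a grain-yield scale with mean 6 t/ha) put the
between-site genetic correlation $(\sigma^2_g + \sigma^2_a)/
(\sigma^2_g + \sigma^2_a + \sigma^2_{gE} + \sigma^2_{aE})$ near 0.65,
typical of yield trials across heterogeneous temperate sites; heritability
per plot is moderate. Tests that require highly correlated sites (the
scheme-ordering properties assume genetic correlation $\ge 0.8$) raise
$\sigma^2_g$ relative to $\sigma^2_{gE}$ explicitly.

What the generator does *not* emulate: spatial field trend, sequencing-read
noise or marker-calling artifacts, missing line-site cells, multi-trait
correlation. Passing recovery tests therefore demonstrate correctness of
the estimation machinery under the model's own assumptions, not robustness
to real-data pathologies.

## Numerical and scale choices

Kernels are dense observation-level matrices; memory is
$O(n_{obs}^2)$ per kernel, fine for a few thousand plots. Tests and
examples run at reduced scale (≤ 300 lines, ≤ 1000 markers; the full-model
recovery study uses 300 lines × 5 sites ≈ 1900 plots with ten effect
redraws on a fixed trial frame, which keeps kernel construction out of the
loop), while the generator defaults reproduce the 803-line, 5-site scale.
The acceptance script runs a three-redraw version of the same study.

## Known limitations

* With five sites, the site-level variance split ($\sigma^2_E$ versus
  $\sigma^2_w$) is informed by only five realized site deviations whose two
  covariance structures overlap heavily; individual recovery of these two
  components is noisy *for any estimator* (the sampling CV of a variance
  estimated from five effects exceeds 60% even with the effects known), and
  only their sum is well determined. Line-level components do not suffer
  from this.
* The FA fit requires complete line-by-site cell coverage (p-rep designs
  provide it); incomplete METs would need an EM extension over missing
  cells.
* Prediction into a site with covariables far outside the training range
  extrapolates the linear covariable regression; accuracy claims only hold
  for interpolation-like settings, as in the leave-one-site-out checks.
* Checks are modelled as fixed entries and carry no genomic information;
  trials whose checks are genotyped would warrant including them in $G$.

## A worked example

```{r, eval = FALSE}
library(metGP)
met <- simulate_met(sim_config(n_lines = 150, n_markers = 400, n_sites = 5,
                               seed = 42))
## stage one
ss <- fit_all_sites(met$pheno)
fa <- fit_factor_analytic(met$pheno, genomic_relationship(met$markers))
genetic_correlations(fa)
plot(fa)

## prediction: untested lines under the genomic model
plan <- make_cv_plan("CV1", met$pheno, n_replicates = 10, seed = 1)
rep_g <- run_scheme("E+W+G", met, plan,
                    control = mcmc_control(n_iter = 3000, burn_in = 500,
                                           seed = 2))
summarize_reports(rep_g)$long
```
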