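---
title: "Cladal differential abundance: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cladal differential abundance: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Genus- or family-level tests of microbiome composition presume that the
named rank is the unit at which bacteria share the trait under study. When
the trait evolved at some other depth of the phylogeny — a subgenus clade,
or a clade spanning several genera — phylotype tests dilute or miss it.
The cladal approach instead tests *every* monophyletic clade: for a rooted
ASV phylogeny, each internal node defines a clade whose abundance in a
sample is the sum of its descendant tips' counts. A fully bifurcating
rooted tree over $n$ ASVs yields $n-1$ such clades (the root included, the
tips themselves not: tip abundances are already rows of the ASV table).
`build_clade_matrix()` materialises the matrix $ctu$ with
$ctu_{ij} = \sum_{t \in \mathrm{tips}(j)} y_{it}$, which satisfies two
exact invariants used throughout the tests: the root column equals the
sample totals, and every parent equals the sum of its children.

Clade abundances are counts, so each clade is modelled with a negative
binomial regression with log link and variance $\mu + \mu^2/\theta$
($\theta > 0$ the dispersion; $\theta \to \infty$ recovers the Poisson).
Three batteries mirror the study questions on rarefied clade counts:

* **Age** (weeks 0 and 6, all samples): $\log \mu = \beta_0 + \beta_1\,
  \mathrm{age}$, age coded young = 0 / old = 1. A plain GLM.
* **Diet** (weeks 0 and 6): $\log \mu = \beta_0 + \beta_1\,\mathrm{diet} +
  b_{\mathrm{host}}$, diet coded control (ZA) = 0 / zinc-modified = 1,
  $b_{\mathrm{host}} \sim N(0, \sigma_b^2)$, fitted separately within each
  of the four age-by-study families (young/old × supplementation ZAM1 with
  ZA vs ZS / deficiency ZAM2 with ZA vs ZD) so age and study are controlled
  by design; the random intercept absorbs repeated measures from the same
  mouse.
* **IL-6** (week 6 only, per age group): $\log \mu = \beta_0 + \beta_1\,
  \mathrm{IL6}$ with LPS-induced whole-blood IL-6 in pg/ml.

Each battery Wald-tests its single slope ($z = \hat\beta_1 / \mathrm{SE}$,
two-sided normal reference), adjusts p-values with the Benjamini–Hochberg
step-up across the clades of the battery family (age: one family; diet:
four; IL-6: two — the family is the unit at which BH's guarantee holds),
and then removes from the significant set any clade whose fitted intercept
is negative: count models are bounded below by zero, and a negative
predicted baseline on rarefied counts of this depth indicates a spurious
fit dominated by near-absent samples. The exclusion happens *after* BH, so
it removes clades from the reported set without altering the adjusted
p-values of the rest.

## Fitting machinery

`nb_fit()` is a classic formula-interface model function. The fixed-effects
path alternates iteratively reweighted least squares for $\beta$ at fixed
$\theta$ (working weights $w_i = \mu_i/(1+\mu_i/\theta)$) with a
maximum-likelihood update of $\theta$ by golden-section search on
$\log\theta$, until the relative log-likelihood change falls below the
tolerance (default `1e-6`, maximum 200 iterations). Standard errors come
from the Fisher information $X^\top W X$ at the optimum, the convention of
standard NB GLM implementations. $\theta$ is bounded in $[10^{-3}, 10^6]$
with a boundary flag, which stabilises near-Poisson and extremely
overdispersed clades.

The mixed-model path maximises the *marginal* likelihood: the host random
intercept is integrated out by adaptive Gauss–Hermite quadrature (default 7
points; 1 point gives the Laplace approximation). Per host, an inner Newton
search finds the conditional mode of $b$; quadrature nodes are centred and
scaled there. Nodes and weights come from the Golub–Welsch eigenvalue
construction. The optimizer works on $(\beta, \log\theta, \sigma)$ with
$\sigma$ entering only through $\sigma^2$, so the likelihood is even in
$\sigma$ and the no-random-effect fit $\sigma = 0$ is an interior
stationary point evaluated exactly (the NB GLM likelihood) rather than a
boundary approached asymptotically in log scale — this matters both for
correctness (the spec of a "boundary" fit is $\sigma_b = 0$ with a flag)
and for speed on data without host structure. Standard errors come from
the numerically differentiated observed information of the marginal
likelihood; when the variance components flatten the full Hessian (boundary
fits), the $\beta$ block is inverted alone. Fits with one observation per
group are flagged `boundary` ($\sigma_b$ unidentifiable) and reduce to the
GLM in their slope, a property the tests assert.

Degenerate clades — all zero, or nonzero in fewer than 3 samples of a
family subset — are reported with `excluded_reason = "degenerate"` and not
fitted: unidentifiable fits would pollute the BH family.

## Preprocessing choices

* **Prevalence filter**: features present (count > 0) in at least 5 samples
  are retained — five being half an experimental unit of 10 animals, so a
  taxon must appear in at least half a group to be analysable.
  Filtering precedes rarefaction and tree pruning.
* **Rarefaction** equalises sequencing effort instead of model offsets (the
  batteries deliberately carry no library-size term). Each sample is
  subsampled without replacement to a common depth — by default the minimum
  retained sample total, since no single canonical depth exists — via
  sequential multivariate-hypergeometric draws (`rhyper` per feature),
  which is the exact subsampling distribution and avoids materialising
  130 000-read vectors; the suite cross-checks it distributionally against
  `vegan::rrarefy`. The seed is mandatory and recorded in the run manifest.
* **Midpoint rooting** places the root halfway along the longest tip-to-tip
  path. Ties between equally long paths are broken by the lexicographically
  smallest endpoint pair, so rooting is reproducible across file orderings;
  when the midpoint coincides with an existing node the tree is rooted
  there without inserting a zero-length edge. Pairwise tip distances are
  preserved exactly (tested to 1e-9 on random trees).
* **Placeholder genera**: ASVs with no genus assignment become
  `<Family>_Genus_<ASV>`, i.e. each unassigned ASV is its own genus —
  balancing over-grouping at the family level against discarding data.
* **Genus screens** run on relative abundances of the rarefied,
  genus-agglomerated table (genus-level results are reported as relative
  abundances), with the age screen using all week 0 + week 6 samples and
  the diet (Kruskal–Wallis, age-stratified) screen restricted to week 6,
  when dietary effects have had time to develop. `wilcoxon_screen()` and
  `kruskal_screen()` accept any samples × taxa matrix, so callers preferring
  rarefied absolute counts can pass those instead.
* **Clade identifiers** are content hashes of the sorted member tip labels,
  so a clade keeps its id across reruns, tree file orderings and prunings
  that do not touch its members.

## What the generator emulates — and what it does not

`simulation_design()` encodes the study: 2 studies × 2 ages × 2 diets × 10
mice = 80 hosts, two fecal samples each (weeks 0 and 6, 160 samples), 361
ASVs, NB counts with $\theta = 2$, lognormal baseline abundances spanning
roughly four orders of magnitude (a few taxa dominating the community, as
in real gut data), lognormal library sizes around 130 000 reads (sdlog
0.3), and a host random intercept $b_h \sim N(0, 0.5^2)$ shared by a
host's two samples. IL-6 is generated at week 6 as baseline 60 pg/ml +
40 for old age + 30 for zinc deficiency + $N(0, 20^2)$ noise, truncated at
zero — values not printed in the source material, chosen once to give the
covariate a realistic dynamic range (~40–150 pg/ml) with clear age and
deficiency separation.

Two deliberate properties of the generator deserve emphasis:

* The host intercept multiplies *all* taxa of a host equally. It is a
  host-level load/yield effect: it induces within-host correlation of raw
  counts (asserted by a test) and is removed by rarefaction, exactly as
  library-size variation is. The generator therefore does *not* emulate
  persistent taxon-specific host colonization differences; on simulated
  data the diet GLMM's $\hat\sigma_b$ is typically near zero. The GLMM
  machinery itself is exercised by dedicated tests that simulate host
  effects at the observation level ($\sigma_b$ up to 1.0). On real data,
  where taxon-specific host effects are ubiquitous, the plain age GLM —
  which, following the source analysis, ignores the pairing of a host's
  two samples — is anticonservative; the diet battery's random intercept
  is the model that addresses this, and results from the age battery
  should be read with that caveat.
* Planted effects multiply the member tips of a clade (not the clade sum),
  so the hierarchical consistency of $ctu$ holds by construction, and an
  effect on a clade is genuinely inherited by every enclosing clade.
  Planted clades are chosen with 2–8 tips, pairwise disjoint tip sets, and
  baseline relative abundance in $[10^{-3}, 3\times10^{-3}]$ with no member
  rarer than $10^{-5}$. The window has a purpose at both ends: the lower
  bound keeps planted clades well above the detection floor at realistic
  depth (so sensitivity measures the inference, not the sequencing), and
  the upper bound keeps the spike-ins' total compositional footprint small.
  Rarefied counts are compositional: inflating planted clades by
  $e^{1.5}$ necessarily deflates everything else, and with an unbounded
  footprint that closure effect is itself detectable, making "false
  discovery" ill-defined. Bounding the footprint — the usual convention in
  differential-abundance spike-in benchmarks — keeps the closure shift an
  order of magnitude below the detectable effect size. For the continuous
  IL-6 covariate the planted log fold change is defined across ±1 SD of
  the week-6 IL-6 distribution (per-sample shift $\mathrm{logFC}\cdot z/2$),
  which bounds the most extreme per-sample multiplier; effects apply only
  where IL-6 is observed (week 6). Diet effects apply to treated hosts at
  both timepoints, matching the fitted GLMM, which has no time term;
  pre-treatment equivalence at week 0 is thus not emulated.

Recovery is scored against the truth table at the pipeline level:
sensitivity is the fraction of planted (clade, battery) pairs detected by
their own battery (diet effects in their planted family), and a discovery
counts as false only when its tip set is disjoint from every planted
clade's — lineages containing a planted clade are genuinely differential,
and the design's covariates (age, diet, IL-6) are correlated on purpose,
so cross-battery hits on planted lineages are not errors.

## Problem sizes used by the test suite

The suite's Monte-Carlo blocks run at the design's own scale where that is
what is being claimed, and at reduced scale where only calibration is being
measured: clade-matrix/oracle equivalence on 100 random instances (≤ 50
tips, ≤ 20 samples); NB-GLM vs direct-likelihood oracle on 50 datasets of
n = 100–500; GLMM reduction and bias on 100 + 300 replicates of 40 hosts ×
2 observations; null end-to-end error control on 200 replicates of a
61-tip (60-clade) community with the full 80-host design; planted-effect
recovery on 50 replicates at the full 361-tip design. Those sizes give
Monte-Carlo standard errors a few times smaller than the margins asserted.

## Known limitations

* Wald tests with estimated $\theta$ are mildly anticonservative at small
  n (measured ~0.2% tail mass at the nominal 0.1% for n = 40); the spec'd
  inferential framework is the Wald/BH one, so no small-sample correction
  is applied.
* The age GLM ignores repeated measures (see above); on data with
  taxon-specific host effects its FDR is not controlled. This mirrors the
  modelling choice of the analysis the package reimplements.
* Nested clades are highly correlated tests; BH remains valid under this
  positive dependence but the effective number of independent tests is
  well below the clade count.
* The clade permutation-conservation test of the original cladal framework
  is out of scope; so are ordination, PERMANOVA and plotting.
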