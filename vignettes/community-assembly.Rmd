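---
title: "Inferring community assembly from phylogenetic signal and co-occurrence"
author: "commassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly from phylogenetic signal and co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commassembly)
```

## The scientific question

Microbial community composition can shift under a treatment gradient (for
example, decades of different fertilization regimes in an arable soil)
without revealing *why* it shifted. Community phylogenetics offers a way
in: if environmental preferences are phylogenetically conserved — close
relatives prefer similar conditions — then the phylogenetic structure of
who co-occurs with whom carries a signature of the assembly process.

* **Environmental filtering** admits only taxa whose niche fits the local
  environment; with conserved niches the survivors are close relatives, so
  communities are phylogenetically *clustered*.
* **Competitive exclusion** removes ecologically (hence phylogenetically)
  similar taxa, producing *overdispersion*.
* **Neutral (stochastic) assembly** produces communities whose phylogenetic
  structure is indistinguishable from random draws out of the species pool.

This package implements that inference chain end to end — phylogenetic
signal testing, α/β mean pairwise phylogenetic distance with null models,
SparCC co-occurrence networks, C-score non-randomness, network topology,
and the surrounding group statistics — together with a synthetic-study
generator whose assembly process is known, so every inferential step can be
validated against ground truth.

## The model and its statistics

### αMPD and the nearest relative index (NRI)

For a community $k$ with relative abundances $f_{ik}$ over the taxa present
and patristic distances $\Delta_{ij}$ (sum of branch lengths on the
tip-to-tip path),

$$\alpha\mathrm{MPD}_k \;=\; \sum_{i} f_{ik}\,
  \operatorname{mean}_{j \ne i}\big(\Delta_{ij}\big),$$

the abundance of each focal taxon weighting the *unweighted* mean distance
to its co-occurring partners. This focal-weighted form is the package
default; the fully pairwise-weighted variant
($\sum_{ij} f_i f_j \Delta_{ij} / \sum_{ij} f_i f_j$) is available via
`pairwise_weighted = TRUE` for sensitivity analysis.

The observed αMPD is standardized against a **phylogeny-pool null model**:
each randomization redraws the community's richness-many taxa uniformly
from all tips of the phylogeny and reassigns the observed abundance
multiset to them. With null mean $\mu_0$ and sample standard deviation
$\sigma_0$ over the randomizations (1,000 by default),

$$\mathrm{SES} = \frac{\alpha\mathrm{MPD}_{obs} - \mu_0}{\sigma_0},
\qquad \mathrm{NRI} = -\mathrm{SES}.$$

NRI $> +2$ is read as phylogenetic clustering (environmental filtering),
NRI $< -2$ as overdispersion (competitive exclusion), and the band between
as stochastic assembly — a two-standard-deviation decision rule.

### βMPD and βNRI

Between two communities $k$ and $l$,

$$\beta\mathrm{MPD}_{kl} = \sum_i \sum_j f_{ik}\, f_{jl}\, \Delta_{ij},$$

the fully abundance-weighted mean distance over cross-community taxon
pairs (shared taxa contribute $\Delta = 0$). The null applies the
phylogeny-pool randomization to both communities independently in each
draw, and $\beta\mathrm{NRI} =
(\beta\mathrm{MPD}_{obs} - \mu_0)/\sigma_0$. Values below $-2$ indicate
less-than-expected phylogenetic turnover (*homogeneous selection*: both
communities filtered toward the same optimum), values above $+2$
greater-than-expected turnover (*variable selection*). Because only the α
null is named by the standard toolkits, extending the phylogeny-pool
randomization to β is an explicit assumption of this package, recorded
here.

### Phylogenetic signal: the Mantel correlogram

The inference above is only valid if niches are conserved. The package
tests this the way the field does: each OTU's **environmental optimum** is
its abundance-weighted mean environment,
$o_i = \sum_k f'_{ik}\, \mathrm{env}_k$ (abundances normalized over
samples), and `mantel_correlogram()` partitions patristic distances into
equal-width classes (100 by default) and tests, per class, the Mantel
correlation between class membership and optimum distances with
permutations (999 by default) and progressive Holm correction. Positive,
significant correlation in the small-distance classes is the conservatism
signature. The computation is delegated to `vegan::mantel.correlog`, the
reference implementation.

### SparCC co-occurrence networks

Counts from amplicon sequencing are compositional: closure alone induces
spurious negative correlation of order $-1/(p-1)$ among $p$ taxa. SparCC
estimates the correlations of the unobserved *basis* abundances from
log-ratio variances $t_{ij} = \mathrm{Var}\log(x_i/x_j)$ under a sparsity
assumption: solving $(\mathbf{A} + \mathrm{diag}(\text{rowSums}\mathbf{A}))
\,\boldsymbol\omega^2 = \mathbf{t}$ for the basis variances and deriving
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$.
Each estimate uses Dirichlet-smoothed fractions (counts + 1); the most
strongly correlated pair is iteratively excluded from the system (up to 10
rounds while any $|\rho|$ exceeds 0.1, the original tool's convention),
and the element-wise median over 20 resampling iterations is reported.
Significance comes from permutations that shuffle each OTU's counts across
samples independently; the two-sided pseudo-p is
$(1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(n_{perm}+1)$.

Networks connect pairs with $|\rho| > 0.85$ **and** $p < 0.01$ (both
strict), and `topology_metrics()` reports the standard panel: node/edge
counts by sign, average degree, mean local clustering (0 for degree-<2
nodes), path length and diameter over connected pairs only, Louvain
modularity (best of 10 seeded restarts, resolution 1), module and
component counts, and the cumulative degree distribution. Modularity above
0.4 is annotated as module-structured, the conventional threshold.

### C-score

Co-occurrence non-randomness is measured by the mean checkerboard score
$CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ over taxon pairs, tested against
fixed-fixed null matrices from the sequential checkerboard-swap algorithm
(burn-in $10\times$ fill, thinning $=$ fill), generated by vegan's `swap`
null model.

## The synthetic-study generator

`make_study()` emulates a 7-treatment × 4-replicate field trial (28
samples): a 500-tip Yule phylogeny, Brownian-motion environmental optima
(standardized to unit variance, so niche breadths are in trait-sd units),
Gaussian environmental filtering with a *graded* niche breadth across
treatments (0.15 for NK up to 0.70 for PK — the regime ordering reported
for P-deficient vs P-amended soils), symmetric Dirichlet(1) relative
abundances for the selected taxa, and multinomial counts at depth 10,000
so rarefaction to the conventional 7,000 is non-trivial. Covariates carry
stated monotone links to niche breadth plus Gaussian noise (AP rising with
breadth; yield peaking at intermediate breadth; pH, SOC, TN, Ivt, MC with
weaker links; AK pure noise), and the full per-sample ground truth is
serialized beside the data.

### Why the environment is placed, not fixed

A subtlety discovered while validating the generator: filtering around the
*ancestral* trait value does not produce phylogenetic clustering. Under
Brownian motion the taxa whose optima sit near the root value occur in
every clade — the filtered set is trait-coherent but phylogenetically
scattered, and NRI stays near zero. Clustering requires the filter to
target a *derived* trait syndrome carried by a coherent clade, which is
exactly the niche-conservatism premise of the whole inference chain.
`place_environment()` therefore scans candidate environment values over
the quantiles of the tip optima and selects the one whose Gaussian filter
weights minimize the weighted expected pairwise patristic distance,
subject to the filter retaining an effective pool of at least 30 taxa
(so communities of the default richness 75 are not forced to dilute
beyond the guild). With this construction the recovery properties hold
across arbitrary tree realizations rather than only on favourable ones;
the placed value is recorded in the study's ground truth.

### What the generator does and does not emulate

It emulates: phylogenetically conserved optima, filtering of graded
strength with replicates, compositional counts with known basis
correlation structure (`generate_correlated_counts()` exposes its latent
log-basis draws so ground truth can be checked free of closure bias), and
covariates with known links. It does **not** emulate sequence-level
artifacts (PCR bias, chimeras), taxon-specific abundance distributions,
spatial blocking, or temporal dynamics — so passing tests demonstrate
correctness of the inference chain under its own assumptions, not
robustness to upstream bioinformatic noise.

## Numerical and design choices

* **Null sd** uses the sample standard deviation (n−1), the SES convention
  of the standard community-phylogenetics toolkit; NRI $= -$SES exactly.
* **Singleton communities** have undefined αMPD; they propagate as flagged
  `NA` records, never silent zeros. Degenerate nulls (sd = 0) flag the SES
  rather than dividing by zero.
* **Rank p-values** are two-sided, $\min\!\big(1, 2(\min(n_{\ge}, n_{\le})
  + 1)/(n+1)\big)$, so they live in $(0, 1]$.
* **Rarefaction** subsamples without replacement (hypergeometric); samples
  under depth raise an error naming them. Top-k dominance is summed raw
  count with lexicographic tie-breaks, making the selection deterministic.
* **Table orientation** is declared by a flag, never guessed: silent
  transposition is the classic OTU-table bug.
* **Tukey letters** use the insert-absorb algorithm on the Tukey-adjusted
  p-matrix; normality (Shapiro) and homogeneity (Bartlett) checks are
  advisory warnings, since the analysis convention runs Tukey regardless
  and reports the checks. Letter/p-matrix consistency is audited
  brute-force in the tests.
* **Quadratic fits** report $R = \sqrt{R^2}$ signed by the curvature
  (negative for concave fits with an interior maximum) and the vertex
  $-b/2c$ only when $c < 0$.
* **Seeds**: every stochastic function takes an integer seed and scopes it
  with `withr::with_seed`; the pipeline derives independent per-stage
  streams from one master seed, so reruns are bit-identical.

## Problem sizes used in validation

The test suite validates exact identities on trees of ≤ 6 tips against
naive double-loop oracles (to 1e-12) and exhaustive enumeration of the
4-tip phylogeny pool (null mean 10/3), then exercises the stochastic
properties at study scale: 500-tip pools, communities of 75 taxa, 200
neutral communities / pairs at 999 randomizations for calibration, 40
filtering communities at 499 randomizations for recovery, SparCC at 50
OTUs × 200 samples with 99 permutations, and correlogram calibration over
100 trait permutations. The end-to-end pipeline default (`"scaled"`
profile) keeps the analysis thresholds (rarefaction 7,000; $|\rho| >
0.85$; $p < 0.01$) and shrinks only the permutation counts; the
`"paper"` profile restores the field-standard 1,000 / 999 / 9,999 /
top-500 settings.

## Known limitations

* The ±2 rules classify; they do not partition process contributions
  quantitatively (no Raup–Crick, no nearest-taxon NTI/βNTI variants).
* βNRI's null is the α phylogeny-pool model applied to both communities —
  an assumption, as no β null is canonically defined for this model.
* SparCC p-values at desk-scale permutation counts are coarse
  ($1/(n_{perm}+1)$ granularity); the 0.85/0.01 network thresholds are
  then conservative.
* Louvain modularity is stochastic; values on identical data are
  reproducible only under the seeded-restart scheme used here.
* With four replicates per treatment, per-regime SparCC correlations are
  noisy; the pipeline reproduces the workflow's structure, and the
  planted-correlation validation uses 200 samples where the estimator is
  consistent.

## A minimal worked run

```{r, eval = FALSE}
cfg <- default_run_config(profile = "scaled", seed = 1)
res <- run_pipeline(cfg, out_dir = "commassembly_results")
head(res$alpha[, c("sample_id", "group", "observed", "nri", "classification")])
res$beta_groups
res$topology
```

The results directory contains `alpha.tsv`, `beta.tsv`, `beta_groups.tsv`,
`correlogram.tsv`, per-treatment GraphML networks and edge lists,
`topology.tsv`, `cscore.tsv`, `letters.tsv`, `panel.tsv`, `quad.tsv`, a
structured `run.log`, and `config.json` echoing the full configuration
with its hash for provenance.
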