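---
title: "Methods: factor, network and lifespan analysis of apathy symptoms"
author: "apathynet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: factor, network and lifespan analysis of apathy symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apathynet)
```

# The scientific problem

Multidimensional apathy is assessed with Likert-scale self-report
instruments: the AMI (18 items over three a-priori domains — Behavioural,
Social, Emotional — six items each), the AES (18 items) and the DAS
(24 items). Whether *social* apathy is a separable dimension, rather than
general loss of initiative expressed in a social context, is an empirical
psychometric question. It can be answered at two levels: by latent-variable
models (do social items form their own factor, and how pure is it?) and by
symptom networks (do social items form their own module, at every age and
in every cohort?). `apathynet` implements both routes plus the synthetic
data needed to validate them.

# The generating model behind the synthetic cohorts

`simulateCohort()` draws ordinal responses from a correlated common-factor
model. For items $i$ and factors $f$: factor scores $\mathbf{f} \sim
N(0, \Phi)$, continuous responses $y = \Lambda \mathbf{f} + \varepsilon$
with $\varepsilon \sim N(0, \mathrm{diag}(\theta))$ and $\theta_i = 1 -
(\Lambda \Phi \Lambda^\top)_{ii}$, so each continuous response is
standardised; each item is then discretised into the 0–4 categories by
four ordered cut-points. The implied item correlation matrix has the
closed form $\Lambda \Phi \Lambda^\top + \mathrm{diag}(\theta)$
(`impliedCorrelation()`), which the tests use as a population oracle.

Choices worth knowing:

* **Thresholds** default to the standard-normal quintiles, i.e. equal 20%
  category probabilities. Real questionnaire responses are typically
  right-skewed in healthy cohorts (scale means around 1.4–1.8 of 4); the
  quintile default keeps simulated totals mid-scale and symmetric, which
  is the conservative choice for testing correlation-based machinery. Any
  per-item threshold matrix can be supplied to emulate skew.
* **Age structure** is created by mixing age-band-specific models at the
  participant level, not by interpolating loadings. Every sliding window
  therefore has a well-defined (mixture) generating model, which is what a
  recovery test needs.
* **Reproducibility**: all draws are governed by one seed per
  `simulateCohort()` call; ages and responses use deterministically
  derived sub-streams, so partial re-runs reproduce.
* What the generator does **not** emulate: acquiescence and other
  response-style biases, item-wording effects, informant-report
  discrepancies, and missingness mechanisms (missing cells can be present
  in real data files and are handled, but are not generated). A passing
  recovery suite therefore shows the *statistical machinery* is correct
  under the stated model, not that real questionnaire data satisfy that
  model.

# Exploratory factor analysis

The EFA engine works on the product-moment correlation matrix of the
listwise-complete data, treating the 0–4 responses as numeric (the
convention under which these instruments' totals are scored); Spearman
correlations are reserved for the networks. Components:

* **KMO**: $\mathrm{KMO} = \sum r_{ij}^2 / (\sum r_{ij}^2 + \sum
  q_{ij}^2)$ over $i \neq j$, where $q$ are anti-image partial
  correlations from $R^{-1}$. Near-singular matrices are
  ridge-regularised ($R + 10^{-6} I$, renormalised) with a message.
* **Bartlett sphericity**: $\chi^2 = -(n - 1 - (2p+5)/6)\,\ln\det R$ on
  $p(p-1)/2$ df. For the combined 60-item battery this is 1770 df.
* **Retention**: Kaiser's criterion, eigenvalues strictly greater than 1.
* **Extraction** is maximum likelihood (`stats::factanal` with
  multi-start under a private RNG stream): the reported model test
  $\chi^2 = (n - 1 - (2p+5)/6 - 2k/3) F_{\min}$ on
  $((p-k)^2 - (p+k))/2$ df is only defined for ML, which is why ML rather
  than principal-axis is the default. Heywood cases are bounded at a
  residual variance of 0.005 with a warning.
* **Rotation**: row-normalised varimax, or promax (power 4 by default)
  with the inter-factor correlation matrix recovered from the rotation
  transform. Communalities are rotation-invariant and carried through.
* **Factor purity**: per item, the squared loading on its designated
  factor divided by the sum of its squared loadings. "Designated" defaults
  to the argmax-|loading| factor, with an override map for a-priori
  designations, since designation conventions vary. Purity comparisons use
  a classic one-way ANOVA across factor groups plus a planned one-sided
  Welch test of the focal factor against the pooled remaining items; a
  variance floor of $10^{-12}$ keeps the Welch statistic finite for
  degenerate zero-variance groups, and perfectly separated groups report
  $F = \infty$, $p = 0$ rather than an unstable ratio.

# Confirmatory factor analysis

The CFA engine fits the congeneric three-factor model (each retained item
loads on exactly one factor; unit factor variances; free loadings, residual
variances and factor correlations; no residual covariances) by minimising
the ML discrepancy $F = \ln\det\Sigma + \mathrm{tr}(S\Sigma^{-1}) -
\ln\det S - p$ with analytic gradients (L-BFGS-B; residual variances
bounded below at 0.001 as the Heywood guard; a seeded jittered-restart
ladder on non-convergence; convergence requires a projected gradient norm
$\le 10^{-6}$). The default model spec excludes AMI-2, AMI-6 and AMI-8 —
an *a-priori configuration choice* mirroring their reported low indicator
reliability, not something the package re-derives. Under the shipped AMI
key this leaves 6 Behavioural, 4 Social and 5 Emotional indicators
(15 in total, 87 df).

Numerical conventions, chosen once and documented:

* The analysed matrix is the correlation matrix of the listwise data; the
  ML discrepancy of this model is scale-invariant, so this loses nothing
  and makes the standardised solution direct.
* $\chi^2 = n F_{\min}$ (multiplier $n$, not $n-1$), and RMSEA uses the
  same $n$ in its denominator; the 90% RMSEA interval is obtained by
  root-finding the noncentral-$\chi^2$ coverage equations on a [0, 1]
  bracket with tolerance $10^{-6}$.
* CFI/TLI use the independence model fitted on the same correlation
  matrix ($F_B = -\ln\det R$, $p(p-1)/2$ df). SRMR averages squared
  correlation-metric residuals over the upper triangle including the
  diagonal.
* Robust (mean-adjusted) scaling is not implemented: the package reports
  the plain ML statistics, which are exact under the multivariate-normal
  generating model used throughout validation. This is a known limitation
  for strongly non-normal real data.

# Symptom networks and community detection

`spearmanNetwork()` builds the weighted undirected item graph: edge
weights are absolute Spearman correlations (mid-ranks for ties; pairwise
deletion for missing cells), with the signed matrix retained for export
semantics only. Community detection always runs on the **full** weight
matrix; the $|\rho| \ge 0.1$ threshold (`sparseEdges()`, boundary
retained) exists for visualisation and GraphML export, never for
detection.

Modularity is evaluated exactly as
$Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} - \frac{k_i k_j}{2m}\right]
\delta(c_i, c_j)$, including the diagonal null terms, so the one-community
partition scores exactly 0 and all-singletons is negative.

`louvainOnce()` is a seeded greedy maximiser: local moves over a random
node order (each node to the neighbouring community with the largest
positive gain; ties to the lowest community id; sweeps repeated to
convergence), alternating by default with an aggregation phase that
greedily merges whole communities while $Q$ improves. The aggregation
phase is the default because pure node-level moves provably cannot merge
two communities when every single-node step is negative; on graphs with
genuine block structure the combined procedure reaches the exhaustive
optimum (verified against a brute-force partition enumeration up to eight
nodes, and against igraph's multi-level implementation), while the pure
local variant can stall at split-block optima. The single-pass local
variant remains available (`multilevel = FALSE`) and agrees with the
default on the 18-item networks in the test battery. A documented
limitation: on essentially unstructured graphs (near-null modularity),
*any* greedy maximiser combined with most-frequent-partition selection can
settle below the global optimum; the oracle tests therefore use randomised
planted-block graphs, the regime the method is designed for.

`stablePartition()` runs 1000 seeded restarts by default (tests and the
pipeline scale this down; see below) and selects the most frequent
canonical partition — communities renumbered by first appearance in item
order — breaking frequency ties by higher mean $Q$, then lexicographically.
Module summaries report the modal a-priori domain (ties resolved to the
central node's domain), domain purity, intra-modular strengths and the
central node (highest intra-modular strength; ties to the first item in
scale order, with a message).

# Lifespan scan

For each cohort, windows are centred on every integer age in the observed
range: weights $w_i = \exp(-(a_i - c)^2 / (2\sigma^2))$ with
$\sigma = 5$ years, truncated at the 10-year window's edge (the kernel has
fallen to $e^{-1/2}$ there); truncation reconciles the finite window with
the Gaussian kernel, and an untruncated variant is available. Windows with
Kish effective sample size $(\sum w)^2 / \sum w^2 < 30$ are excluded. The
weighted Spearman network ranks items over the in-window participants and
takes the weighted Pearson correlation of the rank columns — the minimal
weighted construction that reduces *bit-for-bit* to the unweighted network
under uniform weights (a tested invariant). Per window the stable
partition and module summaries are recorded; a domain is "present" at a
centre when some module's modal domain equals it.

The Group × Domain ANOVA on per-window module purities uses Type II sums
of squares because cohorts contribute different numbers of windows
(unbalanced design); on balanced data it coincides with the textbook
decomposition, which the tests exploit as an independent oracle.

The assessment-mode sensitivity analysis re-runs the network pipeline per
mode and reports module compositions, an adjusted-Rand pair agreement and
a per-item correspondence table that localises discordantly assigned items
(modules matched greedily by overlap).

# Problem sizes used in validation

The shipped test-and-acceptance suite uses sizes at which every property
is informative while the whole suite stays quick on a laptop: cohorts of
2,000–6,000 for network recovery (4,000 for the three-block recovery at
200 restarts × 3 seeds), 5,000 for the five-factor EFA recovery, 500
CFA calibration replicates at n = 500, lifespan scans over ages 16–90 at
n = 6,000 with 60 restarts per window, 50,000 draws for moment
convergence, and a 10^6-pair Monte-Carlo oracle for the discretised
Spearman check. The exhaustive modularity oracle enumerates all partitions
of up to eight nodes (Bell(8) = 4,140).

# Known limitations

* Ordinal items are correlated with product-moment (EFA/CFA) or Spearman
  (networks) coefficients; polychoric estimation is out of scope, so
  loadings recovered from discretised data are mildly attenuated (the
  recovery tests use congruence, which is scale-free, and continuous
  draws where exact calibration is asserted).
* The AES and DAS item→domain keys shipped in the registry are
  best-effort reconstructions of the original instruments' subscale
  classifications and are data, not code — edit
  `inst/extdata/scale_registry.tsv` to match your instrument copies. Only
  the AMI key carries analytic weight in the default models.
* Stability selection (most frequent partition) is a mode, not a maximum;
  on weakly structured networks it may not coincide with the best-$Q$
  partition found. The census object exposes the full frequency table so
  users can inspect alternatives.
* No smoothing or uncertainty bands over lifespan trajectories, and no
  formal between-window network comparison tests.
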