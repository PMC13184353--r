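# apathynet

Symptom-level analysis of multidimensional apathy questionnaires.

Apathy — diminished goal-directed behaviour — is measured with self-report
instruments such as the Apathy Motivation Index (AMI, 18 items across
Behavioural / Social / Emotional domains), the Apathy Evaluation Scale
(AES, 18 items) and the Dimensional Apathy Scale (DAS, 24 items). A central
psychometric question is whether *social* apathy (loss of motivation to
engage with others) is a separable dimension or a by-product of general
behavioural inertia or emotional blunting. `apathynet` implements the full
analysis pipeline used to address that question at the level of individual
symptoms:

1. **Exploratory factor analysis** of a combined item battery: KMO sampling
   adequacy, Bartlett's test of sphericity
   (χ² = −(n − 1 − (2p + 5)/6)·ln det R on p(p − 1)/2 df), Kaiser retention
   (eigenvalues > 1), maximum-likelihood extraction with the
   Bartlett-corrected model test, varimax/promax rotation, and a
   **factor-purity index** per item: λ²(designated factor) / Σ_f λ²_f, with
   a one-way ANOVA plus a one-sided Welch t-test comparing the focal
   factor's mean purity with the pooled remainder.
2. **Confirmatory factor analysis** of the a-priori three-factor AMI model
   (unit-variance factors, free loadings/residuals/factor covariances,
   items AMI-2/6/8 excluded) by maximum likelihood with analytic gradients,
   reporting χ², CFI, TLI, RMSEA (with 90% CI) and SRMR.
3. **Symptom networks**: nodes are items, edges are absolute Spearman
   correlations |ρ|; community detection maximises Newman modularity
   Q = (1/2m) Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j) with a seeded
   Louvain-style algorithm, and the **modal partition over random
   restarts** is selected as the stable solution. Modules are summarised by
   a-priori-domain purity and their central node (highest intra-modular
   strength).
4. **Lifespan scan**: sliding 10-year age windows in 1-year steps, weighted
   by a Gaussian kernel (σ = 5 years), gated on a Kish effective sample
   size ≥ 30, with a weighted-Spearman network, stable partition and module
   summary per window, and a Group × Domain two-way ANOVA (Type II) on
   module purities; plus an assessment-mode (online vs in-person)
   sensitivity split.

Because item-level cohort data of this kind are not generally shareable,
the package ships a first-class **synthetic cohort generator**: ordinal 0–4
responses are drawn from a correlated latent-factor model (simple-structure
loadings Λ, inter-factor correlations Φ, Gaussian residuals, threshold
discretisation at standard-normal quintiles), with ages, cohort labels and
assessment modes attached. Every downstream stage is exercised and
validated against this generator.

## Worked example

Simulate an AMI-like cohort whose three a-priori domains are true latent
factors (loadings 0.7, inter-factor correlations 0.3), then recover the
structure by every route:

```r
library(apathynet)

ami <- builtinScale("AMI")
d   <- itemDomains(ami)
ids <- names(d)[order(match(d, c("Behavioural", "Social", "Emotional")))]
gen <- plantedModuleSpec(3, 6, withinLoading = 0.7, betweenCorr = 0.3,
                         itemIds = ids,
                         domains = c("Behavioural", "Social", "Emotional"))
ds  <- simulateCohort(cohortSimSpec(2000, gen, seed = 42), scale = ami)

net <- spearmanNetwork(ds)
cen <- stablePartition(net, nRestarts = 200, seed = 1)
cen
#> PartitionCensus: 200 restarts, 1 distinct partitions
#>   modal: 3 modules, share 100.0%

for (s in summariseModules(net, modalPartition(cen)))
  cat(sprintf("module (%s): purity %.2f, central node %s\n",
              s$modalDomain, s$purity, s$centralNode))
#> module (Emotional): purity 1.00, central node AMI-1
#> module (Social): purity 1.00, central node AMI-8
#> module (Behavioural): purity 1.00, central node AMI-11

res <- runEFA(ds, k = 3)
cat(sprintf("KMO = %.3f; Bartlett chi2(%d) = %.1f\n",
            res$kmo, res$bartlett$df, res$bartlett$chi2))
#> KMO = 0.902; Bartlett chi2(153) = 11140.1

cfaFit(ds)   # a-priori three-factor AMI model, 15 indicators
#> CFAFit: chi2(87) = 87.27, p = 0.472 (n = 2000)
#>   CFI = 1.000; TLI = 1.000; RMSEA = 0.001 [0.000, 0.012]; SRMR = 0.015
```

The network recovers the three planted domains in 100% of restarts with
perfect domain purity; the sphericity test has the expected
18·17/2 = 153 degrees of freedom; and the confirmatory model fits with
χ² ≈ its 87 degrees of freedom, as it should when the generating model is
true.

The staged pipeline (`runPipeline()`, or
`Rscript inst/scripts/apathy_pipeline.R <config.yaml>`) runs
simulate → efa → cfa → network → lifespan → sensitivity from one YAML
configuration and writes per-stage tables, a GraphML network export and a
manifest with derived seeds and content hashes.

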