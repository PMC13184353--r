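test_that("KMO behaves as the anti-image formula dictates", {
  ## p = 2: the partial correlation magnitude equals |r|, so KMO = 1/2
  R2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(kmoOverall(R2), 0.5, tolerance = 1e-12)

  ## strong one-factor structure: high sampling adequacy
  oneF <- plantedModuleSpec(1, 9, 0.8, 0)
  expect_gt(kmoOverall(impliedCorrelation(oneF)), 0.9)

  ## near-identity: marginal and partial correlations coincide, KMO ~ 0.5
  Rni <- diag(6)
  Rni[upper.tri(Rni)] <- Rni[lower.tri(Rni)] <- 1e-6
  expect_equal(kmoOverall(Rni), 0.5, tolerance = 1e-3)
})

test_that("Bartlett's sphericity test matches its closed form", {
  spec5 <- plantedModuleSpec(5, 12, 0.7, 0.3)
  R <- impliedCorrelation(spec5)
  b <- bartlettSphericity(R, 479)
  expect_equal(b$df, 1770)
  expect_equal(b$chi2,
               -(479 - 1 - (2 * 60 + 5) / 6) * log(det(R)), tolerance = 1e-10)

  ident <- bartlettSphericity(diag(18), 100)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$df, 153)

  expect_error(bartlettSphericity(R, 40), "sample size")
})

test_that("Kaiser retention counts eigenvalues strictly above one", {
  expect_equal(kaiserNFactors(c(3.2, 1.5, 1.0, 0.3)), 2)
  expect_equal(kaiserNFactors(diag(10)), 0)
  spec5 <- plantedModuleSpec(5, 12, 0.7, 0.3)
  expect_equal(kaiserNFactors(impliedCorrelation(spec5)), 5)
})

test_that("ML extraction recovers a model-implied structure exactly", {
  spec <- plantedModuleSpec(1, 6, 0.7, 0)
  sol <- extractML(impliedCorrelation(spec), 1, 500)
  expect_lt(abs(sol@fit$chi2), 1e-4)
  expect_equal(unname(abs(sol@pattern[, 1])), rep(0.7, 6), tolerance = 1e-4)
  expect_equal(sol@communality, rep(0.49, 6), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the ML model-test df identity holds across the (p, k) grid", {
  expect_equal(efaModelDf(60, 5), 1480)
  for (p in c(10, 18, 24, 60)) for (k in c(1, 2, 3, 5)) {
    expect_equal(efaModelDf(p, k), ((p - k)^2 - (p + k)) / 2)
  }
  ## and factanal agrees with the closed form
  spec <- plantedModuleSpec(3, 6, 0.7, 0.3)
  sol <- extractML(impliedCorrelation(spec), 3, 500)
  expect_equal(sol@fit$df, efaModelDf(18, 3))
})

test_that("the ML chi-square is calibrated under a true k-factor model", {
  spec <- plantedModuleSpec(3, 6, 0.7, 0.3)
  n <- 20000
  y <- rFactorResponses(spec, n, seed = 5, discretise = FALSE)
  sol <- extractML(cor(y), 3, n)
  df <- sol@fit$df
  expect_gt(sol@fit$chi2, qchisq(0.025, df))
  expect_lt(sol@fit$chi2, qchisq(0.975, df))
})

test_that("varimax leaves simple structure fixed and preserves communalities", {
  spec <- plantedModuleSpec(3, 6, 0.7, 0)
  sol <- extractML(impliedCorrelation(spec), 3, 1000)
  rot <- rotateFactors(sol, "varimax")
  ## communalities are rotation-invariant
  expect_equal(rot@communality, sol@communality, tolerance = 1e-8)
  ## recovered pattern equals the generating loadings up to sign/permutation
  m <- apathynet:::matchFactors(rot@pattern, spec@loadings)
  expect_true(all(m$congruence > 1 - 1e-6))
  expect_equal(unname(m$loadings), unname(spec@loadings), tolerance = 1e-3)
})

test_that("promax recovers oblique planted structure from simulated data", {
  spec <- plantedModuleSpec(5, 12, 0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(5000, spec, seed = 41))
  res <- runEFA(ds, k = 5, rotation = "promax")
  rot <- res$solution
  m <- apathynet:::matchFactors(rot@pattern, spec@loadings)
  expect_true(all(m$congruence >= 0.95))
  ## inter-factor correlations near the generating 0.3
  Phi <- rot@factorCorr[m$perm, m$perm] * tcrossprod(m$sign)
  offd <- Phi[row(Phi) != col(Phi)]
  expect_true(all(abs(offd - 0.3) < 0.1))
})

test_that("promax on orthogonal structure returns a near-identity Phi", {
  spec <- plantedModuleSpec(3, 6, 0.7, 0)
  ds <- simulateCohort(cohortSimSpec(5000, spec, seed = 43))
  res <- runEFA(ds, k = 3, rotation = "promax")
  offd <- res$solution@factorCorr
  expect_true(all(abs(offd[row(offd) != col(offd)]) < 0.05))
})

test_that("single-factor rotation is the identity, with a note", {
  spec <- plantedModuleSpec(1, 6, 0.7, 0)
  sol <- extractML(impliedCorrelation(spec), 1, 500)
  expect_message(rot <- rotateFactors(sol, "varimax"), "identity")
  expect_identical(rot@pattern, sol@pattern)
})

test_that("factor purity follows its squared-loading definition", {
  P <- rbind(c(0.8, 0, 0, 0, 0),
             c(0.6, 0.6, 0, 0, 0),
             c(0.5, 0.3, 0.2, 0, 0))
  pur <- factorPurity(P, assignment = c(I1 = 1, I2 = 1, I3 = 1))
  expect_equal(pur$items$purity[1], 1)
  expect_equal(pur$items$purity[2], 0.5)
  expect_equal(pur$items$purity[3], 0.25 / 0.38)

  ## bounds and the purity-1 characterisation, over random loading matrices
  set.seed(7)
  for (rep in 1:20) {
    L <- matrix(rnorm(8 * 3, 0, 0.4), 8, 3)
    p <- factorPurity(L)$items$purity
    expect_true(all(p >= 0 & p <= 1))
  }
  simple <- diag(c(0.7, 0.5))
  expect_equal(factorPurity(simple)$items$purity, c(1, 1))
})

test_that("zero-communality items are flagged and excluded from factor means", {
  P <- rbind(c(0.8, 0), c(0, 0))
  expect_warning(pur <- factorPurity(P, assignment = c(I1 = 1, I2 = 1)),
                 "zero communality")
  expect_true(is.na(pur$items$purity[2]))
  expect_equal(pur$factors$nItems, 1)
})

test_that("purity comparisons handle degenerate groups and match t.test", {
  ## all purities identical: F = 0, Welch t = 0, one-sided p = 1/2
  flat <- fakePurityTable(rep(0.8, 12), rep(c("A", "B", "C"), each = 4))
  res <- comparePurity(flat, "A")
  expect_equal(res$anova$F, 0)
  expect_equal(res$welch$t, 0)
  expect_equal(res$welch$p, 0.5)

  ## zero-variance groups: variance floor keeps t finite, p -> 0
  sep <- fakePurityTable(c(rep(1, 3), rep(0.5, 3)), rep(c("A", "B"), each = 3))
  res2 <- comparePurity(sep, "A")
  expect_true(is.finite(res2$welch$t))
  expect_gt(res2$welch$t, 1e4)
  expect_lt(res2$welch$p, 1e-8)

  ## against the independent stats::t.test route
  set.seed(11)
  focal <- pmin(pmax(rnorm(12, 0.88, 0.05), 0), 1)
  rest <- pmin(pmax(rnorm(48, 0.74, 0.12), 0), 1)
  tab <- fakePurityTable(c(focal, rest),
                         c(rep("Social", 12), rep(c("B", "C", "D", "E"), 12)))
  res3 <- comparePurity(tab, "Social")
  ref <- t.test(focal, rest, alternative = "greater", var.equal = FALSE)
  expect_equal(res3$welch$t, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res3$welch$df, unname(ref$parameter), tolerance = 1e-6)
  expect_equal(res3$welch$p, ref$p.value, tolerance = 1e-6)
})
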