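test_that("window weights follow the truncated Gaussian kernel", {
  expect_equal(windowWeights(50, 50), 1)
  expect_equal(windowWeights(55, 50), exp(-0.5))
  expect_equal(windowWeights(55.01, 50), 0)     # outside the 10-year window
  expect_equal(windowWeights(c(10, 90), 50), c(0, 0))
  ## untruncated kernel keeps the tail
  expect_gt(windowWeights(57, 50, truncate = FALSE), 0)
})

test_that("effective sample size is the Kish formula", {
  expect_equal(effectiveN(rep(1, 50)), 50)
  expect_equal(effectiveN(rep(0.25, 50)), 50)   # uniform weights: the count
  expect_equal(effectiveN(c(1, 1, 0, 0)), 2)
  expect_equal(effectiveN(c(1, 0.5)), 1.8)
  expect_equal(effectiveN(c(0, 0)), 0)
})

test_that("uniform weights reproduce the unweighted network to 1e-12", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(800, spec, seed = 71),
                       scale = builtinScale("AMI"))
  netU <- spearmanNetwork(ds)
  netW <- weightedSpearmanNetwork(ds, rep(0.37, 800))
  expect_lt(max(abs(weightMatrix(netU) - weightMatrix(netW))), 1e-12)
  expect_lt(max(abs(signedCorrelations(netU) - signedCorrelations(netW))),
            1e-12)
  expect_equal(netW@nEffective, 800)
})

test_that("weights concentrated on one band expose that band's structure", {
  ## before 60: 3 distinct blocks; after 60: a single global factor
  mA <- amiPlantedSpec(0.7, 0.0)
  LB <- matrix(0, 18, 3, dimnames = list(amiBlockIds(), NULL))
  LB[, 1] <- 0.7
  mB <- factorModelSpec(LB, diag(3),
                        domain = itemDomains(builtinScale("AMI"))[amiBlockIds()])
  spec <- cohortSimSpec(4000, ageRange = c(16, 92), seed = 73,
                        ageModels = list(list(min = 16, max = 60, model = mA),
                                         list(min = 60, max = 92, model = mB)))
  ds <- simulateCohort(spec, scale = builtinScale("AMI"))
  ages <- SummarizedExperiment::colData(ds)$age
  netYoung <- spearmanNetwork(ds, windowWeights(ages, 40))
  netOld <- spearmanNetwork(ds, windowWeights(ages, 80))
  Wy <- weightMatrix(netYoung)
  Wo <- weightMatrix(netOld)
  doms <- unname(itemDomains(netYoung)[netYoung@items])
  beh <- which(doms == "Behavioural")
  soc <- which(doms == "Social")
  crossIdx <- cbind(rep(beh, 6), rep(soc, each = 6))
  withinIdx <- cbind(rep(beh, 6), rep(beh, each = 6))
  withinIdx <- withinIdx[withinIdx[, 1] < withinIdx[, 2], ]
  expect_gt(mean(Wy[withinIdx]), mean(Wy[crossIdx]) + 0.2)
  ## in the merged band all items share one factor: cross ~ within
  expect_lt(abs(mean(Wo[withinIdx]) - mean(Wo[crossIdx])), 0.05)
})

test_that("the ESS gate excludes thin windows", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(40, spec, ageRange = c(70, 70), seed = 77),
                       scale = builtinScale("AMI"))
  traj <- lifespanScan(ds, nRestarts = 10, seed = 5)
  ## all participants are 70; only the window centred at 70 exists and passes
  expect_true(all(traj$windows$ess[traj$windows$included] >= 30))
  expect_equal(traj$windows$center[traj$windows$included], 70)
})

test_that("a stationary generating model yields a stable trajectory", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(6000, spec, ageRange = c(16, 90),
                                     seed = 79),
                       scale = builtinScale("AMI"))
  traj <- lifespanScan(ds, nRestarts = 40, seed = 7)
  inc <- traj$windows[traj$windows$included, ]
  expect_true(all(inc$ess >= 30))
  ## contiguous included centers for a unimodal (uniform) age distribution
  expect_equal(inc$center, seq(min(inc$center), max(inc$center)))
  ## the modal partition is identical across >= 95% of included centers
  keys <- vapply(traj$partitions, paste, character(1), collapse = ".")
  expect_gte(max(table(keys)) / length(keys), 0.95)
  ## a Social-modal module is present at every included center
  soc <- traj$presence[traj$presence$domain == "Social", ]
  expect_true(all(soc$present))
  ## purity bounds
  expect_true(all(traj$modules$purity > 0 & traj$modules$purity <= 1))
})

test_that("purity ANOVA matches an independently coded balanced ANOVA", {
  set.seed(101)
  groups <- rep(c("HC", "Depression", "NCD"), each = 30)
  domains <- rep(rep(c("Behavioural", "Social", "Emotional"), each = 10), 3)
  y <- 0.8 +
    0.05 * (domains == "Social") -
    0.04 * (groups == "NCD") +
    rnorm(90, 0, 0.05)
  rec <- data.frame(cohort = groups, domain = domains, purity = y)
  tab <- purityAnova(rec)
  ref <- balancedTwoWayAnova(y, groups, domains)
  expect_equal(tab$F[tab$effect == "Group"], ref$FA, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "Domain"], ref$FB, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "Group:Domain"], ref$FAB, tolerance = 1e-8)
  expect_equal(unique(tab$df2), ref$dfE)
})

test_that("degenerate and incomplete purity designs are handled", {
  rec <- data.frame(cohort = rep(c("A", "B"), each = 6),
                    domain = rep(c("X", "Y"), 6),
                    purity = 0.9)
  tab <- purityAnova(rec)
  expect_true(all(tab$F == 0))

  rec2 <- data.frame(cohort = c(rep("A", 6), rep("B", 3)),
                     domain = c(rep(c("X", "Y"), 3), rep("X", 3)),
                     purity = c(0.9, 0.8, 0.85, 0.9, 0.7, 0.95, 0.8, 0.85, 0.9))
  expect_warning(tab2 <- purityAnova(rec2), "interaction")
  expect_false("Group:Domain" %in% tab2$effect)
})

test_that("assessment-mode splits agree when modes share one model", {
  spec <- amiPlantedSpec(0.7, 0.3)
  d1 <- simulateCohort(cohortSimSpec(900, spec, seed = 83, mode = "online"),
                       scale = builtinScale("AMI"))
  d2 <- simulateCohort(cohortSimSpec(900, spec, seed = 84, mode = "in_person"),
                       scale = builtinScale("AMI"))
  resp <- rbind(responses(d1), responses(d2))
  ds <- cohortDataset(resp, builtinScale("AMI"),
                      age = c(SummarizedExperiment::colData(d1)$age,
                              SummarizedExperiment::colData(d2)$age),
                      mode = rep(c("online", "in_person"), each = 900))
  res <- modeSensitivity(ds, nRestarts = 30, seed = 5)
  expect_equal(res$agreement$adjustedRand, 1)
  expect_true(all(res$agreement$items$concordant))
})

test_that("a single re-wired item is localised by the agreement report", {
  ## online mode: clean 3-block model; in-person: one Emotional-block item
  ## (the 13th, first of the Emotional block) generated from the
  ## Behavioural factor instead
  ids <- amiBlockIds()
  doms <- itemDomains(builtinScale("AMI"))[ids]
  L1 <- matrix(0, 18, 3, dimnames = list(ids, NULL))
  L1[cbind(1:18, rep(1:3, each = 6))] <- 0.7
  m1 <- factorModelSpec(L1, diag(3) * 0.7 + 0.3, domain = doms)
  L2 <- L1
  L2[13, ] <- c(0.7, 0, 0)
  m2 <- factorModelSpec(L2, diag(3) * 0.7 + 0.3, domain = doms)

  d1 <- simulateCohort(cohortSimSpec(1500, m1, seed = 91, mode = "online"),
                       scale = builtinScale("AMI"))
  d2 <- simulateCohort(cohortSimSpec(1500, m2, seed = 92, mode = "in_person"),
                       scale = builtinScale("AMI"))
  ds <- cohortDataset(rbind(responses(d1), responses(d2)),
                      builtinScale("AMI"),
                      age = c(SummarizedExperiment::colData(d1)$age,
                              SummarizedExperiment::colData(d2)$age),
                      mode = rep(c("online", "in_person"), each = 1500))
  res <- modeSensitivity(ds, nRestarts = 40, seed = 6)
  items <- res$agreement$items
  discordant <- items$item[!items$concordant]
  expect_equal(discordant, ids[13])

  ## missing mode metadata is an error
  dsNoMode <- cohortDataset(responses(d1), builtinScale("AMI"),
                            age = SummarizedExperiment::colData(d1)$age,
                            mode = "unknown")
  expect_error(modeSensitivity(dsNoMode), "two assessment modes")
})
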