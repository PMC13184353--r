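test_that("spearman networks encode absolute rank correlations", {
  sc <- scaleDefinition("toy", c("T-1", "T-2", "T-3"),
                        c("T-1" = "A", "T-2" = "A", "T-3" = "B"))
  x <- c(0, 1, 2, 3, 4, 0, 2, 4, 1, 3)
  resp <- cbind("T-1" = x, "T-2" = x, "T-3" = 4 - x)
  ds <- cohortDataset(resp, sc, age = 30)
  net <- spearmanNetwork(ds)
  W <- weightMatrix(net)
  R <- signedCorrelations(net)
  expect_equal(W["T-1", "T-2"], 1)          # identical columns
  expect_equal(R["T-1", "T-3"], -1)         # reverse coding
  expect_equal(W["T-1", "T-3"], 1)          # absolute value
  expect_equal(unname(diag(W)), rep(0, 3))
})

test_that("constant items get zero edges with a warning", {
  sc <- scaleDefinition("toy", c("T-1", "T-2"),
                        c("T-1" = "A", "T-2" = "B"))
  resp <- cbind("T-1" = c(2, 2, 2, 2), "T-2" = c(0, 1, 3, 4))
  ds <- cohortDataset(resp, sc, age = 30)
  expect_warning(net <- spearmanNetwork(ds), "constant")
  expect_equal(weightMatrix(net)["T-1", "T-2"], 0)
})

test_that("modularity evaluates the printed formula exactly", {
  net <- twoTriangles()
  expect_equal(modularityQ(net, rep(1L, 6)), 0)               # one community
  expect_equal(modularityQ(net, rep(1:2, each = 3)), 0.5)     # components
  ## singleton partition reduces to -sum k_i^2 / (2m)^2
  W <- weightMatrix(net)
  k <- rowSums(W)
  expect_equal(modularityQ(net, 1:6), -sum(k^2) / sum(k)^2)
  ## agrees with igraph's implementation on a random weighted graph
  rg <- randomWeightedGraph(7, seed = 5)
  g <- igraph::graph_from_adjacency_matrix(weightMatrix(rg),
                                           mode = "undirected",
                                           weighted = TRUE)
  part <- c(1, 1, 2, 2, 2, 3, 3)
  expect_equal(modularityQ(rg, part),
               igraph::modularity(g, part, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("single-level Louvain finds planted structure deterministically", {
  net <- twoTriangles()
  part <- louvainOnce(net, seed = 5)
  expect_equal(part, rep(1:2, each = 3))
  expect_equal(modularityQ(net, part), 0.5)
  expect_identical(louvainOnce(net, seed = 5), part)

  ## complete equal-weight graph: no split improves on Q = 0
  Wc <- matrix(1, 5, 5); diag(Wc) <- 0
  rownames(Wc) <- colnames(Wc) <- paste0("I", 1:5)
  pc <- louvainOnce(netFromW(Wc), seed = 2)
  expect_equal(pc, rep(1L, 5))
})

test_that("Louvain is near-optimal against the exhaustive-partition oracle", {
  for (seed in 1:5) {
    p <- sample(5:8, 1)
    net <- randomWeightedGraph(p, seed = 100 + seed)
    cen <- stablePartition(net, nRestarts = 20, seed = seed)
    qLouvain <- modularityQ(net, modalPartition(cen))
    ex <- exhaustiveMaxQ(net)
    expect_gte(ex$maxQ, qLouvain - 1e-12)
    expect_gte(qLouvain, 0.95 * ex$maxQ)
  }
})

test_that("restart census selects the modal partition reproducibly", {
  net <- twoTriangles()
  cen <- stablePartition(net, nRestarts = 25, seed = 9)
  expect_equal(modalShare(cen), 1)
  expect_equal(modalPartition(cen), rep(1:2, each = 3))
  expect_equal(sum(cen@counts$count), 25)
  cen1 <- stablePartition(net, nRestarts = 1, seed = 9)
  expect_equal(modalShare(cen1), 1)
  ## same master seed, same census
  cen2 <- stablePartition(net, nRestarts = 25, seed = 9)
  expect_identical(cen@counts, cen2@counts)
})

test_that("planted cohorts are recovered and beat the a-priori partition never", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(4000, spec, seed = 21),
                       scale = builtinScale("AMI"))
  net <- spearmanNetwork(ds)
  cen <- stablePartition(net, nRestarts = 50, seed = 3)
  planted <- plantedDomainPartition(net)
  expect_equal(modalPartition(cen), planted)
  expect_gte(modalShare(cen), 0.9)
  expect_gte(modularityQ(net, modalPartition(cen)),
             modularityQ(net, planted) - 1e-12)
  ## within-block edges dominate between-block edges
  W <- weightMatrix(net)
  beh <- which(unname(itemDomains(net)[net@items]) == "Behavioural")
  oth <- setdiff(seq_len(18), beh)
  within <- mean(W[beh, beh][upper.tri(diag(6))])
  between <- mean(W[beh, oth])
  expect_gt(within, between)
})

test_that("outputs are equivariant under item relabelling", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(2000, spec, seed = 33),
                       scale = builtinScale("AMI"))
  net <- spearmanNetwork(ds)
  cen <- stablePartition(net, nRestarts = 30, seed = 4)

  perm <- c(4, 11, 2, 17, 8, 1, 13, 6, 15, 3, 10, 18, 5, 12, 7, 16, 9, 14)
  W2 <- weightMatrix(net)[perm, perm]
  R2 <- signedCorrelations(net)[perm, perm]
  net2 <- new("SymptomNetwork", items = net@items[perm],
              domain = itemDomains(net)[perm],
              W = W2, signedR = R2, nEffective = net@nEffective)
  cen2 <- stablePartition(net2, nRestarts = 30, seed = 4)
  ## canonical partitions agree after inverse mapping
  m1 <- modalPartition(cen)[perm]
  m2 <- modalPartition(cen2)
  expect_equal(apathynet:::canonicalPartition(m1),
               apathynet:::canonicalPartition(m2))
  ## deterministic statistics permute consistently
  expect_equal(betweenDomainConnectivity(net2),
               betweenDomainConnectivity(net)[perm])
})

test_that("aggregation and pure local-move variants agree on item networks", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(2000, spec, seed = 55),
                       scale = builtinScale("AMI"))
  net <- spearmanNetwork(ds)
  for (s in 1:5) {
    expect_identical(louvainOnce(net, seed = s, multilevel = FALSE),
                     louvainOnce(net, seed = s))
  }
})

test_that("modal share of the planted partition is monotone in the loading", {
  shares <- sapply(c(0.4, 0.55, 0.7), function(lambda) {
    mean(sapply(1:3, function(s) {
      spec <- amiPlantedSpec(lambda, 0.3)
      ds <- simulateCohort(cohortSimSpec(4000, spec, seed = 700 + s),
                           scale = builtinScale("AMI"))
      net <- spearmanNetwork(ds)
      cen <- stablePartition(net, nRestarts = 40, seed = s)
      if (identical(modalPartition(cen), plantedDomainPartition(net)))
        modalShare(cen) else 0
    }))
  })
  expect_true(all(diff(shares) >= 0))
})

test_that("module summaries report purity, central node and domains", {
  net <- twoTriangles()
  summ <- summariseModules(net, rep(1:2, each = 3))
  expect_length(summ, 2)
  expect_equal(summ[[1]]$modalDomain, "A")
  expect_equal(summ[[1]]$purity, 1)
  expect_true(summ[[1]]$centralNode %in% summ[[1]]$members)

  ## mixed module: purity = 4/6, singleton module: purity 1
  doms <- stats::setNames(c(rep("Social", 4), rep("Behavioural", 2), "Emotional"),
                          paste0("I", 1:7))
  W <- matrix(0.5, 7, 7); diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("I", 1:7)
  net2 <- netFromW(W, doms)
  summ2 <- summariseModules(net2, c(rep(1L, 6), 2L))
  expect_equal(summ2[[1]]$purity, 4 / 6)
  expect_equal(summ2[[1]]$modalDomain, "Social")
  expect_equal(summ2[[2]]$purity, 1)
  expect_equal(summ2[[2]]$centralNode, "I7")
})

test_that("between-domain connectivity averages cross-domain weights", {
  doms <- stats::setNames(rep(c("A", "B", "C"), each = 2), paste0("I", 1:6))
  W <- matrix(0.2, 6, 6)
  diag(W) <- 0
  ## make within-domain ties stronger; they must not enter the statistic
  for (b in c(1, 3, 5)) W[b, b + 1] <- W[b + 1, b] <- 0.9
  rownames(W) <- colnames(W) <- paste0("I", 1:6)
  net <- netFromW(W, doms)
  bdc <- betweenDomainConnectivity(net)
  expect_equal(unname(bdc), rep(0.2, 6))

  ## an item uncorrelated with all other-domain items scores 0
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 0.8
  rownames(W2) <- colnames(W2) <- paste0("I", 1:4)
  net2 <- netFromW(W2, stats::setNames(c("A", "A", "B", "B"), paste0("I", 1:4)))
  expect_equal(unname(betweenDomainConnectivity(net2)[1]), 0)
})

test_that("edge sparsification keeps the boundary and carries signs", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.1      # exactly at threshold: retained
  R[1, 3] <- R[3, 1] <- -0.3     # negative: retained with sign
  R[2, 3] <- R[3, 2] <- 0.05     # below: dropped
  W <- abs(R); diag(W) <- 0
  rownames(W) <- colnames(W) <- rownames(R) <- colnames(R) <- paste0("I", 1:3)
  net <- new("SymptomNetwork", items = paste0("I", 1:3),
             domain = stats::setNames(c("A", "A", "B"), paste0("I", 1:3)),
             W = W, signedR = R, nEffective = 50)
  e <- sparseEdges(net)
  expect_equal(nrow(e), 2)
  expect_setequal(e$weight, c(0.1, 0.3))
  expect_equal(e$sign[e$weight == 0.3], "negative")
  ## all weights below threshold: empty list
  expect_equal(nrow(sparseEdges(net, threshold = 0.5)), 0)
})

test_that("GraphML export round-trips through igraph", {
  spec <- amiPlantedSpec(0.7, 0.3)
  ds <- simulateCohort(cohortSimSpec(1000, spec, seed = 61),
                       scale = builtinScale("AMI"))
  net <- spearmanNetwork(ds)
  f <- tempfile(fileext = ".graphml")
  exportGraphML(net, f, partition = rep(1:3, each = 6))
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 18)
  expect_true(all(c("domain", "betweenDomain", "module") %in%
                    igraph::vertex_attr_names(g)))
  expect_true(all(igraph::E(g)$weight >= 0.1))
})
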