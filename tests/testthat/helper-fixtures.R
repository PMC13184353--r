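## Shared fixtures and independent oracles, all built in code.

## network from a bare weight matrix (signed = weights, unit diagonal)
netFromW <- function(W, domain = NULL) {
  if (is.null(rownames(W)))
    rownames(W) <- colnames(W) <- paste0("I", seq_len(nrow(W)))
  if (is.null(domain))
    domain <- stats::setNames(rep("A", nrow(W)), rownames(W))
  R <- W
  diag(R) <- 1
  new("SymptomNetwork", items = rownames(W), domain = domain[rownames(W)],
      W = W, signedR = R, nEffective = 100)
}

## two disconnected unit-weight triangles
twoTriangles <- function() {
  W <- matrix(0, 6, 6)
  tri <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (e in seq_len(3)) {
    W[tri[e, 1], tri[e, 2]] <- W[tri[e, 2], tri[e, 1]] <- 1
    W[tri[e, 1] + 3, tri[e, 2] + 3] <- W[tri[e, 2] + 3, tri[e, 1] + 3] <- 1
  }
  rownames(W) <- colnames(W) <- paste0("I", 1:6)
  netFromW(W, stats::setNames(rep(c("A", "B"), each = 3), rownames(W)))
}

## enumerate all set partitions of n elements as membership vectors
## (restricted-growth strings; Bell(8) = 4140)
enumeratePartitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxUsed) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxUsed + 1L))
      grow(c(prefix, c), max(maxUsed, c))
  }
  grow(integer(), 0L)
  out
}

## exhaustive modularity maximum - the brute-force oracle for small graphs
exhaustiveMaxQ <- function(net) {
  parts <- enumeratePartitions(length(net@items))
  qs <- vapply(parts, function(p) modularityQ(net, p), numeric(1))
  list(maxQ = max(qs), argmax = parts[[which.max(qs)]])
}

## random weighted graph with noisy planted block structure (2-3 blocks,
## strong within-block weights, weak sparse between-block weights) - the
## regime community detection is meant for
randomWeightedGraph <- function(p, seed) {
  set.seed(seed)
  k <- sample(2:3, 1)
  blocks <- sort(rep_len(seq_len(k), p))
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    same <- blocks[i] == blocks[j]
    if (stats::runif(1) < (if (same) 0.9 else 0.4))
      W[i, j] <- W[j, i] <- if (same) stats::runif(1, 0.6, 1)
                            else stats::runif(1, 0, 0.3)
  }
  ## guarantee positive total degree everywhere
  for (i in seq_len(p)) if (sum(W[i, ]) == 0) {
    j <- if (i == 1) 2 else 1
    W[i, j] <- W[j, i] <- stats::runif(1, 0.6, 1)
  }
  rownames(W) <- colnames(W) <- paste0("I", seq_len(p))
  netFromW(W)
}

## AMI item ids ordered into their a-priori domain blocks
amiBlockIds <- function() {
  d <- itemDomains(builtinScale("AMI"))
  names(d)[order(match(d, c("Behavioural", "Social", "Emotional")))]
}

## the planted partition expressed in a network's item order: one community
## per a-priori domain, canonically numbered by first appearance
plantedDomainPartition <- function(net) {
  doms <- unname(itemDomains(net)[net@items])
  match(doms, unique(doms))
}

## an AMI-shaped planted 3-block model (blocks = a-priori domains)
amiPlantedSpec <- function(lambda = 0.7, phi = 0.3) {
  plantedModuleSpec(3, 6, lambda, phi, itemIds = amiBlockIds(),
                    domains = c("Behavioural", "Social", "Emotional"))
}

## independently coded two-way ANOVA with interaction for a BALANCED design
## (textbook sums of squares; equals Type II in the balanced case)
balancedTwoWayAnova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); nTot <- length(y)
  nCell <- nTot / (a * b)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ssA <- b * nCell * sum((mA - grand)^2)
  ssB <- a * nCell * sum((mB - grand)^2)
  ssAB <- nCell * sum((mAB - outer(mA - grand, mB - grand, "+") - grand)^2)
  ssE <- sum((y - mAB[cbind(A, B)])^2)
  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfE <- nTot - a * b
  list(
    FA = (ssA / dfA) / (ssE / dfE),
    FB = (ssB / dfB) / (ssE / dfE),
    FAB = (ssAB / dfAB) / (ssE / dfE),
    dfE = dfE
  )
}

## minimal purity table construction for degenerate-case tests
fakePurityTable <- function(purity, factorOf) {
  structure(list(
    items = data.frame(item = paste0("I", seq_along(purity)),
                       factor = factorOf, purity = purity,
                       communality = 1, excluded = FALSE,
                       stringsAsFactors = FALSE),
    factors = NULL
  ), class = "PurityTable")
}
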