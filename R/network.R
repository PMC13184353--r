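#' @include AllClasses.R cohortIO.R
NULL

## Signed (optionally weighted) Spearman correlation matrix of a
## participants x items matrix.  Mid-ranks are computed per item over the
## participants with positive weight; the correlation is the weighted
## Pearson correlation of the rank columns.  Pairwise deletion for missing
## cells.  Constant (zero rank variance) items get zero correlations with a
## warning.
spearmanMatrix <- function(X, weights = NULL) {
  p <- ncol(X)
  if (is.null(weights)) {
    R <- suppressWarnings(stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  } else {
    keep <- weights > 0
    X <- X[keep, , drop = FALSE]
    w <- weights[keep]
    ranks <- apply(X, 2L, function(col) {
      r <- rep(NA_real_, length(col))
      ok <- !is.na(col)
      r[ok] <- rank(col[ok], ties.method = "average")
      r
    })
    if (!anyNA(ranks)) {
      R <- stats::cov.wt(ranks, wt = w / sum(w), cor = TRUE)$cor
    } else {
      R <- matrix(NA_real_, p, p)
      for (i in seq_len(p)) for (j in i:p) {
        ok <- !is.na(ranks[, i]) & !is.na(ranks[, j])
        if (sum(ok) < 3) next
        ## re-rank over the jointly observed subset, then weighted Pearson
        ri <- rank(X[ok, i], ties.method = "average")
        rj <- rank(X[ok, j], ties.method = "average")
        cw <- stats::cov.wt(cbind(ri, rj), wt = w[ok] / sum(w[ok]), cor = TRUE)
        R[i, j] <- R[j, i] <- cw$cor[1, 2]
      }
      diag(R) <- 1
    }
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  bad <- which(apply(R, 1L, function(r) anyNA(r) | any(!is.finite(r))))
  if (length(bad)) {
    warning("constant item(s), edges set to 0: ",
            paste(colnames(X)[bad], collapse = ", "))
    R[bad, ] <- 0
    R[, bad] <- 0
    diag(R) <- 1
  }
  symmpart2(R)
}

makeNetwork <- function(R, domain, nEffective) {
  W <- abs(R)
  diag(W) <- 0
  W[W > 1] <- 1
  new("SymptomNetwork", items = rownames(R), domain = domain[rownames(R)],
      W = W, signedR = R, nEffective = as.numeric(nEffective))
}

#' Absolute-Spearman symptom network
#'
#' Builds the weighted, undirected item network: nodes are questionnaire
#' items labelled by their a-priori domain, edges are weighted by the
#' absolute Spearman rank correlation between items (robust to the
#' non-normal response distributions typical of Likert scales).  Missing
#' cells are handled by pairwise deletion.  With participant weights the
#' correlation is the weighted Pearson correlation of the per-item
#' mid-ranks, and the network's effective sample size is the Kish
#' \code{(sum w)^2 / sum(w^2)}.
#'
#' @param ds a \linkS4class{CohortDataset}.
#' @param weights optional non-negative per-participant weights.
#' @return a \linkS4class{SymptomNetwork}.
#' @export
spearmanNetwork <- function(ds, weights = NULL) {
  X <- responses(ds)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(X), all(weights >= 0))
    neff <- effectiveN(weights)
    if (neff < 3) stop("fewer than 3 effective participants")
    if (neff < 30) message("low effective sample size: ", round(neff, 1))
  } else {
    neff <- nrow(X)
    if (neff < 3) stop("at least 3 participants required")
  }
  R <- spearmanMatrix(X, weights)
  makeNetwork(R, itemDomains(ds), neff)
}

#' Newman modularity of a partition
#'
#' Exact evaluation of
#' \code{Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)} with
#' \code{A} the absolute-correlation weight matrix, \code{k} the node
#' strengths and \code{m} half the total weight.  The diagonal terms of the
#' degree-product null are included, so the all-in-one partition scores
#' exactly 0 and the all-singletons partition is negative for any graph
#' without self-loops.
#'
#' @param net a \linkS4class{SymptomNetwork} (or a plain symmetric weight
#'   matrix with zero diagonal).
#' @param partition integer community membership vector.
#' @return the modularity Q.
#' @export
modularityQ <- function(net, partition) {
  W <- if (is(net, "SymptomNetwork")) weightMatrix(net) else net
  k <- rowSums(W)
  m2 <- sum(k)                       # 2m
  if (m2 <= 0) stop("network has zero total weight")
  q <- 0
  for (c in unique(partition)) {
    idx <- partition == c
    q <- q + sum(W[idx, idx]) - sum(k[idx])^2 / m2
  }
  q / m2
}

## Canonical form: communities renumbered by first appearance in item order.
canonicalPartition <- function(membership) {
  first <- !duplicated(membership)
  map <- integer(max(membership))
  map[membership[first]] <- seq_len(sum(first))
  as.integer(map[membership])
}

#' One seeded Louvain run
#'
#' Greedy Louvain-style modularity maximisation on the full weighted graph.
#' The local-move phase starts from singleton communities and visits nodes
#' in a seeded random order; each node moves to the neighbouring community
#' with the largest positive modularity gain (ties broken by the lowest
#' community id), with full sweeps repeated until no move improves Q.  By
#' default this alternates with the standard aggregation phase — whole
#' communities are greedily merged while Q improves, then local moves are
#' re-run — until neither phase changes the partition, which is what lets
#' the algorithm escape the split-block optima that pure node moves cannot
#' leave.  Set \code{multilevel = FALSE} for the pure single-pass local
#' variant.  The result is returned in canonical form (communities numbered
#' by first appearance in item order) and always satisfies
#' \code{Q(result) >= Q(singletons)}.
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param seed integer seed controlling the node visit order.
#' @param multilevel include the aggregation (community-merge) phase
#'   (default \code{TRUE}).
#' @return integer membership vector (canonical).
#' @export
louvainOnce <- function(net, seed = 1L, multilevel = TRUE) {
  W <- weightMatrix(net)
  p <- nrow(W)
  if (p < 2) return(rep(1L, p))
  membership <- withSeed(seed, louvainLocal(W, sample.int(p)))
  if (multilevel) {
    ## aggregation pass: greedily merge whole communities while Q improves,
    ## then re-run local moves, until neither phase changes anything
    repeat {
      merged <- mergePhase(W, membership)
      refined <- withSeed(deriveSeed(seed, sum(merged)),
                          louvainLocalFrom(W, sample.int(p), merged))
      if (identical(refined, membership)) break
      membership <- refined
    }
  }
  canonicalPartition(membership)
}

## community-merge phase of the multi-level variant
mergePhase <- function(W, membership) {
  k <- rowSums(W)
  m2 <- sum(k)
  repeat {
    comms <- sort(unique(membership))
    nc <- length(comms)
    if (nc < 2) break
    sigma <- vapply(comms, function(c) sum(k[membership == c]), numeric(1))
    E <- matrix(0, nc, nc)
    for (a in seq_len(nc)) for (b in seq_len(nc))
      E[a, b] <- sum(W[membership == comms[a], membership == comms[b]])
    gain <- 2 * (E / m2 - outer(sigma, sigma) / m2^2)
    diag(gain) <- -Inf
    best <- which.max(gain)
    if (gain[best] <= 1e-12) break
    ij <- arrayInd(best, dim(gain))
    membership[membership == comms[max(ij)]] <- comms[min(ij)]
  }
  membership
}

## local-move phase; `order0` is the sweep visit order
louvainLocal <- function(W, order0) {
  louvainLocalFrom(W, order0, seq_len(nrow(W)))
}

louvainLocalFrom <- function(W, order0, membership) {
  p <- nrow(W)
  k <- rowSums(W)
  m2 <- sum(k)
  sigma <- numeric(p)                # per-community total strength
  for (c in unique(membership)) sigma[c] <- sum(k[membership == c])
  repeat {
    moved <- FALSE
    for (i in order0) {
      ci <- membership[i]
      ## strength from i into each neighbouring community
      wi <- W[i, ]
      comms <- unique(membership[wi > 0])
      if (!length(comms)) next
      kiIn <- vapply(comms, function(c) sum(wi[membership == c]), numeric(1))
      ## gain of moving i from ci to c:
      ##   [k_{i,c} - k_{i,ci\i}]/m - k_i (sigma_c - sigma_{ci\i}) / (2 m^2)
      sigmaNoI <- sigma
      sigmaNoI[ci] <- sigmaNoI[ci] - k[i]
      kiCi <- sum(wi[membership == ci]) # i not included: W[i,i]=0
      base <- -kiCi / (m2 / 2) + k[i] * sigmaNoI[ci] / (m2^2 / 2)
      gains <- kiIn / (m2 / 2) - k[i] * sigmaNoI[comms] / (m2^2 / 2) + base
      gains[comms == ci] <- 0
      best <- max(gains)
      if (best > 1e-12) {
        cand <- comms[gains >= best - 1e-15]
        target <- min(cand)           # deterministic tie-break: lowest id
        sigma[ci] <- sigma[ci] - k[i]
        sigma[target] <- sigma[target] + k[i]
        membership[i] <- target
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  membership
}

#' Restart census and stable partition
#'
#' Runs [louvainOnce()] \code{nRestarts} times with deterministically
#' derived sub-seeds, tabulates the canonical partitions, and returns the
#' most frequently detected partition (the stability criterion used for all
#' downstream module summaries).  Frequency ties are broken by higher mean
#' modularity, then by lexicographic canonical form.
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param nRestarts number of restarts (default 1000).
#' @param seed master seed; sub-seeds are derived deterministically.
#' @param multilevel passed through to [louvainOnce()].
#' @return a \linkS4class{PartitionCensus}.
#' @export
stablePartition <- function(net, nRestarts = 1000, seed = 1L,
                            multilevel = TRUE) {
  stopifnot(nRestarts >= 1)
  keys <- character(nRestarts)
  parts <- list()
  qs <- new.env(parent = emptyenv())
  for (r in seq_len(nRestarts)) {
    part <- louvainOnce(net, seed = deriveSeed(seed, r),
                        multilevel = multilevel)
    key <- paste(part, collapse = ".")
    keys[r] <- key
    if (is.null(parts[[key]])) {
      parts[[key]] <- part
      assign(key, modularityQ(net, part), envir = qs)
    }
  }
  tab <- table(keys)
  counts <- data.frame(key = names(tab), count = as.integer(tab),
                       meanQ = vapply(names(tab), get, numeric(1), envir = qs),
                       stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-counts$count, -counts$meanQ, counts$key)
  counts <- counts[ord, , drop = FALSE]
  modal <- parts[[counts$key[1]]]
  new("PartitionCensus", counts = counts, partitions = parts,
      modal = modal, modalShare = counts$count[1] / nRestarts,
      nRestarts = as.integer(nRestarts))
}

#' Summarise the modules of a partition
#'
#' For every community: its members, the modal a-priori domain (ties go to
#' the central node's domain), the domain purity (fraction of members whose
#' a-priori domain equals the modal domain), each member's intra-modular
#' strength (summed weights to co-members) and the central node (the member
#' with the highest intra-modular strength; ties go to the first item in
#' scale order, with a message).
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param partition integer membership vector over the network's items.
#' @param domainOf optional named domain vector (default: the network's).
#' @return list of per-module lists (class \code{"ModuleSummary"} each) with
#'   elements \code{members}, \code{modalDomain}, \code{purity},
#'   \code{centralNode}, \code{intraStrengths}.
#' @export
summariseModules <- function(net, partition, domainOf = NULL) {
  if (is.null(domainOf)) domainOf <- itemDomains(net)
  W <- weightMatrix(net)
  items <- net@items
  stopifnot(length(partition) == length(items))
  lapply(sort(unique(partition)), function(c) {
    idx <- which(partition == c)
    members <- items[idx]
    strengths <- rowSums(W[idx, idx, drop = FALSE])
    names(strengths) <- members
    topS <- max(strengths)
    topIdx <- which(strengths >= topS - 1e-12)
    if (length(topIdx) > 1)
      message("central-node tie in module ", c, "; first in item order kept")
    central <- members[topIdx[1]]
    doms <- domainOf[members]
    tab <- table(doms)
    topD <- names(tab)[tab == max(tab)]
    modal <- if (length(topD) == 1) topD else unname(domainOf[central])
    structure(list(
      members = members,
      modalDomain = modal,
      purity = unname(tab[modal] / length(members)),
      centralNode = central,
      intraStrengths = strengths
    ), class = "ModuleSummary")
  })
}

#' Between-domain connectivity of items
#'
#' For each item, the mean absolute Spearman correlation with all items
#' whose a-priori domain differs — the bridging statistic used to size
#' nodes in the network figures.
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param domainOf optional named domain vector (default: the network's).
#' @return named numeric vector, one value per item.
#' @export
betweenDomainConnectivity <- function(net, domainOf = NULL) {
  if (is.null(domainOf)) domainOf <- itemDomains(net)
  if (length(unique(domainOf)) < 2)
    stop("at least two domains required")
  W <- weightMatrix(net)
  doms <- domainOf[net@items]
  vapply(seq_along(net@items), function(i) {
    other <- doms != doms[i]
    mean(W[i, other])
  }, numeric(1)) |> stats::setNames(net@items)
}

#' Thresholded edge list for export and visualisation
#'
#' Retains edges with \code{|rho| >= threshold} (default 0.1; the boundary
#' value is kept).  Each edge carries its absolute weight and the sign of
#' the underlying correlation.  This sparsification is for display and
#' export only — community detection always runs on the full weight matrix.
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param threshold minimum absolute correlation (default 0.1).
#' @return data.frame with columns \code{from}, \code{to}, \code{weight},
#'   \code{sign}.
#' @export
sparseEdges <- function(net, threshold = 0.1) {
  W <- weightMatrix(net)
  R <- signedCorrelations(net)
  idx <- which(upper.tri(W) & W >= threshold, arr.ind = TRUE)
  data.frame(
    from = net@items[idx[, 1]],
    to = net@items[idx[, 2]],
    weight = W[idx],
    sign = ifelse(R[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Export a network to GraphML
#'
#' Writes the thresholded network for external viewers, with node
#' attributes (a-priori domain, between-domain connectivity and, if a
#' partition is given, module id) and edge attributes (weight and
#' correlation sign).
#'
#' @param net a \linkS4class{SymptomNetwork}.
#' @param path output file path.
#' @param partition optional membership vector stored as a node attribute.
#' @param threshold edge threshold passed to [sparseEdges()].
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(net, path, partition = NULL, threshold = 0.1) {
  edges <- sparseEdges(net, threshold)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = net@items,
                          domain = unname(itemDomains(net)[net@items])))
  igraph::V(g)$betweenDomain <- unname(betweenDomainConnectivity(net)[net@items])
  if (!is.null(partition)) igraph::V(g)$module <- partition
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
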