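#' @include AllClasses.R network.R
NULL

#' Gaussian age-window weights
#'
#' Kernel weights for a sliding age window:
#' \code{w_i = exp(-(age_i - center)^2 / (2 sigma^2))} for participants
#' within half a window width of the center, and 0 outside.  The defaults
#' follow the lifespan scan design: a 10-year window (half-width 5) weighted
#' by a Gaussian kernel with sigma = 5 years, so the kernel is truncated at
#' the window edge where it has fallen to \code{exp(-1/2)}.
#'
#' @param ages per-participant ages in years.
#' @param center window center age.
#' @param width full window width in years (default 10).
#' @param sigma Gaussian kernel SD in years (default 5).
#' @param truncate if \code{FALSE}, the kernel is not cut at the window
#'   edge (sensitivity option).
#' @return per-participant weights in [0, 1].
#' @export
windowWeights <- function(ages, center, width = 10, sigma = 5,
                          truncate = TRUE) {
  stopifnot(width > 0, sigma > 0)
  w <- exp(-(ages - center)^2 / (2 * sigma^2))
  if (truncate) w[abs(ages - center) > width / 2] <- 0
  w[is.na(ages)] <- 0
  w
}

#' Kish effective sample size
#'
#' \code{ess = (sum w)^2 / sum(w^2)}: equals the count of positive weights
#' when those weights are equal, and shrinks as the weights concentrate.
#' Windows with an effective sample size below 30 are excluded from the
#' lifespan scan.
#'
#' @param weights non-negative weights.
#' @return the effective sample size (0 when all weights are 0).
#' @export
effectiveN <- function(weights) {
  s <- sum(weights)
  if (s <= 0) return(0)
  s^2 / sum(weights^2)
}

#' Kernel-weighted Spearman network
#'
#' Convenience wrapper: [spearmanNetwork()] with participant weights.
#' Per item, mid-ranks are computed over the participants with positive
#' weight, and the network edge is the absolute weighted Pearson
#' correlation of the rank columns.  With uniform weights this reproduces
#' the unweighted Spearman network exactly.
#'
#' @param ds a \linkS4class{CohortDataset}.
#' @param weights non-negative per-participant weights (e.g. from
#'   [windowWeights()]).
#' @return a \linkS4class{SymptomNetwork} with \code{nEffective} set to the
#'   Kish effective sample size.
#' @export
weightedSpearmanNetwork <- function(ds, weights) {
  spearmanNetwork(ds, weights = weights)
}

#' Sliding-window lifespan scan of module structure
#'
#' For every cohort and every window center (1-year increments across the
#' cohort's observed age range): compute Gaussian kernel weights, gate on
#' the Kish effective sample size (windows with ESS < \code{minEss} are
#' excluded), build the weighted Spearman network, select the stable
#' (modal) partition over seeded Louvain restarts, and summarise the
#' modules.  A domain counts as "present" at a center when some module's
#' modal a-priori domain equals it.
#'
#' @param ds a \linkS4class{CohortDataset} with ages.
#' @param width,sigma,step,minEss window parameters (defaults 10, 5, 1, 30).
#' @param nRestarts Louvain restarts per window (default 1000).
#' @param seed master seed; every window derives its own sub-seed.
#' @return list of class \code{"LifespanTrajectory"} with
#'   \code{windows} (data.frame: cohort, center, ess, included, nModules),
#'   \code{modules} (data.frame: cohort, center, module, modalDomain,
#'   purity, centralNode, nItems), \code{purityRecords} (long format for
#'   [purityAnova()]), \code{presence} (data.frame: cohort, center, domain,
#'   present, nModules) and \code{partitions} (named list of membership
#'   vectors).
#' @export
lifespanScan <- function(ds, width = 10, sigma = 5, step = 1, minEss = 30,
                         nRestarts = 1000, seed = 1L) {
  cd <- SummarizedExperiment::colData(ds)
  if (all(is.na(cd$age))) stop("dataset has no ages")
  domains <- unique(unname(itemDomains(ds)))
  windows <- list(); modules <- list(); presence <- list()
  partitions <- list()
  for (coh in unique(cd$cohort)) {
    sub <- ds[, cd$cohort == coh]
    ages <- SummarizedExperiment::colData(sub)$age
    centers <- seq(ceiling(min(ages, na.rm = TRUE)),
                   floor(max(ages, na.rm = TRUE)), by = step)
    for (center in centers) {
      w <- windowWeights(ages, center, width, sigma)
      ess <- effectiveN(w)
      included <- ess >= minEss
      rec <- data.frame(cohort = coh, center = center, ess = ess,
                        included = included, nModules = NA_integer_)
      if (included) {
        net <- spearmanNetwork(sub, weights = w)
        census <- stablePartition(net, nRestarts = nRestarts,
                                  seed = deriveSeed(seed, paste0(coh, center)))
        part <- modalPartition(census)
        partitions[[paste(coh, center, sep = ":")]] <- part
        summ <- summariseModules(net, part)
        rec$nModules <- length(summ)
        modules[[length(modules) + 1L]] <- data.frame(
          cohort = coh, center = center,
          module = seq_along(summ),
          modalDomain = vapply(summ, `[[`, character(1), "modalDomain"),
          purity = vapply(summ, `[[`, numeric(1), "purity"),
          centralNode = vapply(summ, `[[`, character(1), "centralNode"),
          nItems = vapply(summ, function(s) length(s$members), integer(1)),
          modalShare = modalShare(census),
          stringsAsFactors = FALSE)
        modDoms <- vapply(summ, `[[`, character(1), "modalDomain")
        presence[[length(presence) + 1L]] <- data.frame(
          cohort = coh, center = center, domain = domains,
          present = domains %in% modDoms,
          nModules = vapply(domains, function(d) sum(modDoms == d), integer(1)),
          stringsAsFactors = FALSE)
      }
      windows[[length(windows) + 1L]] <- rec
    }
  }
  modules <- if (length(modules)) do.call(rbind, modules) else
    data.frame(cohort = character(), center = numeric(), module = integer(),
               modalDomain = character(), purity = numeric(),
               centralNode = character(), nItems = integer(),
               modalShare = numeric())
  purityRecords <- modules[, c("cohort", "modalDomain", "center", "purity")]
  names(purityRecords)[2] <- "domain"
  structure(list(
    windows = do.call(rbind, windows),
    modules = modules,
    purityRecords = purityRecords,
    presence = if (length(presence)) do.call(rbind, presence) else NULL,
    partitions = partitions
  ), class = "LifespanTrajectory")
}

#' Two-way ANOVA of module purity
#'
#' Fixed-effects two-way ANOVA with interaction of per-window module
#' purities on Group (cohort) and Domain, using Type II sums of squares
#' because the number of included windows differs between cohorts
#' (unbalanced design).  If some Group x Domain cell is empty the
#' interaction is dropped with a warning.
#'
#' @param records long-format data.frame with columns \code{cohort},
#'   \code{domain}, \code{purity} (e.g. a trajectory's
#'   \code{purityRecords}).
#' @return data.frame with one row per effect: \code{effect}, \code{F},
#'   \code{df1}, \code{df2}, \code{p}.
#' @export
purityAnova <- function(records) {
  stopifnot(all(c("cohort", "domain", "purity") %in% names(records)))
  records$cohort <- factor(records$cohort)
  records$domain <- factor(records$domain)
  cells <- table(records$cohort, records$domain)
  hasInteraction <- all(cells >= 2)
  if (!hasInteraction)
    warning("empty or single-observation Group x Domain cell(s); ",
            "interaction term dropped")
  form <- if (hasInteraction) purity ~ cohort * domain else purity ~ cohort + domain
  fit <- stats::lm(form, data = records)
  if (stats::sd(stats::residuals(fit)) < 1e-14 &&
      stats::sd(records$purity) < 1e-14) {
    effects <- c("cohort", "domain", if (hasInteraction) "cohort:domain")
    return(data.frame(effect = c("Group", "Domain",
                                 if (hasInteraction) "Group:Domain"),
                      F = 0, df1 = NA_real_, df2 = NA_real_, p = 1))
  }
  tab <- car::Anova(fit, type = 2)
  rows <- rownames(tab)
  keep <- rows != "Residuals"
  df2 <- tab[rows == "Residuals", "Df"]
  out <- data.frame(
    effect = sub("cohort:domain", "Group:Domain",
                 sub("^domain$", "Domain", sub("^cohort$", "Group",
                                               rows[keep]))),
    F = tab[keep, "F value"],
    df1 = tab[keep, "Df"],
    df2 = df2,
    p = tab[keep, "Pr(>F)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out
}

#' Assessment-mode sensitivity analysis
#'
#' Re-runs the full-cohort network pipeline separately per assessment mode
#' (online / in-person), and reports per mode the restart census and module
#' summaries plus an agreement report between the modal partitions:
#' adjusted-Rand pair agreement and a per-item module-correspondence table
#' that localises any discordantly assigned items.
#'
#' @param ds a \linkS4class{CohortDataset} whose \code{mode} metadata has
#'   at least two levels (modes with fewer than 30 participants are skipped
#'   with a warning).
#' @param nRestarts Louvain restarts per subgroup (default 1000).
#' @param seed master seed.
#' @return list with per-mode entries (\code{census}, \code{modules},
#'   \code{network}) and \code{agreement} (list: \code{adjustedRand},
#'   \code{items} data.frame with per-item module assignments and a
#'   \code{concordant} flag).
#' @export
modeSensitivity <- function(ds, nRestarts = 1000, seed = 1L) {
  cd <- SummarizedExperiment::colData(ds)
  if (!"mode" %in% colnames(cd) || all(is.na(cd$mode)))
    stop("mode metadata required")
  modes <- names(which(table(cd$mode) > 0))
  if (length(modes) < 2) stop("at least two assessment modes required")
  results <- list()
  for (mo in modes) {
    idx <- which(cd$mode == mo)
    if (length(idx) < 30) {
      warning(sprintf("mode '%s' has n = %d < 30; skipped", mo, length(idx)))
      next
    }
    sub <- ds[, idx]
    net <- spearmanNetwork(sub)
    census <- stablePartition(net, nRestarts = nRestarts,
                              seed = deriveSeed(seed, mo))
    results[[mo]] <- list(
      census = census,
      modules = summariseModules(net, modalPartition(census)),
      network = net
    )
  }
  if (length(results) < 2)
    stop("fewer than two modes had enough participants")
  agreement <- NULL
  if (length(results) >= 2) {
    m1 <- names(results)[1]
    m2 <- names(results)[2]
    p1 <- modalPartition(results[[m1]]$census)
    p2 <- modalPartition(results[[m2]]$census)
    ari <- mclust::adjustedRandIndex(p1, p2)
    items <- scaleDef(ds)@items
    ## match modules by maximal overlap, then flag discordant items
    map <- matchModulesByOverlap(p1, p2)
    concordant <- map[p2] == p1
    agreement <- list(
      adjustedRand = ari,
      items = data.frame(item = items,
                         moduleA = p1, moduleB = p2,
                         concordant = concordant,
                         stringsAsFactors = FALSE),
      modes = c(m1, m2)
    )
  }
  c(results, list(agreement = agreement))
}

## greedy max-overlap matching: returns map such that map[b] is the
## partition-A module best matching partition-B module b
matchModulesByOverlap <- function(p1, p2) {
  tab <- table(p2, p1)
  map <- integer(nrow(tab))
  usedA <- logical(ncol(tab))
  for (step in seq_len(min(dim(tab)))) {
    t2 <- tab
    t2[map > 0, ] <- -1
    t2[, usedA] <- -1
    ij <- arrayInd(which.max(t2), dim(tab))
    map[ij[1]] <- as.integer(colnames(tab)[ij[2]])
    usedA[ij[2]] <- TRUE
  }
  map[map == 0] <- NA_integer_
  map
}
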