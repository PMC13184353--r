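#' @include AllClasses.R cohortIO.R
NULL

## Standard-normal quintile cut-points: equal 20% category probabilities,
## which puts simulated scale means mid-range (about 2 on the 0-4 scale).
defaultThresholds <- function(p) {
  matrix(rep(qnorm(c(0.2, 0.4, 0.6, 0.8)), each = p), nrow = p)
}

#' Construct a FactorModelSpec
#'
#' Builds and validates the correlated latent-factor generating model.
#' Residual variances are derived as \code{1 - diag(Lambda Phi t(Lambda))}
#' so that the continuous (pre-discretisation) responses are standardised.
#'
#' @param loadings items x factors matrix Lambda; row names are item ids
#'   (defaults \code{I1..Ip}).
#' @param factorCorr factors x factors correlation matrix Phi (default
#'   identity).
#' @param thresholds items x 4 matrix of strictly increasing cut-points on
#'   the standard-normal scale (default: quintiles, giving equal 20\%
#'   category probabilities).
#' @param domain named character vector of intended domains (default: one
#'   domain label per factor, assigned by primary loading).
#' @return a validated \linkS4class{FactorModelSpec}.
#' @export
factorModelSpec <- function(loadings, factorCorr = NULL, thresholds = NULL,
                            domain = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  if (is.null(rownames(loadings))) rownames(loadings) <- paste0("I", seq_len(p))
  if (is.null(factorCorr)) factorCorr <- diag(ncol(loadings))
  common <- diag(loadings %*% factorCorr %*% t(loadings))
  theta <- 1 - common
  if (any(theta <= 0))
    stop("spec error: residual variance <= 0 (Heywood by construction); ",
         "reduce the loadings or the factor correlations")
  if (is.null(thresholds)) thresholds <- defaultThresholds(p)
  if (is.null(domain)) {
    primary <- apply(abs(loadings), 1L, which.max)
    domain <- stats::setNames(paste0("F", primary), rownames(loadings))
  }
  new("FactorModelSpec", loadings = loadings,
      factorCorr = symmpart2(as.matrix(factorCorr)),
      residualVar = theta,
      thresholds = as.matrix(thresholds),
      domain = domain[rownames(loadings)])
}

#' Block simple-structure generating model
#'
#' Convenience constructor for planted-structure recovery fixtures:
#' \code{kModules} disjoint blocks of \code{itemsPerModule} items, each item
#' loading \code{withinLoading} on its block factor and zero elsewhere, with
#' an equicorrelated factor matrix (off-diagonal \code{betweenCorr}).
#'
#' @param kModules number of factors / planted modules.
#' @param itemsPerModule items per block.
#' @param withinLoading primary loading, in (0, 1).
#' @param betweenCorr common inter-factor correlation.
#' @param itemIds optional item ids (default \code{I1..Ip}).
#' @param domains optional per-factor domain labels (default
#'   \code{F1..Fk}); recycled across the blocks.
#' @param thresholds optional items x 4 threshold matrix.
#' @return a \linkS4class{FactorModelSpec} with block simple structure.
#' @examples
#' spec <- plantedModuleSpec(3, 6, 0.7, 0.3)
#' round(impliedCorrelation(spec)[1:4, 1:4], 3)
#' @export
plantedModuleSpec <- function(kModules, itemsPerModule, withinLoading,
                              betweenCorr = 0, itemIds = NULL,
                              domains = NULL, thresholds = NULL) {
  if (withinLoading <= 0 || withinLoading >= 1)
    stop("spec error: withinLoading must lie in (0, 1)")
  if (abs(betweenCorr) > 1)
    stop("spec error: betweenCorr must be a valid correlation")
  p <- kModules * itemsPerModule
  if (is.null(itemIds)) itemIds <- paste0("I", seq_len(p))
  if (is.null(domains)) domains <- paste0("F", seq_len(kModules))
  L <- matrix(0, p, kModules, dimnames = list(itemIds, domains))
  block <- rep(seq_len(kModules), each = itemsPerModule)
  L[cbind(seq_len(p), block)] <- withinLoading
  Phi <- matrix(betweenCorr, kModules, kModules)
  diag(Phi) <- 1
  factorModelSpec(L, Phi, thresholds = thresholds,
                  domain = stats::setNames(domains[block], itemIds))
}

#' Model-implied item correlation matrix
#'
#' Closed form of the common-factor model:
#' \code{Lambda Phi t(Lambda) + diag(theta)}, which has unit diagonal by
#' construction of the residual variances.
#'
#' @param model a \linkS4class{FactorModelSpec}.
#' @return the items x items implied correlation matrix.
#' @export
impliedCorrelation <- function(model) {
  stopifnot(is(model, "FactorModelSpec"))
  R <- model@loadings %*% model@factorCorr %*% t(model@loadings)
  diag(R) <- diag(R) + model@residualVar
  dimnames(R) <- list(rownames(model@loadings), rownames(model@loadings))
  symmpart2(R)
}

#' Draw continuous or discretised responses from a factor model
#'
#' Samples factor scores from \code{N(0, Phi)}, forms continuous responses
#' \code{y = f t(Lambda) + e} with \code{e ~ N(0, diag(theta))}, and (by
#' default) discretises each item by its thresholds into the 0-4 Likert
#' categories.
#'
#' @param model a \linkS4class{FactorModelSpec}.
#' @param n number of draws.
#' @param seed integer seed (draws are deterministic given the seed).
#' @param discretise if \code{FALSE}, return the continuous standardised
#'   responses instead of Likert categories.
#' @return an n x items numeric matrix.
#' @export
rFactorResponses <- function(model, n, seed, discretise = TRUE) {
  stopifnot(is(model, "FactorModelSpec"), n >= 1)
  withSeed(seed, {
    k <- ncol(model@loadings)
    f <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = model@factorCorr)
    f <- matrix(f, nrow = n)
    eps <- matrix(rnorm(n * nrow(model@loadings)), n) %*%
      diag(sqrt(model@residualVar), nrow(model@loadings))
    y <- f %*% t(model@loadings) + eps
    colnames(y) <- rownames(model@loadings)
    if (!discretise) return(y)
    out <- y
    for (j in seq_len(ncol(y)))
      out[, j] <- findInterval(y[, j], model@thresholds[j, ])
    out
  })
}

#' Cohort simulation specification
#'
#' Bundles the generating model with cohort metadata: sample size, the age
#' law (uniform over a range by default), cohort label and seed.  A list of
#' age-band-specific models can be supplied for non-stationary lifespan
#' fixtures; participants are assigned the model of their age band, so each
#' age window's generating model stays well-defined.
#'
#' @param n number of participants (>= 1).
#' @param model a \linkS4class{FactorModelSpec}, or \code{NULL} when
#'   \code{ageModels} is given.
#' @param ageRange two-element numeric, default \code{c(16, 93)} matching
#'   the study population's span.
#' @param cohortLabel cohort label for all participants.
#' @param mode assessment-mode label(s); recycled.
#' @param seed integer seed.
#' @param ageModels optional named list of \code{list(min=, max=, model=)}
#'   bands partitioning the age range.
#' @return a list of class \code{"CohortSimSpec"}.
#' @export
cohortSimSpec <- function(n, model = NULL, ageRange = c(16, 93),
                          cohortLabel = "HC", mode = "unknown", seed = 1L,
                          ageModels = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(model) && is.null(ageModels))
    stop("either 'model' or 'ageModels' must be given")
  if (!is.null(ageModels)) {
    lims <- t(vapply(ageModels, function(b) c(b$min, b$max), numeric(2)))
    o <- order(lims[, 1])
    lims <- lims[o, , drop = FALSE]
    if (lims[1, 1] > ageRange[1] || lims[nrow(lims), 2] < ageRange[2] ||
        (nrow(lims) > 1 && any(lims[-1, 1] != lims[-nrow(lims), 2])))
      stop("ageModels bands must partition the age range")
  }
  structure(list(n = as.integer(n), model = model, ageRange = ageRange,
                 cohortLabel = cohortLabel, mode = mode,
                 seed = as.integer(seed), ageModels = ageModels),
            class = "CohortSimSpec")
}

#' Simulate an ordinal questionnaire cohort
#'
#' Generates a \linkS4class{CohortDataset} from a correlated latent-factor
#' model: ages are drawn uniformly over the age range (integer years),
#' factor scores and residuals are Gaussian, and continuous responses are
#' discretised by the per-item thresholds.  With age-band models, each
#' participant's responses come from the model of their band.  All draws are
#' deterministic given the spec's seed; sub-streams are derived
#' deterministically so bands reproduce independently.
#'
#' @param spec a \code{CohortSimSpec} from [cohortSimSpec()].
#' @param scale optional \linkS4class{ScaleDefinition}; default is a custom
#'   scale built from the model's items and domains.
#' @return a \linkS4class{CohortDataset}.
#' @examples
#' spec <- cohortSimSpec(200, plantedModuleSpec(3, 6, 0.7, 0.3), seed = 7)
#' ds <- simulateCohort(spec)
#' ds
#' @export
simulateCohort <- function(spec, scale = NULL) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  refModel <- if (!is.null(spec$model)) spec$model else spec$ageModels[[1]]$model
  items <- rownames(refModel@loadings)
  ages <- withSeed(deriveSeed(spec$seed, "ages"), {
    floor(runif(spec$n, spec$ageRange[1], spec$ageRange[2] + 1))
  })
  ages <- pmin(ages, spec$ageRange[2])
  resp <- matrix(NA_real_, spec$n, length(items),
                 dimnames = list(NULL, items))
  if (is.null(spec$ageModels)) {
    resp[, ] <- rFactorResponses(spec$model, spec$n,
                                 seed = deriveSeed(spec$seed, "responses"))
  } else {
    for (bi in seq_along(spec$ageModels)) {
      b <- spec$ageModels[[bi]]
      inBand <- ages >= b$min & ages < b$max
      if (bi == length(spec$ageModels)) inBand <- inBand | ages == b$max
      if (!any(inBand)) next
      resp[inBand, ] <- rFactorResponses(
        b$model, sum(inBand), seed = deriveSeed(spec$seed, paste0("band", bi)))
    }
  }
  if (is.null(scale)) {
    scale <- scaleDefinition(
      name = "custom", items = items, domain = refModel@domain,
      responseMin = 0L, responseMax = 4L)
  }
  cohortDataset(resp, scale, cohort = spec$cohortLabel, age = ages,
                mode = spec$mode)
}
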