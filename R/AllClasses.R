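#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ScaleDefinition: an apathy instrument and its a-priori domain structure
#'
#' Describes one self-report apathy questionnaire: its ordered item
#' identifiers, the a-priori domain of every item, the response range of the
#' Likert scale and the set of reverse-keyed items.  The three instruments
#' analysed throughout the package are the Apathy Motivation Index (AMI,
#' 18 items, Behavioural/Social/Emotional, six items per domain), the Apathy
#' Evaluation Scale (AES, 18 items) and the Dimensional Apathy Scale
#' (DAS, 24 items).
#'
#' @slot name scale identifier ("AMI", "AES", "DAS" or a custom label).
#' @slot items character vector of unique item ids, e.g. \code{"AMI-14"}.
#' @slot domain named character vector mapping every item id to its a-priori
#'   domain label (Behavioural, Social, Emotional, Cognitive, Executive or
#'   Initiation).
#' @slot responseMin,responseMax integer bounds of the Likert response scale
#'   (0 and 4 for the AMI).
#' @slot reverseKeyed character vector (possibly empty) of reverse-keyed
#'   item ids.
#'
#' @seealso [builtinScale()] for the shipped registry entries.
#' @export
setClass("ScaleDefinition",
  representation(
    name = "character",
    items = "character",
    domain = "character",
    responseMin = "integer",
    responseMax = "integer",
    reverseKeyed = "character"
  )
)

setValidity("ScaleDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@items)) msg <- c(msg, "item ids must be unique")
  if (!setequal(names(object@domain), object@items) ||
      length(object@domain) != length(object@items))
    msg <- c(msg, "every item must have exactly one domain label")
  if (length(object@responseMin) != 1L || length(object@responseMax) != 1L ||
      object@responseMin >= object@responseMax)
    msg <- c(msg, "responseMin must be < responseMax")
  if (!all(object@reverseKeyed %in% object@items))
    msg <- c(msg, "reverseKeyed items must be scale items")
  if (identical(object@name, "AMI")) {
    if (length(object@items) != 18L)
      msg <- c(msg, "AMI must have 18 items")
    tab <- table(object@domain)
    need <- c("Behavioural", "Social", "Emotional")
    if (!setequal(names(tab), need) || !all(tab[need] == 6L))
      msg <- c(msg, "AMI must assign 6 items each to Behavioural/Social/Emotional")
  }
  if (identical(object@name, "AES") && length(object@items) != 18L)
    msg <- c(msg, "AES must have 18 items")
  if (identical(object@name, "DAS") && length(object@items) != 24L)
    msg <- c(msg, "DAS must have 24 items")
  if (length(msg)) msg else TRUE
})

#' CohortDataset: participants-by-items ordinal questionnaire responses
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one cohort's item
#' responses.  Items are rows (features) and participants are columns
#' (samples), following the assay convention; the \code{responses()} accessor
#' returns the analysis-oriented participants x items matrix.  Missing
#' responses are stored as \code{NA}.  Per-participant metadata live in
#' \code{colData}: \code{cohort} (HC / Depression / NCD or a diagnosis
#' subgroup), \code{age} in years, and assessment \code{mode} (online /
#' in_person / unknown).
#'
#' @slot scaleDef the \linkS4class{ScaleDefinition} the columns conform to.
#' @slot reverseApplied logical flag; \code{TRUE} once [applyReverseKeys()]
#'   has re-coded the reverse-keyed items (a second application is an error).
#'
#' @export
setClass("CohortDataset",
  contains = "SummarizedExperiment",
  representation(
    scaleDef = "ScaleDefinition",
    reverseApplied = "logical"
  )
)

setValidity("CohortDataset", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assay(object, "responses")
  sc <- object@scaleDef
  if (!identical(rownames(a), sc@items))
    msg <- c(msg, "assay rows must equal the scale's items, in scale order")
  vals <- a[!is.na(a)]
  if (length(vals) && (any(vals < sc@responseMin) || any(vals > sc@responseMax)))
    msg <- c(msg, sprintf("responses must lie in [%d, %d]",
                          sc@responseMin, sc@responseMax))
  cd <- SummarizedExperiment::colData(object)
  need <- c("cohort", "age", "mode")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain cohort, age and mode")
  else if (any(!is.na(cd$age) & cd$age < 0))
    msg <- c(msg, "ages must be non-negative")
  if (length(object@reverseApplied) != 1L)
    msg <- c(msg, "reverseApplied must be a single logical")
  if (length(msg)) msg else TRUE
})

#' FactorModelSpec: a correlated latent-factor generating model
#'
#' Defines the population model used by the synthetic cohort generator: a
#' (typically simple-structure) standardised loading matrix Lambda, an
#' inter-factor correlation matrix Phi, residual variances theta chosen so
#' that the continuous responses have unit variance, and per-item ordered
#' thresholds that discretise the standard-normal-scale response into the
#' 0-4 Likert categories.
#'
#' @slot loadings items x factors matrix Lambda.
#' @slot factorCorr factors x factors matrix Phi (unit diagonal, PSD).
#' @slot residualVar per-item residual variance theta,
#'   \code{theta = 1 - diag(Lambda Phi t(Lambda))}.
#' @slot thresholds items x 4 matrix of strictly increasing cut-points.
#' @slot domain named character vector: intended domain per item.
#'
#' @seealso [plantedModuleSpec()], [impliedCorrelation()], [simulateCohort()]
#' @export
setClass("FactorModelSpec",
  representation(
    loadings = "matrix",
    factorCorr = "matrix",
    residualVar = "numeric",
    thresholds = "matrix",
    domain = "character"
  )
)

setValidity("FactorModelSpec", function(object) {
  msg <- character()
  L <- object@loadings
  Phi <- object@factorCorr
  th <- object@thresholds
  p <- nrow(L)
  if (!isSquareNumeric(Phi) || ncol(Phi) != ncol(L))
    msg <- c(msg, "factorCorr must be square, matching ncol(loadings)")
  else {
    if (max(abs(Phi - t(Phi))) > 1e-8) msg <- c(msg, "factorCorr must be symmetric")
    if (max(abs(diag(Phi) - 1)) > 1e-8) msg <- c(msg, "factorCorr must have unit diagonal")
    if (min(eigen(symmpart2(Phi), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "factorCorr must be positive semidefinite")
  }
  if (length(object@residualVar) != p)
    msg <- c(msg, "residualVar must have one entry per item")
  else if (length(msg) == 0L) {
    common <- diag(L %*% Phi %*% t(L))
    if (max(abs(common + object@residualVar - 1)) > 1e-6)
      msg <- c(msg, "Lambda Phi Lambda' + diag(theta) must have unit diagonal")
    if (any(object@residualVar <= 0))
      msg <- c(msg, "residual variances must be positive (Heywood by construction)")
  }
  if (nrow(th) != p || ncol(th) != 4L)
    msg <- c(msg, "thresholds must be an items x 4 matrix")
  else if (any(apply(th, 1L, function(x) any(diff(x) <= 0))))
    msg <- c(msg, "thresholds must be strictly increasing within item")
  if (!setequal(names(object@domain), rownames(L)))
    msg <- c(msg, "domain must be named by the items")
  if (length(msg)) msg else TRUE
})

#' FactorSolution: an exploratory factor analysis solution
#'
#' Holds the (possibly rotated) pattern loadings, the inter-factor
#' correlation matrix (identity for orthogonal solutions), per-item
#' communalities defined as the sum of squared pattern loadings, the
#' eigenvalues of the analysed correlation matrix, and, for maximum
#' likelihood extraction, the chi-square goodness-of-fit test.
#'
#' @slot pattern items x k loading matrix.
#' @slot factorCorr k x k inter-factor correlation matrix Phi.
#' @slot communality per-item h^2 (sum of squared loadings).
#' @slot eigenvalues eigenvalues of the item correlation matrix, descending.
#' @slot method extraction tag (e.g. "ml").
#' @slot rotation rotation tag ("none", "varimax", "promax").
#' @slot fit list with chi2, df, p for ML extraction (empty otherwise).
#' @slot n sample size used for the fit statistic.
#'
#' @export
setClass("FactorSolution",
  representation(
    pattern = "matrix",
    factorCorr = "matrix",
    communality = "numeric",
    eigenvalues = "numeric",
    method = "character",
    rotation = "character",
    fit = "list",
    n = "numeric"
  )
)

setValidity("FactorSolution", function(object) {
  msg <- character()
  k <- ncol(object@pattern)
  if (k < 1L) msg <- c(msg, "at least one factor required")
  if (!isSquareNumeric(object@factorCorr) || ncol(object@factorCorr) != k)
    msg <- c(msg, "factorCorr must be k x k")
  else if (max(abs(diag(object@factorCorr) - 1)) > 1e-6)
    msg <- c(msg, "factorCorr must have unit diagonal")
  if (length(object@communality) != nrow(object@pattern))
    msg <- c(msg, "one communality per item required")
  else if (any(object@communality < -1e-8) || any(object@communality > 1 + 1e-6))
    msg <- c(msg, "communalities must lie in [0, 1] (up to tolerance)")
  if (length(msg)) msg else TRUE
})

#' SymptomNetwork: an absolute-Spearman item network
#'
#' Nodes are questionnaire items carrying their a-priori domain label; edges
#' are weighted by the absolute Spearman rank correlation between items.
#' The signed correlation matrix is retained for export semantics (positive
#' versus negative associations); community detection always operates on the
#' absolute weights.
#'
#' @slot items ordered item ids.
#' @slot domain named character: a-priori domain per item.
#' @slot W symmetric non-negative weight matrix, zero diagonal,
#'   \code{W = abs(signedR)} off-diagonal.
#' @slot signedR the underlying signed Spearman correlation matrix.
#' @slot nEffective sample size behind the correlations (Kish effective
#'   sample size for kernel-weighted networks).
#'
#' @export
setClass("SymptomNetwork",
  representation(
    items = "character",
    domain = "character",
    W = "matrix",
    signedR = "matrix",
    nEffective = "numeric"
  )
)

setValidity("SymptomNetwork", function(object) {
  msg <- character()
  W <- object@W
  p <- length(object@items)
  if (!isSquareNumeric(W) || nrow(W) != p)
    msg <- c(msg, "W must be items x items")
  else {
    if (max(abs(W - t(W))) > 1e-10) msg <- c(msg, "W must be symmetric")
    if (max(abs(diag(W))) > 0) msg <- c(msg, "W must have zero diagonal")
    if (any(W < 0) || any(W > 1 + 1e-12)) msg <- c(msg, "weights must lie in [0, 1]")
    off <- row(W) != col(W)
    if (max(abs(W[off] - abs(object@signedR[off]))) > 1e-12)
      msg <- c(msg, "W must equal |signedR| off-diagonal")
  }
  if (!setequal(names(object@domain), object@items))
    msg <- c(msg, "domain must be named by the items")
  if (length(msg)) msg else TRUE
})

#' PartitionCensus: restart frequencies of Louvain partitions
#'
#' Tabulates the canonical partitions found over repeated seeded Louvain
#' runs, following the stability criterion of selecting the most frequently
#' detected module partition across restarts.
#'
#' @slot counts data.frame with columns \code{key} (canonical partition
#'   encoding), \code{count}, \code{meanQ}.
#' @slot partitions named list mapping each key to its canonical integer
#'   membership vector.
#' @slot modal canonical membership vector of the modal partition.
#' @slot modalShare fraction of restarts that produced the modal partition.
#' @slot nRestarts number of restarts.
#'
#' @export
setClass("PartitionCensus",
  representation(
    counts = "data.frame",
    partitions = "list",
    modal = "integer",
    modalShare = "numeric",
    nRestarts = "integer"
  )
)

setValidity("PartitionCensus", function(object) {
  msg <- character()
  if (sum(object@counts$count) != object@nRestarts)
    msg <- c(msg, "counts must sum to nRestarts")
  if (length(object@modalShare) != 1L || object@modalShare <= 0 ||
      object@modalShare > 1)
    msg <- c(msg, "modalShare must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CFAModelSpec: the a-priori confirmatory factor model
#'
#' A congeneric confirmatory model: each retained item loads on exactly one
#' factor, factor variances are fixed to 1, loadings and residual variances
#' are free, factor covariances are free, and there are no residual
#' covariances.  The default model is the three-factor AMI structure
#' (Behavioural, Social, Emotional) with items AMI-2, AMI-6 and AMI-8
#' excluded for low indicator reliability.
#'
#' @slot factors ordered factor labels.
#' @slot indicatorOf named character vector mapping each retained item to
#'   its factor.
#' @slot excludedItems items removed before fitting.
#'
#' @seealso [cfaModelSpec()], [modelDf()], [cfaFit()]
#' @export
setClass("CFAModelSpec",
  representation(
    factors = "character",
    indicatorOf = "character",
    excludedItems = "character"
  )
)

setValidity("CFAModelSpec", function(object) {
  msg <- character()
  if (!all(object@indicatorOf %in% object@factors))
    msg <- c(msg, "every indicator must map to a declared factor")
  if (any(names(object@indicatorOf) %in% object@excludedItems))
    msg <- c(msg, "excluded items must not appear as indicators")
  tab <- table(factor(object@indicatorOf, levels = object@factors))
  if (any(tab < 3L))
    msg <- c(msg, "every factor needs at least 3 indicators")
  if (length(msg)) msg else TRUE
})

#' CFAFit: a fitted confirmatory factor model
#'
#' @slot loadings standardised loading per item (named).
#' @slot factorCorr factor correlation matrix.
#' @slot residuals standardised residual variances per item.
#' @slot chi2,df,p the ML chi-square model test.
#' @slot baselineChi2,baselineDf the independence-model test.
#' @slot cfi,tli,rmsea,srmr fit indices; \code{rmseaCI} the 90\% interval.
#' @slot n listwise-complete sample size.
#' @slot converged optimiser convergence flag (gradient-norm criterion).
#'
#' @export
setClass("CFAFit",
  representation(
    loadings = "numeric",
    factorCorr = "matrix",
    residuals = "numeric",
    chi2 = "numeric", df = "numeric", p = "numeric",
    baselineChi2 = "numeric", baselineDf = "numeric",
    cfi = "numeric", tli = "numeric",
    rmsea = "numeric", rmseaCI = "numeric", srmr = "numeric",
    n = "numeric",
    converged = "logical"
  )
)

setValidity("CFAFit", function(object) {
  msg <- character()
  if (object@rmsea < 0) msg <- c(msg, "rmsea must be non-negative")
  if (object@srmr < 0) msg <- c(msg, "srmr must be non-negative")
  if (object@cfi > 1 + 1e-8 || object@tli > 1 + 1e-6) {
    ## TLI may exceed 1 slightly for over-fitting models; CFI is capped
    if (object@cfi > 1 + 1e-8) msg <- c(msg, "cfi must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})
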