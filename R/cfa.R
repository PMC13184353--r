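#' @include AllClasses.R scaleRegistry.R
NULL

#' Construct a confirmatory factor model specification
#'
#' The default is the a-priori three-factor AMI model: Behavioural, Social
#' and Emotional factors with each retained AMI item loading on its a-priori
#' domain factor, and items AMI-2, AMI-6 and AMI-8 excluded for low
#' indicator reliability.  Identification: factor variances fixed to 1, all
#' loadings free, factor covariances free, residual variances free, no
#' residual covariances.
#'
#' @param factors ordered factor labels.
#' @param indicatorOf named character vector: item id to factor label; the
#'   default derives it from the AMI registry domains.
#' @param excludedItems items dropped before fitting.
#' @return a validated \linkS4class{CFAModelSpec}.
#' @examples
#' spec <- cfaModelSpec()
#' modelDf(spec)
#' @export
cfaModelSpec <- function(factors = c("Behavioural", "Social", "Emotional"),
                         indicatorOf = NULL,
                         excludedItems = c("AMI-2", "AMI-6", "AMI-8")) {
  if (is.null(indicatorOf)) {
    ami <- builtinScale("AMI")
    indicatorOf <- itemDomains(ami)
  }
  indicatorOf <- indicatorOf[!names(indicatorOf) %in% excludedItems]
  new("CFAModelSpec", factors = factors, indicatorOf = indicatorOf,
      excludedItems = as.character(excludedItems))
}

#' Degrees of freedom of a confirmatory factor model
#'
#' \code{df = p(p + 1)/2 - (p loadings + p residuals + f(f - 1)/2 factor
#' covariances)}.  The default 15-indicator three-factor AMI model has 87
#' degrees of freedom.
#'
#' @param spec a \linkS4class{CFAModelSpec}.
#' @param p retained item count (default: the number of indicators in
#'   \code{spec}).
#' @return the model degrees of freedom.
#' @export
modelDf <- function(spec, p = length(spec@indicatorOf)) {
  f <- length(spec@factors)
  df <- p * (p + 1) / 2 - (2 * p + f * (f - 1) / 2)
  if (df < 0) stop("model is under-identified (negative degrees of freedom)")
  df
}

## Pack/unpack free parameters: p loadings, p log-residuals, f(f-1)/2
## factor correlations (row-major lower triangle).
cfaSigma <- function(par, p, f, blockIdx) {
  lambda <- par[seq_len(p)]
  theta <- par[p + seq_len(p)]
  phi <- diag(f)
  phi[lower.tri(phi)] <- par[2 * p + seq_len(f * (f - 1) / 2)]
  phi <- phi + t(phi) - diag(f)
  L <- matrix(0, p, f)
  L[cbind(seq_len(p), blockIdx)] <- lambda
  Sigma <- L %*% phi %*% t(L)
  diag(Sigma) <- diag(Sigma) + theta
  list(Sigma = Sigma, L = L, phi = phi, lambda = lambda, theta = theta)
}

cfaObjective <- function(par, R, nItems, nFac, blockIdx, logdetR) {
  m <- cfaSigma(par, nItems, nFac, blockIdx)
  ev <- eigen(symmpart2(m$Sigma), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e6 - 1e4 * min(ev))
  Sinv <- chol2inv(chol(m$Sigma))
  sum(log(ev)) + sum(Sinv * R) - logdetR - nItems
}

cfaGradient <- function(par, R, nItems, nFac, blockIdx, logdetR) {
  m <- cfaSigma(par, nItems, nFac, blockIdx)
  ev <- min(eigen(symmpart2(m$Sigma), symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev < 1e-10) return(rep(0, length(par)))
  Sinv <- chol2inv(chol(m$Sigma))
  G <- Sinv %*% (m$Sigma - R) %*% Sinv  # dF/dSigma
  gL <- 2 * G %*% m$L %*% m$phi         # dF/dLambda (free cells only)
  gLambda <- gL[cbind(seq_len(nItems), blockIdx)]
  gTheta <- diag(G)
  M <- t(m$L) %*% G %*% m$L             # dF/dPhi
  gPhi <- 2 * M[lower.tri(M)]
  c(gLambda, gTheta, gPhi)
}

cfaStartValues <- function(R, p, f, blockIdx, jitterSeed = NULL) {
  lambda <- numeric(p)
  for (b in seq_len(f)) {
    idx <- which(blockIdx == b)
    rr <- R[idx, idx, drop = FALSE]
    mbar <- mean(rr[row(rr) != col(rr)])
    lambda[idx] <- sqrt(min(max(mbar, 0.09), 0.81))
  }
  phi0 <- diag(f)
  for (a in seq_len(f)) for (b in seq_len(f)) if (a > b) {
    cross <- mean(R[blockIdx == a, blockIdx == b])
    phi0[a, b] <- min(max(cross / (lambda[blockIdx == a][1] *
                                   lambda[blockIdx == b][1]), -0.8), 0.8)
  }
  par <- c(lambda, 1 - lambda^2, phi0[lower.tri(phi0)])
  if (!is.null(jitterSeed))
    par <- withSeed(jitterSeed,
                    par + rnorm(length(par), 0, 0.05))
  nphi <- f * (f - 1) / 2
  par[p + seq_len(p)] <- pmax(par[p + seq_len(p)], 0.05)
  par[2 * p + seq_len(nphi)] <- pmin(pmax(par[2 * p + seq_len(nphi)], -0.9), 0.9)
  par
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimises the ML discrepancy
#' \code{F = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p} over the free
#' parameters (one loading and one residual variance per item, free factor
#' correlations, unit factor variances) with an analytic gradient and a
#' seeded jittered-restart ladder on non-convergence.  The analysed matrix
#' is the correlation matrix of the listwise-complete data, so the returned
#' solution is the standardised one; the chi-square statistic uses the
#' multiplier \code{n}.  Residual variances are bounded below at 0.001
#' (Heywood guard) with a warning when the bound is active.
#'
#' @param x a \linkS4class{CohortDataset}, or a covariance/correlation
#'   matrix with item names (then \code{n} is required).
#' @param spec a \linkS4class{CFAModelSpec} (default: the three-factor AMI
#'   model).
#' @param n sample size when \code{x} is a matrix.
#' @return a \linkS4class{CFAFit}.
#' @examples
#' amiSpec <- plantedModuleSpec(3, 6, 0.7, 0.65,
#'   itemIds = paste0("AMI-", c(5, 9, 10, 11, 12, 15, 2, 3, 4, 8, 14, 17,
#'                              1, 6, 7, 13, 16, 18)))
#' R <- impliedCorrelation(amiSpec)
#' fit <- cfaFit(R, cfaModelSpec(excludedItems = character()), n = 1000)
#' round(fit@chi2, 6)
#' @export
cfaFit <- function(x, spec = cfaModelSpec(), n = NULL) {
  if (is(x, "CohortDataset")) {
    X <- responses(x)
    keepItems <- names(spec@indicatorOf)
    miss <- setdiff(keepItems, colnames(X))
    if (length(miss)) stop("dataset lacks indicator(s): ",
                           paste(miss, collapse = ", "))
    X <- X[, keepItems, drop = FALSE]
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    S <- stats::cov(X)
  } else {
    if (is.null(n)) stop("'n' is required when fitting a matrix")
    S <- as.matrix(x)
    keepItems <- names(spec@indicatorOf)
    miss <- setdiff(keepItems, rownames(S))
    if (length(miss)) stop("matrix lacks indicator(s): ",
                           paste(miss, collapse = ", "))
    S <- S[keepItems, keepItems]
  }
  p <- length(keepItems)
  if (n <= p) stop("listwise-complete n must exceed the indicator count")
  R <- cov2cor(symmpart2(S))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sample covariance must be positive definite")
  f <- length(spec@factors)
  blockIdx <- match(spec@indicatorOf, spec@factors)
  logdetR <- determinant(R, logarithm = TRUE)$modulus
  nphi <- f * (f - 1) / 2
  lower <- c(rep(-1.5, p), rep(0.001, p), rep(-0.995, nphi))
  upper <- c(rep(1.5, p), rep(10, p), rep(0.995, nphi))

  fitOnce <- function(start) {
    stats::optim(start, cfaObjective, cfaGradient,
                 R = R, nItems = p, nFac = f, blockIdx = blockIdx,
                 logdetR = logdetR,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 1000, factr = 1e4))
  }
  gradNorm <- function(par) {
    g <- cfaGradient(par, R, p, f, blockIdx, logdetR)
    atBound <- (par <= lower + 1e-10 & g > 0) | (par >= upper - 1e-10 & g < 0)
    max(abs(g[!atBound]), 0)
  }
  opt <- fitOnce(cfaStartValues(R, p, f, blockIdx))
  tries <- 0L
  while ((opt$convergence != 0 || gradNorm(opt$par) > 1e-6) && tries < 5L) {
    tries <- tries + 1L
    opt2 <- fitOnce(cfaStartValues(R, p, f, blockIdx,
                                   jitterSeed = deriveSeed(20260921L, tries)))
    if (opt2$value < opt$value) opt <- opt2
  }
  converged <- opt$convergence == 0 && gradNorm(opt$par) <= 1e-6
  if (opt$convergence != 0 && opt$value > 1e5)
    stop("CFA optimiser failed to converge after the restart ladder")
  m <- cfaSigma(opt$par, p, f, blockIdx)
  if (any(m$theta <= 0.001 + 1e-9))
    warning("Heywood case: residual variance bounded at 0.001")
  ## sign convention: majority-positive loadings per factor
  for (b in seq_len(f)) {
    idx <- which(blockIdx == b)
    if (sum(m$lambda[idx] < 0) > length(idx) / 2) {
      m$lambda[idx] <- -m$lambda[idx]
      m$phi[b, -b] <- -m$phi[b, -b]
      m$phi[-b, b] <- -m$phi[-b, b]
    }
  }
  Fmin <- max(opt$value, 0)
  chi2 <- n * Fmin
  df <- modelDf(spec, p)
  baselineChi2 <- n * (-as.numeric(logdetR))
  baselineDf <- p * (p - 1) / 2
  Sigma <- m$Sigma
  dimnames(Sigma) <- dimnames(R)
  idx <- fitIndices(chi2, df, baselineChi2, baselineDf, n, R, Sigma)
  phi <- m$phi
  dimnames(phi) <- list(spec@factors, spec@factors)
  new("CFAFit",
      loadings = stats::setNames(m$lambda, keepItems),
      factorCorr = phi,
      residuals = stats::setNames(m$theta, keepItems),
      chi2 = chi2, df = df,
      p = stats::pchisq(chi2, df, lower.tail = FALSE),
      baselineChi2 = baselineChi2, baselineDf = baselineDf,
      cfi = idx$cfi, tli = idx$tli,
      rmsea = idx$rmsea, rmseaCI = idx$rmseaCI, srmr = idx$srmr,
      n = n, converged = converged)
}

#' Goodness-of-fit indices for a covariance structure model
#'
#' Computes the standard battery: CFI, TLI, RMSEA with a 90\% confidence
#' interval obtained by root-finding the noncentral chi-square coverage
#' equations, and SRMR over correlation-metric residuals (upper triangle
#' including the diagonal).  The RMSEA denominator uses \code{n},
#' consistent with the chi-square multiplier convention of [cfaFit()].
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param baselineChi2,baselineDf independence-model chi-square and df.
#' @param n sample size.
#' @param S sample covariance (or correlation) matrix.
#' @param Sigma model-implied covariance matrix.
#' @return list with \code{cfi}, \code{tli}, \code{rmsea}, \code{rmseaCI},
#'   \code{srmr}.  With \code{df = 0}, RMSEA and TLI are returned as
#'   \code{NA} (undefined).
#' @export
fitIndices <- function(chi2, df, baselineChi2, baselineDf, n, S, Sigma) {
  dev <- max(chi2 - df, 0)
  devB <- max(baselineChi2 - baselineDf, 0)
  cfi <- 1 - dev / max(devB, dev, .Machine$double.eps)
  if (df > 0) {
    tli <- (baselineChi2 / baselineDf - chi2 / df) /
      max(baselineChi2 / baselineDf - 1, .Machine$double.eps)
    rmsea <- sqrt(dev / (df * n))
    rmseaCI <- rmseaConfInt(chi2, df, n)
  } else {
    tli <- NA_real_
    rmsea <- NA_real_
    rmseaCI <- c(NA_real_, NA_real_)
  }
  Ds <- diag(1 / sqrt(diag(S)), nrow(S))
  Rs <- Ds %*% S %*% Ds
  Rm <- Ds %*% Sigma %*% Ds
  resid <- (Rs - Rm)[upper.tri(Rs, diag = TRUE)]
  srmr <- sqrt(mean(resid^2))
  list(cfi = cfi, tli = tli, rmsea = rmsea, rmseaCI = rmseaCI, srmr = srmr)
}

## 90% CI for RMSEA: solve the noncentral-chi-square coverage equations in
## the noncentrality parameter, bracket [0, 1] on the RMSEA scale, tol 1e-6.
rmseaConfInt <- function(chi2, df, n, level = 0.90) {
  alpha <- (1 - level) / 2
  ncpFromRmsea <- function(eps) eps^2 * df * n
  coverage <- function(eps, target)
    stats::pchisq(chi2, df, ncp = ncpFromRmsea(eps)) - target
  lo <- 0
  if (coverage(0, 1 - alpha) > 0) {   # pchisq(chi2, df) > 0.95
    lo <- stats::uniroot(coverage, c(0, 1), target = 1 - alpha,
                         tol = 1e-6)$root
  }
  hi <- 0
  if (coverage(0, alpha) > 0) {       # pchisq(chi2, df) > 0.05
    hi <- stats::uniroot(coverage, c(0, 1), target = alpha, tol = 1e-6)$root
  }
  c(lo, hi)
}
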