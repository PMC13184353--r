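#' @include AllClasses.R utils.R
NULL

## Ridge-regularise a (near-)singular correlation matrix before inversion,
## then renormalise to unit diagonal.  Logged via message().
ridgeCorr <- function(R, eps = 1e-6) {
  message(sprintf("correlation matrix near-singular; ridge-regularising (+%g I)", eps))
  R <- R + diag(eps, nrow(R))
  cov2cor(R)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of summed squared off-diagonal correlations to the
#' same sum plus the summed squared anti-image partial correlations
#' \code{q_ij = -s_ij / sqrt(s_ii s_jj)} with \code{S = solve(R)}.  Values
#' near 1 indicate the correlation structure is dominated by shared variance
#' and well suited to factoring; values near 0.5 indicate the partial and
#' marginal correlations are comparable and the matrix is unsuitable.
#'
#' @param R item correlation matrix (symmetric, unit diagonal).
#' @return the KMO measure in [0, 1].
#' @export
kmoOverall <- function(R) {
  checkCorrMatrix(R)
  S <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(S) || !all(is.finite(S))) {
    R <- ridgeCorr(R)
    S <- tryCatch(solve(R), error = function(e)
      stop("singular correlation matrix even after ridge regularisation"))
  }
  d <- 1 / sqrt(diag(S))
  Q <- -S * tcrossprod(d)
  off <- row(R) != col(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix differs from the identity:
#' \code{chi2 = -(n - 1 - (2p + 5)/6) * log(det(R))} on
#' \code{p(p - 1)/2} degrees of freedom.  For the combined 60-item
#' AMI + AES + DAS battery the test has 1770 degrees of freedom.
#'
#' @param R item correlation matrix.
#' @param n sample size (must exceed the number of items).
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
bartlettSphericity <- function(R, n) {
  checkCorrMatrix(R)
  p <- nrow(R)
  if (n <= p) stop("sample size must exceed the number of items")
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix must have positive determinant")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser's criterion for factor retention
#'
#' Counts eigenvalues of the full item correlation matrix that are strictly
#' greater than 1.
#'
#' @param x either a numeric vector of eigenvalues (descending) or a
#'   correlation matrix whose eigenvalues are computed.
#' @return the retained factor count.
#' @export
kaiserNFactors <- function(x) {
  ev <- if (is.matrix(x)) eigen(symmpart2(x), symmetric = TRUE,
                                only.values = TRUE)$values else x
  sum(ev > 1)
}

#' Maximum-likelihood factor extraction
#'
#' Fits the unrotated common-factor model by maximum likelihood (minimising
#' the ML discrepancy between the sample correlation matrix and
#' \code{Lambda t(Lambda) + diag(theta)}), with the Bartlett-corrected
#' chi-square goodness-of-fit statistic
#' \code{(n - 1 - (2p + 5)/6 - 2k/3) * F_min} on
#' \code{((p - k)^2 - (p + k))/2} degrees of freedom.  Heywood cases are
#' bounded at a residual variance of 0.005 with a warning.
#'
#' @param R item correlation matrix.
#' @param k number of factors (\code{k < p}).
#' @param n sample size behind \code{R}.
#' @return an unrotated \linkS4class{FactorSolution}.
#' @export
extractML <- function(R, k, n) {
  checkCorrMatrix(R)
  p <- nrow(R)
  if (k >= p) stop("k must be smaller than the number of items")
  if (is.null(rownames(R))) dimnames(R) <- list(paste0("I", seq_len(p)),
                                                paste0("I", seq_len(p)))
  ## multi-start extraction under a private RNG stream so results are a
  ## deterministic function of (R, k, n)
  fa <- tryCatch(
    withSeed(271828L,
             stats::factanal(covmat = R, factors = k, n.obs = n,
                             rotation = "none", control = list(nstart = 3))),
    error = function(e) stop("ML extraction did not converge: ",
                             conditionMessage(e)))
  if (any(fa$uniquenesses <= 0.005 + 1e-12))
    warning("Heywood case: residual variance bounded at 0.005")
  L <- unclass(fa$loadings)
  ev <- eigen(symmpart2(R), symmetric = TRUE, only.values = TRUE)$values
  fit <- list()
  if (!is.null(fa$STATISTIC)) {
    fit <- list(chi2 = unname(fa$STATISTIC), df = unname(fa$dof),
                p = unname(fa$PVAL))
  } else {
    fit <- list(chi2 = NA_real_, df = ((p - k)^2 - (p + k)) / 2, p = NA_real_)
  }
  new("FactorSolution",
      pattern = L,
      factorCorr = diag(k),
      communality = rowSums(L^2),
      eigenvalues = ev,
      method = "ml", rotation = "none",
      fit = fit, n = as.numeric(n))
}

#' Degrees of freedom of the ML factor model test
#'
#' \code{df = ((p - k)^2 - (p + k)) / 2}; for the 60-item battery with five
#' factors this is 1480.
#'
#' @param p number of items.
#' @param k number of factors.
#' @return degrees of freedom.
#' @export
efaModelDf <- function(p, k) ((p - k)^2 - (p + k)) / 2

#' Rotate a factor solution
#'
#' Varimax maximises the row-normalised (Kaiser) varimax criterion and
#' returns an orthogonal solution (\code{Phi = I}).  Promax raises the
#' varimax loadings to \code{promaxPower} (default 4) preserving sign,
#' solves the least-squares target transformation, and returns oblique
#' pattern loadings with the implied inter-factor correlation matrix.
#' Communalities are recomputed as pattern-based sums of squared loadings
#' for the orthogonal case and carried over from the unrotated solution for
#' the oblique case (rotation leaves explained variance unchanged).
#'
#' @param sol an (unrotated) \linkS4class{FactorSolution}.
#' @param method \code{"varimax"} or \code{"promax"}.
#' @param promaxPower integer power for the promax target (default 4).
#' @return the rotated \linkS4class{FactorSolution}.
#' @export
rotateFactors <- function(sol, method = c("promax", "varimax"),
                          promaxPower = 4) {
  method <- match.arg(method)
  L <- sol@pattern
  k <- ncol(L)
  if (k < 2) {
    message("single factor: rotation is the identity")
    return(sol)
  }
  if (method == "varimax") {
    v <- stats::varimax(L)
    P <- unclass(v$loadings)
    out <- new("FactorSolution", pattern = P, factorCorr = diag(k),
               communality = rowSums(P^2), eigenvalues = sol@eigenvalues,
               method = sol@method, rotation = "varimax",
               fit = sol@fit, n = sol@n)
  } else {
    pr <- stats::promax(L, m = promaxPower)
    P <- unclass(pr$loadings)
    Phi <- solve(crossprod(pr$rotmat))
    Phi <- symmpart2(cov2cor(Phi))
    out <- new("FactorSolution", pattern = P, factorCorr = Phi,
               communality = sol@communality, eigenvalues = sol@eigenvalues,
               method = sol@method, rotation = "promax",
               fit = sol@fit, n = sol@n)
  }
  out
}

#' Full exploratory factor analysis of a cohort
#'
#' Convenience wrapper running the complete exploratory sequence on the
#' listwise-complete product-moment correlation matrix of one or more
#' datasets' items: KMO, Bartlett's sphericity test, Kaiser retention
#' (unless \code{k} is given), ML extraction and rotation.
#'
#' @param ds a \linkS4class{CohortDataset}, or a list of datasets over the
#'   same participants whose item columns are combined (e.g. AMI + AES +
#'   DAS).
#' @param k optional factor count override.
#' @param rotation rotation method passed to [rotateFactors()].
#' @param promaxPower promax target power.
#' @return list with \code{solution} (\linkS4class{FactorSolution}),
#'   \code{kmo}, \code{bartlett}, \code{nFactors}, \code{n} (complete
#'   cases), \code{R}.
#' @export
runEFA <- function(ds, k = NULL, rotation = "promax", promaxPower = 4) {
  X <- if (is(ds, "CohortDataset")) responses(ds)
       else do.call(cbind, lapply(ds, responses))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  constant <- apply(X, 2L, function(x) stats::var(x) == 0)
  if (any(constant))
    stop("constant item(s): ", paste(colnames(X)[constant], collapse = ", "))
  R <- stats::cor(X)
  kmo <- kmoOverall(R)
  bart <- bartlettSphericity(R, n)
  nf <- if (is.null(k)) kaiserNFactors(R) else k
  sol <- extractML(R, nf, n)
  if (nf >= 2) sol <- rotateFactors(sol, rotation, promaxPower)
  list(solution = sol, kmo = kmo, bartlett = bart, nFactors = nf,
       n = n, R = R)
}
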