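#' @importFrom methods new validObject is slot
#' @importFrom stats cor pchisq qnorm pnorm rnorm runif uniroot optim
#'   pf pt anova lm aov t.test var sd setNames cov2cor factanal varimax promax
#' @importFrom utils read.table write.table
NULL

## Run expr with a private RNG state so package functions are deterministic
## given their seed argument and never disturb the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic sub-seed derivation (Lehmer-style step, kept < 2^31).
## `salt` may be an integer or a character tag (e.g. a pipeline stage name).
deriveSeed <- function(seed, salt) {
  if (is.character(salt)) salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  a <- 48271
  m <- 2147483647
  s <- (as.double(seed) %% m + 1) # avoid the absorbing state 0
  s <- (s * a) %% m
  s <- (s + as.double(salt) %% m) %% m
  s <- (s * a) %% m
  as.integer(s %% 2147483646 + 1)
}

## symmetrise, guard rounding noise
symmpart2 <- function(M) (M + t(M)) / 2

isSquareNumeric <- function(M) is.matrix(M) && is.numeric(M) && nrow(M) == ncol(M)

checkCorrMatrix <- function(R, what = "R", requireUnitDiag = TRUE, tol = 1e-8) {
  if (!isSquareNumeric(R)) stop(sprintf("'%s' must be a square numeric matrix", what))
  if (max(abs(R - t(R))) > 1e-8) stop(sprintf("'%s' must be symmetric", what))
  if (requireUnitDiag && max(abs(diag(R) - 1)) > tol)
    stop(sprintf("'%s' must have unit diagonal", what))
  invisible(TRUE)
}

## Tucker's congruence coefficient between two loading columns
tuckerCongruence <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

## Greedy column matching of a recovered loading matrix to a target matrix:
## assign each target column the unmatched recovered column with maximal
## absolute congruence, then flip signs so congruence is positive.
matchFactors <- function(recovered, target) {
  k <- ncol(target)
  stopifnot(ncol(recovered) >= k)
  C <- matrix(0, ncol(recovered), k)
  for (i in seq_len(ncol(recovered)))
    for (j in seq_len(k))
      C[i, j] <- tuckerCongruence(recovered[, i], target[, j])
  perm <- integer(k)
  sign <- numeric(k)
  free <- rep(TRUE, ncol(recovered))
  ## assign in order of decreasing |congruence|
  for (step in seq_len(k)) {
    A <- abs(C)
    A[!free, ] <- -Inf
    A[, perm > 0] <- -Inf
    idx <- arrayInd(which.max(A), dim(A))
    perm[idx[2]] <- idx[1]
    sign[idx[2]] <- base::sign(C[idx[1], idx[2]])
    free[idx[1]] <- FALSE
  }
  matched <- recovered[, perm, drop = FALSE] %*% diag(sign, k)
  congr <- vapply(seq_len(k), function(j)
    tuckerCongruence(matched[, j], target[, j]), numeric(1))
  list(loadings = matched, perm = perm, sign = sign, congruence = congr)
}
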