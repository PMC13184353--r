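#' @include AllClasses.R efa.R
NULL

#' Factor purity of items
#'
#' For each item, purity is the squared loading on its designated factor
#' divided by the sum of its squared loadings across all factors (its
#' communality in the squared-loading-sum sense).  A purity approaching 1
#' means the item's explained variance is attributable to a single factor.
#' Per-factor mean purity and its standard error of the mean are computed
#' over member items.
#'
#' @param pattern items x k loading matrix (or a
#'   \linkS4class{FactorSolution}, whose pattern is used).
#' @param assignment optional named vector mapping item id to designated
#'   factor (index or column name).  Default: the factor with the largest
#'   absolute loading.
#' @return list of class \code{"PurityTable"} with \code{items} (data.frame:
#'   item, factor, purity, communality, excluded) and \code{factors}
#'   (data.frame: factor, meanPurity, sem, nItems).
#' @examples
#' P <- rbind(c(0.8, 0), c(0.6, 0.6), c(0.5, 0.3))
#' factorPurity(P)$items
#' @export
factorPurity <- function(pattern, assignment = NULL) {
  if (is(pattern, "FactorSolution")) pattern <- pattern@pattern
  pattern <- as.matrix(pattern)
  p <- nrow(pattern)
  if (is.null(rownames(pattern))) rownames(pattern) <- paste0("I", seq_len(p))
  if (is.null(colnames(pattern))) colnames(pattern) <- paste0("F", seq_len(ncol(pattern)))
  sq <- pattern^2
  h2 <- rowSums(sq)
  if (is.null(assignment)) {
    primary <- apply(abs(pattern), 1L, which.max)
  } else {
    a <- assignment[rownames(pattern)]
    primary <- if (is.numeric(a)) as.integer(a) else match(a, colnames(pattern))
    if (anyNA(primary)) stop("assignment must cover every item with a valid factor")
  }
  excluded <- h2 <= 0
  if (any(excluded))
    warning("item(s) with zero communality excluded from factor means: ",
            paste(rownames(pattern)[excluded], collapse = ", "))
  purity <- ifelse(excluded, NA_real_, sq[cbind(seq_len(p), primary)] / h2)
  items <- data.frame(
    item = rownames(pattern),
    factor = colnames(pattern)[primary],
    purity = purity,
    communality = h2,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  keep <- items[!items$excluded, , drop = FALSE]
  facs <- split(keep$purity, keep$factor)
  factors <- data.frame(
    factor = names(facs),
    meanPurity = vapply(facs, mean, numeric(1)),
    sem = vapply(facs, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    nItems = lengths(facs),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(items = items, factors = factors), class = "PurityTable")
}

## Welch t with a variance floor so zero-variance groups stay finite.
welchT <- function(x, y, varFloor = 1e-12) {
  vx <- max(stats::var(x), varFloor)
  vy <- max(stats::var(y), varFloor)
  nx <- length(x)
  ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

#' Compare per-item purity across factors
#'
#' Runs (i) a one-way ANOVA of item purities across the factor groups and
#' (ii) the planned comparison: a one-sided Welch unequal-variance t-test of
#' whether the focal factor's mean purity exceeds the pooled purity of the
#' remaining items.  Degenerate zero-variance groups are handled with a
#' variance floor of 1e-12 so the statistic stays finite.  Factor groups
#' with fewer than two items are excluded from the ANOVA with a warning.
#'
#' @param purity a \code{"PurityTable"} from [factorPurity()].
#' @param focalFactor the factor label whose coherence is being tested
#'   (e.g. the Social Apathy factor).
#' @return list with \code{anova} (F, df1, df2, p) and \code{welch}
#'   (t, df, p; one-sided, focal > rest).
#' @export
comparePurity <- function(purity, focalFactor) {
  stopifnot(inherits(purity, "PurityTable"))
  items <- purity$items[!purity$items$excluded, , drop = FALSE]
  if (!focalFactor %in% items$factor)
    stop(sprintf("no items designated to factor '%s'", focalFactor))
  sizes <- table(items$factor)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("factor group(s) with < 2 items excluded from the ANOVA: ",
            paste(small, collapse = ", "))
    aovItems <- items[!items$factor %in% small, , drop = FALSE]
  } else aovItems <- items
  g <- factor(aovItems$factor)
  grandVar <- stats::var(aovItems$purity)
  df1 <- nlevels(g) - 1L
  df2 <- nrow(aovItems) - nlevels(g)
  if (is.na(grandVar) || grandVar < 1e-15) {
    an <- list(F = 0, df1 = df1, df2 = df2, p = 1)
  } else {
    fitLm <- stats::lm(purity ~ g, data = aovItems)
    rss <- sum(stats::residuals(fitLm)^2)
    if (rss / df2 < 1e-12 * grandVar) {
      ## groups are perfectly separated: report a degenerate, decisive test
      an <- list(F = Inf, df1 = df1, df2 = df2, p = 0)
    } else {
      tab <- stats::anova(fitLm)
      an <- list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
                 p = tab$`Pr(>F)`[1])
    }
  }
  focal <- items$purity[items$factor == focalFactor]
  rest <- items$purity[items$factor != focalFactor]
  w <- welchT(focal, rest)
  list(anova = an, welch = w)
}
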