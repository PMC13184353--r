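#' @include AllClasses.R
NULL

#' Accessors for apathynet classes
#'
#' Small accessor generics so downstream code never reaches into slots:
#' \code{responses()} returns the participants x items response matrix (with
#' \code{NA} for missing cells), \code{missingMask()} the same-shaped logical
#' mask, \code{scaleDef()} the scale a dataset conforms to,
#' \code{itemDomains()} the named a-priori domain vector,
#' \code{weightMatrix()} / \code{signedCorrelations()} a network's absolute /
#' signed Spearman matrices, and \code{modalPartition()} /
#' \code{modalShare()} the stability-selected partition of a restart census.
#'
#' @param x an apathynet object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("scaleDef", function(x) standardGeneric("scaleDef"))

#' @rdname accessors
#' @export
setGeneric("itemDomains", function(x) standardGeneric("itemDomains"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("signedCorrelations", function(x) standardGeneric("signedCorrelations"))

#' @rdname accessors
#' @export
setGeneric("modalPartition", function(x) standardGeneric("modalPartition"))

#' @rdname accessors
#' @export
setGeneric("modalShare", function(x) standardGeneric("modalShare"))

#' @rdname accessors
#' @export
setMethod("responses", "CohortDataset", function(x) {
  m <- t(SummarizedExperiment::assay(x, "responses"))
  dimnames(m) <- list(colnames(x), rownames(x))
  m
})

#' @rdname accessors
#' @export
setMethod("missingMask", "CohortDataset", function(x)
  is.na(responses(x)))

#' @rdname accessors
#' @export
setMethod("scaleDef", "CohortDataset", function(x) x@scaleDef)

#' @rdname accessors
#' @export
setMethod("itemDomains", "ScaleDefinition", function(x) x@domain)

#' @rdname accessors
#' @export
setMethod("itemDomains", "CohortDataset", function(x) x@scaleDef@domain)

#' @rdname accessors
#' @export
setMethod("itemDomains", "SymptomNetwork", function(x) x@domain)

#' @rdname accessors
#' @export
setMethod("weightMatrix", "SymptomNetwork", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("signedCorrelations", "SymptomNetwork", function(x) x@signedR)

#' @rdname accessors
#' @export
setMethod("modalPartition", "PartitionCensus", function(x) x@modal)

#' @rdname accessors
#' @export
setMethod("modalShare", "PartitionCensus", function(x) x@modalShare)

setMethod("show", "ScaleDefinition", function(object) {
  cat(sprintf("ScaleDefinition '%s': %d items, responses %d-%d\n",
              object@name, length(object@items),
              object@responseMin, object@responseMax))
  tab <- table(object@domain)
  cat("  domains:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (length(object@reverseKeyed))
    cat("  reverse-keyed:", paste(object@reverseKeyed, collapse = ", "), "\n")
})

setMethod("show", "CohortDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("CohortDataset: %d participants x %d %s items\n",
              ncol(object), nrow(object), object@scaleDef@name))
  tab <- table(cd$cohort)
  cat("  cohorts:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  ages <- cd$age[!is.na(cd$age)]
  if (length(ages))
    cat(sprintf("  ages: %.0f-%.0f (mean %.1f)\n", min(ages), max(ages), mean(ages)))
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "responses")))
  cat(sprintf("  missing cells: %d; reverse keys applied: %s\n",
              nmiss, object@reverseApplied))
})

setMethod("show", "FactorModelSpec", function(object) {
  cat(sprintf("FactorModelSpec: %d items, %d factors\n",
              nrow(object@loadings), ncol(object@loadings)))
})

setMethod("show", "FactorSolution", function(object) {
  cat(sprintf("FactorSolution: %d items, %d factors (%s extraction, %s rotation)\n",
              nrow(object@pattern), ncol(object@pattern),
              object@method, object@rotation))
  if (length(object@fit))
    cat(sprintf("  model test: chi2(%d) = %.2f, p = %.3g\n",
                object@fit$df, object@fit$chi2, object@fit$p))
})

setMethod("show", "SymptomNetwork", function(object) {
  cat(sprintf("SymptomNetwork: %d items, n_eff = %.1f, mean |rho| = %.3f\n",
              length(object@items), object@nEffective,
              mean(object@W[row(object@W) != col(object@W)])))
})

setMethod("show", "PartitionCensus", function(object) {
  cat(sprintf("PartitionCensus: %d restarts, %d distinct partitions\n",
              object@nRestarts, nrow(object@counts)))
  cat(sprintf("  modal: %d modules, share %.1f%%\n",
              max(object@modal), 100 * object@modalShare))
})

setMethod("show", "CFAFit", function(object) {
  cat(sprintf("CFAFit: chi2(%d) = %.2f, p = %.3g (n = %d)\n",
              object@df, object@chi2, object@p, object@n))
  cat(sprintf("  CFI = %.3f; TLI = %.3f; RMSEA = %.3f [%.3f, %.3f]; SRMR = %.3f\n",
              object@cfi, object@tli, object@rmsea,
              object@rmseaCI[1], object@rmseaCI[2], object@srmr))
})
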