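#' @include AllClasses.R scaleRegistry.R
NULL

#' Construct a CohortDataset
#'
#' Assembles the participants x items response matrix and per-participant
#' metadata into the package's central container (a
#' \linkS4class{SummarizedExperiment} subclass with items as rows).
#'
#' @param resp participants x items numeric matrix; \code{NA} marks missing
#'   responses.  Columns must be named by the scale's item ids (any order;
#'   they are reordered to scale order).
#' @param scale a \linkS4class{ScaleDefinition}.
#' @param cohort per-participant cohort label (recycled if length 1).
#' @param age per-participant age in years.
#' @param mode per-participant assessment mode (\code{"online"},
#'   \code{"in_person"} or \code{"unknown"}).
#' @param participantIds optional ids (default \code{P1..Pn}).
#' @param reverseApplied logical; set \code{TRUE} if reverse-keyed items have
#'   already been re-coded.
#' @return a validated \linkS4class{CohortDataset}.
#' @export
cohortDataset <- function(resp, scale, cohort = "HC", age = NA_real_,
                          mode = "unknown", participantIds = NULL,
                          reverseApplied = FALSE) {
  resp <- as.matrix(resp)
  if (is.null(colnames(resp)))
    stop("response matrix must have item-id column names")
  missingItems <- setdiff(scale@items, colnames(resp))
  if (length(missingItems))
    stop("missing item column(s): ", paste(missingItems, collapse = ", "))
  resp <- resp[, scale@items, drop = FALSE]
  rownames(resp) <- NULL
  n <- nrow(resp)
  if (is.null(participantIds)) participantIds <- paste0("P", seq_len(n))
  cohort <- rep_len(as.character(cohort), n)
  age <- rep_len(as.numeric(age), n)
  mode <- rep_len(as.character(mode), n)
  bad <- which(!is.na(resp) & (resp < scale@responseMin | resp > scale@responseMax),
               arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop(sprintf(
      "out-of-range response %s at row %d (participant %s), column %s (and %d more)",
      format(resp[b[1], b[2]]), b[1], participantIds[b[1]],
      colnames(resp)[b[2]], nrow(bad) - 1L))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(responses = t(resp)),
    colData = S4Vectors::DataFrame(cohort = cohort, age = age, mode = mode,
                                   row.names = participantIds),
    rowData = S4Vectors::DataFrame(domain = unname(scale@domain[scale@items]),
                                   row.names = scale@items)
  )
  new("CohortDataset", se, scaleDef = scale, reverseApplied = reverseApplied)
}

detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a cohort dataset from delimited text
#'
#' Reads a comma- or tab-delimited UTF-8 file with a header row containing
#' \code{id}, \code{cohort}, \code{age}, optionally \code{mode}, and one
#' column per scale item (any order).  Blank and \code{NA} cells become
#' missing responses; out-of-range responses raise a validation error naming
#' the offending row and column.
#'
#' @param path file path.
#' @param scale the \linkS4class{ScaleDefinition} the columns must match.
#' @return a \linkS4class{CohortDataset} with columns in scale order.
#' @seealso [writeCohort()] for the bit-exact inverse.
#' @export
readCohort <- function(path, scale) {
  sep <- detectSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           encoding = "UTF-8")
  if (!all(c("id", "cohort", "age") %in% colnames(tab)))
    stop("file must have 'id', 'cohort' and 'age' columns")
  missingItems <- setdiff(scale@items, colnames(tab))
  if (length(missingItems))
    stop("schema error: missing item column(s): ",
         paste(missingItems, collapse = ", "))
  resp <- as.matrix(tab[, scale@items, drop = FALSE])
  storage.mode(resp) <- "numeric"
  mode <- if ("mode" %in% colnames(tab)) tab$mode else "unknown"
  mode[is.na(mode)] <- "unknown"
  cohortDataset(resp, scale,
                cohort = tab$cohort, age = tab$age, mode = mode,
                participantIds = as.character(tab$id))
}

#' Write a cohort dataset to delimited text
#'
#' Inverse of [readCohort()]: writes \code{id}, \code{cohort}, \code{age},
#' \code{mode} and the item columns in scale order, with empty cells for
#' missing responses.  A read/write round trip reproduces cell values and
#' missingness exactly.
#'
#' @param ds a \linkS4class{CohortDataset}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(ds, path, sep = "\t") {
  cd <- SummarizedExperiment::colData(ds)
  resp <- responses(ds)
  out <- data.frame(id = rownames(cd), cohort = cd$cohort, age = cd$age,
                    mode = cd$mode, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(resp, check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-code reverse-keyed items
#'
#' Replaces the response on every reverse-keyed item with
#' \code{responseMax - response} so that higher always means more apathetic.
#' The operation is deliberately not idempotent: the dataset carries a flag
#' and a second application raises an error rather than silently undoing
#' the first.
#'
#' @param ds a \linkS4class{CohortDataset}.
#' @return the re-coded dataset with \code{reverseApplied = TRUE}.
#' @export
applyReverseKeys <- function(ds) {
  if (ds@reverseApplied)
    stop("reverse keys were already applied to this dataset")
  sc <- scaleDef(ds)
  a <- SummarizedExperiment::assay(ds, "responses")
  rk <- sc@reverseKeyed
  if (length(rk))
    a[rk, ] <- sc@responseMax - a[rk, ]
  SummarizedExperiment::assay(ds, "responses") <- a
  ds@reverseApplied <- TRUE
  validObject(ds)
  ds
}

#' Subset a cohort dataset by participant
#'
#' @param ds a \linkS4class{CohortDataset}.
#' @param keep logical or integer index over participants.
#' @return the subsetted \linkS4class{CohortDataset}.
#' @export
subsetParticipants <- function(ds, keep) {
  ds[, keep]
}
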