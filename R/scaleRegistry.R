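#' @include AllClasses.R
NULL

registryCache <- new.env(parent = emptyenv())

readRegistry <- function() {
  if (!is.null(registryCache$tab)) return(registryCache$tab)
  path <- system.file("extdata", "scale_registry.tsv", package = "apathynet")
  if (path == "") stop("scale registry file not found")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "", encoding = "UTF-8")
  registryCache$tab <- tab
  tab
}

#' Built-in apathy scale definitions
#'
#' Returns the registry entry for one of the three shipped instruments: the
#' 18-item AMI (six items each in the Behavioural, Social and Emotional
#' domains), the 18-item AES, or the 24-item DAS.  Item-to-domain keys and
#' reverse-key flags are read from the plain-text registry shipped in
#' \code{extdata/scale_registry.tsv}, which can be edited without touching
#' code.  All three scales use a 0-4 Likert response range, coded so that
#' higher (after reverse-keying) means more apathetic.
#'
#' @param name one of \code{"AMI"}, \code{"AES"}, \code{"DAS"}.
#' @return a \linkS4class{ScaleDefinition}.
#' @examples
#' ami <- builtinScale("AMI")
#' table(itemDomains(ami))
#' @export
builtinScale <- function(name) {
  tab <- readRegistry()
  if (!name %in% unique(tab$scale))
    stop(sprintf("unknown scale '%s'; registry defines: %s",
                 name, paste(unique(tab$scale), collapse = ", ")))
  rec <- tab[tab$scale == name, , drop = FALSE]
  scaleDefinition(
    name = name,
    items = rec$item,
    domain = stats::setNames(rec$domain, rec$item),
    responseMin = 0L, responseMax = 4L,
    reverseKeyed = rec$item[rec$reverse == 1]
  )
}

#' Construct a ScaleDefinition
#'
#' @param name scale identifier.
#' @param items ordered character vector of unique item ids.
#' @param domain named character vector mapping item id to domain label.
#' @param responseMin,responseMax integer response bounds.
#' @param reverseKeyed character vector of reverse-keyed item ids.
#' @return a validated \linkS4class{ScaleDefinition}.
#' @export
scaleDefinition <- function(name, items, domain,
                            responseMin = 0L, responseMax = 4L,
                            reverseKeyed = character()) {
  new("ScaleDefinition", name = name, items = as.character(items),
      domain = domain[items],
      responseMin = as.integer(responseMin),
      responseMax = as.integer(responseMax),
      reverseKeyed = as.character(reverseKeyed))
}
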