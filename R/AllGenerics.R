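#' @rdname filterSpecies
#' @export
setGeneric("filterSpecies", function(x, minOccurrence = 5L, ...)
    standardGeneric("filterSpecies"))

#' @rdname relativeComposition
#' @export
setGeneric("relativeComposition", function(x, sample)
    standardGeneric("relativeComposition"))

#' @rdname spearmanSimilarity
#' @export
setGeneric("spearmanSimilarity", function(x, ...)
    standardGeneric("spearmanSimilarity"))

#' @rdname sampleDiversity
#' @export
setGeneric("sampleDiversity", function(x, distances, ...)
    standardGeneric("sampleDiversity"))

#' Species identifiers of an object
#'
#' @param x an object carrying species identifiers.
#' @return character vector of species ids.
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "AbundanceTable", function(x) rownames(x))
#' @rdname speciesIds
#' @export
setMethod("speciesIds", "TrustedNetwork", function(x) x@speciesIds)
#' @rdname speciesIds
#' @export
setMethod("speciesIds", "TraitSpace", function(x) x@speciesIds)
#' @rdname speciesIds
#' @export
setMethod("speciesIds", "SpeciesTraits", function(x) rownames(x@Rstar))
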