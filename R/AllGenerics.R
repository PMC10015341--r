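#' @rdname GeneModel-class
#' @param object,x a `GeneModel`, `SignatureCatalog` or `MutationAttribution`.
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))

#' @rdname GeneModel-class
#' @export
setGeneric("canonicalJunctions", function(x) standardGeneric("canonicalJunctions"))

#' @rdname GeneModel-class
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' @rdname GeneModel-class
#' @param gene gene symbol present in the model.
#' @export
setGeneric("geneStrand", function(x, gene) standardGeneric("geneStrand"))

#' @rdname GeneModel-class
#' @export
setGeneric("donorSites", function(x, gene) standardGeneric("donorSites"))

#' @rdname GeneModel-class
#' @export
setGeneric("acceptorSites", function(x, gene) standardGeneric("acceptorSites"))

#' @rdname SignatureCatalog-class
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @rdname SignatureCatalog-class
#' @export
setGeneric("signatureProbs", function(x) standardGeneric("signatureProbs"))

#' @rdname MutationAttribution-class
#' @export
setGeneric("attributionProbs", function(x) standardGeneric("attributionProbs"))

#' @rdname MutationAttribution-class
#' @export
setGeneric("spliceFlag", function(x) standardGeneric("spliceFlag"))

#' @rdname MutationAttribution-class
#' @export
setGeneric("mutationInfo", function(x) standardGeneric("mutationInfo"))
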