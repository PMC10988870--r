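#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @export
setGeneric("gtStrings", function(x) standardGeneric("gtStrings"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setGeneric("asHaplotypes", function(x, ...) standardGeneric("asHaplotypes"))
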