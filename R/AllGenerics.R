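#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @export
setGeneric("rtime", function(x) standardGeneric("rtime"))

#' @export
setGeneric("spectrumStrain", function(x) standardGeneric("spectrumStrain"))

#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @export
setGeneric("strainsObserved", function(x) standardGeneric("strainsObserved"))

#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @export
setGeneric("referenceStrain", function(x) standardGeneric("referenceStrain"))

#' @export
setGeneric("raFlags", function(x) standardGeneric("raFlags"))

#' @export
setGeneric("bgcPresence", function(x) standardGeneric("bgcPresence"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
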