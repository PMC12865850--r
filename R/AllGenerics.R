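#' @rdname ComboToxDataset-class
#' @param x A package object.
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))

#' @rdname ComboToxDataset-class
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname ComboToxDataset-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname InteractionNetwork-class
#' @param x An \code{InteractionNetwork}.
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("idMap", function(x) standardGeneric("idMap"))

#' @rdname PathwayHierarchy-class
#' @param x A \code{PathwayHierarchy}.
#' @param view One of \code{"lowest"}, \code{"all"}.
#' @export
setGeneric("pathwayView", function(x, view) standardGeneric("pathwayView"))

#' @rdname Fingerprint-class
#' @param x A \code{Fingerprint}.
#' @export
setGeneric("onBits", function(x) standardGeneric("onBits"))
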