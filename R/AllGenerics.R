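#' @rdname ColonySet-accessors
#' @export
setGeneric("diameters", function(object) standardGeneric("diameters"))

#' @rdname ColonySet-accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))

#' @rdname ColonySet-accessors
#' @export
setGeneric("nColonies", function(object) standardGeneric("nColonies"))

#' @rdname ColonySet-accessors
#' @export
setGeneric("rejectedCounts", function(object) standardGeneric("rejectedCounts"))

#' @rdname ColonySet-accessors
#' @export
setGeneric("colonyTable", function(object) standardGeneric("colonyTable"))

#' Shell width implied by the fitted models at a given diameter
#'
#' @param object a [ShellEstimate-class].
#' @param x micro-colony diameter(s) in micrometres.
#' @return shell radial width(s) in micrometres.
#' @export
setGeneric("shellWidth", function(object, x) standardGeneric("shellWidth"))
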