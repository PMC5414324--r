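#' @include AllClasses.R
NULL

#' Accessors for vessel graphs and registration objects
#'
#' Small generic accessors used throughout the package instead of direct slot
#' access.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return \code{nNodes}/\code{nEdges}: counts; \code{nodeIds}: integer ids;
#'   \code{nodeCoords}: an n x dim matrix; \code{nodeRadii}: named numeric;
#'   \code{graphEdges}: a two-column id matrix; \code{graphDim}: 2 or 3;
#'   \code{graphExtent}: per-axis bounding-box lengths (max - min).
#' @name vesselgraph-accessors
#' @aliases nNodes nEdges nodeIds nodeCoords nodeRadii graphEdges graphDim
#'   graphExtent
NULL

#' @rdname vesselgraph-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("nodeRadii", function(x) standardGeneric("nodeRadii"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("graphDim", function(x) standardGeneric("graphDim"))
#' @rdname vesselgraph-accessors
#' @export
setGeneric("graphExtent", function(x) standardGeneric("graphExtent"))

#' @rdname computeNSI
#' @export
setGeneric("nsiValues", function(x) standardGeneric("nsiValues"))

#' Branch accessors
#'
#' @param x a [Branch].
#' @return member ids, anchor id, terminal id, kind string, or the feature
#'   values of the branch.
#' @name branch-accessors
#' @aliases branchNodes branchAnchor branchTerminal branchKind
NULL

#' @rdname branch-accessors
#' @export
setGeneric("branchNodes", function(x) standardGeneric("branchNodes"))
#' @rdname branch-accessors
#' @export
setGeneric("branchAnchor", function(x) standardGeneric("branchAnchor"))
#' @rdname branch-accessors
#' @export
setGeneric("branchTerminal", function(x) standardGeneric("branchTerminal"))
#' @rdname branch-accessors
#' @export
setGeneric("branchKind", function(x) standardGeneric("branchKind"))

#' Voltage sequence accessors
#'
#' @param x a [VoltageSequence].
#' @return \code{voltages}: the complex integrated voltages;
#'   \code{voltageMagnitude}/\code{voltageArgument}: their modulus and
#'   (unwrapped) argument in radians.
#' @name voltage-accessors
#' @aliases voltages voltageMagnitude voltageArgument
NULL

#' @rdname voltage-accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname voltage-accessors
#' @export
setGeneric("voltageMagnitude", function(x) standardGeneric("voltageMagnitude"))
#' @rdname voltage-accessors
#' @export
setGeneric("voltageArgument", function(x) standardGeneric("voltageArgument"))

#' @rdname fuseGraphs
#' @export
setGeneric("fusedNodes", function(x) standardGeneric("fusedNodes"))
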