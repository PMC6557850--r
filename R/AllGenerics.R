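#' Accessor generics
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{numNodes}/\code{numEdges}: integer counts;
#'   \code{nodeLabels}: character vector of node labels in internal order;
#'   \code{asIgraph}: the underlying \code{igraph} object;
#'   \code{scores}/\code{stdErrors}: named numeric vectors;
#'   \code{scoreMethod}: method identifier string;
#'   \code{scoreParams}: named list of method parameters.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname accessors
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))
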