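#' @rdname Topology
#' @param object,x a \linkS4class{Topology} or \linkS4class{Trajectory}.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Topology
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Topology
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname Topology
#' @export
setGeneric("lipidIds", function(x) standardGeneric("lipidIds"))

#' @rdname Topology
#' @export
setGeneric("lipidSpecies", function(x) standardGeneric("lipidSpecies"))

#' @rdname Topology
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname Trajectory
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname Trajectory
#' @export
setGeneric("frameBox", function(x, i) standardGeneric("frameBox"))

#' @rdname Trajectory
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname Trajectory
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
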