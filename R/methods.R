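#' @rdname Topology
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname Topology
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname Topology
#' @export
setMethod("peptideIds", "Topology", function(x) x@peptideIds)

#' @rdname Topology
#' @export
setMethod("lipidIds", "Topology", function(x)
  sort(unique(x@atoms$molecule_id[x@atoms$molecule_kind == "lipid"])))

#' @rdname Topology
#' @export
setMethod("lipidSpecies", "Topology", function(x) x@lipidSpecies)

#' @rdname Topology
#' @export
setMethod("regions", "Topology", function(x) x@regions)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  kinds <- table(factor(a$molecule_kind,
                        levels = c("peptide", "lipid", "water", "ion")))
  nmol <- length(unique(a$molecule_id))
  cat("Topology:", nrow(a), "atoms in", nmol, "molecules\n")
  cat("  peptides:", length(object@peptideIds),
      " lipids:", length(lipidIds(object)), "\n")
  if (length(object@lipidSpecies))
    cat("  lipid composition:",
        paste(sprintf("%s=%d", names(table(object@lipidSpecies)),
                      as.integer(table(object@lipidSpecies))), collapse = " "),
        "\n")
  cat("  atoms by kind:",
      paste(sprintf("%s=%d", names(kinds), as.integer(kinds)), collapse = " "),
      "\n")
  invisible(NULL)
})

#' @rdname Trajectory
#' @param i frame index (1-based).
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname Trajectory
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' @rdname Trajectory
#' @export
setMethod("frameBox", "Trajectory", function(x, i) x@box[i, ])

#' @rdname Trajectory
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@time)

#' @rdname Trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname Trajectory
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname Trajectory
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object), "atoms\n")
  cat("  time [ns]:", format(min(object@time)), "-", format(max(object@time)), "\n")
  cat("  box [A]  :", paste(format(object@box[1, ], digits = 5), collapse = " x "),
      "\n")
  invisible(NULL)
})

#' Subset a trajectory by frame
#'
#' @param x a \linkS4class{Trajectory}.
#' @param i frame indices.
#' @param j,...,drop ignored.
#' @return A \linkS4class{Trajectory} with the selected frames.
#' @export
setMethod("[", "Trajectory", function(x, i, j, ..., drop = FALSE) {
  new("Trajectory", topology = x@topology,
      coords = x@coords[, , i, drop = FALSE],
      box = x@box[i, , drop = FALSE],
      time = x@time[i])
})

setMethod("show", "PeptideRegions", function(object) {
  cat(sprintf("PeptideRegions: N-patch %d-%d | AH core %d-%d | C-patch %d-%d | second half %d-%d\n",
              object@nPatch[1], object@nPatch[2], object@ahCore[1], object@ahCore[2],
              object@cPatch[1], object@cPatch[2], object@secondHalf[1],
              object@secondHalf[2]))
  invisible(NULL)
})
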