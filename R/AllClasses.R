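#' @import methods
NULL

#' Peptide region definitions
#'
#' Holds the residue ranges used throughout the package to partition an
#' extended amphipathic-helix (AH) peptide: the N-terminal patch, the AH core,
#' the C-terminal patch, and the "second half" used by the orientation
#' classifier.  Ranges are 1-based and inclusive on both ends.
#'
#' @slot nPatch integer(2), first/last residue of the N-terminal patch.
#' @slot ahCore integer(2), residue range of the amphipathic-helix core.
#' @slot cPatch integer(2), residue range of the C-terminal patch.
#' @slot secondHalf integer(2), residue range of the peptide second half.
#'
#' @examples
#' PeptideRegions()                       # defaults for the 34-residue peptide
#' PeptideRegions(nPatch = c(1, 8), ahCore = c(9, 26),
#'                cPatch = c(27, 34), secondHalf = c(17, 34))
#' @export
setClass("PeptideRegions",
  representation(
    nPatch = "integer",
    ahCore = "integer",
    cPatch = "integer",
    secondHalf = "integer"
  ),
  prototype(
    nPatch = c(1L, 8L),
    ahCore = c(9L, 26L),
    cPatch = c(27L, 34L),
    secondHalf = c(17L, 34L)
  )
)

setValidity("PeptideRegions", function(object) {
  msg <- character(0)
  for (nm in c("nPatch", "ahCore", "cPatch", "secondHalf")) {
    r <- slot(object, nm)
    if (length(r) != 2L || anyNA(r) || r[1] < 1L || r[2] < r[1])
      msg <- c(msg, sprintf("'%s' must be an increasing 1-based range of length 2", nm))
  }
  if (!length(msg) && object@nPatch[2] >= object@cPatch[1])
    msg <- c(msg, "nPatch must precede cPatch")
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideRegions object
#'
#' @param nPatch,ahCore,cPatch,secondHalf length-2 integer ranges (inclusive).
#'   The defaults correspond to the 34-residue extended AH peptide: N-patch
#'   1-8, AH core 9-26, C-patch 27-34, second half 17-34.
#' @return A \linkS4class{PeptideRegions} object.
#' @export
PeptideRegions <- function(nPatch = c(1L, 8L), ahCore = c(9L, 26L),
                           cPatch = c(27L, 34L), secondHalf = c(17L, 34L)) {
  new("PeptideRegions",
      nPatch = as.integer(nPatch), ahCore = as.integer(ahCore),
      cPatch = as.integer(cPatch), secondHalf = as.integer(secondHalf))
}

#' Molecular topology
#'
#' Static annotation of every atom in a scene: identity, residue, parent
#' molecule and molecule kind, plus per-species lipid metadata (phosphate
#' anchor atom name and tail-chain atom names) and the peptide region
#' definitions.  A \code{Topology} never stores coordinates; those live in a
#' \linkS4class{Trajectory}.
#'
#' @slot atoms data.frame with one row per atom and columns \code{atom_id}
#'   (unique 1-based integer), \code{name}, \code{element}, \code{residue_index}
#'   (1-based within the molecule), \code{residue_name}, \code{molecule_id},
#'   \code{molecule_kind} (one of peptide/lipid/water/ion) and \code{is_heavy}.
#' @slot lipidSpecies named character, species (e.g. "DOPC"/"PLPI") keyed by
#'   lipid molecule id.
#' @slot peptideIds integer, molecule ids of the peptides.
#' @slot phosphateNames named character, phosphate atom name per lipid species.
#' @slot tailAtoms named list, per species a list of tail chains, each a
#'   character vector of at least 3 atom names in chain order.
#' @slot regions \linkS4class{PeptideRegions}.
#' @export
setClass("Topology",
  representation(
    atoms = "data.frame",
    lipidSpecies = "character",
    peptideIds = "integer",
    phosphateNames = "character",
    tailAtoms = "list",
    regions = "PeptideRegions"
  )
)

.topology_cols <- c("atom_id", "name", "element", "residue_index",
                    "residue_name", "molecule_id", "molecule_kind", "is_heavy")

setValidity("Topology", function(object) {
  a <- object@atoms
  msg <- character(0)
  missing_cols <- setdiff(.topology_cols, names(a))
  if (length(missing_cols))
    return(sprintf("atoms is missing columns: %s",
                   paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(a$atom_id))
    msg <- c(msg, "atom_id values must be unique")
  if (!all(a$molecule_kind %in% c("peptide", "lipid", "water", "ion")))
    msg <- c(msg, "molecule_kind must be peptide, lipid, water or ion")
  if (!all(a$is_heavy == (a$element != "H")))
    msg <- c(msg, "is_heavy must equal (element != 'H')")
  ## residue_index non-decreasing within each molecule
  if (nrow(a)) {
    bad <- vapply(split(a$residue_index, a$molecule_id),
                  function(ri) any(diff(ri) < 0), logical(1))
    if (any(bad))
      msg <- c(msg, "residue_index must be non-decreasing within a molecule")
  }
  ## lipids: species known, phosphate present, tails plausible
  lip_ids <- unique(a$molecule_id[a$molecule_kind == "lipid"])
  sp <- object@lipidSpecies
  if (length(lip_ids)) {
    unk <- setdiff(as.character(lip_ids), names(sp))
    if (length(unk))
      msg <- c(msg, sprintf("lipid molecules without species annotation: %s",
                            paste(unk, collapse = ", ")))
    for (id in lip_ids) {
      species <- sp[[as.character(id)]]
      if (is.null(species) || is.na(species)) next
      pname <- object@phosphateNames[[species]]
      rows <- a[a$molecule_id == id, , drop = FALSE]
      if (is.null(pname) || sum(rows$name == pname) != 1L) {
        msg <- c(msg, sprintf(
          "lipid %d (%s) must have exactly one phosphate atom", id, species))
        break
      }
      chains <- object@tailAtoms[[species]]
      if (is.null(chains) || !length(chains) ||
          any(vapply(chains, length, 1L) < 3L)) {
        msg <- c(msg, sprintf(
          "species %s must declare >= 1 tail chain of >= 3 atoms", species))
        break
      }
    }
  }
  pep <- object@peptideIds
  if (length(pep) && !all(pep %in% a$molecule_id[a$molecule_kind == "peptide"]))
    msg <- c(msg, "peptideIds must refer to peptide molecules")
  if (length(msg)) msg else TRUE
})

#' Construct a Topology
#'
#' @param atoms data.frame of per-atom records (see \linkS4class{Topology}).
#'   \code{is_heavy} is derived from \code{element} when absent.
#' @param lipidSpecies named character vector, species by lipid molecule id.
#' @param peptideIds integer vector of peptide molecule ids; defaults to all
#'   molecules of kind "peptide".
#' @param phosphateNames named character, phosphate atom name per species.
#' @param tailAtoms named list of tail chains per species.
#' @param regions a \linkS4class{PeptideRegions}.
#' @return A \linkS4class{Topology}.
#' @export
Topology <- function(atoms, lipidSpecies = character(0),
                     peptideIds = NULL,
                     phosphateNames = c(DOPC = "P", PLPI = "P"),
                     tailAtoms = list(),
                     regions = PeptideRegions()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$is_heavy))
    atoms$is_heavy <- atoms$element != "H"
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  if (is.null(peptideIds))
    peptideIds <- sort(unique(atoms$molecule_id[atoms$molecule_kind == "peptide"]))
  new("Topology", atoms = atoms,
      lipidSpecies = lipidSpecies,
      peptideIds = as.integer(peptideIds),
      phosphateNames = phosphateNames,
      tailAtoms = tailAtoms,
      regions = regions)
}

#' Coordinate trajectory
#'
#' A sequence of frames over a fixed \linkS4class{Topology}.  Coordinates are
#' stored in Angstrom as an atoms x 3 x frames array; boxes are orthorhombic
#' (three box lengths per frame); times are in nanoseconds.
#'
#' @slot topology \linkS4class{Topology}.
#' @slot coords numeric array \code{[nAtoms, 3, nFrames]}, Angstrom.
#' @slot box numeric matrix \code{[nFrames, 3]} of box lengths, Angstrom.
#' @slot time numeric vector of frame times, ns.
#' @export
setClass("Trajectory",
  representation(
    topology = "Topology",
    coords = "array",
    box = "matrix",
    time = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character(0)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an [nAtoms, 3, nFrames] array")
  if (d[1] != nrow(object@topology@atoms))
    msg <- c(msg, "coords atom count must equal topology atom count")
  if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
    msg <- c(msg, "box must be an [nFrames, 3] matrix")
  else if (any(object@box <= 0))
    msg <- c(msg, "box lengths must be positive")
  if (length(object@time) != d[3])
    msg <- c(msg, "time must have one entry per frame")
  else if (any(object@time < 0))
    msg <- c(msg, "frame times must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param topology a \linkS4class{Topology}.
#' @param coords an \code{[nAtoms, 3, nFrames]} array, or an \code{[nAtoms, 3]}
#'   matrix for a single frame (Angstrom).
#' @param box numeric; a length-3 vector recycled across frames, or an
#'   \code{[nFrames, 3]} matrix of orthorhombic box lengths (Angstrom).
#' @param time numeric frame times in ns; defaults to \code{0, dt, 2 dt, ...}
#'   with \code{dt = 1}.
#' @return A \linkS4class{Trajectory}.
#' @export
Trajectory <- function(topology, coords, box, time = NULL) {
  if (is.matrix(coords))
    coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box)))
    box <- matrix(rep(as.numeric(box), length.out = 3L * nf),
                  nrow = nf, ncol = 3L, byrow = TRUE)
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  new("Trajectory", topology = topology, coords = coords,
      box = box, time = as.numeric(time))
}
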