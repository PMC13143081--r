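## Multi-model PDB reader/writer.
##
## The package uses plain multi-model PDB (MODEL/ENDMDL) as its trajectory
## interchange format, with an orthorhombic CRYST1 record for the box.  A
## structured JSON "topology sidecar" carries annotation the PDB cannot
## (molecule kinds, lipid species, phosphate/tail atom names, peptide region
## definitions); the reader reconstructs sensible defaults when no sidecar is
## given.

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.aa1 <- structure(names(.aa3), names = unname(.aa3))

.water_res <- c("HOH", "TIP3", "SOL", "WAT")
.ion_res <- c("SOD", "CLA", "POT", "NA", "CL", "K", "MG", "CA2")

.kind_of_res <- function(resname) {
  ifelse(resname %in% names(.aa3), "peptide",
    ifelse(resname %in% .water_res, "water",
      ifelse(resname %in% .ion_res, "ion", "lipid")))
}

#' Read a (multi-model) PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks into frames over a single topology.  Files
#' without MODEL records yield one frame.  Chains of standard amino-acid
#' residues become one peptide molecule per chain; every non-peptide residue
#' (lipid, water, ion) becomes its own molecule.  Only orthorhombic boxes are
#' supported; a CRYST1 record with any cell angle other than 90 degrees is an
#' unsupported-format error.
#'
#' @param path path to a PDB file.
#' @param sidecar optional path to a topology sidecar JSON written by
#'   \code{\link{writeTopologySidecar}}; supplies phosphate/tail atom names and
#'   peptide regions.
#' @return A \linkS4class{Trajectory}.
#' @seealso \code{\link{writeMultimodelPDB}}
#' @export
readMultimodelPDB <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)

  box <- c(NA_real_, NA_real_, NA_real_)
  ic <- which(rec == "CRYST1")
  if (length(ic)) {
    cl <- lines[ic[1]]
    box <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33)))
    ang <- as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)))
    if (any(abs(ang - 90) > 1e-3))
      stop("unsupported format: triclinic box (cell angles must be 90 degrees)")
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) {
    groups <- list(which(is_atom))
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("structural error: unmatched MODEL/ENDMDL records")
    groups <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  if (!length(groups[[1]])) stop("no ATOM records found in ", path)

  counts <- vapply(groups, length, 1L)
  if (length(unique(counts)) != 1L)
    stop("structural error: models have differing atom counts (",
         paste(counts, collapse = ", "), ")")

  parse_block <- function(idx, with_meta) {
    ll <- lines[idx]
    x <- suppressWarnings(as.numeric(substr(ll, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ll, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ll, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop(sprintf("parse error at line %d: unparseable ATOM record", idx[bad[1]]))
    out <- list(xyz = cbind(x, y, z))
    if (with_meta) {
      out$name <- trimws(substr(ll, 13, 16))
      out$resname <- trimws(substr(ll, 18, 21))
      out$chain <- substr(ll, 22, 22)
      out$resseq <- suppressWarnings(as.integer(substr(ll, 23, 26)))
      if (anyNA(out$resseq))
        stop(sprintf("parse error at line %d: bad residue number",
                     idx[which(is.na(out$resseq))[1]]))
      out$element <- trimws(substr(ll, 77, 78))
      ## fall back on first letter of the atom name when element is absent
      noel <- out$element == ""
      out$element[noel] <- substr(gsub("[^A-Za-z].*$", "", out$name[noel]), 1, 1)
    }
    out
  }

  first <- parse_block(groups[[1]], with_meta = TRUE)
  nat <- length(first$name)
  ## also require identical atom ordering across models
  if (length(groups) > 1L) {
    ref_names <- first$name
    for (g in 2:length(groups)) {
      nm <- trimws(substr(lines[groups[[g]]], 13, 16))
      if (!identical(nm, ref_names))
        stop("structural error: atom ordering differs between models")
    }
  }

  kind <- .kind_of_res(first$resname)
  ## molecule assignment: peptide chains are one molecule; each non-peptide
  ## residue is its own molecule
  mol_key <- ifelse(kind == "peptide",
                    paste0("pep:", first$chain),
                    paste0(kind, ":", first$chain, ":", first$resseq))
  molecule_id <- as.integer(factor(mol_key, levels = unique(mol_key)))
  residue_index <- integer(nat)
  for (m in unique(molecule_id)) {
    sel <- molecule_id == m
    if (kind[sel][1] == "peptide") {
      rs <- first$resseq[sel]
      residue_index[sel] <- rs - min(rs) + 1L
    } else residue_index[sel] <- 1L
  }

  atoms_df <- data.frame(
    atom_id = seq_len(nat),
    name = first$name,
    element = first$element,
    residue_index = residue_index,
    residue_name = first$resname,
    molecule_id = molecule_id,
    molecule_kind = kind,
    is_heavy = first$element != "H",
    stringsAsFactors = FALSE)

  lip_mask <- kind == "lipid"
  lip_map <- character(0)
  phos <- c(DOPC = "P", PLPI = "P")
  tails <- list()
  if (any(lip_mask)) {
    lip_first <- !duplicated(molecule_id) & lip_mask
    lip_map <- structure(first$resname[lip_first],
                         names = as.character(molecule_id[lip_first]))
    for (sp in unique(lip_map)) {
      rows <- atoms_df[atoms_df$molecule_id == as.integer(names(lip_map)[lip_map == sp][1]), ]
      p_at <- rows$name[rows$element == "P"]
      phos[sp] <- if (length(p_at)) p_at[1] else "P"
      tails[[sp]] <- list(grep("^C", rows$name, value = TRUE))
    }
  }

  reg <- PeptideRegions()
  if (!is.null(sidecar)) {
    sc <- readTopologySidecar(sidecar)
    if (!is.null(sc$phosphateNames)) phos <- sc$phosphateNames
    if (!is.null(sc$tailAtoms)) tails <- sc$tailAtoms
    if (!is.null(sc$regions)) reg <- sc$regions
    if (!is.null(sc$lipidSpecies) && length(sc$lipidSpecies) == length(lip_map))
      lip_map <- sc$lipidSpecies
  }

  topo <- Topology(atoms_df, lipidSpecies = lip_map,
                   phosphateNames = phos, tailAtoms = tails, regions = reg)

  nf <- length(groups)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  coords[, , 1] <- first$xyz
  if (nf > 1L)
    for (g in 2:nf) coords[, , g] <- parse_block(groups[[g]], FALSE)$xyz
  if (anyNA(box)) box <- rep(max(apply(coords, 2, max) - apply(coords, 2, min)) + 10, 3)
  Trajectory(topo, coords, box)
}

#' Write a (multi-model) PDB trajectory
#'
#' Writes one MODEL/ENDMDL block per frame with a CRYST1 record carrying the
#' first frame's orthorhombic box.  Coordinates beyond the fixed-width PDB
#' field (|x| > 9999.999) are a formatting error.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMultimodelPDB <- function(traj, path) {
  nf <- nFrames(traj)
  if (nf < 1L) stop("input error: trajectory has no frames")
  if (any(abs(traj@coords) > 9999.999))
    stop("formatting error: coordinate exceeds the PDB fixed-width field")
  a <- atoms(traj)
  chain_pool <- c(LETTERS, letters, 0:9)
  mol_ids <- unique(a$molecule_id)
  pep_mols <- mol_ids[vapply(mol_ids, function(m)
    a$molecule_kind[a$molecule_id == m][1] == "peptide", logical(1))]
  chain <- rep("X", nrow(a))
  for (i in seq_along(pep_mols))
    chain[a$molecule_id == pep_mols[i]] <-
      chain_pool[((i - 1L) %% length(chain_pool)) + 1L]
  resseq <- ifelse(a$molecule_kind == "peptide", a$residue_index, a$molecule_id)
  resseq <- resseq %% 10000L

  con <- file(path, "w")
  on.exit(close(con))
  b <- frameBox(traj, 1)
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  name_field <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
                       sprintf("%-4s", a$name))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , f]
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, name_field, substr(a$residue_name, 1, 4),
      chain, resseq, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read the topology sidecar
#'
#' The sidecar is a JSON file carrying the annotation a PDB cannot express:
#' per-molecule kinds and lipid species, the phosphate anchor atom name per
#' species, tail-chain atom name lists, and the peptide region definitions.
#'
#' @param topology a \linkS4class{Topology}.
#' @param path file path.
#' @return \code{writeTopologySidecar}: invisibly, \code{path}.
#'   \code{readTopologySidecar}: a list with elements \code{lipidSpecies},
#'   \code{phosphateNames}, \code{tailAtoms}, \code{regions}.
#' @export
writeTopologySidecar <- function(topology, path) {
  r <- topology@regions
  obj <- list(
    lipidSpecies = as.list(topology@lipidSpecies),
    phosphateNames = as.list(topology@phosphateNames),
    tailAtoms = topology@tailAtoms,
    regions = list(nPatch = r@nPatch, ahCore = r@ahCore,
                   cPatch = r@cPatch, secondHalf = r@secondHalf))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTopologySidecar
#' @export
readTopologySidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(obj$lipidSpecies))
    out$lipidSpecies <- unlist(obj$lipidSpecies)
  if (!is.null(obj$phosphateNames))
    out$phosphateNames <- unlist(obj$phosphateNames)
  if (!is.null(obj$tailAtoms))
    out$tailAtoms <- lapply(obj$tailAtoms, function(ch)
      if (is.list(ch)) lapply(ch, as.character) else list(as.character(ch)))
  if (!is.null(obj$regions))
    out$regions <- PeptideRegions(obj$regions$nPatch, obj$regions$ahCore,
                                  obj$regions$cPatch, obj$regions$secondHalf)
  out
}
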