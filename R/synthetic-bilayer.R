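## Synthetic planar bilayer generator.
##
## Each lipid is one phosphate bead plus a straight chain of tail beads along
## a single director, so the per-lipid nematic order parameter has the exact
## analytic value (3 cos^2 theta - 1)/2 of its drawn tilt.  Lipids sit on a
## square lattice, which makes the ground-truth area per lipid exactly
## spacing^2.  Both leaflets point their tails toward the midplane.

#' Generate a planar two-leaflet lattice bilayer
#'
#' Places \code{nx * ny} lipids per leaflet on a square lattice of the given
#' spacing, with species assigned DOPC/PLPI at the requested composition
#' (exact counts: floor then fill, positions shuffled deterministically by the
#' seed).  Each lipid is one phosphate bead ("P") plus \code{tailBeads}
#' collinear tail beads ("C1".."Cn", bond length 1.5 A) along a director
#' tilted from the membrane normal by an angle drawn from
#' \code{tiltDistribution}; the azimuth is uniform.
#'
#' @param nx,ny lattice counts per leaflet (\code{nx * ny >= 16}).
#' @param spacing lattice spacing in Angstrom; ground-truth area per lipid is
#'   \code{spacing^2}.
#' @param composition fraction DOPC (default 0.75 for the DOPC:PLPI 75:25
#'   membrane).
#' @param tailBeads number of tail beads per lipid (>= 4).
#' @param tiltDistribution list describing the tilt draw: one of
#'   \code{list(kind = "fixed", theta0 = <deg>)},
#'   \code{list(kind = "gaussian", mean = <deg>, sd = <deg>)} or
#'   \code{list(kind = "isotropic")} (uniform on the hemisphere).
#' @param leafletSeparation distance between the two phosphate planes,
#'   Angstrom.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A single-frame \linkS4class{Trajectory} with box
#'   \code{(nx * spacing, ny * spacing, leafletSeparation + 40)}.  The
#'   \code{"manifest"} attribute records per-lipid tilt angles (degrees), the
#'   analytic per-lipid order parameter, species counts per leaflet and the
#'   ground-truth area per lipid.
#' @examples
#' b <- makeBilayer(nx = 5, ny = 5, seed = 1)
#' attr(b, "manifest")$apl    # 64 for the default 8 A spacing
#' @export
makeBilayer <- function(nx = 8L, ny = 8L, spacing = 8,
                        composition = 0.75, tailBeads = 8L,
                        tiltDistribution = list(kind = "fixed", theta0 = 0),
                        leafletSeparation = 38, seed = 1L) {
  if (nx * ny < 16L) stop("input error: need nx * ny >= 16 lipids per leaflet")
  if (composition < 0 || composition > 1)
    stop("input error: composition must be in [0, 1]")
  if (spacing <= 0) stop("input error: spacing must be positive")
  if (tailBeads < 4L) stop("input error: tailBeads must be >= 4")
  n_leaf <- nx * ny
  rng <- .seeded_rng(seed)

  draw_tilt <- function(n) {
    kind <- tiltDistribution$kind
    if (kind == "fixed") rep(tiltDistribution$theta0, n)
    else if (kind == "gaussian")
      pmin(pmax(stats::rnorm(n, tiltDistribution$mean, tiltDistribution$sd), 0), 90)
    else if (kind == "isotropic") acos(stats::runif(n)) * 180 / pi
    else stop("input error: unknown tilt distribution kind: ", kind)
  }

  ## exact species counts: floor(composition * n) DOPC then fill with PLPI,
  ## order shuffled deterministically by the seed
  n_dopc <- floor(composition * n_leaf)
  species_leaf <- function() {
    sp <- c(rep("DOPC", n_dopc), rep("PLPI", n_leaf - n_dopc))
    sp[sample.int(n_leaf)]
  }

  grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  bond <- 1.5
  z_top <- leafletSeparation / 2

  all_xyz <- NULL
  name <- element <- resname <- character(0)
  mol <- integer(0)
  tilt_all <- numeric(0)
  sp_all <- character(0)
  mol_id <- 0L
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    sp <- species_leaf()
    th <- draw_tilt(n_leaf)
    phi <- stats::runif(n_leaf, 0, 2 * pi)
    for (i in seq_len(n_leaf)) {
      mol_id <- mol_id + 1L
      px <- (grid$ix[i] + 0.5) * spacing
      py <- (grid$iy[i] + 0.5) * spacing
      pz <- sgn * z_top
      tr <- th[i] * pi / 180
      ## director points from headgroup toward the midplane, mirrored between
      ## leaflets; tail bond vectors all share it, so the per-lipid order
      ## parameter is exactly (3 cos^2 theta - 1)/2
      dirv <- c(sin(tr) * cos(phi[i]), sin(tr) * sin(phi[i]), -sgn * cos(tr))
      beads <- t(sapply(seq_len(tailBeads),
                        function(k) c(px, py, pz) + k * bond * dirv))
      all_xyz <- rbind(all_xyz, c(px, py, pz), beads)
      name <- c(name, "P", paste0("C", seq_len(tailBeads)))
      element <- c(element, "P", rep("C", tailBeads))
      resname <- c(resname, rep(sp[i], tailBeads + 1L))
      mol <- c(mol, rep(mol_id, tailBeads + 1L))
      tilt_all <- c(tilt_all, th[i])
      sp_all <- c(sp_all, sp[i])
    }
  }
  .restore_rng(rng)

  atoms_df <- data.frame(
    atom_id = seq_len(nrow(all_xyz)),
    name = name, element = element,
    residue_index = 1L, residue_name = resname,
    molecule_id = mol, molecule_kind = "lipid",
    is_heavy = TRUE, stringsAsFactors = FALSE)
  lip_map <- structure(sp_all, names = as.character(seq_len(2L * n_leaf)))
  tails <- list(DOPC = list(paste0("C", seq_len(tailBeads))),
                PLPI = list(paste0("C", seq_len(tailBeads))))
  topo <- Topology(atoms_df, lipidSpecies = lip_map,
                   phosphateNames = c(DOPC = "P", PLPI = "P"),
                   tailAtoms = tails)
  box <- c(nx * spacing, ny * spacing, leafletSeparation + 40)
  traj <- Trajectory(topo, all_xyz, box)
  attr(traj, "manifest") <- list(
    apl = spacing^2,
    tilt_deg = tilt_all,
    order_parameter = (3 * cos(tilt_all * pi / 180)^2 - 1) / 2,
    species = sp_all,
    counts_per_leaflet = c(DOPC = n_dopc, PLPI = n_leaf - n_dopc),
    leaflet_separation = leafletSeparation)
  traj
}

## Seed the RNG for a generator call and restore the caller's state after.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Merge a peptide trajectory into a bilayer scene
#'
#' Places the peptide at a given height above the bilayer midplane and
#' concatenates topologies (atom ids and molecule ids are renumbered).
#' Single-frame inputs only.
#'
#' @param bilayer,peptide single-frame \linkS4class{Trajectory} objects.
#' @param zOffset height (Angstrom) of the peptide Calpha centroid above the
#'   bilayer midplane.
#' @param xyCenter optional length-2 XY position for the peptide centroid;
#'   defaults to the box centre.
#' @return A single-frame \linkS4class{Trajectory} with the bilayer box.
#' @export
mergeScene <- function(bilayer, peptide, zOffset = 30, xyCenter = NULL) {
  stopifnot(nFrames(bilayer) == 1L, nFrames(peptide) == 1L)
  bt <- topology(bilayer); pt <- topology(peptide)
  bx <- frameCoords(bilayer, 1); px <- frameCoords(peptide, 1)
  box <- frameBox(bilayer, 1)
  if (is.null(xyCenter)) xyCenter <- box[1:2] / 2
  midz <- mean(bx[bt@atoms$name == unname(bt@phosphateNames[1]), 3])
  ctr <- colMeans(px)
  px <- sweep(px, 2, ctr)
  px[, 1] <- px[, 1] + xyCenter[1]
  px[, 2] <- px[, 2] + xyCenter[2]
  px[, 3] <- px[, 3] + midz + zOffset
  pa <- pt@atoms
  ba <- bt@atoms
  pa$atom_id <- pa$atom_id + max(ba$atom_id)
  mol_shift <- max(ba$molecule_id)
  pa$molecule_id <- pa$molecule_id + mol_shift
  topo <- Topology(rbind(ba, pa),
                   lipidSpecies = bt@lipidSpecies,
                   phosphateNames = bt@phosphateNames,
                   tailAtoms = bt@tailAtoms,
                   regions = pt@regions)
  Trajectory(topo, rbind(bx, px), box)
}
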