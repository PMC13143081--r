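## Leaflet assignment, area-per-lipid maps, lipid-tail nematic order.
##
## Area per lipid uses an exact periodic 2D Voronoi tessellation of the
## phosphate XY positions: every seed's cell is obtained by half-plane
## clipping against the bisectors to all other seeds and all 8 periodic
## images, so per-lipid areas partition the box exactly (the conservation
## invariant is asserted on every call).  No installed R package provides a
## periodic Voronoi, hence the in-package implementation; `deldir` serves as
## an independent oracle in the tests.

## Sutherland-Hodgman clip of polygon P (k x 2) by half-plane
## dot(x - m, u) <= 0.
.clip_halfplane <- function(P, m, u) {
  k <- nrow(P)
  d <- (P[, 1] - m[1]) * u[1] + (P[, 2] - m[2]) * u[2]
  inside <- d <= 0
  if (all(inside)) return(P)
  if (!any(inside)) return(NULL)
  out <- matrix(NA_real_, k + 4L, 2L)
  n_out <- 0L
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) {
      n_out <- n_out + 1L
      out[n_out, ] <- P[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      n_out <- n_out + 1L
      out[n_out, ] <- P[i, ] + t * (P[j, ] - P[i, ])
    }
  }
  out[seq_len(n_out), , drop = FALSE]
}

.polygon_area <- function(P) {
  if (is.null(P) || nrow(P) < 3L) return(0)
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Periodic Voronoi cell areas for seeds xy (n x 2) in an Lx x Ly box.
## Returns list(areas, cells).  Coincident seeds are perturbed by 1e-6 A
## with a warning (the tessellation is undefined otherwise).
.periodic_voronoi <- function(xy, box_xy) {
  n <- nrow(xy)
  xy[, 1] <- xy[, 1] %% box_xy[1]
  xy[, 2] <- xy[, 2] %% box_xy[2]
  if (anyDuplicated(round(xy, 6))) {
    warning("coincident XY seeds perturbed by 1e-6 A")
    dup <- duplicated(round(xy, 6))
    xy[dup, ] <- xy[dup, ] + 1e-6 * seq_len(sum(dup))
  }
  shifts <- as.matrix(expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1)))
  img <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    cbind(xy[, 1] + shifts[s, 1] * box_xy[1],
          xy[, 2] + shifts[s, 2] * box_xy[2])))
  central <- which(shifts[, 1] == 0 & shifts[, 2] == 0)
  half <- max(box_xy)
  areas <- numeric(n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    s <- xy[i, ]
    P <- cbind(s[1] + c(-half, half, half, -half),
               s[2] + c(-half, -half, half, half))
    self_row <- (central - 1L) * n + i
    d2 <- (img[, 1] - s[1])^2 + (img[, 2] - s[2])^2
    ord <- order(d2)
    ord <- ord[ord != self_row]
    for (j in ord) {
      dj <- sqrt(d2[j])
      vmax2 <- max((P[, 1] - s[1])^2 + (P[, 2] - s[2])^2)
      if (dj / 2 > sqrt(vmax2)) break  # bisector cannot cut the cell
      m <- (s + img[j, ]) / 2
      u <- img[j, ] - s
      P <- .clip_halfplane(P, m, u)
      if (is.null(P)) break
    }
    areas[i] <- .polygon_area(P)
    cells[[i]] <- P
  }
  list(areas = areas, cells = cells)
}

#' Assign lipids to leaflets
#'
#' Leaflet by the sign of the phosphate z relative to the global phosphate
#' mean; the midplane is the mean of the two leaflet means.
#'
#' @param traj a \linkS4class{Trajectory} with lipids.
#' @param frame frame index.
#' @return A list of class \code{LeafletAssignment}: \code{leaflet} (named
#'   character "upper"/"lower" by lipid molecule id), \code{midplane_z}
#'   (Angstrom).  Degenerate single-leaflet systems give a warning.
#' @export
assignLeaflets <- function(traj, frame = 1L) {
  topo <- topology(traj)
  a <- atoms(traj)
  lids <- lipidIds(topo)
  if (length(lids) < 2L) stop("input error: need at least 2 lipids")
  x <- frameCoords(traj, frame)
  pz <- vapply(lids, function(id) {
    sp <- topo@lipidSpecies[[as.character(id)]]
    sel <- a$molecule_id == id & a$name == topo@phosphateNames[[sp]]
    x[sel, 3][1]
  }, numeric(1))
  gm <- mean(pz)
  leaf <- ifelse(pz > gm, "upper", "lower")
  if (length(unique(leaf)) == 1L) {
    warning("degenerate bilayer: all lipids on one side of the phosphate mean")
    midplane <- gm
  } else {
    midplane <- mean(c(mean(pz[leaf == "upper"]), mean(pz[leaf == "lower"])))
  }
  structure(list(leaflet = structure(leaf, names = as.character(lids)),
                 phosphate_z = structure(pz, names = as.character(lids)),
                 midplane_z = midplane),
            class = "LeafletAssignment")
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Tessellates the phosphate XY positions of one leaflet with a periodic 2D
#' Voronoi diagram; each lipid's area is its cell area, and the areas
#' partition the box XY area exactly.  Optionally, peptide heavy atoms lying
#' in the leaflet band can be inserted as area-excluding seeds whose cells
#' are discarded (off by default; the conservation invariant then no longer
#' holds and is not asserted).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param leaflet "upper" or "lower".
#' @param binSize raster bin size in Angstrom for the plotting grid.
#' @param peptideSeeds logical; include peptide heavy atoms in the leaflet
#'   band as excluded seeds.
#' @param bandWidth half-width (Angstrom) of the leaflet band around the
#'   leaflet phosphate plane used to select peptide seed atoms.
#' @return A list of class \code{APLMap}: \code{lipids} (data.frame with
#'   molecule_id, species, x, y, area), \code{raster} (matrix of per-bin cell
#'   areas), \code{bin_size}, \code{leaflet}, \code{box_area}.
#' @export
areaPerLipid <- function(traj, frame = 1L, leaflet = c("upper", "lower"),
                         binSize = 2, peptideSeeds = FALSE, bandWidth = 10) {
  leaflet <- match.arg(leaflet)
  topo <- topology(traj)
  a <- atoms(traj)
  la <- assignLeaflets(traj, frame)
  ids <- as.integer(names(la$leaflet)[la$leaflet == leaflet])
  if (length(ids) < 4L) stop("input error: leaflet has fewer than 4 lipids")
  x <- frameCoords(traj, frame)
  box <- frameBox(traj, frame)
  seeds <- t(vapply(ids, function(id) {
    sp <- topo@lipidSpecies[[as.character(id)]]
    sel <- a$molecule_id == id & a$name == topo@phosphateNames[[sp]]
    x[sel, 1:2, drop = FALSE][1, ]
  }, numeric(2)))
  n_lip <- nrow(seeds)
  n_pep <- 0L
  if (peptideSeeds && length(peptideIds(topo))) {
    zplane <- mean(la$phosphate_z[la$leaflet == leaflet])
    psel <- a$molecule_id %in% peptideIds(topo) & a$is_heavy &
      abs(x[, 3] - zplane) <= bandWidth
    if (any(psel)) {
      seeds <- rbind(seeds, x[psel, 1:2, drop = FALSE])
      n_pep <- sum(psel)
    }
  }
  vor <- .periodic_voronoi(seeds, box[1:2])
  areas <- vor$areas[seq_len(n_lip)]
  box_area <- box[1] * box[2]
  if (n_pep == 0L &&
      abs(sum(vor$areas) - box_area) > 1e-6 * box_area)
    stop("internal error: Voronoi areas do not partition the box")
  species <- vapply(ids, function(id)
    topo@lipidSpecies[[as.character(id)]], character(1))
  lips <- data.frame(molecule_id = ids, species = species,
                     x = seeds[seq_len(n_lip), 1], y = seeds[seq_len(n_lip), 2],
                     area = areas, stringsAsFactors = FALSE)
  ## raster: per-bin area of the owning lipid (nearest seed, minimum image)
  gx <- seq(binSize / 2, box[1], by = binSize)
  gy <- seq(binSize / 2, box[2], by = binSize)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  dmat <- .mi_crossdist_xy(grid, seeds[seq_len(n_lip), , drop = FALSE],
                           c(box[1:2], 1))
  owner <- max.col(-dmat)
  raster <- matrix(areas[owner], nrow = length(gx), ncol = length(gy))
  dimnames(raster) <- list(format(gx), format(gy))
  structure(list(lipids = lips, raster = raster, bin_size = binSize,
                 leaflet = leaflet, box_area = box_area,
                 n_peptide_seeds = n_pep),
            class = "APLMap")
}

#' @export
print.APLMap <- function(x, ...) {
  cat(sprintf("APL map (%s leaflet): %d lipids, mean %.2f A^2 (box %.1f A^2)\n",
              x$leaflet, nrow(x$lipids), mean(x$lipids$area), x$box_area))
  invisible(x)
}

#' Per-lipid nematic order parameter
#'
#' For each lipid, S = <(3 cos^2 theta - 1)/2> averaged over all consecutive
#' tail-bead bond vectors of all its tail chains, where theta is the angle
#' between the bond vector and the membrane normal (+z).  S = 1 for tails
#' along the normal, 0 at the magic angle (54.7356 degrees), -0.5
#' perpendicular.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param lipidIds lipid molecule ids (default all).
#' @return data.frame with columns \code{molecule_id}, \code{species},
#'   \code{S}, \code{mean_tilt_deg}.
#' @export
nematicOrder <- function(traj, frame = 1L, lipidIds = NULL) {
  topo <- topology(traj)
  a <- atoms(traj)
  if (is.null(lipidIds)) lipidIds <- .lipid_ids(topo)
  x <- frameCoords(traj, frame)
  out <- lapply(lipidIds, function(id) {
    sp <- topo@lipidSpecies[[as.character(id)]]
    chains <- topo@tailAtoms[[sp]]
    if (is.null(chains)) stop("input error: no tail atoms declared for ", sp)
    cos2 <- tilt <- numeric(0)
    for (ch in chains) {
      idx <- vapply(ch, function(nm) {
        w <- which(a$molecule_id == id & a$name == nm)
        if (length(w) != 1L)
          stop("input error: lipid ", id, " missing tail atom ", nm)
        w
      }, 1L)
      if (length(idx) < 2L) stop("input error: tail chain shorter than 2 beads")
      bonds <- diff(x[idx, , drop = FALSE])
      bu <- bonds / sqrt(rowSums(bonds^2))
      cos2 <- c(cos2, bu[, 3]^2)
      tilt <- c(tilt, acos(pmin(1, abs(bu[, 3]))) * 180 / pi)
    }
    c(S = mean((3 * cos2 - 1) / 2), tilt = mean(tilt))
  })
  m <- do.call(rbind, out)
  data.frame(molecule_id = lipidIds,
             species = vapply(lipidIds, function(id)
               topo@lipidSpecies[[as.character(id)]], character(1)),
             S = m[, "S"], mean_tilt_deg = m[, "tilt"],
             stringsAsFactors = FALSE)
}

.lipid_ids <- function(topo)
  sort(unique(topo@atoms$molecule_id[topo@atoms$molecule_kind == "lipid"]))

#' Lipid order near versus far from a bound peptide
#'
#' Splits lipids by the lateral (XY, minimum-image) distance from their
#' phosphate to the nearest peptide heavy atom: "near" at or below
#' \code{nearCutoff}, "far" at or beyond \code{farCutoff}; intermediate
#' lipids are excluded.  Returns pooled order-parameter histograms for the
#' two groups.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frames frame indices (pooled); default all.
#' @param nearCutoff,farCutoff lateral distance cutoffs in Angstrom
#'   (defaults 10 and 25).
#' @param breaks histogram bin edges for S.
#' @return A list with \code{near}, \code{far} (data.frames of per-lipid S),
#'   \code{hist_near}, \code{hist_far} (bin mids + counts), and the cutoffs.
#' @export
nearFarHistogram <- function(traj, frames = seq_len(nFrames(traj)),
                             nearCutoff = 10, farCutoff = 25,
                             breaks = seq(-0.5, 1, by = 0.05)) {
  if (nearCutoff <= 0 || farCutoff <= 0 || nearCutoff >= farCutoff)
    stop("input error: cutoffs must be positive with nearCutoff < farCutoff")
  topo <- topology(traj)
  a <- atoms(traj)
  pep <- peptideIds(topo)
  near <- far <- NULL
  for (f in frames) {
    x <- frameCoords(traj, f)
    box <- frameBox(traj, f)
    ord <- nematicOrder(traj, f)
    lids <- ord$molecule_id
    pxy <- t(vapply(lids, function(id) {
      sp <- topo@lipidSpecies[[as.character(id)]]
      sel <- a$molecule_id == id & a$name == topo@phosphateNames[[sp]]
      x[sel, 1:2, drop = FALSE][1, ]
    }, numeric(2)))
    if (length(pep)) {
      psel <- a$molecule_id %in% pep & a$is_heavy
      dl <- .mi_crossdist_xy(pxy, x[psel, , drop = FALSE], box)
      dmin <- apply(dl, 1, min)
    } else dmin <- rep(Inf, length(lids))
    near <- rbind(near, ord[dmin <= nearCutoff, ])
    far <- rbind(far, ord[dmin >= farCutoff, ])
  }
  if (is.null(near) || !nrow(near)) warning("empty 'near' partition")
  if (is.null(far) || !nrow(far)) warning("empty 'far' partition")
  mk_hist <- function(df) {
    if (is.null(df) || !nrow(df))
      return(data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                        count = 0L))
    h <- hist(pmin(pmax(df$S, min(breaks)), max(breaks)),
              breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  list(near = near, far = far,
       hist_near = mk_hist(near), hist_far = mk_hist(far),
       near_cutoff = nearCutoff, far_cutoff = farCutoff)
}

#' Z-density of a selection relative to the bilayer midplane
#'
#' Histogram of selected atoms' z minus the per-frame midplane, pooled over
#' frames.  With the phosphate selection this is the membrane reference
#' curve; with a peptide selection it is a Z-COM-style positional density.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection integer atom indices or a logical mask over atoms.
#' @param frames frame indices; default all.
#' @param binWidth bin width in Angstrom (default 1).
#' @return data.frame with columns \code{z_mid}, \code{count},
#'   \code{density}.
#' @export
zDensity <- function(traj, selection, frames = seq_len(nFrames(traj)),
                     binWidth = 1) {
  if (is.logical(selection)) selection <- which(selection)
  if (!length(selection)) stop("input error: empty selection")
  zz <- numeric(0)
  has_lipids <- length(.lipid_ids(topology(traj))) >= 2L
  for (f in frames) {
    x <- frameCoords(traj, f)
    mid <- if (has_lipids) assignLeaflets(traj, f)$midplane_z else 0
    zz <- c(zz, x[selection, 3] - mid)
  }
  lo <- floor(min(zz) / binWidth) * binWidth
  hi <- ceiling(max(zz) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  h <- hist(zz, breaks = seq(lo, hi, by = binWidth), plot = FALSE)
  data.frame(z_mid = h$mids, count = h$counts, density = h$density)
}

#' Select phosphate atoms
#'
#' Convenience selector for the lipid phosphate reference atoms.
#'
#' @param topo a \linkS4class{Topology}.
#' @return Integer atom indices.
#' @export
phosphateSelection <- function(topo) {
  a <- topo@atoms
  sel <- integer(0)
  for (id in .lipid_ids(topo)) {
    sp <- topo@lipidSpecies[[as.character(id)]]
    sel <- c(sel, which(a$molecule_id == id & a$name == topo@phosphateNames[[sp]]))
  }
  sel
}
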