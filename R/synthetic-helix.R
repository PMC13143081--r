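## Synthetic peptide generator.
##
## Helices are built in internal coordinates (NeRF chain extension) with ideal
## backbone bond lengths/angles and alpha-helical dihedrals (phi = -57,
## psi = -47, omega = 180), which guarantees exact helical geometry: 1.5 A
## rise, ~100 degree twist and 3.8 A consecutive Calpha spacing emerge from
## the dihedrals.  Side chains are a single pseudo-heavy-atom at the Cbeta
## position; bending maps the finished helix onto a circular arc with
## parallel-transported local frames, so internal geometry is preserved and
## curvature is the only signal added.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

## NeRF atom placement: position D bonded to C, given chain A-B-C, bond length
## r(C-D), planar angle theta(B-C-D) and dihedral phi(A-B-C-D), in degrees.
.place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  C + bc * d[1] + m * d[2] + n * d[3]
}

.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
            ang_cnca = 121.7, ang_ncac = 111.2, ang_cacn = 116.2,
            ang_caco = 120.8, ang_ccacb = 110.6, improper_cb = 122.6)

## Build backbone N/CA/C/O (+CB) for a chain with given per-residue (phi, psi).
## Returns list(xyz [n_atoms x 3], atom data.frame fields).
.build_chain <- function(sequence, phi, psi) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(length(phi) == n, length(psi) == n)
  b <- .bb
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b$n_ca, 0, 0)
  a1 <- b$ang_ncac * pi / 180
  C[1, ] <- CA[1, ] + b$ca_c * c(-cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            b$c_n, b$ang_cacn, psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             b$n_ca, b$ang_cnca, 180)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            b$ca_c, b$ang_ncac, phi[i])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          b$c_o, b$ang_caco, psi[i] + 180)
  }
  xyz <- NULL
  name <- element <- character(0)
  resi <- integer(0)
  for (i in seq_len(n)) {
    at <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    if (aa[i] != "G") {
      CB <- .place_atom(N[i, ], C[i, ], CA[i, ],
                        b$ca_cb, b$ang_ccacb, -b$improper_cb)
      at <- rbind(at, CB)
      nm <- c(nm, "CB")
      el <- c(el, "C")
    }
    xyz <- rbind(xyz, at)
    name <- c(name, nm)
    element <- c(element, el)
    resi <- c(resi, rep(i, length(nm)))
  }
  list(xyz = xyz, name = name, element = element, residue_index = resi, aa = aa)
}

## Rotate/translate so the best-fit Calpha line is +x through the origin, with
## N -> C pointing toward +x and the first axis position at x = 0.
.align_to_x <- function(xyz, ca_idx) {
  ca <- xyz[ca_idx, , drop = FALSE]
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  ax <- sv$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  ## orthonormal frame with ax -> x
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ey <- .unit(.cross3(ref, ax))
  ez <- .cross3(ax, ey)
  Rm <- rbind(ax, ey, ez)
  out <- sweep(xyz, 2, ctr) %*% t(Rm)
  out[, 1] <- out[, 1] - min(out[ca_idx, 1])
  out
}

## Map a +x-aligned structure onto a circular arc of radius R in the xz-plane.
## The axis coordinate s = x becomes arc length; transverse offsets are
## carried by the transported frame, so local helical geometry is unchanged.
.bend_about_arc <- function(xyz, R) {
  s <- xyz[, 1]
  a <- s / R
  w <- cbind(-sin(a), 0, cos(a))            # transported z direction
  t(vapply(seq_len(nrow(xyz)), function(i) {
    c(R * sin(a[i]), xyz[i, 2], R * (1 - cos(a[i]))) +
      xyz[i, 3] * w[i, ]
  }, numeric(3)))
}

.aa3_of <- function(aa) {
  m <- structure(names(.aa3), names = unname(.aa3))
  unname(m[aa])
}

#' Generate an ideal or arc-bent alpha-helical peptide
#'
#' Builds a full-backbone (N, CA, C, O, plus a Cbeta pseudo side-chain atom on
#' non-glycine residues) alpha-helix for the given sequence, aligned with its
#' axis along +x starting at the origin.  If \code{bendRadius} is finite, the
#' helix axis is mapped onto a circular arc of that radius in the xz-plane
#' with parallel-transported local frames, so the internal rise/twist are
#' preserved and the arc radius is the exact ground truth for curvature
#' analyses.  Generation is deterministic.
#'
#' @param sequence one-letter amino-acid string (>= 4 residues).
#' @param bendRadius arc radius R in Angstrom, or \code{NULL} for a straight
#'   helix.  Must exceed helix length / pi so the arc stays below a half turn.
#' @param moleculeId molecule id for the topology (default 1).
#' @param regions \linkS4class{PeptideRegions} stored in the topology.
#' @param box box lengths (Angstrom); default encloses the helix with margin.
#' @return A single-frame \linkS4class{Trajectory}.  The attribute
#'   \code{"manifest"} records the ground truth (\code{bend_radius}).
#' @examples
#' h <- makeHelix(buildConstruct("extended_AH")$sequence, bendRadius = 60)
#' attr(h, "manifest")$bend_radius
#' @export
makeHelix <- function(sequence, bendRadius = NULL, moleculeId = 1L,
                      regions = PeptideRegions(), box = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 4L) stop("input error: need at least 4 residues")
  if (!all(aa %in% .valid_aa))
    stop("input error: invalid residue letter(s) in sequence")
  ch <- .build_chain(sequence, phi = rep(-57, n), psi = rep(-47, n))
  ca_idx <- which(ch$name == "CA")
  xyz <- .align_to_x(ch$xyz, ca_idx)
  helix_len <- diff(range(xyz[ca_idx, 1]))
  if (!is.null(bendRadius)) {
    if (bendRadius <= helix_len / pi)
      stop("input error: bend_radius must exceed helix length / pi")
    xyz <- .bend_about_arc(xyz, bendRadius)
  }
  atoms_df <- data.frame(
    atom_id = seq_len(nrow(xyz)),
    name = ch$name, element = ch$element,
    residue_index = ch$residue_index,
    residue_name = .aa3_of(ch$aa)[ch$residue_index],
    molecule_id = as.integer(moleculeId), molecule_kind = "peptide",
    is_heavy = TRUE, stringsAsFactors = FALSE)
  topo <- Topology(atoms_df, regions = regions)
  if (is.null(box)) {
    ext <- apply(xyz, 2, function(v) diff(range(v)))
    box <- pmax(ext + 40, 60)
  }
  traj <- Trajectory(topo, xyz, box)
  attr(traj, "manifest") <- list(
    sequence = sequence, n_residues = n,
    bend_radius = if (is.null(bendRadius)) Inf else bendRadius)
  traj
}
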