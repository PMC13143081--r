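## Shared fixtures and independent oracle implementations.
##
## Oracles deliberately avoid the package's code paths: distances enumerate
## all 27 periodic images explicitly, and contact counting loops over every
## atom pair.

ah_seq <- function() "ERIRLNGDLEEIQGKVKKLEEQVKSLQVKKSHLK"

## brute-force minimum-image distance: explicit 27-image enumeration
brute_mi_dist <- function(a, b, box) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- a - (b + c(sx, sy, sz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

## brute-force residue-level contact matrix between two atom sets
brute_contact_matrix <- function(x, box, idx1, res1, idx2, res2, cutoff,
                                 strict = FALSE) {
  r1 <- sort(unique(res1))
  r2 <- sort(unique(res2))
  m <- matrix(FALSE, length(r1), length(r2), dimnames = list(r1, r2))
  for (a in seq_along(idx1)) for (b in seq_along(idx2)) {
    d <- brute_mi_dist(x[idx1[a], ], x[idx2[b], ], box)
    hit <- if (strict) d < cutoff else d <= cutoff
    if (hit)
      m[as.character(res1[a]), as.character(res2[b])] <- TRUE
  }
  m
}

## toy two-peptide system with named salt-bridge atoms; O-N distances are
## scripted per frame through `dists` (list: pair label -> numeric vector of
## per-frame O-N distances)
make_saltbridge_toy <- function(dists, dt_ns = 1) {
  ## molecule 1: GLU 10 and GLU 20 (OE1/OE2); molecule 2: ARG 4 (NH1/NH2/NE)
  ## and LYS 18 (NZ)
  at <- data.frame(
    atom_id = 1:12,
    name = c("CA", "OE1", "OE2", "CA", "OE1", "OE2",
             "CA", "NH1", "NH2", "NE", "CA", "NZ"),
    element = c("C", "O", "O", "C", "O", "O",
                "C", "N", "N", "N", "C", "N"),
    residue_index = c(10L, 10L, 10L, 20L, 20L, 20L,
                      4L, 4L, 4L, 4L, 18L, 18L),
    residue_name = c(rep("GLU", 3), rep("GLU", 3),
                     rep("ARG", 4), rep("LYS", 2)),
    molecule_id = c(rep(1L, 6), rep(2L, 6)),
    molecule_kind = "peptide",
    is_heavy = TRUE, stringsAsFactors = FALSE)
  topo <- Topology(at)
  nf <- length(dists[[1]])
  coords <- array(0, dim = c(12, 3, nf))
  ## static scaffold: separate the four residues far apart in y
  base_y <- c(0, 0, 0, 60, 60, 60, 0, 0, 2, 4, 60, 60)
  base_z <- c(0, 0, 2, 0, 0, 2, 30, 30, 30, 30, 30, 30)
  for (f in seq_len(nf)) {
    coords[, 2, f] <- base_y
    coords[, 3, f] <- base_z
    ## E10 (OE1 at row 2) vs R4 (NH1 at row 8): x distance controls the pair
    coords[8, 1, f] <- if (!is.null(dists$E10_R4)) dists$E10_R4[f] else 200
    coords[8, 3, f] <- 0
    ## E20 (OE1 at row 5) vs K18 (NZ at row 12)
    coords[12, 1, f] <- if (!is.null(dists$E20_K18)) dists$E20_K18[f] else 200
    coords[12, 3, f] <- 0
    coords[12, 2, f] <- 60
  }
  Trajectory(topo, coords, box = c(500, 500, 500),
             time = (seq_len(nf) - 1) * dt_ns)
}

## minimal single-lipid-species bilayer row for topology validity tests
make_bad_lipid_topology <- function(drop_phosphate = FALSE) {
  nm <- c("P", "C1", "C2", "C3", "C4")
  if (drop_phosphate) nm[1] <- "C0"
  at <- data.frame(
    atom_id = 1:5, name = nm,
    element = c(if (drop_phosphate) "C" else "P", rep("C", 4)),
    residue_index = 1L, residue_name = "DOPC",
    molecule_id = 1L, molecule_kind = "lipid",
    is_heavy = TRUE, stringsAsFactors = FALSE)
  Topology(at, lipidSpecies = c("1" = "DOPC"),
           phosphateNames = c(DOPC = "P"),
           tailAtoms = list(DOPC = list(c("C1", "C2", "C3", "C4"))))
}

## random rigid transform (rotation + translation), seeded by the caller
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% t(tr$R), 2, tr$t, "+")

## rebuild a Trajectory with transformed coordinates (same topology/box)
with_coords <- function(traj, xyz, frame = 1L) {
  co <- traj@coords
  co[, , frame] <- xyz
  Trajectory(topology(traj), co, traj@box, frameTimes(traj))
}
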