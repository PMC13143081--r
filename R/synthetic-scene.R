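## Two-peptide scene generator with prescribed inter-axis angle and forced
## patch contacts.  Used as the closed-loop oracle for the orientation
## classifier: the manifest records the achieved cos(theta) and the planted
## A/P contact counts, which downstream analysis must recover exactly.

## Rodrigues rotation matrix mapping unit vector a onto unit vector b.
.rot_between <- function(a, b) {
  v <- .cross3(a, b)
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    ## opposite vectors: rotate pi about any axis perpendicular to a
    ax <- if (abs(a[1]) < 0.9) .unit(.cross3(a, c(1, 0, 0)))
          else .unit(.cross3(a, c(0, 1, 0)))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Generate a two-peptide scene with known orientation and contacts
#'
#' Places two copies of an ideal helix so that the angle between their
#' N-patch-to-C-patch heavy-atom COM axis vectors equals
#' \code{interAxisAngle} within 0.5 degrees, and plants exactly
#' \code{nForcedContactsA} heavy-atom contact pairs between peptide 1's
#' N-terminal patch and peptide 2's second half (and analogously
#' \code{nForcedContactsP} pairs between peptide 1's C-terminal patch and
#' peptide 2's second half) at 4.0 A, strictly inside the 4.5 A classifier
#' cutoff.
#'
#' Forced contacts are realised as extra pseudo-heavy-atoms ("CX" beads)
#' assigned to the residues of each planted pair and placed pairwise at
#' 4.0 A in the inter-peptide gap, laterally spread (8 A apart) so no
#' unintended residue pair falls below the cutoff.  Peptide 2 partner
#' residues are drawn from the second half outside its C-patch, so the beads
#' never perturb peptide 2's axis; peptide 1's axis is computed after bead
#' placement and peptide 2 is then rotated to meet the requested angle
#' exactly.
#'
#' @param sequence one-letter amino-acid string covering the region
#'   definitions (34 residues for the defaults).
#' @param interAxisAngle requested inter-axis angle, degrees in [0, 180].
#' @param centerSeparation distance between the two helix centres, Angstrom.
#' @param nForcedContactsA,nForcedContactsP planted contact-pair counts.
#' @param nFrames number of (identical) frames to emit.
#' @param aboveMembrane logical; if TRUE the whole scene is shifted +30 A
#'   in z.
#' @param regions \linkS4class{PeptideRegions}.
#' @param seed kept for interface symmetry; the construction is
#'   deterministic.
#' @return A \linkS4class{Trajectory} whose \code{"manifest"} attribute
#'   records \code{cos_theta} (achieved), \code{inter_axis_angle}, \code{A},
#'   \code{P}.
#' @examples
#' sc <- makeTwoPeptideScene(buildConstruct("extended_AH")$sequence,
#'                           interAxisAngle = 180, nForcedContactsA = 8)
#' attr(sc, "manifest")
#' @export
makeTwoPeptideScene <- function(sequence, interAxisAngle = 180,
                                centerSeparation = 25,
                                nForcedContactsA = 0L, nForcedContactsP = 0L,
                                nFrames = 5L, aboveMembrane = FALSE,
                                regions = PeptideRegions(), seed = 1L) {
  if (interAxisAngle < 0 || interAxisAngle > 180)
    stop("input error: interAxisAngle must be in [0, 180] degrees")
  if (nForcedContactsA < 0L || nForcedContactsP < 0L)
    stop("input error: forced contact counts must be >= 0")
  n <- nchar(sequence)
  if (n < regions@secondHalf[2])
    stop("input error: sequence shorter than the region definitions")
  ## peptide-2 partner residues: second half outside the C-patch, so beads
  ## never touch peptide 2's axis patches
  partner <- setdiff(seq(regions@secondHalf[1], regions@secondHalf[2]),
                     seq(regions@cPatch[1], regions@cPatch[2]))
  n_a_max <- (diff(regions@nPatch) + 1L) * length(partner)
  n_p_max <- (diff(regions@cPatch) + 1L) * length(partner)
  if (nForcedContactsA > n_a_max || nForcedContactsP > n_p_max)
    stop("construction error: more forced contacts than available residue pairs")
  if (centerSeparation < 12)
    stop("construction error: centerSeparation too small for contact-free helices")

  h1 <- makeHelix(sequence, moleculeId = 1L, regions = regions)
  xyz1 <- frameCoords(h1, 1)
  a1 <- atoms(h1)
  zmid <- centerSeparation / 2
  x0 <- mean(xyz1[, 1])

  ## planted contact beads on fixed lateral rails (A at +y, P at -y)
  bead_block <- function(n_pairs, patch, y0) {
    if (n_pairs == 0L) return(NULL)
    combos <- expand.grid(i = seq(patch[1], patch[2]), j = partner)
    combos <- combos[seq_len(n_pairs), , drop = FALSE]
    xyz <- NULL; at <- NULL
    for (k in seq_len(n_pairs)) {
      yk <- y0 + 8 * k
      xyz <- rbind(xyz, c(x0, yk, zmid + 2), c(x0, yk, zmid - 2))
      at <- rbind(at, data.frame(
        atom_id = 0L, name = "CX", element = "C",
        residue_index = c(combos$i[k], combos$j[k]), residue_name = "UNK",
        molecule_id = c(1L, 2L), molecule_kind = "peptide", is_heavy = TRUE,
        stringsAsFactors = FALSE))
    }
    list(xyz = xyz, at = at)
  }
  blkA <- bead_block(nForcedContactsA, regions@nPatch, y0 = 20)
  blkP <- bead_block(nForcedContactsP, regions@cPatch,
                     y0 = -20 - 8 * (nForcedContactsP + 1L))

  ## peptide 1's axis including its beads (beads of molecule 1 only)
  com_of <- function(xyz, at, mol, range) {
    sel <- at$molecule_id == mol & at$is_heavy &
      at$residue_index >= range[1] & at$residue_index <= range[2]
    colMeans(xyz[sel, , drop = FALSE])
  }
  all_xyz1 <- rbind(xyz1, blkA$xyz, blkP$xyz)
  all_at1 <- rbind(a1, blkA$at, blkP$at)
  m1 <- all_at1$molecule_id == 1L
  v1 <- .unit(com_of(all_xyz1[m1, , drop = FALSE], all_at1[m1, , drop = FALSE],
                     1L, regions@cPatch) -
              com_of(all_xyz1[m1, , drop = FALSE], all_at1[m1, , drop = FALSE],
                     1L, regions@nPatch))

  ## rotate peptide 2 so its axis makes the requested angle with v1
  a2 <- a1
  a2$molecule_id <- 2L
  v2_0 <- .unit(com_of(xyz1, a1, 1L, regions@cPatch) -
                com_of(xyz1, a1, 1L, regions@nPatch))
  tgt <- interAxisAngle * pi / 180
  eperp <- if (abs(v1[3]) < 0.99) .unit(.cross3(v1, c(0, 0, 1)))
           else .unit(.cross3(v1, c(0, 1, 0)))
  w <- cos(tgt) * v1 + sin(tgt) * eperp
  Rm <- .rot_between(v2_0, w)
  ctr1 <- colMeans(xyz1)
  xyz2 <- sweep(xyz1, 2, ctr1) %*% t(Rm)
  xyz2 <- sweep(xyz2, 2, c(ctr1[1], ctr1[2], ctr1[3] + centerSeparation), "+")

  if (min(.mi_crossdist(xyz1, xyz2, c(1e9, 1e9, 1e9))) < 4.5)
    stop("construction error: forced separation incompatible with contact-free helices")

  at <- rbind(a1, a2, blkA$at, blkP$at)
  xyz <- rbind(xyz1, xyz2, blkA$xyz, blkP$xyz)
  if (aboveMembrane) xyz[, 3] <- xyz[, 3] + 30
  ord <- order(at$molecule_id, at$residue_index)
  at <- at[ord, , drop = FALSE]
  xyz <- xyz[ord, , drop = FALSE]
  at$atom_id <- seq_len(nrow(at))
  topo <- Topology(at, regions = regions)
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  traj <- Trajectory(topo,
                     array(rep(xyz, nFrames), dim = c(nrow(xyz), 3, nFrames)),
                     pmax(ext + 60, 120))

  ## achieved angle measured from the assembled scene (sanity bound 0.5 deg)
  v2 <- .unit(com_of(xyz, at, 2L, regions@cPatch) -
              com_of(xyz, at, 2L, regions@nPatch))
  v1f <- .unit(com_of(xyz, at, 1L, regions@cPatch) -
               com_of(xyz, at, 1L, regions@nPatch))
  ach <- acos(max(-1, min(1, sum(v1f * v2)))) * 180 / pi
  if (abs(ach - interAxisAngle) > 0.5)
    stop("construction error: achieved axis angle ", round(ach, 3),
         " deviates from the request")
  attr(traj, "manifest") <- list(
    cos_theta = sum(v1f * v2),
    inter_axis_angle = ach,
    A = as.integer(nForcedContactsA), P = as.integer(nForcedContactsP))
  traj
}

#' Generate a telegraph (alternating exponential on/off) contact series
#'
#' Samples a two-state renewal process with exponential on- and off-dwell
#' times at a fixed frame interval.  The true occupancy is
#' \code{meanOn / (meanOn + meanOff)} and the true mean on-duration is
#' \code{meanOn}; both are recorded in the ground-truth summary for
#' closed-loop tests of occupancy/lifetime estimators.
#'
#' @param nFrames number of sampled frames.
#' @param dtNs frame interval, ns.
#' @param meanOnNs,meanOffNs mean dwell times of the on and off states, ns.
#' @param seed integer seed.
#' @return A list with \code{series} (logical vector of length
#'   \code{nFrames}), \code{dt_ns}, and \code{truth} (list with
#'   \code{occupancy} and \code{mean_on_ns}).
#' @examples
#' ts <- makeTelegraphSeries(1000, dtNs = 1, meanOnNs = 20, meanOffNs = 20,
#'                           seed = 7)
#' mean(ts$series)
#' @export
makeTelegraphSeries <- function(nFrames, dtNs = 1, meanOnNs = 20,
                                meanOffNs = 20, seed = 1L) {
  if (nFrames < 1L || dtNs <= 0 || meanOnNs <= 0 || meanOffNs <= 0)
    stop("input error: all telegraph parameters must be positive")
  rng <- .seeded_rng(seed)
  total <- nFrames * dtNs
  ## start in a state drawn from the stationary distribution
  state <- stats::runif(1) < meanOnNs / (meanOnNs + meanOffNs)
  states <- logical(0)
  t_edges <- 0
  while (t_edges[length(t_edges)] < total) {
    n_more <- ceiling(2.5 * total / (meanOnNs + meanOffNs)) + 50L
    new_states <- rep(c(state, !state), length.out = n_more)
    dwell <- stats::rexp(n_more) * ifelse(new_states, meanOnNs, meanOffNs)
    states <- c(states, new_states)
    t_edges <- c(t_edges, t_edges[length(t_edges)] + cumsum(dwell))
    state <- !new_states[n_more]
  }
  .restore_rng(rng)
  t_sample <- (seq_len(nFrames) - 0.5) * dtNs
  idx <- findInterval(t_sample, t_edges, rightmost.closed = TRUE)
  series <- states[idx]
  list(series = series, dt_ns = dtNs,
       truth = list(occupancy = meanOnNs / (meanOnNs + meanOffNs),
                    mean_on_ns = meanOnNs))
}
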