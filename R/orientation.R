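## Two-peptide orientation analysis.
##
## Each peptide gets an axis vector v = COM(C-patch heavy atoms) -
## COM(N-patch heavy atoms); cos(theta) between the two axes separates
## antiparallel (≈ -1) from parallel (≈ +1) arrangements.  Frames count as
## "interacting" when the patch contact count T = A + P exceeds the
## threshold (strictly; default T > 5), where A counts N-patch-to-second-half
## residue contacts over both peptide directions and P the analogous C-patch
## contacts, both at a 4.5 A heavy-atom cutoff.

.patch_com <- function(x, a, pep, range) {
  sel <- a$molecule_id == pep & a$is_heavy &
    a$residue_index >= range[1] & a$residue_index <= range[2]
  if (!any(sel)) stop("input error: empty patch for peptide ", pep)
  colMeans(x[sel, , drop = FALSE])
}

#' Peptide axis vector
#'
#' Unit vector from the heavy-atom centre of mass of the N-terminal patch to
#' that of the C-terminal patch (geometric centroid, unweighted by mass).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptideId peptide molecule id.
#' @param frame frame index.
#' @param regions a \linkS4class{PeptideRegions}.
#' @return Unit 3-vector.
#' @export
axisVector <- function(traj, peptideId = peptideIds(topology(traj))[1],
                       frame = 1L, regions = topology(traj)@regions) {
  x <- frameCoords(traj, frame)
  a <- atoms(traj)
  v <- .patch_com(x, a, peptideId, regions@cPatch) -
    .patch_com(x, a, peptideId, regions@nPatch)
  .unit(v)
}

## residue-level contact count between patch residues of peptide `p_from`
## and second-half residues of `p_to` (strict < cutoff, heavy atoms)
.patch_contacts_dir <- function(x, box, a, p_from, patch, p_to, second_half,
                                cutoff, count_mode) {
  i1 <- which(a$molecule_id == p_from & a$is_heavy &
                a$residue_index >= patch[1] & a$residue_index <= patch[2])
  i2 <- which(a$molecule_id == p_to & a$is_heavy &
                a$residue_index >= second_half[1] &
                a$residue_index <= second_half[2])
  if (!length(i1) || !length(i2)) return(0L)
  if (count_mode == "atom_pairs") {
    d <- .mi_crossdist(x[i1, , drop = FALSE], x[i2, , drop = FALSE], box)
    return(sum(d < cutoff))
  }
  m <- .residue_min_dist(x, box, i1, a$residue_index[i1], i2,
                         a$residue_index[i2])
  sum(m < cutoff)
}

#' Patch contact counts A and P
#'
#' A counts residue-level heavy-atom contacts (strictly below the cutoff)
#' between the N-terminal patch of one peptide and the second half of the
#' other, summed over both directions; P is the analogous count for the
#' C-terminal patches.
#'
#' @param traj a \linkS4class{Trajectory} with two peptides.
#' @param frame frame index.
#' @param regions a \linkS4class{PeptideRegions}.
#' @param cutoff heavy-atom cutoff in Angstrom (default 4.5).
#' @param peptides length-2 molecule ids.
#' @param countMode \code{"residue_pairs"} (default: a residue pair with
#'   several close atom pairs counts once) or \code{"atom_pairs"}.
#' @return Named integer vector \code{c(A = , P = )}.
#' @export
patchContactCounts <- function(traj, frame = 1L,
                               regions = topology(traj)@regions,
                               cutoff = 4.5,
                               peptides = peptideIds(topology(traj)),
                               countMode = c("residue_pairs", "atom_pairs")) {
  countMode <- match.arg(countMode)
  stopifnot(length(peptides) == 2L)
  x <- frameCoords(traj, frame)
  box <- frameBox(traj, frame)
  a <- atoms(traj)
  A <- .patch_contacts_dir(x, box, a, peptides[1], regions@nPatch,
                           peptides[2], regions@secondHalf, cutoff, countMode) +
    .patch_contacts_dir(x, box, a, peptides[2], regions@nPatch,
                        peptides[1], regions@secondHalf, cutoff, countMode)
  P <- .patch_contacts_dir(x, box, a, peptides[1], regions@cPatch,
                           peptides[2], regions@secondHalf, cutoff, countMode) +
    .patch_contacts_dir(x, box, a, peptides[2], regions@cPatch,
                        peptides[1], regions@secondHalf, cutoff, countMode)
  c(A = as.integer(A), P = as.integer(P))
}

#' Per-frame orientation records
#'
#' Computes, for every frame, the two axis vectors, cos(theta), the patch
#' contact counts A and P and their sum T.
#'
#' @inheritParams patchContactCounts
#' @param frames frame indices; default all.
#' @return data.frame with columns \code{frame}, \code{time_ns},
#'   \code{cos_theta}, \code{A}, \code{P}, \code{T}.
#' @export
orientationSeries <- function(traj, regions = topology(traj)@regions,
                              cutoff = 4.5,
                              peptides = peptideIds(topology(traj)),
                              countMode = "residue_pairs",
                              frames = seq_len(nFrames(traj))) {
  stopifnot(length(peptides) == 2L)
  rows <- lapply(frames, function(f) {
    v1 <- axisVector(traj, peptides[1], f, regions)
    v2 <- axisVector(traj, peptides[2], f, regions)
    ap <- patchContactCounts(traj, f, regions, cutoff, peptides,
                             countMode = countMode)
    data.frame(frame = f, time_ns = frameTimes(traj)[f],
               cos_theta = sum(v1 * v2), A = ap["A"], P = ap["P"],
               T = ap["A"] + ap["P"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify frames by interaction state and orientation
#'
#' A frame is "interacting" when T = A + P strictly exceeds the threshold
#' (default T > 5).  Interacting frames are labelled
#' \code{antiparallel_like} when A > P (N-terminal-mediated association),
#' \code{parallel_like} when P > A, and \code{mixed} on ties; non-interacting
#' frames are labelled \code{none}.  Pooled cos(theta) histograms are
#' returned split by the interacting flag.
#'
#' @param records data.frame from \code{\link{orientationSeries}} (or a list
#'   of them, pooled across replicas).
#' @param threshold contact-count threshold T0; interacting iff T > T0.
#' @param breaks histogram bin edges for cos(theta).
#' @return A list: \code{records} (input plus \code{interacting} and
#'   \code{label} columns), \code{hist_interacting},
#'   \code{hist_noninteracting} (bin mids + counts).
#' @export
classifyFrames <- function(records, threshold = 5L,
                           breaks = seq(-1, 1, by = 0.1)) {
  if (is.data.frame(records)) records <- list(records)
  if (!length(records) || !nrow(records[[1]]))
    stop("input error: no orientation records")
  rec <- do.call(rbind, records)
  rec$interacting <- rec$T > threshold
  rec$label <- ifelse(!rec$interacting, "none",
                      ifelse(rec$A > rec$P, "antiparallel_like",
                             ifelse(rec$P > rec$A, "parallel_like", "mixed")))
  mk <- function(v) {
    if (!length(v))
      return(data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                        count = 0L))
    h <- hist(pmin(pmax(v, -1), 1), breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  list(records = rec,
       hist_interacting = mk(rec$cos_theta[rec$interacting]),
       hist_noninteracting = mk(rec$cos_theta[!rec$interacting]),
       threshold = threshold)
}

#' Z position of a peptide's centre of mass over frames
#'
#' Per-frame heavy-atom COM z minus the bilayer midplane (0 for
#' membrane-free scenes), optionally restricted to a residue range (e.g. the
#' AH core), with a pooled histogram.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptideId peptide molecule id.
#' @param region optional length-2 residue range restriction.
#' @param frames frame indices; default all.
#' @param binWidth histogram bin width, Angstrom.
#' @return A list: \code{records} (data.frame frame/time_ns/z),
#'   \code{histogram} (z_mid + count + density).
#' @export
zcomDistribution <- function(traj, peptideId = peptideIds(topology(traj))[1],
                             region = NULL,
                             frames = seq_len(nFrames(traj)), binWidth = 1) {
  a <- atoms(traj)
  sel <- a$molecule_id == peptideId & a$is_heavy
  if (!is.null(region))
    sel <- sel & a$residue_index >= region[1] & a$residue_index <= region[2]
  has_lipids <- length(.lipid_ids(topology(traj))) >= 2L
  z <- vapply(frames, function(f) {
    mid <- if (has_lipids) assignLeaflets(traj, f)$midplane_z else 0
    mean(frameCoords(traj, f)[sel, 3]) - mid
  }, numeric(1))
  lo <- floor(min(z) / binWidth) * binWidth
  hi <- ceiling(max(z) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  h <- hist(z, breaks = seq(lo, hi, by = binWidth), plot = FALSE)
  list(records = data.frame(frame = frames,
                            time_ns = frameTimes(traj)[frames], z = z),
       histogram = data.frame(z_mid = h$mids, count = h$counts,
                              density = h$density))
}

#' Per-residue Z-COM summaries
#'
#' For every residue, the heavy-atom COM z minus the bilayer midplane is
#' collected over frames and summarised by min/Q1/median/Q3/max (the box-plot
#' statistics of residue height above the membrane).
#'
#' @inheritParams zcomDistribution
#' @return data.frame with columns \code{residue}, \code{min}, \code{q1},
#'   \code{median}, \code{q3}, \code{max}.
#' @export
perResidueZcom <- function(traj, peptideId = peptideIds(topology(traj))[1],
                           frames = seq_len(nFrames(traj))) {
  a <- atoms(traj)
  res <- sort(unique(a$residue_index[a$molecule_id == peptideId]))
  has_lipids <- length(.lipid_ids(topology(traj))) >= 2L
  zmat <- matrix(NA_real_, length(frames), length(res))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    x <- frameCoords(traj, f)
    mid <- if (has_lipids) assignLeaflets(traj, f)$midplane_z else 0
    for (ri in seq_along(res)) {
      sel <- a$molecule_id == peptideId & a$is_heavy &
        a$residue_index == res[ri]
      zmat[fi, ri] <- mean(x[sel, 3]) - mid
    }
  }
  q <- apply(zmat, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1))
  data.frame(residue = res, min = q[1, ], q1 = q[2, ], median = q[3, ],
             q3 = q[4, ], max = q[5, ])
}
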