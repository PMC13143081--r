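## Residue contact maps, residue-class contacts, headgroup contacts, and
## salt-bridge occupancy/lifetime statistics.
##
## A residue pair is "in contact" in a frame when the minimum distance
## between its selected atoms is within the cutoff (minimum-image).  Salt
## bridges use the carboxylate-O to side-chain-N criterion (D: OD1/OD2,
## E: OE1/OE2 versus K: NZ, R: NH1/NH2/NE) at 3.2 A, the common default of
## trajectory salt-bridge tools; histidine is excluded (neutral at pH 7.4).

.res_letter <- function(resname) {
  out <- unname(.aa3[resname])
  out[is.na(out)] <- "X"
  out
}

## per-frame residue-pair minimum distances between two atom selections
.residue_min_dist <- function(x, box, idx1, res1, idx2, res2) {
  d <- .mi_crossdist(x[idx1, , drop = FALSE], x[idx2, , drop = FALSE], box)
  r1 <- sort(unique(res1)); r2 <- sort(unique(res2))
  ## two-stage group minimum: rows by residue of peptide 1, then columns
  step1 <- matrix(Inf, length(r1), length(idx2))
  for (i in seq_along(r1))
    step1[i, ] <- suppressWarnings(
      apply(d[res1 == r1[i], , drop = FALSE], 2, min))
  m <- matrix(Inf, length(r1), length(r2), dimnames = list(r1, r2))
  for (j in seq_along(r2))
    m[, j] <- suppressWarnings(
      apply(step1[, res2 == r2[j], drop = FALSE], 1, min))
  m
}

.pep_sel <- function(a, pep, mode) {
  sel <- a$molecule_id == pep
  if (mode == "calpha") sel <- sel & a$name == "CA"
  else sel <- sel & a$is_heavy
  if (!any(sel)) stop("input error: empty atom selection for peptide ", pep)
  which(sel)
}

#' Residue-residue contact map
#'
#' Fraction of frames in which each residue pair is in contact, i.e. the
#' minimum distance between the selected atoms of the two residues is within
#' the cutoff.  The default follows the Calpha convention with a 7.5 A
#' cutoff, chosen to admit interactions mediated by long flexible side
#' chains; \code{mode = "heavy"} switches to all heavy atoms.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptide1,peptide2 molecule ids; equal ids (or omitted
#'   \code{peptide2}) give the symmetric intra-peptide map.
#' @param mode atom selection, \code{"calpha"} or \code{"heavy"}.
#' @param cutoff contact cutoff in Angstrom.
#' @param frames frame indices; default all.
#' @return A list of class \code{ContactMapResult}: \code{frequency}
#'   (matrix residues1 x residues2 in [0, 1]), \code{per_frame} (logical
#'   array), \code{cutoff}, \code{mode}.
#' @export
contactMap <- function(traj, peptide1, peptide2 = peptide1,
                       mode = c("calpha", "heavy"), cutoff = 7.5,
                       frames = seq_len(nFrames(traj))) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("input error: cutoff must be positive")
  a <- atoms(traj)
  i1 <- .pep_sel(a, peptide1, mode)
  i2 <- .pep_sel(a, peptide2, mode)
  r1 <- a$residue_index[i1]; r2 <- a$residue_index[i2]
  acc <- NULL
  per_frame <- list()
  for (f in frames) {
    m <- .residue_min_dist(frameCoords(traj, f), frameBox(traj, f),
                           i1, r1, i2, r2)
    contact <- m <= cutoff
    per_frame[[length(per_frame) + 1L]] <- contact
    acc <- if (is.null(acc)) contact + 0 else acc + contact
  }
  freq <- acc / length(frames)
  structure(list(frequency = freq,
                 per_frame = simplify2array(per_frame),
                 cutoff = cutoff, mode = mode,
                 peptides = c(peptide1, peptide2)),
            class = "ContactMapResult")
}

#' @export
print.ContactMapResult <- function(x, ...) {
  cat(sprintf("Contact map (%s, %.1f A): %d x %d residues, mean frequency %.3f\n",
              x$mode, x$cutoff, nrow(x$frequency), ncol(x$frequency),
              mean(x$frequency)))
  invisible(x)
}

#' Domain-level time-windowed contact maps
#'
#' Coarse-grains a residue contact map over the three peptide regions
#' (N-term patch, AH core, C-term patch) and splits the trajectory into
#' contiguous time windows (the last window absorbs any remainder).  Each
#' coarse cell is the mean of its constituent residue-pair frequencies
#' within the window.
#'
#' @param cm a \code{ContactMapResult} from \code{\link{contactMap}}.
#' @param regions a \linkS4class{PeptideRegions}.
#' @param nWindows number of time windows (default 4).
#' @return A list of class \code{DomainContactMap}: \code{windows} (list of
#'   3 x 3 matrices, dimnames N-term/AH/C-term), \code{frame_ranges}.
#' @export
domainContactMap <- function(cm, regions = PeptideRegions(), nWindows = 4L) {
  nf <- dim(cm$per_frame)[3]
  if (nWindows < 1L || nWindows > nf)
    stop("input error: nWindows must be between 1 and the frame count")
  dom <- list("N-term" = regions@nPatch, "AH" = regions@ahCore,
              "C-term" = regions@cPatch)
  rr <- as.integer(rownames(cm$frequency))
  cc <- as.integer(colnames(cm$frequency))
  base <- floor(nf / nWindows)
  starts <- (seq_len(nWindows) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, nf)
  windows <- vector("list", nWindows)
  for (w in seq_len(nWindows)) {
    freq_w <- apply(cm$per_frame[, , starts[w]:ends[w], drop = FALSE],
                    c(1, 2), mean)
    m <- matrix(NA_real_, 3, 3, dimnames = list(names(dom), names(dom)))
    for (di in seq_along(dom)) for (dj in seq_along(dom)) {
      ri <- rr >= dom[[di]][1] & rr <= dom[[di]][2]
      cj <- cc >= dom[[dj]][1] & cc <= dom[[dj]][2]
      m[di, dj] <- mean(freq_w[ri, cj])
    }
    windows[[w]] <- m
  }
  structure(list(windows = windows,
                 frame_ranges = data.frame(window = seq_len(nWindows),
                                           first = starts, last = ends)),
            class = "DomainContactMap")
}

#' Inter-peptide contacts by residue class
#'
#' Counts, at every frame, inter-peptide residue pairs with any heavy-atom
#' pair within the cutoff (default 3.5 A), and aggregates the totals by
#' (class, class) and per residue.  Classes are acidic/basic/polar/
#' hydrophobic as in \code{\link{classifyResidue}}.
#'
#' @param traj a \linkS4class{Trajectory} with two peptides.
#' @param peptide1,peptide2 molecule ids.
#' @param cutoff heavy-atom cutoff in Angstrom.
#' @param frames frame indices; default all.
#' @return A list: \code{class_counts} (4 x 4 matrix of contact counts summed
#'   over frames, classes of peptide1 x classes of peptide2),
#'   \code{per_residue} (data.frame of per-residue totals for both peptides),
#'   \code{total}.
#' @export
residueClassContacts <- function(traj, peptide1 = 1L, peptide2 = 2L,
                                 cutoff = 3.5,
                                 frames = seq_len(nFrames(traj))) {
  a <- atoms(traj)
  i1 <- .pep_sel(a, peptide1, "heavy")
  i2 <- .pep_sel(a, peptide2, "heavy")
  r1 <- a$residue_index[i1]; r2 <- a$residue_index[i2]
  cls <- c("acidic", "basic", "polar", "hydrophobic")
  cmat <- matrix(0L, 4, 4, dimnames = list(cls, cls))
  letter_of <- function(pep, res) {
    rn <- a$residue_name[a$molecule_id == pep & a$residue_index == res][1]
    .res_letter(rn)
  }
  pr <- list()
  for (f in frames) {
    m <- .residue_min_dist(frameCoords(traj, f), frameBox(traj, f),
                           i1, r1, i2, r2)
    hits <- which(m <= cutoff, arr.ind = TRUE)
    if (!nrow(hits)) next
    for (h in seq_len(nrow(hits))) {
      res_i <- as.integer(rownames(m)[hits[h, 1]])
      res_j <- as.integer(colnames(m)[hits[h, 2]])
      li <- letter_of(peptide1, res_i)
      lj <- letter_of(peptide2, res_j)
      if (li == "X" || lj == "X") next
      ci <- classifyResidue(li); cj <- classifyResidue(lj)
      cmat[ci, cj] <- cmat[ci, cj] + 1L
      key_i <- paste0("p", peptide1, ":", res_i)
      key_j <- paste0("p", peptide2, ":", res_j)
      pr[[key_i]] <- (pr[[key_i]] %||% 0L) + 1L
      pr[[key_j]] <- (pr[[key_j]] %||% 0L) + 1L
    }
  }
  per_residue <- if (length(pr))
    data.frame(residue = names(pr), count = unlist(pr), row.names = NULL)
  else data.frame(residue = character(0), count = integer(0))
  list(class_counts = cmat, per_residue = per_residue, total = sum(cmat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-residue lipid headgroup contact profile
#'
#' For each peptide residue, the fraction of frames in which any of its heavy
#' atoms lies within the cutoff of any headgroup (phosphate) atom, reported
#' separately per lipid species (DOPC and PLPI).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptideId peptide molecule id.
#' @param cutoff heavy-atom to headgroup cutoff in Angstrom.
#' @param frames frame indices; default all.
#' @return data.frame with columns \code{residue} and one frequency column
#'   per species.  A species absent from the membrane yields a zero column
#'   with a warning.
#' @export
headgroupContactProfile <- function(traj, peptideId = peptideIds(topology(traj))[1],
                                    cutoff = 4.5,
                                    frames = seq_len(nFrames(traj))) {
  topo <- topology(traj)
  a <- atoms(traj)
  ip <- .pep_sel(a, peptideId, "heavy")
  rp <- a$residue_index[ip]
  res <- sort(unique(rp))
  species <- c("DOPC", "PLPI")
  phos_idx <- lapply(species, function(sp) {
    ids <- as.integer(names(topo@lipidSpecies)[topo@lipidSpecies == sp])
    if (!length(ids)) return(integer(0))
    which(a$molecule_id %in% ids & a$name == topo@phosphateNames[[sp]])
  })
  names(phos_idx) <- species
  for (sp in species)
    if (!length(phos_idx[[sp]]))
      warning("species ", sp, " absent from the membrane; zero-filled column")
  counts <- matrix(0L, length(res), length(species),
                   dimnames = list(res, species))
  for (f in frames) {
    x <- frameCoords(traj, f)
    box <- frameBox(traj, f)
    for (sp in species) {
      if (!length(phos_idx[[sp]])) next
      d <- .mi_crossdist(x[ip, , drop = FALSE],
                         x[phos_idx[[sp]], , drop = FALSE], box)
      close_res <- unique(rp[apply(d <= cutoff, 1, any)])
      counts[as.character(close_res), sp] <-
        counts[as.character(close_res), sp] + 1L
    }
  }
  out <- data.frame(residue = res, counts / length(frames))
  names(out)[-1] <- species
  out
}

.acidic_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_N <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))

## enumerate candidate salt-bridge pairs with their atom indices
.sb_pairs <- function(a) {
  pep_atoms <- a[a$molecule_kind == "peptide", , drop = FALSE]
  res <- unique(pep_atoms[, c("molecule_id", "residue_index", "residue_name")])
  acidic <- res[res$residue_name %in% names(.acidic_O), , drop = FALSE]
  basic <- res[res$residue_name %in% names(.basic_N), , drop = FALSE]
  if (!nrow(acidic) || !nrow(basic)) return(NULL)
  missing <- character(0)
  atom_idx <- function(mol, resi, nms) {
    which(a$molecule_id == mol & a$residue_index == resi & a$name %in% nms)
  }
  pairs <- list()
  for (i in seq_len(nrow(acidic))) {
    oi <- atom_idx(acidic$molecule_id[i], acidic$residue_index[i],
                   .acidic_O[[acidic$residue_name[i]]])
    if (!length(oi)) {
      missing <- c(missing, sprintf("%s%d (mol %d)", acidic$residue_name[i],
                                    acidic$residue_index[i],
                                    acidic$molecule_id[i]))
      next
    }
    for (j in seq_len(nrow(basic))) {
      nj <- atom_idx(basic$molecule_id[j], basic$residue_index[j],
                     .basic_N[[basic$residue_name[j]]])
      if (!length(nj)) {
        missing <- c(missing, sprintf("%s%d (mol %d)", basic$residue_name[j],
                                      basic$residue_index[j],
                                      basic$molecule_id[j]))
        next
      }
      lab <- sprintf("%s%d(m%d)-%s%d(m%d)",
                     .res_letter(acidic$residue_name[i]),
                     acidic$residue_index[i], acidic$molecule_id[i],
                     .res_letter(basic$residue_name[j]),
                     basic$residue_index[j], basic$molecule_id[j])
      pairs[[lab]] <- list(
        label = lab, o_idx = oi, n_idx = nj,
        acidic_res = acidic$residue_index[i], acidic_mol = acidic$molecule_id[i],
        basic_res = basic$residue_index[j], basic_mol = basic$molecule_id[j])
    }
  }
  missing <- unique(missing)
  if (length(missing))
    stop("input error: charged residues lack named side-chain O/N atoms: ",
         paste(missing, collapse = ", "))
  pairs
}

#' Detect salt bridges in one frame
#'
#' A (D/E, K/R) residue pair is an active salt bridge when any of its
#' carboxylate oxygens lies within \code{onCutoff} of any basic side-chain
#' nitrogen (residue-level: several close atom pairs still count once).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param onCutoff O-N distance cutoff in Angstrom (default 3.2).
#' @return data.frame of active pairs with columns \code{pair},
#'   \code{acidic_mol}, \code{acidic_res}, \code{basic_mol},
#'   \code{basic_res}, \code{min_dist}.
#' @export
detectSaltBridges <- function(traj, frame = 1L, onCutoff = 3.2) {
  pairs <- .sb_pairs(atoms(traj))
  x <- frameCoords(traj, frame)
  box <- frameBox(traj, frame)
  rows <- lapply(pairs, function(p) {
    d <- min(.mi_crossdist(x[p$o_idx, , drop = FALSE],
                           x[p$n_idx, , drop = FALSE], box))
    if (d <= onCutoff)
      data.frame(pair = p$label, acidic_mol = p$acidic_mol,
                 acidic_res = p$acidic_res, basic_mol = p$basic_mol,
                 basic_res = p$basic_res, min_dist = d,
                 stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(pair = character(0), acidic_mol = integer(0),
                      acidic_res = integer(0), basic_mol = integer(0),
                      basic_res = integer(0), min_dist = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-pair salt-bridge activity and distance series
#'
#' Evaluates the salt-bridge criterion for every candidate (D/E, K/R) pair at
#' every frame.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param onCutoff O-N cutoff in Angstrom.
#' @param frames frame indices; default all.
#' @return A list of class \code{SaltBridgeSeries}: \code{active} (logical
#'   matrix pairs x frames), \code{distance} (numeric matrix of per-frame
#'   minimum O-N distances), \code{dt_ns} (median frame spacing),
#'   \code{pairs} (bookkeeping data.frame).
#' @export
saltBridgeSeries <- function(traj, onCutoff = 3.2,
                             frames = seq_len(nFrames(traj))) {
  pairs <- .sb_pairs(atoms(traj))
  if (is.null(pairs))
    stop("input error: no candidate acidic/basic residue pairs")
  nd <- matrix(NA_real_, length(pairs), length(frames),
               dimnames = list(names(pairs), NULL))
  for (fi in seq_along(frames)) {
    x <- frameCoords(traj, frames[fi])
    box <- frameBox(traj, frames[fi])
    nd[, fi] <- vapply(pairs, function(p)
      min(.mi_crossdist(x[p$o_idx, , drop = FALSE],
                        x[p$n_idx, , drop = FALSE], box)), numeric(1))
  }
  tt <- frameTimes(traj)[frames]
  dt <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  meta <- do.call(rbind, lapply(pairs, function(p)
    data.frame(pair = p$label, acidic_res = p$acidic_res,
               basic_res = p$basic_res, stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  structure(list(active = nd <= onCutoff, distance = nd, dt_ns = dt,
                 pairs = meta, on_cutoff = onCutoff),
            class = "SaltBridgeSeries")
}

.as_active_matrix <- function(series) {
  if (inherits(series, "SaltBridgeSeries")) series$active
  else if (is.logical(series) && is.null(dim(series)))
    matrix(series, nrow = 1, dimnames = list("series", NULL))
  else as.matrix(series)
}

#' Salt-bridge occupancy
#'
#' Occupancy = active frames / total frames per pair.  With several replicas
#' (a list of series), the mean and standard deviation across replicas are
#' reported.  Pairs never active in any replica are dropped (sparse report).
#'
#' @param series a \code{SaltBridgeSeries}, a logical matrix (pairs x
#'   frames), a logical vector, or a list of these (replicas).
#' @return data.frame with columns \code{pair}, \code{occupancy_mean},
#'   \code{occupancy_sd} (NA for a single replica), \code{n_replicas}.
#' @export
bridgeOccupancy <- function(series) {
  reps <- if (is.list(series) && !inherits(series, "SaltBridgeSeries"))
    lapply(series, .as_active_matrix) else list(.as_active_matrix(series))
  pairs <- unique(unlist(lapply(reps, rownames)))
  occ <- vapply(pairs, function(p) {
    vals <- vapply(reps, function(m)
      if (p %in% rownames(m)) mean(m[p, ]) else NA_real_, numeric(1))
    c(mean = mean(vals, na.rm = TRUE),
      sd = if (sum(!is.na(vals)) > 1L) stats::sd(vals, na.rm = TRUE) else NA_real_)
  }, numeric(2))
  out <- data.frame(pair = pairs, occupancy_mean = occ["mean", ],
                    occupancy_sd = occ["sd", ], n_replicas = length(reps),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$occupancy_mean > 0, , drop = FALSE]
  out[order(-out$occupancy_mean, out$pair), , drop = FALSE]
}

## maximal on-runs of a logical vector; runs separated by <= gap inactive
## frames are merged
.events_of <- function(x, gap = 0L) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(data.frame(start = integer(0), end = integer(0)))
  ev <- data.frame(start = starts[on], end = ends[on])
  if (gap > 0L && nrow(ev) > 1L) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - merged$end[nrow(merged)] - 1L <= gap)
        merged$end[nrow(merged)] <- ev$end[i]
      else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged
  }
  ev
}

#' Salt-bridge event lifetimes
#'
#' Maximal runs of consecutive active frames become events (runs separated by
#' at most \code{gapTolerance} inactive frames are merged); event duration is
#' run length x dt.  The 95th percentile uses linear interpolation between
#' order statistics (inclusive method).
#'
#' @param series as in \code{\link{bridgeOccupancy}} (single replica).
#' @param dtNs frame spacing in ns; taken from a \code{SaltBridgeSeries} when
#'   available.
#' @param gapTolerance inactive frames tolerated inside one event (default 0).
#' @return data.frame with columns \code{pair}, \code{n_events},
#'   \code{total_on_ns}, \code{median_ns}, \code{p95_ns}.
#' @export
bridgeLifetimes <- function(series, dtNs = NULL, gapTolerance = 0L) {
  if (inherits(series, "SaltBridgeSeries") && is.null(dtNs))
    dtNs <- series$dt_ns
  if (is.null(dtNs)) dtNs <- 1
  m <- .as_active_matrix(series)
  rows <- lapply(rownames(m), function(p) {
    ev <- .events_of(m[p, ], gap = as.integer(gapTolerance))
    if (!nrow(ev)) return(NULL)
    dur <- (ev$end - ev$start + 1L) * dtNs
    data.frame(pair = p, n_events = nrow(ev), total_on_ns = sum(dur),
               median_ns = stats::median(dur),
               p95_ns = unname(stats::quantile(dur, 0.95, type = 7)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(pair = character(0), n_events = integer(0),
                      total_on_ns = numeric(0), median_ns = numeric(0),
                      p95_ns = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance traces of the top-occupancy salt-bridge pairs
#'
#' Per-frame minimum O-N distance for the k pairs with the highest occupancy
#' (ties broken by acidic then basic residue index).
#'
#' @param series a \code{SaltBridgeSeries}.
#' @param k number of pairs requested.
#' @return Numeric matrix k' x frames (k' <= k with a warning when fewer
#'   pairs were ever active).
#' @export
topPairsTimeseries <- function(series, k = 3L) {
  stopifnot(inherits(series, "SaltBridgeSeries"), k >= 1L)
  occ <- rowMeans(series$active)
  meta <- series$pairs
  keep <- which(occ > 0)
  if (!length(keep)) {
    warning("no pair was ever active")
    return(series$distance[integer(0), , drop = FALSE])
  }
  ord <- keep[order(-occ[keep], meta$acidic_res[keep], meta$basic_res[keep])]
  if (length(ord) < k)
    warning("only ", length(ord), " active pair(s) observed; returning all")
  series$distance[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
}
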