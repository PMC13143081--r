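## Helix bending and curvature analyses.
##
## The local bending angle is the turning angle between two chords of length
## `side` (default 7.2 A, roughly one helical turn of Calpha atoms) drawn
## backward and forward along the helix-axis polyline; 0 degrees = straight.
## The corresponding local radius of curvature is side / angle(rad).  The
## global curvature is summarised by a circle fit to the Calpha positions
## projected onto their PCA best-fit plane.

#' Extract Calpha coordinates of a peptide
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptideId molecule id of the peptide.
#' @param frame frame index.
#' @return Matrix of Calpha coordinates in residue order.
#' @export
calphaCoords <- function(traj, peptideId = peptideIds(topology(traj))[1],
                         frame = 1L) {
  a <- atoms(traj)
  sel <- a$molecule_id == peptideId & a$name == "CA"
  if (!any(sel)) stop("input error: no Calpha atoms for peptide ", peptideId)
  xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
  xyz[order(a$residue_index[sel]), , drop = FALSE]
}

#' Helix axis polyline from Calpha positions
#'
#' Two estimators are available.  \code{"frenet"} (default) reconstructs the
#' axis point at each interior residue from the discrete second difference of
#' the Calpha trace, \code{A_i = P_i + H_i / (2 (1 - cos w))} with
#' \code{H_i = P_(i-1) - 2 P_i + P_(i+1)} and the helical twist \code{w}
#' estimated from the rotation of successive \code{H} vectors; this is exact
#' on an ideal helix.  \code{"centroid"} is the simpler sliding-window
#' centroid of \code{window} consecutive Calpha atoms; on an ideal helix it
#' retains a residual off-axis wobble of about 0.11 x helix radius for the
#' default 4-residue window, so it is kept only for comparison.
#'
#' @param ca matrix of ordered Calpha coordinates (one peptide).
#' @param window residues per local-axis point for the centroid method
#'   (>= 3).
#' @param method \code{"frenet"} or \code{"centroid"}.
#' @return Matrix of axis points with a \code{"residue"} attribute giving the
#'   anchor residue of each point (the interior residue for frenet, the
#'   window start for centroid).
#' @export
helixAxisPoints <- function(ca, window = 4L, method = c("frenet", "centroid")) {
  method <- match.arg(method)
  n <- nrow(ca)
  if (window < 3L) stop("input error: window must be >= 3")
  if (n < window + 2L)
    stop("input error: need at least window + 2 residues")
  if (method == "centroid") {
    m <- n - window + 1L
    ax <- t(vapply(seq_len(m), function(i)
      colMeans(ca[i:(i + window - 1L), , drop = FALSE]), numeric(3)))
    attr(ax, "residue") <- seq_len(m)
    return(ax)
  }
  idx <- 2:(n - 1L)
  H <- ca[idx - 1L, , drop = FALSE] - 2 * ca[idx, , drop = FALSE] +
    ca[idx + 1L, , drop = FALSE]
  Hu <- H / sqrt(rowSums(H^2))
  cosw <- rowSums(Hu[-nrow(Hu), , drop = FALSE] * Hu[-1L, , drop = FALSE])
  cw <- stats::median(cosw)
  if (cw > 1 - 1e-9)
    stop("degenerate geometry: no helical twist detected")
  ax <- ca[idx, , drop = FALSE] + H / (2 * (1 - cw))
  attr(ax, "residue") <- idx
  ax
}

#' Local bending angles along the helix axis
#'
#' At each axis point, chords of arc length \code{side} are drawn backward and
#' forward along the axis polyline (linear interpolation between axis
#' points); the bending angle is the turn between the two chord directions,
#' so a straight axis scores 0 degrees.  The local radius of curvature is
#' \code{side / angle_rad}; on a circular arc of radius R the angle converges
#' to \code{side / R} radians (equivalently \code{2 asin(side / 2R)} for
#' straight-chord sampling, identical to first order).
#'
#' @param axis matrix of axis points from \code{\link{helixAxisPoints}}.
#' @param side chord length in Angstrom (default 7.2, one helical turn of
#'   Calpha chord).
#' @return data.frame with columns \code{axis_point}, \code{residue},
#'   \code{arc_pos}, \code{angle_deg}, \code{radius} (Angstrom, \code{Inf}
#'   when straight; \code{NA} within \code{side} of either end where the
#'   chords do not fit).
#' @export
localBendingAngles <- function(axis, side = 7.2) {
  if (side <= 0) stop("input error: side must be positive")
  m <- nrow(axis)
  if (m < 3L) stop("input error: axis needs at least 3 points")
  seg <- sqrt(rowSums(diff(axis)^2))
  s <- c(0, cumsum(seg))
  L <- s[m]
  if (L < 2 * side)
    stop("input error: axis length ", round(L, 2),
         " A is shorter than two chords (2 x ", side, " A)")
  interp <- function(at) {
    j <- findInterval(at, s, rightmost.closed = TRUE)
    j <- max(1L, min(j, m - 1L))
    f <- (at - s[j]) / (s[j + 1L] - s[j])
    axis[j, ] + f * (axis[j + 1L, ] - axis[j, ])
  }
  angle <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (s[i] < side - 1e-9 || s[i] > L - side + 1e-9) next
    p0 <- interp(s[i] - side)
    p1 <- axis[i, ]
    p2 <- interp(s[i] + side)
    v1 <- .unit(p1 - p0)
    v2 <- .unit(p2 - p1)
    angle[i] <- acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
  }
  residue <- attr(axis, "residue")
  if (is.null(residue)) residue <- seq_len(m)
  data.frame(axis_point = seq_len(m), residue = residue, arc_pos = s,
             angle_deg = angle,
             radius = ifelse(is.na(angle), NA_real_,
                             ifelse(angle < 1e-12, Inf,
                                    side / (angle * pi / 180))))
}

#' Circle fit on the PCA best-fit plane
#'
#' Projects the Calpha positions onto the plane of their two leading
#' principal components, runs an algebraic (Kasa) least-squares circle fit,
#' and applies one geometric Gauss-Newton refinement pass.  The fitted radius
#' is the peptide's overall radius of curvature.
#'
#' @param ca matrix of ordered Calpha coordinates (>= 4 points).
#' @return A list of class \code{CurvatureFit}: \code{radius} (Angstrom),
#'   \code{center} (3-vector), \code{normal} (unit plane normal),
#'   \code{rms_residual} (in-plane RMS distance to the circle, Angstrom).
#' @examples
#' h <- makeHelix(strrep("A", 34), bendRadius = 60)
#' fitCirclePCA(helixAxisPoints(calphaCoords(h)))$radius
#' @export
fitCirclePCA <- function(ca) {
  n <- nrow(ca)
  if (n < 4L) stop("input error: need at least 4 points")
  ctr <- colMeans(ca)
  X <- sweep(ca, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop(structure(class = c("degenerateGeometryError", "error", "condition"),
                   list(message = "degenerate geometry: points are collinear, radius unbounded",
                        call = sys.call())))
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; normal <- sv$v[, 3]
  u <- X %*% e1
  v <- X %*% e2
  ## Kasa algebraic fit: u^2 + v^2 = 2 a u + 2 b v + c
  A <- cbind(2 * u, 2 * v, 1)
  y <- u^2 + v^2
  coef <- qr.solve(A, y)
  a <- coef[1]; b <- coef[2]
  R <- sqrt(coef[3] + a^2 + b^2)
  ## one geometric Gauss-Newton pass on (a, b, R)
  for (pass in 1:1) {
    di <- sqrt((u - a)^2 + (v - b)^2)
    r <- di - R
    J <- cbind(-(u - a) / di, -(v - b) / di, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) c(0, 0, 0))
    a <- a + step[1]; b <- b + step[2]; R <- R + step[3]
  }
  di <- sqrt((u - a)^2 + (v - b)^2)
  structure(list(radius = R,
                 center = ctr + as.numeric(a) * e1 + as.numeric(b) * e2,
                 normal = normal,
                 rms_residual = sqrt(mean((di - R)^2))),
            class = "CurvatureFit")
}

#' @export
print.CurvatureFit <- function(x, ...) {
  cat(sprintf("Circle fit: R = %.3f A (rms residual %.4f A)\n",
              x$radius, x$rms_residual))
  invisible(x)
}

## Dihedral angle (degrees) of four points, IUPAC sign convention.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Per-residue helical fraction over frames
#'
#' A residue counts as helical in a frame when its backbone dihedrals fall in
#' the alpha-helical basin, phi in [-100, -30] and psi in [-80, -5] degrees.
#' Terminal residues lacking a dihedral are reported as \code{NA}.
#'
#' @param traj a \linkS4class{Trajectory} with N/CA/C atoms per residue.
#' @param peptideId molecule id of the peptide.
#' @return data.frame with columns \code{residue} and \code{helical_fraction}.
#' @export
helicityProfile <- function(traj, peptideId = peptideIds(topology(traj))[1]) {
  a <- atoms(traj)
  sel <- a$molecule_id == peptideId
  res_ids <- sort(unique(a$residue_index[sel]))
  idx_of <- function(res, nm) {
    w <- which(sel & a$residue_index == res & a$name == nm)
    if (length(w) != 1L)
      stop("input error: residue ", res, " lacks backbone atom ", nm)
    w
  }
  iN <- vapply(res_ids, idx_of, 1L, nm = "N")
  iCA <- vapply(res_ids, idx_of, 1L, nm = "CA")
  iC <- vapply(res_ids, idx_of, 1L, nm = "C")
  nf <- nFrames(traj)
  nres <- length(res_ids)
  helical <- matrix(NA, nf, nres)
  for (f in seq_len(nf)) {
    x <- frameCoords(traj, f)
    for (r in seq_len(nres)) {
      if (r == 1L || r == nres) next
      phi <- .dihedral(x[iC[r - 1L], ], x[iN[r], ], x[iCA[r], ], x[iC[r], ])
      psi <- .dihedral(x[iN[r], ], x[iCA[r], ], x[iC[r], ], x[iN[r + 1L], ])
      helical[f, r] <- phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5
    }
  }
  data.frame(residue = res_ids,
             helical_fraction = colMeans(helical))
}

#' Time x residue bending-angle matrix
#'
#' Runs the axis construction and local bending angles on every frame and
#' stacks the profiles into a matrix (rows = frames), the quantity behind the
#' bending-angle-over-time heat map.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param peptideId molecule id of the peptide.
#' @param side chord length in Angstrom.
#' @param method axis method, see \code{\link{helixAxisPoints}}.
#' @return Numeric matrix frames x axis points, with frame times as row names
#'   and anchor residues as column names.
#' @export
bendingHeatmapTable <- function(traj, peptideId = peptideIds(topology(traj))[1],
                                side = 7.2, method = "frenet") {
  nf <- nFrames(traj)
  if (nf < 1L) stop("input error: trajectory has no frames")
  rows <- lapply(seq_len(nf), function(f) {
    ax <- helixAxisPoints(calphaCoords(traj, peptideId, f), method = method)
    localBendingAngles(ax, side = side)$angle_deg
  })
  m <- do.call(rbind, rows)
  ax1 <- helixAxisPoints(calphaCoords(traj, peptideId, 1L), method = method)
  colnames(m) <- paste0("res", attr(ax1, "residue"))
  rownames(m) <- format(frameTimes(traj))
  m
}
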