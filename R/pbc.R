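#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Euclidean distance between two points using the nearest periodic copy in an
#' orthorhombic box.  All cutoff-based analyses in the package use this
#' convention.
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @param box numeric length-3 positive box lengths (Angstrom).
#' @return Distance in Angstrom; never exceeds half the box diagonal.
#' @examples
#' minimumImageDistance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10))  # 1
#' @export
minimumImageDistance <- function(a, b, box) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(box) == 3L)
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

## Pairwise minimum-image distance matrix between coordinate sets A [n x 3]
## and B [m x 3]; returns [n x m].  Vectorised per dimension.
.mi_crossdist <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

## Minimum-image displacement of the XY components only (lateral distances).
.mi_crossdist_xy <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:2) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
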