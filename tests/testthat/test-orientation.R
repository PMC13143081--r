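test_that("axis vector points from N-patch to C-patch and is equivariant", {
  h <- makeHelix(ah_seq())
  v <- axisVector(h)
  expect_lt(sqrt(sum((v - c(1, 0, 0))^2)), 0.05)
  expect_equal(sqrt(sum(v^2)), 1)
  ## rigid rotation rotates the axis identically
  set.seed(23)
  for (i in 1:5) {
    tr <- random_rigid()
    rot <- with_coords(h, apply_rigid(frameCoords(h, 1), tr))
    expect_equal(axisVector(rot), as.numeric(tr$R %*% v), tolerance = 1e-9)
  }
  ## bent helix: axis equals the chord between the patch COMs, computed
  ## directly as the oracle
  hb <- makeHelix(ah_seq(), bendRadius = 60)
  a <- atoms(hb)
  x <- frameCoords(hb, 1)
  com <- function(range) {
    sel <- a$residue_index >= range[1] & a$residue_index <= range[2]
    colMeans(x[sel, , drop = FALSE])
  }
  chord <- com(c(27, 34)) - com(c(1, 8))
  expect_equal(axisVector(hb), chord / sqrt(sum(chord^2)), tolerance = 1e-12)
})

test_that("patch contact counts recover the scene manifests", {
  scA <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                             nForcedContactsA = 8L)
  expect_identical(unname(patchContactCounts(scA)), c(8L, 0L))
  scP <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 0,
                             nForcedContactsP = 4L)
  expect_identical(unname(patchContactCounts(scP)), c(0L, 4L))
  ## far-apart peptides: no contacts
  far <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 90,
                             centerSeparation = 100)
  expect_identical(unname(patchContactCounts(far)), c(0L, 0L))
  ## raising the cutoff never decreases A or P
  c1 <- patchContactCounts(scA, cutoff = 4.5)
  c2 <- patchContactCounts(scA, cutoff = 8)
  expect_true(all(c2 >= c1))
})

test_that("patch counts equal a brute-force reimplementation on scene fixtures", {
  sc <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                            nForcedContactsA = 6L, nForcedContactsP = 2L)
  expect_lt(nAtoms(sc), 500L)
  a <- atoms(sc)
  x <- frameCoords(sc, 1)
  box <- frameBox(sc, 1)
  regions <- PeptideRegions()
  brute_dir <- function(p_from, patch, p_to) {
    i1 <- which(a$molecule_id == p_from & a$is_heavy &
                  a$residue_index >= patch[1] & a$residue_index <= patch[2])
    i2 <- which(a$molecule_id == p_to & a$is_heavy &
                  a$residue_index >= regions@secondHalf[1] &
                  a$residue_index <= regions@secondHalf[2])
    sum(brute_contact_matrix(x, box, i1, a$residue_index[i1],
                             i2, a$residue_index[i2], 4.5, strict = TRUE))
  }
  A_brute <- brute_dir(1L, regions@nPatch, 2L) +
    brute_dir(2L, regions@nPatch, 1L)
  P_brute <- brute_dir(1L, regions@cPatch, 2L) +
    brute_dir(2L, regions@cPatch, 1L)
  expect_identical(unname(patchContactCounts(sc)),
                   c(as.integer(A_brute), as.integer(P_brute)))
  expect_identical(unname(patchContactCounts(sc)), c(6L, 2L))
})

test_that("frame classification applies the strict T > threshold rule", {
  rec <- data.frame(frame = 1:4, time_ns = 0:3,
                    cos_theta = c(-0.95, -0.95, 0.9, 0.1),
                    A = c(8L, 3L, 1L, 4L), P = c(0L, 1L, 4L, 4L))
  rec$T <- rec$A + rec$P
  cl <- classifyFrames(rec, threshold = 5L)
  expect_identical(cl$records$interacting, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(cl$records$label,
                   c("antiparallel_like", "none", "none", "mixed"))
  ## T = 6 with P majority is parallel_like
  rec2 <- data.frame(frame = 1, time_ns = 0, cos_theta = 0.98,
                     A = 1L, P = 5L, T = 6L)
  expect_identical(classifyFrames(rec2)$records$label, "parallel_like")
  ## histograms split by the interacting flag
  expect_identical(sum(cl$hist_interacting$count), 2L)
  expect_identical(sum(cl$hist_noninteracting$count), 2L)
  expect_error(classifyFrames(rec[0, ]), "no orientation records")
})

test_that("closed-loop recovery: planted scenes classify 100% correctly", {
  scA <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                             nForcedContactsA = 8L, nFrames = 4L)
  clA <- classifyFrames(orientationSeries(scA))
  expect_true(all(clA$records$label == "antiparallel_like"))
  expect_true(all(clA$records$cos_theta < -0.99))
  scP <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 0,
                             nForcedContactsP = 7L, nFrames = 4L)
  clP <- classifyFrames(orientationSeries(scP))
  expect_true(all(clP$records$label == "parallel_like"))
  expect_true(all(clP$records$cos_theta > 0.99))
  ## cos(theta) is invariant to swapping the peptides
  os12 <- orientationSeries(scA, peptides = c(1L, 2L), frames = 1L)
  os21 <- orientationSeries(scA, peptides = c(2L, 1L), frames = 1L)
  expect_equal(os12$cos_theta, os21$cos_theta, tolerance = 1e-12)
})

test_that("Z-COM records follow construction heights and symmetries", {
  b <- makeBilayer(nx = 5, ny = 5, seed = 10)
  pep <- makeHelix(ah_seq())
  scene <- mergeScene(b, pep, zOffset = 30)
  zc <- zcomDistribution(scene)
  expect_true(all(abs(zc$records$z - 30) < 3))
  ## z-inversion negates the records
  x <- frameCoords(scene, 1)
  x[, 3] <- -x[, 3]
  zc_inv <- zcomDistribution(with_coords(scene, x))
  expect_equal(zc_inv$records$z, -zc$records$z, tolerance = 1e-9)
  ## membrane-free scene measures absolute z
  zc0 <- zcomDistribution(pep)
  com_z <- mean(frameCoords(pep, 1)[atoms(pep)$is_heavy, 3])
  expect_equal(zc0$records$z, com_z)
})

test_that("per-residue Z-COM summaries resolve a tilted helix", {
  pep <- makeHelix(ah_seq())
  ## helix along +x at uniform height: all residue medians within the helix
  ## radius of the common height
  x <- frameCoords(pep, 1)
  x[, 3] <- x[, 3] + 20
  flat <- with_coords(pep, x)
  pr <- perResidueZcom(flat)
  expect_true(all(abs(pr$median - 20) < 3))
  ## N-terminus-down tilt: medians increase with residue index
  xt <- frameCoords(pep, 1)
  xt[, 3] <- xt[, 3] + 0.5 * xt[, 1]
  tilted <- with_coords(pep, xt)
  prt <- perResidueZcom(tilted)
  fit <- stats::lm(median ~ residue, data = prt)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(stats::cor(prt$residue, prt$median), 0.95)
  ## single frame: quartiles collapse onto the point value
  expect_equal(prt$min, prt$max)
  expect_equal(prt$q1, prt$median)
})
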