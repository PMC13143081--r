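test_that("helix axis reconstruction is exact on ideal helices", {
  h <- makeHelix(ah_seq())
  ca <- calphaCoords(h)
  ax <- helixAxisPoints(ca)
  ## collinearity: residual from the best-fit line
  X <- sweep(ax, 2, colMeans(ax))
  sv <- svd(X)
  dev <- sqrt(rowSums((X - X %*% sv$v[, 1] %*% t(sv$v[, 1]))^2))
  expect_lt(max(dev), 0.1)
  ## the centroid axis keeps its documented point count
  axc <- helixAxisPoints(ca, window = 4, method = "centroid")
  expect_identical(nrow(axc), 34L - 4L + 1L)
  expect_identical(nrow(helixAxisPoints(ca[1:6, ], window = 4,
                                        method = "centroid")), 3L)
  expect_error(helixAxisPoints(ca[1:4, ]), "window \\+ 2")
})

test_that("bending angles recover the closed-form chord-turning angle on arcs", {
  for (R in c(30, 60, 200)) {
    hb <- makeHelix(ah_seq(), bendRadius = R)
    ax <- helixAxisPoints(calphaCoords(hb))
    prof <- localBendingAngles(ax, side = 7.2)
    expected <- 2 * asin(7.2 / (2 * R)) * 180 / pi
    interior <- prof$angle_deg[!is.na(prof$angle_deg)]
    expect_gt(length(interior), 5)
    expect_true(all(abs(interior - expected) / expected < 0.02),
                label = sprintf("angles within 2%% at R = %g", R))
    ## radius = side / angle recovers the generator radius within 2%
    radii <- prof$radius[!is.na(prof$radius)]
    expect_true(all(abs(radii - R) / R < 0.02))
  }
  ## straight helix: all angles essentially zero
  prof0 <- localBendingAngles(helixAxisPoints(calphaCoords(makeHelix(ah_seq()))))
  expect_lt(max(prof0$angle_deg, na.rm = TRUE), 1)
  ## halving the chord halves the angle (small-angle linearity) within 5%
  hb <- makeHelix(ah_seq(), bendRadius = 60)
  ax <- helixAxisPoints(calphaCoords(hb))
  a1 <- mean(localBendingAngles(ax, side = 7.2)$angle_deg, na.rm = TRUE)
  a2 <- mean(localBendingAngles(ax, side = 3.6)$angle_deg, na.rm = TRUE)
  expect_lt(abs(a1 / a2 - 2), 0.1)
  expect_error(localBendingAngles(ax, side = 100), "shorter than")
})

test_that("bending angles are invariant under rigid transforms", {
  hb <- makeHelix(ah_seq(), bendRadius = 60)
  ca <- calphaCoords(hb)
  ref <- localBendingAngles(helixAxisPoints(ca))$angle_deg
  set.seed(31)
  for (i in 1:5) {
    tr <- random_rigid()
    got <- localBendingAngles(helixAxisPoints(apply_rigid(ca, tr)))$angle_deg
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("PCA circle fit recovers exact and noisy circles and flags degeneracy", {
  ## exact circle in a tilted plane: 1e-6 relative recovery
  th <- seq(0, 2 * pi, length.out = 35)[-35]
  pts <- cbind(60 * cos(th), 60 * sin(th), 0)
  tilt <- matrix(c(1, 0, 0,
                   0, cos(0.6), -sin(0.6),
                   0, sin(0.6), cos(0.6)), 3, 3, byrow = TRUE)
  pts_t <- pts %*% t(tilt) + rep(c(5, -3, 12), each = nrow(pts))
  fit <- fitCirclePCA(pts_t)
  expect_lt(abs(fit$radius - 60) / 60, 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  ## seeded Gaussian noise sigma = 0.5 A: within 2%
  set.seed(17)
  noisy <- pts_t + matrix(rnorm(length(pts_t), sd = 0.5), ncol = 3)
  fitn <- fitCirclePCA(noisy)
  expect_lt(abs(fitn$radius - 60) / 60, 0.02)
  ## invariance to point order and rigid motion
  set.seed(18)
  tr <- random_rigid()
  fit2 <- fitCirclePCA(apply_rigid(pts_t[sample(nrow(pts_t)), ], tr))
  expect_equal(fit2$radius, fit$radius, tolerance = 1e-9)
  ## collinear points signal degenerate geometry
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fitCirclePCA(line), "collinear")
  expect_error(fitCirclePCA(pts_t[1:3, ]), "at least 4")
})

test_that("helicity profile separates helical, extended and mixed ensembles", {
  h <- makeHelix(ah_seq())
  prof <- helicityProfile(h)
  interior <- prof$helical_fraction[-c(1, nrow(prof))]
  expect_true(all(interior == 1))
  expect_true(is.na(prof$helical_fraction[1]))
  expect_true(is.na(prof$helical_fraction[nrow(prof)]))
  ## fully extended chain scores zero
  ext <- septinAH:::.build_chain(ah_seq(), phi = rep(-179, 34),
                                 psi = rep(179, 34))
  topo <- topology(h)
  ext_traj <- Trajectory(topo, ext$xyz, box = c(200, 200, 200))
  prof_ext <- helicityProfile(ext_traj)
  expect_true(all(prof_ext$helical_fraction[-c(1, 34)] == 0))
  ## half-helical / half-extended frame set scores 0.5
  xyz_h <- frameCoords(h, 1)
  mix <- Trajectory(topo, array(c(xyz_h, ext$xyz),
                                dim = c(nrow(xyz_h), 3, 2)),
                    box = c(200, 200, 200))
  prof_mix <- helicityProfile(mix)
  expect_true(all(prof_mix$helical_fraction[-c(1, 34)] == 0.5))
})

test_that("bending heat map stacks per-frame profiles", {
  hb <- makeHelix(ah_seq(), bendRadius = 60)
  xyz <- frameCoords(hb, 1)
  static <- Trajectory(topology(hb),
                       array(rep(xyz, 10), dim = c(nrow(xyz), 3, 10)),
                       box = c(200, 200, 200))
  m <- bendingHeatmapTable(static)
  expect_identical(nrow(m), 10L)
  for (f in 2:10) expect_equal(m[f, ], m[1, ])
  ## straight-to-bent morph: mean interior angle increases monotonically
  hs <- makeHelix(ah_seq())
  xs <- frameCoords(hs, 1)
  frames <- lapply(seq(0, 1, length.out = 5), function(w) (1 - w) * xs + w * xyz)
  morph <- Trajectory(topology(hb),
                      array(unlist(frames), dim = c(nrow(xyz), 3, 5)),
                      box = c(200, 200, 200))
  mm <- bendingHeatmapTable(morph)
  means <- rowMeans(mm, na.rm = TRUE)
  expect_true(all(diff(means) > -1e-9))
  ## single frame -> single row
  expect_identical(nrow(bendingHeatmapTable(hb)), 1L)
})
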