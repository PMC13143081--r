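test_that("leaflet assignment splits the lattice bilayer evenly", {
  b <- makeBilayer(nx = 5, ny = 5, seed = 3)
  la <- assignLeaflets(b)
  expect_identical(sum(la$leaflet == "upper"), 25L)
  expect_identical(sum(la$leaflet == "lower"), 25L)
  ## symmetric bilayer: midplane at the phosphate-plane average
  expect_lt(abs(la$midplane_z - 0), 1e-9)
  ## single flat leaflet is flagged degenerate
  x <- frameCoords(b, 1)
  a <- atoms(b)
  up_ids <- as.integer(names(la$leaflet)[la$leaflet == "upper"])
  keep <- a$molecule_id %in% up_ids
  topo_up <- Topology(a[keep, ],
                      lipidSpecies = lipidSpecies(topology(b))[as.character(up_ids)],
                      phosphateNames = topology(b)@phosphateNames,
                      tailAtoms = topology(b)@tailAtoms)
  traj_up <- Trajectory(topo_up, x[keep, ], frameBox(b, 1))
  expect_warning(assignLeaflets(traj_up), "degenerate")
})

test_that("Voronoi areas partition the box and match the lattice ground truth", {
  b <- makeBilayer(nx = 6, ny = 6, spacing = 8, seed = 1)
  apl <- areaPerLipid(b, leaflet = "upper")
  expect_true(all(abs(apl$lipids$area - 64) < 1e-6))
  expect_lt(abs(sum(apl$lipids$area) - apl$box_area), 1e-6 * apl$box_area)
  ## jittered (non-lattice) seeds still partition exactly
  x <- frameCoords(b, 1)
  a <- atoms(b)
  set.seed(9)
  psel <- a$name == "P"
  x[psel, 1:2] <- x[psel, 1:2] + matrix(rnorm(sum(psel) * 2, sd = 1.5),
                                        ncol = 2)
  bj <- with_coords(b, x)
  aplj <- areaPerLipid(bj, leaflet = "upper")
  expect_lt(abs(sum(aplj$lipids$area) - aplj$box_area),
            1e-6 * aplj$box_area)
  expect_gt(stats::sd(aplj$lipids$area), 0)
})

test_that("removing one lipid redistributes its area to the XY neighbours", {
  b <- makeBilayer(nx = 6, ny = 6, spacing = 8, seed = 1)
  apl0 <- areaPerLipid(b, leaflet = "upper")
  ## drop the lipid whose phosphate sits nearest the box centre
  ctr <- frameBox(b, 1)[1:2] / 2
  d2 <- (apl0$lipids$x - ctr[1])^2 + (apl0$lipids$y - ctr[2])^2
  victim <- apl0$lipids$molecule_id[which.min(d2)]
  a <- atoms(b)
  keep <- a$molecule_id != victim
  topo2 <- Topology(a[keep, ],
                    lipidSpecies = lipidSpecies(topology(b))[
                      setdiff(names(lipidSpecies(topology(b))),
                              as.character(victim))],
                    phosphateNames = topology(b)@phosphateNames,
                    tailAtoms = topology(b)@tailAtoms)
  b2 <- Trajectory(topo2, frameCoords(b, 1)[keep, ], frameBox(b, 1))
  apl1 <- areaPerLipid(b2, leaflet = "upper")
  ## conservation still exact
  expect_lt(abs(sum(apl1$lipids$area) - apl1$box_area),
            1e-6 * apl1$box_area)
  ## the four lattice neighbours each gain a quarter of the freed cell
  vx <- apl0$lipids$x[apl0$lipids$molecule_id == victim]
  vy <- apl0$lipids$y[apl0$lipids$molecule_id == victim]
  nb <- apl1$lipids[abs(abs(apl1$lipids$x - vx) - 8) < 1e-6 &
                      abs(apl1$lipids$y - vy) < 1e-6 |
                      abs(abs(apl1$lipids$y - vy) - 8) < 1e-6 &
                      abs(apl1$lipids$x - vx) < 1e-6, ]
  expect_identical(nrow(nb), 4L)
  expect_true(all(abs(nb$area - 80) < 1e-6))  # 64 + 64/4
  untouched <- apl1$lipids[apl1$lipids$x != vx & apl1$lipids$y != vy, ]
  expect_true(all(abs(untouched$area - 64) < 1e-6))
})

test_that("periodic Voronoi agrees with the deldir oracle on random seeds", {
  skip_if_not_installed("deldir")
  set.seed(14)
  box <- c(48, 40)
  xy <- cbind(runif(40, 0, box[1]), runif(40, 0, box[2]))
  mine <- septinAH:::.periodic_voronoi(xy, box)$areas
  ## oracle: deldir on the 9-fold periodic expansion; the central copies are
  ## fully surrounded by images, so their (unclipped) tiles are the periodic
  ## Voronoi cells
  img <- do.call(rbind, lapply(-1:1, function(sx)
    do.call(rbind, lapply(-1:1, function(sy)
      cbind(xy[, 1] + sx * box[1], xy[, 2] + sy * box[2])))))
  central_rows <- 4L * 40L + seq_len(40L)  # block (sx = 0, sy = 0)
  dd <- deldir::deldir(img[, 1], img[, 2],
                       rw = c(-box[1], 2 * box[1], -box[2], 2 * box[2]))
  tl <- deldir::tile.list(dd)
  pt_num <- vapply(tl, function(t) t$ptNum, 1L)
  oracle <- vapply(central_rows, function(k)
    tl[[which(pt_num == k)]]$area, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-6)
})

test_that("nematic order hits the analytic values at canonical tilts", {
  for (case in list(list(t = 0, S = 1), list(t = 54.7356, S = 0),
                    list(t = 90, S = -0.5))) {
    b <- makeBilayer(nx = 4, ny = 4,
                     tiltDistribution = list(kind = "fixed",
                                             theta0 = case$t), seed = 2)
    no <- nematicOrder(b)
    expect_true(all(abs(no$S - case$S) < 1e-6),
                label = sprintf("S at tilt %g", case$t))
  }
  ## Gaussian tilt ensemble: mean S within 3 SE of the Monte-Carlo analytic
  ## expectation of the same distribution
  b <- makeBilayer(nx = 10, ny = 10,
                   tiltDistribution = list(kind = "gaussian", mean = 25,
                                           sd = 8), seed = 33)
  no <- nematicOrder(b)
  set.seed(1000)
  th <- pmin(pmax(rnorm(2e5, 25, 8), 0), 90) * pi / 180
  s_mc <- (3 * cos(th)^2 - 1) / 2
  se <- stats::sd(no$S) / sqrt(nrow(no))
  expect_lt(abs(mean(no$S) - mean(s_mc)), 3 * se)
})

test_that("order parameter is invariant to XY translation and z-inversion", {
  b <- makeBilayer(nx = 4, ny = 4,
                   tiltDistribution = list(kind = "gaussian", mean = 20,
                                           sd = 10), seed = 8)
  ref <- nematicOrder(b)$S
  x <- frameCoords(b, 1)
  shifted <- x
  shifted[, 1] <- shifted[, 1] + 13.7
  shifted[, 2] <- shifted[, 2] - 4.2
  expect_equal(nematicOrder(with_coords(b, shifted))$S, ref,
               tolerance = 1e-12)
  inverted <- x
  inverted[, 3] <- -inverted[, 3]
  expect_equal(nematicOrder(with_coords(b, inverted))$S, ref,
               tolerance = 1e-12)
})

test_that("near/far split recovers a planted low-order region", {
  b <- makeBilayer(nx = 8, ny = 8, spacing = 8, seed = 12)
  pep <- makeHelix(ah_seq())
  scene <- mergeScene(b, pep, zOffset = 25)
  topo <- topology(scene)
  a <- atoms(scene)
  x <- frameCoords(scene, 1)
  ## tilt the tails of lipids within 10 A (lateral) of the peptide to 90 deg
  psel <- a$molecule_id %in% peptideIds(topo) & a$is_heavy
  for (id in lipidIds(topo)) {
    prow <- which(a$molecule_id == id & a$name == "P")
    dxy <- min(septinAH:::.mi_crossdist_xy(x[prow, , drop = FALSE],
                                           x[psel, , drop = FALSE],
                                           frameBox(scene, 1)))
    if (dxy <= 10) {
      trows <- which(a$molecule_id == id & a$name != "P")
      for (k in seq_along(trows))
        x[trows[k], ] <- x[prow, ] + c(1.5 * k, 0, 0)  # tails along +x
    }
  }
  planted <- with_coords(scene, x)
  nf <- nearFarHistogram(planted, frames = 1L)
  expect_gt(nrow(nf$near), 0)
  expect_gt(nrow(nf$far), 0)
  expect_lt(mean(nf$near$S), mean(nf$far$S))
  expect_true(all(abs(nf$near$S - (-0.5)) < 1e-9))
  expect_error(nearFarHistogram(planted, nearCutoff = 30, farCutoff = 25),
               "input error")
  ## membrane-only scene: every lipid is "far"
  expect_warning(nf0 <- nearFarHistogram(b, frames = 1L), "empty 'near'")
  expect_identical(nrow(nf0$far), length(lipidIds(topology(b))))
})

test_that("z-density shows the two phosphate planes and scales with frames", {
  b <- makeBilayer(nx = 5, ny = 5, leafletSeparation = 38, seed = 4)
  zd <- zDensity(b, phosphateSelection(topology(b)))
  peaks <- zd$z_mid[zd$count > 0]
  expect_equal(sort(peaks), c(-18.5, 18.5))
  ## doubling frames doubles counts but leaves the density unchanged
  x <- frameCoords(b, 1)
  b2 <- Trajectory(topology(b), array(rep(x, 2), dim = c(nrow(x), 3, 2)),
                   frameBox(b, 1))
  zd2 <- zDensity(b2, phosphateSelection(topology(b)))
  expect_equal(zd2$count, 2L * zd$count)
  expect_equal(zd2$density, zd$density)
  expect_error(zDensity(b, integer(0)), "empty selection")
})
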