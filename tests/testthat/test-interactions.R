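test_that("contact map matches a brute-force all-pairs oracle", {
  sc <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                            nForcedContactsA = 3L, centerSeparation = 14)
  expect_lt(nAtoms(sc), 500L)
  a <- atoms(sc)
  x <- frameCoords(sc, 1)
  box <- frameBox(sc, 1)
  for (mode in c("calpha", "heavy")) {
    cutoff <- if (mode == "calpha") 7.5 else 4.5
    cm <- contactMap(sc, 1L, 2L, mode, cutoff, frames = 1L)
    sel <- function(p) {
      s <- a$molecule_id == p
      if (mode == "calpha") which(s & a$name == "CA") else which(s & a$is_heavy)
    }
    i1 <- sel(1L); i2 <- sel(2L)
    oracle <- brute_contact_matrix(x, box, i1, a$residue_index[i1],
                                   i2, a$residue_index[i2], cutoff)
    expect_identical(unname(cm$frequency == 1), unname(oracle))
  }
})

test_that("contact map satisfies its basic identities", {
  far <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                             centerSeparation = 100)
  cm_far <- contactMap(far, 1L, 2L, "calpha", 7.5, frames = 1L)
  expect_true(all(cm_far$frequency == 0))
  ## intra map: symmetric with unit diagonal (self-distance 0)
  h <- makeHelix(ah_seq())
  cm_intra <- contactMap(h, 1L, 1L, "calpha", 7.5)
  expect_true(all(diag(cm_intra$frequency) == 1))
  expect_identical(cm_intra$frequency, t(cm_intra$frequency))
  ## monotone in the cutoff
  sc <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                            nForcedContactsA = 5L, centerSeparation = 14)
  f1 <- contactMap(sc, 1L, 2L, "heavy", 4.0, frames = 1L)$frequency
  f2 <- contactMap(sc, 1L, 2L, "heavy", 6.0, frames = 1L)$frequency
  expect_true(all(f2 >= f1))
  expect_error(contactMap(sc, 1L, 2L, "calpha", -1), "cutoff")
})

test_that("domain contact maps coarse-grain and window correctly", {
  sc <- makeTwoPeptideScene(ah_seq(), interAxisAngle = 180,
                            nForcedContactsA = 4L, nFrames = 8L)
  cm <- contactMap(sc, 1L, 2L, "heavy", 4.5)
  ## planted block: only peptide-1 N-patch x peptide-2 positions 17-26
  dcm <- domainContactMap(cm, nWindows = 4L)
  expect_identical(length(dcm$windows), 4L)
  for (w in dcm$windows) {
    expect_gt(w["N-term", "AH"], 0)
    expect_equal(w["C-term", "C-term"], 0)
    expect_equal(w["AH", "AH"], 0)
  }
  ## n_windows = 1 equals the whole-trajectory mean
  d1 <- domainContactMap(cm, nWindows = 1L)$windows[[1]]
  regions <- PeptideRegions()
  dom <- list(regions@nPatch, regions@ahCore, regions@cPatch)
  rr <- as.integer(rownames(cm$frequency))
  for (di in 1:3) for (dj in 1:3) {
    sel_i <- rr >= dom[[di]][1] & rr <= dom[[di]][2]
    sel_j <- rr >= dom[[dj]][1] & rr <= dom[[dj]][2]
    expect_equal(d1[di, dj], mean(cm$frequency[sel_i, sel_j]))
  }
  ## uniform all-ones map gives all-ones coarse cells
  cm1 <- cm
  cm1$per_frame[] <- TRUE
  cm1$frequency[] <- 1
  du <- domainContactMap(cm1, nWindows = 2L)
  for (w in du$windows) expect_true(all(w == 1))
  expect_error(domainContactMap(cm, nWindows = 100L), "nWindows")
})

test_that("residue-class contacts count planted charged pairs", {
  ## toy: one GLU oxygen within 3 A of one ARG nitrogen
  toy <- make_saltbridge_toy(list(E10_R4 = rep(3.0, 4)))
  rcc <- residueClassContacts(toy, 1L, 2L, cutoff = 3.5)
  expect_identical(rcc$class_counts["acidic", "basic"], 4L)  # 1 pair x 4 frames
  expect_identical(rcc$total, 4L)
  ## class totals partition the residue-pair contact count
  expect_identical(sum(rcc$class_counts), rcc$total)
  ## everything farther than the cutoff: zero counts
  toy0 <- make_saltbridge_toy(list(E10_R4 = rep(50, 2)))
  rcc0 <- residueClassContacts(toy0, 1L, 2L, cutoff = 3.5)
  expect_identical(rcc0$total, 0L)
})

test_that("headgroup contact profile localises a planted PLPI contact", {
  ## 8 x 8 lattice so the 64 A box exceeds the ~52 A helix and the planted
  ## contact cannot wrap onto the far end of the peptide
  b <- makeBilayer(nx = 8, ny = 8, seed = 6)
  pep <- makeHelix(ah_seq())
  ## peptide held well above the headgroups (11 A clearance, inside the box
  ## so the minimum-image convention cannot wrap it onto the lower leaflet)
  high <- mergeScene(b, pep, zOffset = 30)
  prof <- headgroupContactProfile(high, cutoff = 4.5)
  expect_true(all(prof$DOPC == 0) && all(prof$PLPI == 0))
  ## plant: move one PLPI phosphate 4 A beyond residue 34's Calpha, along
  ## the outward chain direction so no other residue comes within the cutoff
  scene <- mergeScene(b, pep, zOffset = 30)
  topo <- topology(scene)
  a <- atoms(scene)
  x <- frameCoords(scene, 1)
  plpi_ids <- as.integer(names(lipidSpecies(topo))[lipidSpecies(topo) == "PLPI"])
  prow <- which(a$molecule_id == plpi_ids[1] & a$name == "P")
  ca34 <- which(a$molecule_kind == "peptide" & a$residue_index == 34L &
                  a$name == "CA")
  ca33 <- which(a$molecule_kind == "peptide" & a$residue_index == 33L &
                  a$name == "CA")
  u <- x[ca34, ] - x[ca33, ]
  u <- u / sqrt(sum(u^2))
  x[prow, ] <- x[ca34, ] + 4 * u
  planted <- with_coords(scene, x)
  prof2 <- headgroupContactProfile(planted, cutoff = 4.5)
  expect_true(prof2$PLPI[prof2$residue == 34] > 0)
  expect_true(all(prof2$PLPI[prof2$residue != 34] == 0))
  expect_true(all(prof2$DOPC == 0))
})

test_that("salt-bridge detection applies the O-N criterion with residue dedup", {
  on <- make_saltbridge_toy(list(E10_R4 = c(3.0)))
  hits <- detectSaltBridges(on, 1L, onCutoff = 3.2)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$acidic_res, 10L)
  expect_identical(hits$basic_res, 4L)
  off <- make_saltbridge_toy(list(E10_R4 = c(3.5)))
  expect_identical(nrow(detectSaltBridges(off, 1L, onCutoff = 3.2)), 0L)
  ## several close O-N atom pairs of one residue pair count once: place NH1
  ## near both OE1 and OE2 (OE2 sits 2 A above OE1)
  near2 <- make_saltbridge_toy(list(E10_R4 = c(1.5)))
  hits2 <- detectSaltBridges(near2, 1L, onCutoff = 3.2)
  expect_identical(nrow(hits2), 1L)
  ## missing named side-chain atoms is an input error naming the residue
  h <- makeHelix(ah_seq())  # side chains are CB pseudo-atoms only
  expect_error(detectSaltBridges(h), "GLU")
})

test_that("occupancy and lifetime statistics match hand counts", {
  ## pattern: on(10), off(5), on(10) at dt = 1 ns
  pat <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 10))
  lt <- bridgeLifetimes(pat, dtNs = 1)
  expect_identical(lt$n_events, 2L)
  expect_equal(lt$total_on_ns, 20)
  expect_equal(lt$median_ns, 10)
  ## gap tolerance 5 absorbs the gap into one 25 ns event
  lt5 <- bridgeLifetimes(pat, dtNs = 1, gapTolerance = 5L)
  expect_identical(lt5$n_events, 1L)
  expect_equal(lt5$total_on_ns, 25)
  ## occupancy: always-on pair
  expect_equal(bridgeOccupancy(rep(TRUE, 400))$occupancy_mean, 1.0)
  ## never-active pairs are absent from the sparse report
  m <- rbind(a = c(TRUE, FALSE, TRUE), b = c(FALSE, FALSE, FALSE))
  occ <- bridgeOccupancy(m)
  expect_identical(occ$pair, "a")
  ## duration sum identity: total on time = occupancy x total time (gap 0)
  set.seed(40)
  x <- runif(500) < 0.3
  expect_equal(sum(bridgeLifetimes(x, dtNs = 2)$total_on_ns),
               mean(x) * 500 * 2)
  ## replica aggregation reports mean and sd
  occ2 <- bridgeOccupancy(list(rep(TRUE, 10), c(rep(TRUE, 5), rep(FALSE, 5))))
  expect_equal(occ2$occupancy_mean, 0.75)
  expect_equal(occ2$occupancy_sd, sd(c(1, 0.5)))
})

test_that("telegraph fixtures are recovered within 3 standard errors", {
  ## dt = 0.1 ns, fine relative to the 20 ns dwells: event statistics from a
  ## sampled series carry an O(dt) discretisation bias, so the sampling must
  ## resolve the dwell times for the estimator to be comparable to the truth
  ts <- makeTelegraphSeries(100000, dtNs = 0.1, meanOnNs = 20,
                            meanOffNs = 20, seed = 77)
  occ <- bridgeOccupancy(ts$series)
  n_dwell <- 100000 * 0.1 / 40
  expect_lt(abs(occ$occupancy_mean - ts$truth$occupancy),
            3 * 0.5 / sqrt(n_dwell))
  lt <- bridgeLifetimes(ts$series, dtNs = ts$dt_ns)
  ## mean event duration vs the true 20 ns mean on-time (exponential:
  ## se = mean / sqrt(n))
  mean_dur <- lt$total_on_ns / lt$n_events
  expect_lt(abs(mean_dur - 20), 3 * 20 / sqrt(lt$n_events))
})

test_that("salt-bridge series, occupancy and traces work end to end", {
  ## E10-R4 on for frames 1-6, off 7-10; E20-K18 on at frames 2-3 only
  d1 <- c(rep(2.9, 6), rep(8, 4))
  d2 <- c(8, 2.5, 2.5, rep(9, 7))
  toy <- make_saltbridge_toy(list(E10_R4 = d1, E20_K18 = d2))
  sb <- saltBridgeSeries(toy)
  occ <- bridgeOccupancy(sb)
  expect_identical(nrow(occ), 2L)
  expect_equal(occ$occupancy_mean[1], 0.6)  # top pair first
  lt <- bridgeLifetimes(sb)
  expect_identical(lt$n_events, c(1L, 1L))
  ## distance traces of the top pair reproduce the scripted distances
  tr <- topPairsTimeseries(sb, k = 1L)
  expect_identical(nrow(tr), 1L)
  expect_equal(unname(tr[1, ]), d1, tolerance = 1e-9)
  ## asking for more pairs than observed warns and returns all
  expect_warning(tr3 <- topPairsTimeseries(sb, k = 5L), "only")
  expect_identical(nrow(tr3), 2L)
  ## ranking follows occupancy order
  expect_identical(rownames(tr3)[1], occ$pair[1])
})
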