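## Orchestration: one config drives all analysis stages over a trajectory and
## writes a CSV report bundle plus a JSON run manifest.  The spec-facing CLI
## subcommands (generate, bend, membrane, contacts, saltbridges, orient,
## constructs, run-all) map 1:1 onto exported functions; this module wires
## them together.

#' Analysis configuration
#'
#' Collects every tunable threshold in one place, with the package defaults:
#' Calpha contact cutoff 7.5 A, orientation heavy-atom cutoff 4.5 A with
#' threshold T > 5, residue-class cutoff 3.5 A, salt-bridge O-N cutoff
#' 3.2 A, bending chord (side) 7.2 A, near/far lateral cutoffs 10/25 A,
#' 4 contact-map time windows.
#'
#' @param trajectory,sidecar input paths (multi-model PDB + optional JSON
#'   sidecar); may be NULL when a trajectory object is passed to
#'   \code{\link{runAll}} directly.
#' @param outputDir directory for the report bundle.
#' @param contactCutoff,orientCutoff,classCutoff,saltBridgeCutoff,side,
#'   nearCutoff,farCutoff cutoffs in Angstrom.
#' @param orientThreshold interacting threshold T0 (strict inequality).
#' @param nWindows time windows for the domain contact map.
#' @param stride frame stride (analyse every stride-th frame).
#' @param seed integer seed recorded in the manifest.
#' @return A list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(trajectory = NULL, sidecar = NULL,
                           outputDir = "septinAH-out",
                           contactCutoff = 7.5, orientCutoff = 4.5,
                           classCutoff = 3.5, saltBridgeCutoff = 3.2,
                           side = 7.2, nearCutoff = 10, farCutoff = 25,
                           orientThreshold = 5L, nWindows = 4L,
                           stride = 1L, seed = 1L) {
  cfg <- list(trajectory = trajectory, sidecar = sidecar,
              outputDir = outputDir,
              contactCutoff = as.numeric(contactCutoff),
              orientCutoff = as.numeric(orientCutoff),
              classCutoff = as.numeric(classCutoff),
              saltBridgeCutoff = as.numeric(saltBridgeCutoff),
              side = as.numeric(side), nearCutoff = as.numeric(nearCutoff),
              farCutoff = as.numeric(farCutoff),
              orientThreshold = as.integer(orientThreshold),
              nWindows = as.integer(nWindows), stride = as.integer(stride),
              seed = as.integer(seed))
  num <- c("contactCutoff", "orientCutoff", "classCutoff", "saltBridgeCutoff",
           "side", "nearCutoff", "farCutoff", "stride")
  if (any(vapply(cfg[num], function(v) v <= 0, TRUE)))
    stop("input error: all cutoffs and the stride must be positive")
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read/write an analysis configuration
#'
#' JSON round-trip of an \code{AnalysisConfig}; the round-trip is lossless.
#'
#' @param config an \code{AnalysisConfig}.
#' @param path file path.
#' @return \code{writeAnalysisConfig}: invisibly \code{path};
#'   \code{readAnalysisConfig}: an \code{AnalysisConfig}.
#' @export
writeAnalysisConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysisConfig, obj)
}

#' Run the full analysis pipeline
#'
#' Runs the geometry, membrane, interaction and orientation stages as
#' applicable to the input (membrane stages are skipped with a notice when
#' the scene has no lipids; two-peptide stages when it has fewer than two
#' peptides), writes each result as CSV under \code{config$outputDir}, and a
#' \code{manifest.json} recording the config, per-stage status and collected
#' warnings.
#'
#' @param config an \code{AnalysisConfig}.
#' @param traj optional \linkS4class{Trajectory}; when NULL the trajectory is
#'   read from \code{config$trajectory}.
#' @return Invisibly, the manifest list.
#' @export
runAll <- function(config, traj = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (is.null(traj)) {
    if (is.null(config$trajectory))
      stop("input error: no trajectory path or object supplied")
    traj <- readMultimodelPDB(config$trajectory, sidecar = config$sidecar)
  }
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  frames <- seq(1L, nFrames(traj), by = config$stride)
  topo <- topology(traj)
  pep <- peptideIds(topo)
  has_membrane <- length(.lipid_ids(topo)) >= 4L
  stages <- list()
  warns <- character(0)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    elapsed <- round(proc.time()[3] - t0, 3)
    if (inherits(res, "error")) {
      stages[[name]] <<- list(status = "failed",
                              message = conditionMessage(res),
                              seconds = elapsed)
      FALSE
    } else {
      stages[[name]] <<- list(status = "ok", seconds = elapsed)
      TRUE
    }
  }
  wcsv <- function(x, name)
    utils::write.csv(x, file.path(out, name), row.names = FALSE)

  if (length(pep)) {
    run_stage("geometry", function() {
      bh <- bendingHeatmapTable(traj[frames], pep[1], side = config$side)
      utils::write.csv(cbind(time_ns = rownames(bh), as.data.frame(bh)),
                       file.path(out, "bending_heatmap.csv"), row.names = FALSE)
      ax <- helixAxisPoints(calphaCoords(traj, pep[1], frames[1]))
      wcsv(localBendingAngles(ax, side = config$side), "bending_profile.csv")
      fit <- fitCirclePCA(calphaCoords(traj, pep[1], frames[1]))
      wcsv(data.frame(radius = fit$radius, rms_residual = fit$rms_residual),
           "curvature_fit.csv")
      wcsv(helicityProfile(traj[frames], pep[1]), "helicity.csv")
    })
  }
  if (has_membrane) {
    run_stage("membrane", function() {
      apl <- areaPerLipid(traj, frames[1], "upper")
      wcsv(apl$lipids, "apl_upper.csv")
      utils::write.csv(apl$raster, file.path(out, "apl_raster_upper.csv"))
      wcsv(nematicOrder(traj, frames[1]), "nematic_order.csv")
      wcsv(zDensity(traj, phosphateSelection(topo), frames),
           "phosphate_zdensity.csv")
      if (length(pep)) {
        nf <- nearFarHistogram(traj, frames, config$nearCutoff,
                               config$farCutoff)
        wcsv(data.frame(nf$hist_near, group = "near"), "order_near.csv")
        wcsv(data.frame(nf$hist_far, group = "far"), "order_far.csv")
      }
    })
  } else stages[["membrane"]] <- list(status = "skipped",
                                      message = "no lipids in the scene")
  if (length(pep) >= 2L) {
    run_stage("contacts", function() {
      cm <- contactMap(traj, pep[1], pep[2], "calpha",
                       config$contactCutoff, frames)
      utils::write.csv(cm$frequency, file.path(out, "contact_map.csv"))
      dcm <- domainContactMap(cm, topo@regions,
                              min(config$nWindows, length(frames)))
      for (w in seq_along(dcm$windows))
        utils::write.csv(dcm$windows[[w]],
                         file.path(out, sprintf("domain_contacts_w%d.csv", w)))
      rcc <- residueClassContacts(traj, pep[1], pep[2],
                                  config$classCutoff, frames)
      utils::write.csv(rcc$class_counts, file.path(out, "class_contacts.csv"))
    })
    sb_atoms <- unlist(c(.acidic_O, .basic_N))
    if (any(atoms(traj)$name %in% sb_atoms)) {
      run_stage("saltbridges", function() {
        sb <- saltBridgeSeries(traj, config$saltBridgeCutoff, frames)
        occ <- bridgeOccupancy(sb)
        lt <- bridgeLifetimes(sb)
        wcsv(merge(occ, lt, by = "pair", all = TRUE), "saltbridge_stats.csv")
      })
    } else stages[["saltbridges"]] <- list(
      status = "skipped", message = "no named side-chain O/N atoms")
    run_stage("orientation", function() {
      os <- orientationSeries(traj, topo@regions, config$orientCutoff,
                              pep[1:2], frames = frames)
      cl <- classifyFrames(os, config$orientThreshold)
      wcsv(cl$records, "orientation_records.csv")
      wcsv(cl$hist_interacting, "cos_theta_interacting.csv")
      wcsv(cl$hist_noninteracting, "cos_theta_noninteracting.csv")
    })
  } else stages[["orientation"]] <- list(status = "skipped",
                                         message = "fewer than two peptides")
  if (length(pep)) {
    run_stage("zcom", function() {
      zc <- zcomDistribution(traj, pep[1], frames = frames)
      wcsv(zc$records, "zcom_records.csv")
      wcsv(zc$histogram, "zcom_histogram.csv")
      wcsv(perResidueZcom(traj, pep[1], frames), "zcom_per_residue.csv")
    })
  }
  manifest <- list(package = "septinAH",
                   version = as.character(utils::packageVersion("septinAH")),
                   config = unclass(config),
                   n_frames_analysed = length(frames),
                   stages = stages, warnings = warns)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  failed <- vapply(stages, function(s) identical(s$status, "failed"), TRUE)
  if (any(failed))
    stop("pipeline stage(s) failed: ",
         paste(names(stages)[failed], collapse = ", "),
         " (see manifest.json)")
  invisible(manifest)
}

.fixture_names <- c("bent_helix_r60", "straight_helix", "bilayer_75_25",
                    "antiparallel_scene", "parallel_scene")

#' Generate a named fixture scene on disk
#'
#' Writes a scene PDB, topology sidecar and ground-truth manifest JSON for
#' one of the built-in fixtures:
#' \code{bent_helix_r60} (extended AH bent on a 60 A arc),
#' \code{straight_helix}, \code{bilayer_75_25} (8 x 8 DOPC:PLPI lattice),
#' \code{antiparallel_scene} (180 degrees, A = 8 planted contacts),
#' \code{parallel_scene} (0 degrees, P = 4).
#'
#' @param name fixture name.
#' @param outDir output directory.
#' @param seed integer seed for the stochastic generators.
#' @param ... overrides passed to the underlying generator.
#' @return Invisibly, a list with the written paths and the manifest.
#' @export
generateFixture <- function(name, outDir = ".", seed = 1L, ...) {
  if (!name %in% .fixture_names)
    stop("input error: unknown fixture '", name, "'; available: ",
         paste(.fixture_names, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seqc <- buildConstruct("extended_AH")$sequence
  traj <- switch(name,
    bent_helix_r60 = makeHelix(seqc, bendRadius = 60, ...),
    straight_helix = makeHelix(seqc, ...),
    bilayer_75_25 = makeBilayer(seed = seed, ...),
    antiparallel_scene = makeTwoPeptideScene(seqc, interAxisAngle = 180,
                                             nForcedContactsA = 8L,
                                             seed = seed, ...),
    parallel_scene = makeTwoPeptideScene(seqc, interAxisAngle = 0,
                                         nForcedContactsP = 4L,
                                         seed = seed, ...))
  paths <- list(pdb = file.path(outDir, paste0(name, ".pdb")),
                sidecar = file.path(outDir, paste0(name, "_topology.json")),
                manifest = file.path(outDir, paste0(name, "_manifest.json")))
  writeMultimodelPDB(traj, paths$pdb)
  writeTopologySidecar(topology(traj), paths$sidecar)
  jsonlite::write_json(attr(traj, "manifest"), paths$manifest,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, list(manifest_data = attr(traj, "manifest"))))
}
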