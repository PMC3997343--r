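## End-to-end driver: (simulate ->) stack -> silhouettes -> poses ->
## carve -> mesh -> texture -> pin removal -> export, with a manifest
## recording parameters and per-stage counts so a run is reproducible
## from its outputs.

#' Build a pipeline configuration
#'
#' Collects the per-stage parameter blocks with their defaults. The
#' configuration is an ordinary list (serializable to YAML) validated
#' here.
#'
#' @param mode "normal" or "macro".
#' @param panSteps,tiltAngles,focusCount,focusStepMm,cameraDistanceMm
#'   acquisition parameters (see \code{\link{generatePlan}}).
#' @param imageWidthPx,focalPx render/capture geometry.
#' @param silhouetteThreshold chroma-key distance threshold.
#' @param silhouetteKeepAll keep all above-size silhouette components
#'   (TRUE suits multi-part synthetic phantoms; see
#'   \code{\link{extractSilhouette}}).
#' @param dilatePx conservative silhouette dilation before carving; 0 is
#'   appropriate when the masks are exact synthetic silhouettes.
#' @param gridResolution voxel grid resolution per axis.
#' @param bboxHalfMm half-extent of the carving cube in mm (NULL = from
#'   the scene bounding radius).
#' @param atlasSize texture atlas edge in px.
#' @param blurGain macro defocus gain, px blur per mm defocus.
#' @param pinRemoval "none", "component" or "cylinder".
#' @param exportFormats formats written at the end.
#' @param seed integer seed recorded in the manifest.
#' @return a named list ("pipelineConfig").
#' @export
pipelineConfig <- function(mode = "normal", panSteps = 24L,
                           tiltAngles = c(-45, -27, -9, 9, 27, 45),
                           focusCount = 31L, focusStepMm = 0.25,
                           cameraDistanceMm = 60,
                           imageWidthPx = 200L, focalPx = NULL,
                           silhouetteThreshold = 0.12,
                           silhouetteKeepAll = TRUE, dilatePx = 1L,
                           gridResolution = 96L, bboxHalfMm = NULL,
                           atlasSize = 1024L, blurGain = 2,
                           pinRemoval = "component",
                           exportFormats = "obj", seed = 1L) {
  cfg <- list(mode = mode, panSteps = as.integer(panSteps),
              tiltAngles = tiltAngles, focusCount = as.integer(focusCount),
              focusStepMm = focusStepMm,
              cameraDistanceMm = cameraDistanceMm,
              imageWidthPx = as.integer(imageWidthPx), focalPx = focalPx,
              silhouetteThreshold = silhouetteThreshold,
              silhouetteKeepAll = isTRUE(silhouetteKeepAll),
              dilatePx = as.integer(dilatePx),
              gridResolution = as.integer(gridResolution),
              bboxHalfMm = bboxHalfMm, atlasSize = as.integer(atlasSize),
              blurGain = blurGain, pinRemoval = pinRemoval,
              exportFormats = exportFormats, seed = as.integer(seed))
  stopifnot(cfg$mode %in% c("normal", "macro"),
            cfg$pinRemoval %in% c("none", "component", "cylinder"))
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a configuration from \code{\link{pipelineConfig}}.
#' @param path file path.
#' @return \code{readPipelineConfig} returns the configuration list.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full reconstruction pipeline on a synthetic scene
#'
#' Executes the whole workflow against the bundled renderer: capture
#' simulation (with focus sweeps in macro mode), focus stacking,
#' silhouette extraction, turntable pose computation, visual-hull
#' carving, isosurface meshing, largest-component cleanup, texture
#' baking, optional pin removal, and export. Deterministic given
#' (config, scene): the same inputs give byte-identical geometry.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param scene a \linkS4class{SyntheticScene} (default: the synthetic
#'   weevil).
#' @param outDir output directory for exports and the manifest (NULL =
#'   nothing written).
#' @param verbose log per-stage counts.
#' @return list with \code{model} (\linkS4class{TexturedMesh}),
#'   \code{grid} (carved \linkS4class{VoxelGrid}), \code{manifest} and
#'   \code{files}.
#' @export
runPipeline <- function(cfg, scene = weevilScene(), outDir = NULL,
                        verbose = FALSE) {
  t0 <- Sys.time()
  plan <- generatePlan(cfg$mode, cfg$panSteps, cfg$tiltAngles,
                       cfg$focusCount, cfg$focusStepMm,
                       cfg$cameraDistanceMm)
  rad <- sceneBoundingRadius(scene)
  if (cfg$cameraDistanceMm <= rad)
    stop("camera distance must exceed the scene bounding radius")
  half <- if (is.null(cfg$bboxHalfMm)) 1.05 * rad else cfg$bboxHalfMm
  w <- cfg$imageWidthPx
  focal <- if (is.null(cfg$focalPx)) 0.42 * w * cfg$cameraDistanceMm / rad
           else cfg$focalPx
  intr <- cameraIntrinsics(focal, c(w, w))
  views <- planViews(plan, intr)
  stageLog(verbose, "plan", "%d views, %d captures", length(views),
           totalCaptures(plan))
  ## capture (+ stack in macro mode)
  images <- vector("list", length(views))
  masks <- vector("list", length(views))
  for (i in seq_along(views)) {
    if (cfg$mode == "macro") {
      defo <- defocusModel(cfg$cameraDistanceMm, cfg$blurGain)
      fs <- renderFocusStack(scene, views[[i]], defo,
                             plan@focusPositionsMm)
      st <- stackFocus(fs$stack)
      images[[i]] <- st$image
    } else {
      images[[i]] <- renderView(scene, views[[i]])$image
    }
    masks[[i]] <- extractSilhouette(images[[i]], scene@background,
                                    cfg$silhouetteThreshold,
                                    viewId = views[[i]]@viewId,
                                    keepAll = cfg$silhouetteKeepAll)
  }
  stageLog(verbose, "silhouette", "%d masks, mean foreground %.1f%%",
           length(masks),
           100 * mean(vapply(masks, function(m) mean(m@mask), numeric(1))))
  grid <- carve(masks, views, voxelGrid(half, cfg$gridResolution),
                dilatePx = cfg$dilatePx)
  stageLog(verbose, "carve", "%d occupied voxels (%.3g mm^3)",
           sum(grid@occupancy), voxelVolume(grid))
  mesh <- meshFromGrid(grid)
  stageLog(verbose, "mesh", "%d vertices, %d faces", nrow(mesh@vertices),
           nrow(mesh@faces))
  assign <- selectBestView(mesh, views)
  tm <- bakeAtlas(mesh, assign, images, views, cfg$atlasSize)
  stageLog(verbose, "texture", "%d faces textured, %d unseen",
           sum(!is.na(assign)), sum(is.na(assign)))
  removedComponents <- 0L
  if (cfg$pinRemoval != "none") {
    nBefore <- max(meshComponents(tm@mesh))
    tm <- withCallingHandlers(
      removePin(tm, cfg$pinRemoval),
      warning = function(w) {
        if (grepl("nothing removed", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    removedComponents <- nBefore - max(meshComponents(tm@mesh))
    stageLog(verbose, "editpin", "%d component(s) removed",
             removedComponents)
  }
  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (fmt in cfg$exportFormats)
      files <- c(files, exportMesh(tm, file.path(outDir,
                   paste0("model.", fmt))))
    writePlan(plan, file.path(outDir, "plan.yaml"))
    writePoseTable(views, file.path(outDir, "poses.tsv"))
    files <- c(files, file.path(outDir, c("plan.yaml", "poses.tsv")))
  }
  manifest <- list(
    package = "insecthull",
    version = as.character(utils::packageVersion("insecthull")),
    seed = cfg$seed,
    config = unclass(cfg),
    counts = list(
      views = length(views), captures = totalCaptures(plan),
      occupiedVoxels = sum(grid@occupancy),
      hullVolumeMm3 = voxelVolume(grid),
      meshVertices = nrow(tm@mesh@vertices),
      meshFaces = nrow(tm@mesh@faces),
      unseenFaces = sum(is.na(tm@sourceView)),
      removedComponents = removedComponents),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(outDir, "manifest.json"))
  }
  list(model = tm, grid = grid, manifest = manifest, files = files)
}
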