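## Capture scheduling. Normal mode: one image per (pan, tilt) view.
## Macro mode: a multi-focus sweep at every view, later collapsed by the
## focus stacker. The classic full schedule is 144 views (24 pan steps x 6
## tilt angles) and, with a 31-position focus sweep, 4464 capture events.

#' Generate an acquisition plan
#'
#' Enumerates the capture schedule: \code{panSteps} uniformly spaced pan
#' angles at each tilt angle, in pan-major order (all pans at the first
#' tilt, then the next tilt). Macro mode attaches \code{focusCount} focus
#' positions spaced \code{focusStepMm} apart, centred on the specimen
#' origin.
#'
#' @param mode "normal" or "macro".
#' @param panSteps number of uniform pan steps per tilt (>= 1).
#' @param tiltAngles numeric vector of tilt angles in degrees.
#' @param focusCount number of focus positions (macro mode, >= 2).
#' @param focusStepMm focus increment in mm (> 0).
#' @param cameraDistanceMm rig camera distance, mm.
#' @return an \linkS4class{AcquisitionPlan}.
#' @examples
#' plan <- generatePlan("normal", panSteps = 24,
#'                      tiltAngles = c(-45, -27, -9, 9, 27, 45))
#' totalCaptures(plan)  # 144
#' @export
generatePlan <- function(mode = c("normal", "macro"), panSteps = 24L,
                         tiltAngles = c(-45, -27, -9, 9, 27, 45),
                         focusCount = 31L, focusStepMm = 0.25,
                         cameraDistanceMm = 200) {
  mode <- match.arg(mode)
  panSteps <- as.integer(panSteps)
  if (panSteps < 1L || length(tiltAngles) < 1L)
    stop("invalid schedule: need at least one pan step and one tilt angle")
  pans <- (seq_len(panSteps) - 1L) * 360 / panSteps
  views <- data.frame(
    view = seq_len(panSteps * length(tiltAngles)),
    panDeg = rep(pans, times = length(tiltAngles)),
    tiltDeg = rep(tiltAngles, each = panSteps))
  if (mode == "macro") {
    focusCount <- as.integer(focusCount)
    if (focusCount < 2L) stop("invalid schedule: macro mode needs focusCount >= 2")
    if (focusStepMm <= 0) stop("invalid schedule: focusStepMm must be positive")
    focus <- (seq_len(focusCount) - (focusCount + 1) / 2) * focusStepMm
  } else {
    focus <- numeric(0)
  }
  new("AcquisitionPlan", mode = mode, views = views,
      focusPositionsMm = focus,
      totalCaptures = as.integer(nrow(views) * max(1L, length(focus))),
      cameraDistanceMm = as.numeric(cameraDistanceMm))
}

#' Total capture events of a plan
#'
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @return integer capture count.
#' @export
totalCaptures <- function(plan) plan@totalCaptures

#' Camera views for every plan slot
#'
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @param intrinsics a \linkS4class{CameraIntrinsics}.
#' @return list of \linkS4class{CameraView}, one per plan view.
#' @export
planViews <- function(plan, intrinsics) {
  lapply(seq_len(nrow(plan@views)), function(i) {
    st <- turntableState(plan@views$panDeg[i], plan@views$tiltDeg[i],
                         plan@cameraDistanceMm)
    cameraView(intrinsics, poseFromTurntable(st), viewId = plan@views$view[i])
  })
}

#' Write / read a plan as YAML
#'
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @param path file path.
#' @return \code{readPlan} returns the \linkS4class{AcquisitionPlan};
#'   serialization round-trips losslessly.
#' @export
writePlan <- function(plan, path) {
  yaml::write_yaml(list(
    mode = plan@mode,
    cameraDistanceMm = plan@cameraDistanceMm,
    focusPositionsMm = as.numeric(plan@focusPositionsMm),
    views = lapply(seq_len(nrow(plan@views)), function(i) list(
      view = plan@views$view[i],
      panDeg = plan@views$panDeg[i],
      tiltDeg = plan@views$tiltDeg[i]))), path,
    precision = 15L)
  invisible(path)
}

#' @rdname writePlan
#' @export
readPlan <- function(path) {
  y <- yaml::read_yaml(path)
  views <- do.call(rbind, lapply(y$views, function(v)
    data.frame(view = as.integer(v$view), panDeg = v$panDeg,
               tiltDeg = v$tiltDeg)))
  focus <- as.numeric(unlist(y$focusPositionsMm))
  new("AcquisitionPlan", mode = y$mode, views = views,
      focusPositionsMm = focus,
      totalCaptures = as.integer(nrow(views) * max(1L, length(focus))),
      cameraDistanceMm = as.numeric(y$cameraDistanceMm))
}

#' File name of one capture slot
#'
#' The on-disk convention mapping plan slots to files:
#' \code{view\{i:04d\}_focus\{j:03d\}.png} with j = 0 in normal mode.
#'
#' @param view view id (1-based).
#' @param focus focus index (1-based in macro mode, 0 in normal mode).
#' @param ext file extension.
#' @return character file name.
#' @export
captureFileName <- function(view, focus = 0L, ext = "png") {
  sprintf("view%04d_focus%03d.%s", view, focus, ext)
}

#' Match a capture directory against a plan
#'
#' Maps every plan slot to an image file and groups macro slots into
#' per-view focus stacks. Incomplete directories raise "missing capture"
#' naming the absent slots; files not claimed by any slot raise
#' "orphan file".
#'
#' @param plan an \linkS4class{AcquisitionPlan}.
#' @param dir directory of captures named per \code{\link{captureFileName}}.
#' @return list with one element per view; each element is a character
#'   vector of file paths (length 1 in normal mode, focusCount in macro
#'   mode, in focus order).
#' @export
ingestCaptures <- function(plan, dir) {
  nf <- max(1L, length(plan@focusPositionsMm))
  focusIdx <- if (plan@mode == "macro") seq_len(nf) else 0L
  slots <- expand.grid(focus = focusIdx, view = plan@views$view)
  expected <- captureFileName(slots$view, slots$focus)
  have <- list.files(dir, pattern = "\\.(png|jpg)$")
  haveStem <- sub("\\.(png|jpg)$", "", have)
  expStem <- sub("\\.png$", "", expected)
  missing <- setdiff(expStem, haveStem)
  if (length(missing))
    stop("missing capture: ", paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  orphan <- setdiff(haveStem, expStem)
  if (length(orphan))
    stop("orphan file: ", paste(utils::head(orphan, 10), collapse = ", "))
  paths <- file.path(dir, have[match(expStem, haveStem)])
  split(paths, factor(rep(plan@views$view, each = length(focusIdx)),
                      levels = plan@views$view))
}

setMethod("show", "AcquisitionPlan", function(object) {
  cat(sprintf("AcquisitionPlan: %s mode, %d views", object@mode,
              nrow(object@views)))
  if (length(object@focusPositionsMm))
    cat(sprintf(" x %d focus positions", length(object@focusPositionsMm)))
  cat(sprintf(" = %d captures\n", object@totalCaptures))
})
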