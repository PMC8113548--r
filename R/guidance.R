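## Intraoperative guidance: drill-tip distance to the planned surface and the
## two-state GREEN/RED colour logic.

#' Guidance configuration constructor
#' @param threshold state threshold in mm (default 1.0: GREEN strictly above,
#'   RED at or below).
#' @param hysteresis optional hysteresis half-band in mm (default 0, the
#'   literal two-rule logic).
#' @return a [GuidanceConfig-class].
#' @export
guidanceConfig <- function(threshold = 1.0, hysteresis = 0.0) {
  new("GuidanceConfig", threshold = threshold, hysteresis = hysteresis)
}

#' Classify the guidance state from a distance
#'
#' GREEN while the signed distance to the planned surface exceeds the
#' threshold (> 1 mm by default: drill still clear of the planned surface);
#' RED at or below it, including the boundary value and any overshoot
#' (negative distance). Pure function of distance and threshold: no
#' hysteresis, no state memory.
#'
#' @param distance signed distance(s) to the planned surface (mm).
#' @param config a [GuidanceConfig-class].
#' @return character vector, \code{"GREEN"} or \code{"RED"}.
#' @examples
#' cfg <- guidanceConfig(threshold = 1.0)
#' classifyState(c(1.5, 1.0, 0.8, -0.2), cfg)
#' @export
classifyState <- function(distance, config = guidanceConfig()) {
  stopifnot(all(is.finite(distance)))
  ifelse(distance > config@threshold, "GREEN", "RED")
}

#' Replay a tracked pose stream into guidance samples
#'
#' For every time at which the drill DRF was sampled, the drill tip is mapped
#' into image space through the frame chain
#' DRILL_DRF -> TRACKER -> PATIENT_DRF -> IMAGE, its signed distance to the
#' planned surface computed, and the GREEN/RED state assigned. Samples whose
#' frames cannot be resolved (e.g. the patient DRF was not tracked at that
#' time) are skipped and counted, never silently dropped. Every GREEN/RED
#' crossing is logged with its linearly interpolated crossing time, making
#' the transition log independent of the sampling rate.
#'
#' @param stream pose-stream data.frame (see [readPoseStream()]) with rows
#'   for frames \code{"DRILL_DRF"} and \code{"PATIENT_DRF"} in the tracker
#'   frame.
#' @param plannedSurface the planned target [TriMesh-class] (in image
#'   space), e.g. \code{plannedSurface(plan)}.
#' @param registration [RigidTransform-class] PATIENT_DRF -> IMAGE (the
#'   patient-to-image registration).
#' @param tip a [TipCalibration-class].
#' @param config a [GuidanceConfig-class].
#' @return list with \code{samples} (data.frame: time_s, tip_x, tip_y,
#'   tip_z, distance_mm, state), \code{transitions} (data.frame: time_s,
#'   from, to), and \code{nSkipped}.
#' @export
processPoseStream <- function(stream, plannedSurface, registration, tip,
                              config = guidanceConfig()) {
  if (is(plannedSurface, "PlanModel"))
    plannedSurface <- plannedSurface@plannedSurface
  stopifnot(is(plannedSurface, "TriMesh"), nFaces(plannedSurface) > 0L)
  graph <- frameGraph()
  graph <- addStaticEdge(graph, rigidTransform(registration@rotation,
                                               registration@translation,
                                               "PATIENT_DRF", "IMAGE"))
  drill <- poseTrackFromStream(stream, "DRILL_DRF")
  patient <- poseTrackFromStream(stream, "PATIENT_DRF")
  graph <- addTrackedEdge(graph, drill)
  graph <- addTrackedEdge(graph, patient)

  times <- drill$times
  ok <- times >= patient$times[1] & times <= patient$times[length(patient$times)]
  nSkipped <- sum(!ok)
  times <- times[ok]
  if (is.unsorted(times)) stop("pose stream is not time-ordered")

  tips <- matrix(NA_real_, length(times), 3)
  for (i in seq_along(times))
    tips[i, ] <- drillTipInImage(graph, tip, times[i])
  dist <- signedDistance(tips, plannedSurface)

  thr <- config@threshold
  h <- config@hysteresis
  if (h <= 0) {
    state <- classifyState(dist, config)
  } else {
    ## hysteresis: fall to RED at <= thr, recover to GREEN only above thr + h
    state <- character(length(dist))
    cur <- if (dist[1] > thr) "GREEN" else "RED"
    for (i in seq_along(dist)) {
      if (cur == "GREEN" && dist[i] <= thr) cur <- "RED"
      else if (cur == "RED" && dist[i] > thr + h) cur <- "GREEN"
      state[i] <- cur
    }
  }

  trans <- data.frame(time_s = numeric(0), from = character(0),
                      to = character(0))
  if (length(state) > 1) {
    ch <- which(state[-1] != state[-length(state)])
    if (length(ch)) {
      d0 <- dist[ch]; d1 <- dist[ch + 1]
      s <- (thr - d0) / (d1 - d0)   # distance crosses thr between samples
      s[!is.finite(s) | s < 0 | s > 1] <- 0.5
      trans <- data.frame(
        time_s = times[ch] + s * (times[ch + 1] - times[ch]),
        from = state[ch], to = state[ch + 1])
    }
  }
  list(samples = data.frame(time_s = times, tip_x = tips[, 1],
                            tip_y = tips[, 2], tip_z = tips[, 3],
                            distance_mm = dist, state = state),
       transitions = trans, nSkipped = nSkipped)
}

#' Write a guidance run to disk
#'
#' The per-sample log goes to CSV (time, tip position, signed distance
#' rounded to 0.01 mm as displayed, state); the transition summary to JSON.
#'
#' @param run result of [processPoseStream()].
#' @param csvPath per-sample log CSV path.
#' @param jsonPath optional transition-summary JSON path.
#' @return invisibly, \code{csvPath}.
#' @export
writeGuidanceLog <- function(run, csvPath, jsonPath = NULL) {
  out <- run$samples
  out$distance_mm <- round(out$distance_mm, 2)
  utils::write.csv(out, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(nSamples = nrow(run$samples), nSkipped = run$nSkipped,
           nTransitions = nrow(run$transitions),
           transitions = run$transitions),
      jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(csvPath)
}
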