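## Rigid registration (Kabsch, ICP) and the tracked coordinate-frame graph.

#' Paired-point rigid registration (Kabsch)
#'
#' Closed-form least-squares rigid fit of ordered point pairs by SVD of the
#' cross-covariance, with the reflection case handled by flipping the
#' smallest singular direction so that \eqn{\det R = +1}. The fiducial
#' registration error (FRE) is the root-mean-square residual of the
#' transformed source against the target, the standard image-guidance
#' convention.
#'
#' @param corr a [CorrespondenceSet-class] with >= 3 non-collinear source
#'   points.
#' @param source,target frame names for the returned transform.
#' @return list with \code{transform} (a [RigidTransform-class] mapping
#'   source points onto target points) and \code{fre} (mm).
#' @export
pairedPointRegister <- function(corr, source = "source", target = "target") {
  S <- corr@source
  Tg <- corr@target
  if (nrow(S) < 3L) stop("need at least 3 point pairs")
  sBar <- colMeans(S)
  tBar <- colMeans(Tg)
  Sc <- sweep(S, 2, sBar)
  Tc <- sweep(Tg, 2, tBar)
  sv <- svd(Sc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate configuration: source points are collinear")
  H <- crossprod(Sc, Tc)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- as.vector(tBar - R %*% sBar)
  Tfit <- rigidTransform(R, tr, source, target)
  res <- applyTransform(Tfit, S) - Tg
  list(transform = Tfit, fre = sqrt(mean(rowSums(res^2))))
}

#' Iterative closest point refinement against a surface
#'
#' Alternates exact closest-point correspondence on the target mesh with the
#' Kabsch fit, starting from \code{init}. Correspondences farther than
#' \code{rejectFactor} times the median closest-point distance are discarded
#' per iteration (robustness to partial overlap). Stops when the RMS
#' improvement falls below \code{tol} or after \code{maxIter} iterations;
#' reaching \code{maxIter} flags non-convergence but is not an error.
#'
#' @param sourcePoints n x 3 matrix of points to align (mm).
#' @param target a [TriMesh-class].
#' @param init initial [RigidTransform-class] guess.
#' @param maxIter,tol iteration cap and RMS-change stopping tolerance (mm).
#' @param rejectFactor median-distance multiple beyond which pairs are
#'   rejected; \code{Inf} disables rejection.
#' @details Tangential sliding on smooth surfaces makes plain
#'   closest-point iteration converge geometrically with a ratio near 1, so
#'   the loop extrapolates along the current motion increment (an
#'   Aitken-type jump in the twist coordinates, in the spirit of the
#'   classic accelerated ICP) whenever successive increments are aligned; a
#'   jump is kept only when it lowers the RMS, preserving the monotone
#'   non-increasing RMS sequence.
#' @return list with \code{transform}, \code{rms} (mm, over retained
#'   pairs), \code{iterations}, \code{converged}, \code{rmsHistory}.
#' @export
icpRefine <- function(sourcePoints, target, init = identityTransform("source", "target"),
                      maxIter = 100L, tol = 1e-9, rejectFactor = 5) {
  stopifnot(nrow(sourcePoints) >= 3L)
  rmsAt <- function(T) {
    moved <- applyTransform(T, sourcePoints)
    sqrt(mean(closestPointOnMesh(moved, target)$distance^2))
  }
  twistOf <- function(Tdelta) {
    R <- Tdelta@rotation
    ang <- rotationAngle(R)
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    nrm <- sqrt(sum(axis^2))
    w <- if (nrm > 1e-15) axis / nrm * ang else c(0, 0, 0)
    c(w, Tdelta@translation)
  }
  Tcur <- init
  rmsHistory <- numeric(0)
  prev <- Inf
  prevStep <- NULL
  converged <- FALSE
  iterations <- 0L
  for (k in seq_len(maxIter)) {
    iterations <- k
    moved <- applyTransform(Tcur, sourcePoints)
    cp <- closestPointOnMesh(moved, target)
    keep <- seq_len(nrow(moved))
    med <- stats::median(cp$distance)
    if (is.finite(rejectFactor) && med > 0)
      keep <- which(cp$distance <= rejectFactor * med)
    if (length(keep) < 3L) keep <- seq_len(nrow(moved))
    fit <- pairedPointRegister(
      correspondenceSet(sourcePoints[keep, , drop = FALSE],
                        cp$point[keep, , drop = FALSE]),
      source = Tcur@sourceFrame, target = Tcur@targetFrame)
    Tnext <- fit$transform
    step <- twistOf(composeTransforms(invertTransform(Tcur), Tnext))
    rms <- rmsAt(Tnext)

    ## Aitken extrapolation along the twist when increments are collinear
    if (!is.null(prevStep)) {
      n1 <- sqrt(sum(prevStep^2)); n2 <- sqrt(sum(step^2))
      if (n1 > 0 && n2 > 0 && sum(prevStep * step) / (n1 * n2) > 0.98 &&
          n2 < n1) {
        r <- min(n2 / n1, 0.995)
        lam <- r / (1 - r)
        w <- step[1:3] * lam
        ang <- sqrt(sum(w^2))
        Rj <- if (ang > 1e-15) rotationAxisAngle(w, ang) else diag(3)
        # the increment acts on the target side: T_ext = exp(lam*twist) o T
        jump <- rigidTransform(Rj, step[4:6] * lam, Tcur@targetFrame,
                               Tcur@targetFrame)
        Tcand <- composeTransforms(Tnext, jump)
        rmsCand <- rmsAt(Tcand)
        if (rmsCand < rms) {
          Tnext <- Tcand
          rms <- rmsCand
          step <- NULL   # restart the step memory after a jump
        }
      }
    }
    Tcur <- Tnext
    prevStep <- step
    rmsHistory <- c(rmsHistory, rms)
    if (is.finite(prev) && abs(prev - rms) < tol) {
      converged <- TRUE
      break
    }
    prev <- rms
  }
  list(transform = Tcur, rms = rmsHistory[length(rmsHistory)],
       iterations = iterations, converged = converged,
       rmsHistory = rmsHistory)
}

## -- frame graph -------------------------------------------------------------

#' Standard navigation frame names
#' @export
navigationFrames <- function() c("TRACKER", "PATIENT_DRF", "DRILL_DRF", "IMAGE")

#' Build a coordinate-frame graph
#'
#' @param frames character vector of frame names
#'   (default [navigationFrames()]).
#' @return an empty [FrameGraph-class].
#' @export
frameGraph <- function(frames = navigationFrames()) {
  new("FrameGraph", frames = frames, staticEdges = list(),
      trackedEdges = list())
}

#' @rdname frameGraph
#' @param graph a [FrameGraph-class].
#' @param transform a [RigidTransform-class] whose frames are in the graph.
#' @export
addStaticEdge <- function(graph, transform) {
  stopifnot(transform@sourceFrame %in% graph@frames,
            transform@targetFrame %in% graph@frames)
  graph@staticEdges <- c(graph@staticEdges, list(transform))
  graph
}

#' Time-stamped pose track for one tracked frame
#'
#' The pose of \code{source} expressed in \code{target} (conventionally a
#' DRF in the tracker frame), sampled at increasing times. Between samples,
#' translation is interpolated linearly and rotation by spherical-linear
#' interpolation (slerp) on unit quaternions.
#'
#' @param source,target frame names.
#' @param times increasing numeric timestamps (s).
#' @param quaternions n x 4 matrix of unit quaternions (w, x, y, z).
#' @param translations n x 3 matrix (mm).
#' @return a pose-track object.
#' @export
poseTrack <- function(source, target, times, quaternions, translations) {
  stopifnot(length(times) == nrow(quaternions),
            length(times) == nrow(translations),
            !is.unsorted(times))
  structure(list(source = source, target = target, times = as.numeric(times),
                 quaternions = quaternions, translations = translations),
            class = "PoseTrack")
}

#' @rdname frameGraph
#' @param track a [poseTrack()] object.
#' @export
addTrackedEdge <- function(graph, track) {
  stopifnot(inherits(track, "PoseTrack"),
            track$source %in% graph@frames, track$target %in% graph@frames)
  graph@trackedEdges <- c(graph@trackedEdges, list(track))
  graph
}

## Build a PoseTrack from the pose-stream CSV dialect for one frame name.
#' Extract one frame's pose track from a pose-stream data.frame
#' @param stream pose-stream data.frame (see [readPoseStream()]).
#' @param frame frame name to extract (e.g. \code{"DRILL_DRF"}).
#' @param target the frame the poses are expressed in
#'   (default \code{"TRACKER"}).
#' @return a [poseTrack()] object.
#' @export
poseTrackFromStream <- function(stream, frame, target = "TRACKER") {
  sub <- stream[stream$frame == frame, , drop = FALSE]
  if (!nrow(sub)) stop("no samples for frame ", frame)
  sub <- sub[order(sub$time_s), , drop = FALSE]
  poseTrack(frame, target, sub$time_s,
            as.matrix(sub[, c("qw", "qx", "qy", "qz")]),
            as.matrix(sub[, c("tx", "ty", "tz")]))
}

## Interpolate a PoseTrack at time `at` -> RigidTransform (source -> target).
.trackAt <- function(track, at) {
  tms <- track$times
  if (is.null(at)) stop("a timestamp is required to resolve a tracked edge")
  if (at < tms[1] || at > tms[length(tms)])
    stop(sprintf("timestamp %g outside tracked range [%g, %g]",
                 at, tms[1], tms[length(tms)]))
  i <- findInterval(at, tms)
  if (i == length(tms) || at == tms[i]) {
    q <- track$quaternions[i, ]
    tr <- track$translations[i, ]
  } else {
    s <- (at - tms[i]) / (tms[i + 1] - tms[i])
    q <- slerpQuaternion(track$quaternions[i, ], track$quaternions[i + 1, ], s)
    tr <- (1 - s) * track$translations[i, ] + s * track$translations[i + 1, ]
  }
  rigidTransform(matrixFromQuaternion(q), tr, track$source, track$target)
}

#' Resolve the transform between two frames
#'
#' Breadth-first path search over static and tracked edges, composing along
#' the path; tracked edges are interpolated at \code{at} (translation
#' linearly, rotation by slerp).
#'
#' @param graph a [FrameGraph-class].
#' @param from,to frame names.
#' @param at timestamp (s); required when the path crosses a tracked edge.
#' @return a [RigidTransform-class] mapping \code{from} to \code{to}.
#' @export
resolveFrames <- function(graph, from, to, at = NULL) {
  stopifnot(from %in% graph@frames, to %in% graph@frames)
  if (from == to) return(identityTransform(from))
  edges <- list()
  for (e in graph@staticEdges) {
    edges <- c(edges, list(list(a = e@sourceFrame, b = e@targetFrame,
                                get = local({ee <- e; function(at) ee}))))
  }
  for (tr in graph@trackedEdges) {
    edges <- c(edges, list(list(a = tr$source, b = tr$target,
                                get = local({tt <- tr; function(at) .trackAt(tt, at)}))))
  }
  ## BFS over frames
  prev <- list()
  visited <- from
  queue <- list(from)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    if (cur == to) break
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      nxt <- if (e$a == cur) e$b else if (e$b == cur) e$a else next
      if (nxt %in% visited) next
      visited <- c(visited, nxt)
      prev[[nxt]] <- list(frame = cur, edge = i, forward = e$a == cur)
      queue <- c(queue, list(nxt))
    }
  }
  if (!to %in% visited)
    stop(sprintf("frames %s and %s are not connected", from, to))
  ## walk back from `to`
  chain <- list()
  cur <- to
  while (cur != from) {
    step <- prev[[cur]]
    chain <- c(list(step), chain)
    cur <- step$frame
  }
  Tacc <- identityTransform(from)
  for (step in chain) {
    e <- edges[[step$edge]]
    Te <- e$get(at)
    if (!step$forward) Te <- invertTransform(Te)
    Tacc <- composeTransforms(Tacc, Te)
  }
  Tacc
}

#' Drill-tip calibration constructor
#' @param offset tip offset in the drill DRF frame (mm), |offset| < 500.
#' @return a [TipCalibration-class].
#' @export
tipCalibration <- function(offset) new("TipCalibration",
                                       offset = as.numeric(offset))

#' Drill-tip position in image space
#'
#' Maps the calibrated tip offset through the
#' DRILL_DRF -> TRACKER -> PATIENT_DRF -> IMAGE chain at the given time.
#'
#' @param graph a [FrameGraph-class] connecting \code{DRILL_DRF} to
#'   \code{IMAGE}.
#' @param tip a [TipCalibration-class].
#' @param at timestamp (s).
#' @return length-3 tip position in the IMAGE frame (mm).
#' @export
drillTipInImage <- function(graph, tip, at) {
  T <- resolveFrames(graph, "DRILL_DRF", "IMAGE", at)
  applyTransform(T, tip@offset)
}
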