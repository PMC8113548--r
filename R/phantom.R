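## Synthetic skull phantom: bilaterally symmetric ellipsoid head with a
## unilateral Gaussian lesion bump, exact landmarks/fiducials, simulated
## recontouring procedures and noisy tracked pose streams -- all with full
## ground truth, so every pipeline stage is testable without patient data.

## Run expr with a local seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided \code{subdivisions} times with vertices projected
#' onto the unit sphere. The vertex set is bilaterally symmetric about
#' x = 0 to machine precision (reflection and midpoint subdivision commute
#' exactly in floating point).
#'
#' @param subdivisions subdivision level; faces = 20 * 4^subdivisions.
#' @return list with \code{vertices} (unit directions) and \code{faces}.
#' @export
icosphere <- function(subdivisions = 3L) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    Vlist <- asplit(V, 1)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (Vlist[[i]] + Vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      Vlist[[length(Vlist) + 1]] <<- m
      idx <- length(Vlist)
      cache[[key]] <- idx
      idx
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c_, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, Vlist)
    F <- newF
  }
  list(vertices = V, faces = F)
}

#' Phantom specification constructor
#'
#' Defaults describe an adult-cranium-scale ellipsoid (semi-axes 70, 90,
#' 65 mm for the left-right, antero-posterior and vertical axes) with a
#' 6 mm Gaussian lesion bump over the right zygomaticomaxillary-like
#' region (lateral-anterior-inferior direction, angular footprint sigma
#' 0.25 rad, about 17 mm of arc).
#'
#' @param semiAxes ellipsoid semi-axes (mm).
#' @param subdivisions icosphere subdivision level (4 gives 5120 faces).
#' @param lesionSide \code{"right"} or \code{"left"}.
#' @param lesionCenter direction of the bump centre (normalized; x > 0
#'   side is the anatomical right).
#' @param lesionHeight bump height (mm).
#' @param lesionRadius angular Gaussian sigma of the footprint (rad).
#' @param nFiducials fiducial markers placed on the unaffected side.
#' @param seed integer seed fixing all phantom randomness.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(semiAxes = c(70, 90, 65), subdivisions = 4L,
                        lesionSide = "right",
                        lesionCenter = c(0.8, 0.45, -0.35),
                        lesionHeight = 6, lesionRadius = 0.25,
                        nFiducials = 6L, seed = 1L) {
  lc <- lesionCenter / sqrt(sum(lesionCenter^2))
  if (lesionSide == "left") lc[1] <- -abs(lc[1]) else lc[1] <- abs(lc[1])
  new("PhantomSpec", semiAxes = as.numeric(semiAxes),
      subdivisions = as.integer(subdivisions), lesionSide = lesionSide,
      lesionCenter = lc, lesionHeight = as.numeric(lesionHeight),
      lesionRadius = as.numeric(lesionRadius),
      nFiducials = as.integer(nFiducials), seed = as.integer(seed))
}

#' Generate a skull-like phantom with ground truth
#'
#' Ellipsoid icosphere displaced along the outward ellipsoid normal by a
#' Gaussian bump on the lesion side. Returns, besides the mesh (vertex
#' labels \code{"surgical_area"} where the true bump displacement exceeds
#' 0.5 mm, \code{"unchanged"} elsewhere): the exact per-vertex displacement,
#' the ground-truth lesion faces, a landmark set (4 exact midline points on
#' the smooth ellipsoid plus 3 exactly mirrored left/right pairs placed
#' away from the lesion), and seeded fiducial points on the unaffected
#' side.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{mesh}, \code{landmarks}, \code{fiducials}
#'   (matrix), \code{displacement} (mm per vertex), \code{lesionFaces}
#'   (integer), \code{spec}.
#' @export
makePhantom <- function(spec) {
  ico <- icosphere(spec@subdivisions)
  if (nrow(ico$faces) < 1000L)
    stop("resolution too coarse: fewer than 1000 faces")
  U <- ico$vertices
  a <- spec@semiAxes
  V <- sweep(U, 2, a, "*")
  ## outward ellipsoid normal at V = a*u is proportional to u / a
  N <- sweep(U, 2, a, "/")
  N <- N / sqrt(rowSums(N^2))
  th <- acos(pmin(1, pmax(-1, as.vector(U %*% spec@lesionCenter))))
  disp <- spec@lesionHeight * exp(-th^2 / (2 * spec@lesionRadius^2))
  disp[disp < 1e-12] <- 0
  V <- V + disp * N
  labs <- ifelse(disp > 0.5, "surgical_area", "unchanged")
  mesh <- new("TriMesh", vertices = V, faces = ico$faces, vertexLabels = labs)
  over <- disp > 0.5
  lesionFaces <- which(rowSums(matrix(over[ico$faces], ncol = 3)) == 3L)

  onEll <- function(u) as.numeric(a * u / sqrt(sum(u^2)))
  midline <- rbind(nasion = onEll(c(0, 1, 0.15)),
                   inion = onEll(c(0, -1, 0.1)),
                   bregma = onEll(c(0, 0.1, 1)),
                   basion = onEll(c(0, -0.2, -1)))
  pairDirs <- rbind(euryon = c(0.95, -0.1, 0.3),
                    mastoidale = c(0.7, -0.6, -0.4),
                    frontotemporale = c(0.6, 0.55, 0.55))
  pairs <- NULL
  for (i in seq_len(nrow(pairDirs))) {
    r <- onEll(pairDirs[i, ])
    l <- r * c(-1, 1, 1)
    pairs <- rbind(pairs, l, r)
    rownames(pairs)[(2 * i - 1):(2 * i)] <-
      paste0(rownames(pairDirs)[i], c("_left", "_right"))
  }
  landmarks <- landmarkSet(rbind(midline, pairs))

  healthySign <- if (spec@lesionSide == "right") -1 else 1
  fiducials <- .withSeed(spec@seed, {
    dirs <- matrix(rnorm(3 * spec@nFiducials), ncol = 3)
    dirs[, 1] <- healthySign * abs(dirs[, 1])
    t(apply(dirs, 1, onEll))
  })

  list(mesh = mesh, landmarks = landmarks, fiducials = fiducials,
       displacement = disp, lesionFaces = lesionFaces, spec = spec)
}

## Smooth low-order basis on the sphere directions of `pts`
## (linear + quadratic spherical-harmonic-like terms).
.sphericalBasis <- function(pts) {
  u <- pts / sqrt(rowSums(pts^2))
  cbind(u[, 1], u[, 2], u[, 3],
        u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3],
        u[, 1]^2 - u[, 2]^2, 3 * u[, 3]^2 - 1)
}

#' Simulate a recontouring procedure with full ground truth
#'
#' The post-operative surface is the pre-operative mesh with every
#' resection-region vertex moved onto the planned (mirrored) surface and
#' offset along the local planned normal by a smooth seeded residual field
#' with the requested area-weighted mean and SD (mm) -- the residual models
#' the surgeon's remaining over/under-resection. The post-op model is then
#' placed in its own coordinate space by a random rigid motion, and noisy
#' unchanged-region fiducial correspondences plus a scripted noisy drill
#' pose stream (approach-and-retreat passes over the region) are generated.
#' Everything downstream derives from \code{seed}; with all noise at zero
#' the stream replays the ground truth exactly.
#'
#' @param phantom output of [makePhantom()].
#' @param plan [PlanModel-class] built from the phantom.
#' @param residualMean,residualSd residual error field statistics (mm);
#'   defaults on the scale of reported recontouring accuracy (1.4 +/- 0.7).
#' @param noise list: \code{transSd} (mm), \code{rotSd} (deg) per pose
#'   sample, \code{fidSd} (mm) fiducial localization.
#' @param nSamples pose samples in the drill stream.
#' @param seed integer seed.
#' @return a [SimulatedProcedure-class].
#' @export
simulateProcedure <- function(phantom, plan, residualMean = 1.4,
                              residualSd = 0.7,
                              noise = list(transSd = 0.15, rotSd = 0.05,
                                           fidSd = 0.1),
                              nSamples = 400L, seed = 1L) {
  .withSeed(seed, {
    preop <- plan@preop
    planned <- plan@plannedSurface
    rf <- plan@resectionFaces
    stopifnot(length(rf) > 0L, nFaces(planned) > 0L)
    regionVerts <- sort(unique(as.vector(preop@faces[rf, ])))

    ## smooth residual field r(x), standardized to the stated area-weighted
    ## mean/SD over the planned surgical area (the domain the evaluation
    ## pipeline samples area-uniformly)
    prf <- surgicalAreaFaces(planned)
    if (!length(prf)) prf <- seq_len(nFaces(planned))
    quadPts <- faceCentroids(planned)[prf, , drop = FALSE]
    quadW <- faceAreas(planned)[prf]
    quadW <- quadW / sum(quadW)
    coefs <- rnorm(8)
    residualField <- if (residualSd > 0) {
      gq <- as.vector(.sphericalBasis(quadPts) %*% coefs)
      m <- sum(quadW * gq)
      s <- sqrt(sum(quadW * (gq - m)^2))
      function(x) residualMean + residualSd *
        (as.vector(.sphericalBasis(x) %*% coefs) - m) / s
    } else function(x) rep(residualMean, nrow(x))

    V2 <- preop@vertices
    cp <- closestPointOnMesh(V2[regionVerts, , drop = FALSE], planned)
    nrm <- faceNormals(planned)[cp$face, , drop = FALSE]
    res <- residualField(cp$point)
    V2[regionVerts, ] <- cp$point + res * nrm
    postopPlan <- new("TriMesh", vertices = V2, faces = preop@faces,
                      vertexLabels = preop@vertexLabels)

    ## post-op model lives in its own (scanner) space
    Tpp <- rigidTransform(
      rotationAxisAngle(rnorm(3), runif(1, 0, 10 * pi / 180)),
      runif(3, -20, 20), "plan", "postop")
    postop <- transformMesh(postopPlan, Tpp)

    fid <- phantom$fiducials
    fidNoise <- matrix(rnorm(length(fid), sd = noise$fidSd), ncol = 3)
    corr <- correspondenceSet(fid, applyTransform(Tpp, fid) + fidNoise)

    ## ground-truth frame chain
    TpatientImage <- rigidTransform(
      rotationAxisAngle(rnorm(3), runif(1, 0, pi)),
      runif(3, -200, 200), "PATIENT_DRF", "IMAGE")
    TtrackerPatient <- rigidTransform(
      rotationAxisAngle(rnorm(3), runif(1, 0, pi)),
      runif(3, -500, 500), "PATIENT_DRF", "TRACKER")
    tipOffset <- c(0, 0, 120)
    Rdrill <- rotationAxisAngle(rnorm(3), runif(1, 0, pi))

    ## scripted shaving passes: approach/retreat over three region targets
    cen <- faceCentroids(planned)
    ord <- order(cen[, 2])
    picks <- cen[ord[round(seq(1, nrow(cen), length.out = 3))], , drop = FALSE]
    pickN <- faceNormals(planned)[ord[round(seq(1, nrow(cen),
                                               length.out = 3))], , drop = FALSE]
    wp <- NULL
    for (i in seq_len(nrow(picks)))
      wp <- rbind(wp, picks[i, ] + 8 * pickN[i, ], picks[i, ] + 0.3 * pickN[i, ],
                  picks[i, ] + 8 * pickN[i, ])
    ts <- seq(0, 1, length.out = nrow(wp))
    tq <- seq(0, 1, length.out = nSamples)
    tipsImage <- cbind(stats::approx(ts, wp[, 1], tq)$y,
                       stats::approx(ts, wp[, 2], tq)$y,
                       stats::approx(ts, wp[, 3], tq)$y)
    times <- tq * 20   # a 20 s run

    Timagepatient <- invertTransform(TpatientImage)
    tipsPatient <- applyTransform(Timagepatient, tipsImage)
    tipsTracker <- applyTransform(TtrackerPatient, tipsPatient)
    tDrill <- tipsTracker - matrix(rep(as.vector(Rdrill %*% tipOffset),
                                       each = nSamples), ncol = 3)
    qDrill <- quaternionFromMatrix(Rdrill)
    qPatient <- quaternionFromMatrix(TtrackerPatient@rotation)
    stream <- rbind(
      data.frame(time_s = times, frame = "DRILL_DRF",
                 qw = qDrill[1], qx = qDrill[2], qy = qDrill[3],
                 qz = qDrill[4], tx = tDrill[, 1], ty = tDrill[, 2],
                 tz = tDrill[, 3]),
      data.frame(time_s = times, frame = "PATIENT_DRF",
                 qw = qPatient[1], qx = qPatient[2], qy = qPatient[3],
                 qz = qPatient[4],
                 tx = TtrackerPatient@translation[1],
                 ty = TtrackerPatient@translation[2],
                 tz = TtrackerPatient@translation[3]))
    stream <- stream[order(stream$time_s, stream$frame), ]
    rownames(stream) <- NULL
    cleanStream <- stream
    if (noise$transSd > 0 || noise$rotSd > 0)
      stream <- addPoseNoise(stream, noise$transSd, noise$rotSd)

    groundTruth <- list(
      planToPostop = Tpp, patientToImage = TpatientImage,
      trackerFromPatient = TtrackerPatient, drillRotation = Rdrill,
      tipOffset = tipOffset, tipTrajectoryImage = tipsImage,
      times = times, cleanStream = cleanStream,
      residuals = res, regionVertices = regionVerts,
      postopInPlanSpace = postopPlan)
    new("SimulatedProcedure", postop = postop, poseStream = stream,
        groundTruth = groundTruth, unchangedCorrespondences = corr,
        residualMean = residualMean, residualSd = residualSd,
        noise = noise, seed = as.integer(seed))
  })
}

#' Add zero-mean tracking noise to a pose stream
#'
#' Independent per-sample perturbations: Gaussian translation noise per
#' axis and a small random-axis rotation with Gaussian angle, composed onto
#' each pose. The input stream is returned untouched when both SDs are 0.
#'
#' @param stream pose-stream data.frame.
#' @param transSd translation noise SD per axis (mm).
#' @param rotSd rotation angle noise SD (degrees).
#' @param seed optional integer seed (caller RNG untouched when given).
#' @return a new pose-stream data.frame.
#' @export
addPoseNoise <- function(stream, transSd, rotSd, seed = NULL) {
  run <- function() {
    if (transSd <= 0 && rotSd <= 0) return(stream)
    out <- stream
    n <- nrow(out)
    if (transSd > 0) {
      out$tx <- out$tx + rnorm(n, sd = transSd)
      out$ty <- out$ty + rnorm(n, sd = transSd)
      out$tz <- out$tz + rnorm(n, sd = transSd)
    }
    if (rotSd > 0) {
      for (i in seq_len(n)) {
        dR <- rotationAxisAngle(rnorm(3), rnorm(1, sd = rotSd * pi / 180))
        R <- dR %*% matrixFromQuaternion(
          c(out$qw[i], out$qx[i], out$qy[i], out$qz[i]))
        q <- quaternionFromMatrix(R)
        out$qw[i] <- q[1]; out$qx[i] <- q[2]
        out$qy[i] <- q[3]; out$qz[i] <- q[4]
      }
    }
    out
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Run the full accuracy-evaluation pipeline on a simulated procedure
#'
#' Aligns the post-operative model onto plan space via the unchanged-region
#' correspondences (paired-point fit plus ICP refinement on the unchanged
#' region), transfers the planned surface into post-op space, generates
#' paired points along the planned-surface normals in the surgical area,
#' and returns the per-case deviation report.
#'
#' @param plan [PlanModel-class].
#' @param procedure [SimulatedProcedure-class].
#' @param n paired points to draw.
#' @param seed sampling seed.
#' @param refine run ICP refinement in the alignment step.
#' @param case case identifier.
#' @return a [DeviationReport-class].
#' @export
evaluateProcedure <- function(plan, procedure, n = 500L, seed = 1L,
                              refine = TRUE, case = "phantom") {
  align <- alignPostop(procedure@postop, plan@preop,
                       procedure@unchangedCorrespondences, refine = refine)
  plannedPost <- transformMesh(plan@plannedSurface, align)
  region <- surgicalAreaFaces(plannedPost)
  pairs <- samplePairedPoints(plannedPost, procedure@postop,
                              faceIndices = region, n = n, seed = seed)
  deviationStats(pairs, case = case)
}
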