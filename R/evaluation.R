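## Accuracy evaluation: superimpose post-op onto the plan via unchanged-region
## correspondences, generate paired points along surface normals in the
## surgical area, and compute the per-case and cross-case deviation reports.

#' Align the post-operative model onto the plan space
#'
#' Paired-point (Kabsch) registration on correspondences picked on the
#' unchanged region of the skull, optionally followed by ICP refinement
#' restricted to the unchanged region, so that the changed (recontoured)
#' area cannot bias the superimposition. Returns the transform mapping plan
#' space into post-operative space.
#'
#' @param postop post-operative [TriMesh-class].
#' @param planContext pre-operative/plan-space [TriMesh-class] (labelled
#'   \code{"unchanged"} / \code{"surgical_area"} when available).
#' @param unchangedCorr [CorrespondenceSet-class]: source points in plan
#'   space on the unchanged region, targets on the post-op model.
#' @param refine logical, run ICP refinement after the paired-point fit.
#' @return a [RigidTransform-class] (\code{"plan"} -> \code{"postop"}).
#' @export
alignPostop <- function(postop, planContext, unchangedCorr, refine = FALSE) {
  if (length(planContext@vertexLabels)) {
    lab <- planContext@vertexLabels
    surg <- which(lab == "surgical_area")
    if (length(surg)) {
      cp <- closestPointOnMesh(unchangedCorr@source, planContext)
      nearLab <- lab[planContext@faces[cp$face, 1]]
      if (any(nearLab == "surgical_area"))
        warning("some correspondences lie on the surgical area; ",
                "alignment should use unchanged regions only")
    }
  }
  fit <- pairedPointRegister(unchangedCorr, source = "plan", target = "postop")
  T <- fit$transform
  if (refine) {
    src <- unchangedCorr@source
    if (length(planContext@vertexLabels)) {
      keep <- which(planContext@vertexLabels == "unchanged")
      if (length(keep) > 3L) {
        extra <- planContext@vertices[keep, , drop = FALSE]
        if (nrow(extra) > 500L)
          extra <- extra[round(seq(1, nrow(extra), length.out = 500L)), ,
                         drop = FALSE]
        src <- rbind(src, extra)
      }
    }
    T <- icpRefine(src, postop, init = T)$transform
  }
  T
}

#' Generate paired points along surface normals in the surgical area
#'
#' Source points are drawn area-uniformly (faces sampled proportionally to
#' area, positions uniform in barycentric coordinates) on the planned
#' surface within the given region; each target point is the nearest
#' intersection (both directions searched) of the line through the source
#' point along its face normal with the post-operative mesh. Pairs with no
#' hit within \code{cutoff} are discarded and counted; larger gaps indicate
#' correspondence failure rather than surgical deviation.
#'
#' @param planned planned-target [TriMesh-class], co-registered with
#'   \code{postop}.
#' @param postop post-operative [TriMesh-class].
#' @param faceIndices faces of \code{planned} to sample from (default all).
#' @param n number of source points to draw (default 500, "hundreds").
#' @param cutoff normal-ray miss cutoff (mm).
#' @param seed optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is untouched.
#' @return a [CorrespondenceSet-class]; attribute \code{"nMissed"} carries
#'   the discarded-pair count. More than 20% discards raises a warning.
#' @export
samplePairedPoints <- function(planned, postop, faceIndices = NULL, n = 500L,
                               cutoff = 10, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(faceIndices)) faceIndices <- seq_len(nFaces(planned))
  if (!length(faceIndices)) stop("empty sampling region")
  stopifnot(n >= 1L)
  areas <- faceAreas(planned)[faceIndices]
  pick <- faceIndices[sample.int(length(faceIndices), n, replace = TRUE,
                                 prob = areas)]
  F <- planned@faces
  V <- planned@vertices
  u <- runif(n); v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  w <- 1 - u - v
  src <- w * V[F[pick, 1], , drop = FALSE] +
    u * V[F[pick, 2], , drop = FALSE] +
    v * V[F[pick, 3], , drop = FALSE]
  nrm <- faceNormals(planned)[pick, , drop = FALSE]
  hit <- lineMeshIntersect(src, nrm, postop, maxAbsT = cutoff)
  keep <- which(hit$hit)
  nMissed <- n - length(keep)
  if (!length(keep)) stop("no paired points found within the cutoff")
  if (nMissed > 0.2 * n)
    warning(sprintf("%d of %d paired points discarded (no hit within %g mm)",
                    nMissed, n, cutoff))
  tgt <- src[keep, , drop = FALSE] + hit$t[keep] * nrm[keep, , drop = FALSE]
  out <- correspondenceSet(src[keep, , drop = FALSE], tgt)
  attr(out, "nMissed") <- nMissed
  out
}

#' Per-case deviation statistics
#'
#' Euclidean separations of the paired points; distances are reported
#' unsigned (planned-vs-achieved discrepancy magnitude). The per-case SD
#' uses the population convention (divide by n), consistent with the
#' cross-case aggregation.
#'
#' @param pairs a non-empty [CorrespondenceSet-class].
#' @param case case identifier.
#' @return a [DeviationReport-class].
#' @export
deviationStats <- function(pairs, case = "case") {
  if (nrow(pairs@source) < 1L) stop("empty correspondence set")
  d <- sqrt(rowSums((pairs@target - pairs@source)^2))
  new("DeviationReport", distances = d, caseId = as.character(case))
}

#' Summary statistics of a deviation report
#' @param report a [DeviationReport-class].
#' @return named numeric: \code{min}, \code{max}, \code{mean}, \code{sd}
#'   (population), \code{n}.
#' @export
deviationSummary <- function(report) {
  d <- report@distances
  c(min = min(d), max = max(d), mean = mean(d),
    sd = sqrt(mean((d - mean(d))^2)), n = length(d))
}

#' Aggregate per-case mean deviations across cases
#'
#' Grand mean is the arithmetic mean of the per-case means; the grand SD is
#' the population standard deviation (divide by n) of the per-case means --
#' the convention consistent with the published cross-patient aggregate of
#' the published per-case means.
#'
#' @param perCaseMeans numeric vector of per-case mean deviations (mm), or a
#'   list of [DeviationReport-class] objects.
#' @return an [AggregateReport-class].
#' @export
aggregateCases <- function(perCaseMeans) {
  if (is.list(perCaseMeans))
    perCaseMeans <- vapply(perCaseMeans,
                           function(r) mean(distances(r)), numeric(1))
  if (!length(perCaseMeans)) stop("no cases to aggregate")
  gm <- mean(perCaseMeans)
  gs <- sqrt(mean((perCaseMeans - gm)^2))
  new("AggregateReport", caseMeans = as.numeric(perCaseMeans),
      grandMean = gm, grandSD = gs)
}

#' Write a deviation report to disk
#'
#' JSON summary (min/max/mean/sd/n) plus an optional CSV of per-point
#' distances.
#'
#' @param report a [DeviationReport-class].
#' @param jsonPath summary JSON path.
#' @param csvPath optional per-point distance CSV path.
#' @return invisibly, \code{jsonPath}.
#' @export
writeDeviationReport <- function(report, jsonPath, csvPath = NULL) {
  s <- deviationSummary(report)
  jsonlite::write_json(
    list(case = report@caseId, n = unname(s["n"]), min_mm = unname(s["min"]),
         max_mm = unname(s["max"]), mean_mm = unname(s["mean"]),
         sd_mm = unname(s["sd"])),
    jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(data.frame(distance_mm = report@distances), csvPath,
                     row.names = FALSE)
  invisible(jsonPath)
}

#' Export a per-vertex deviation heat map
#'
#' Distance of each planned-surface vertex to the post-operative mesh,
#' written as the \code{quality} scalar of an ASCII PLY (the colour-map
#' analogue of surface-comparison software output).
#'
#' @param planned,postop co-registered [TriMesh-class] objects.
#' @param path output PLY path.
#' @return invisibly, the per-vertex distances.
#' @export
exportDeviationHeatmap <- function(planned, postop, path) {
  d <- closestPointOnMesh(planned@vertices, postop)$distance
  writeMesh(planned, path, vertexScalar = d)
  invisible(d)
}
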