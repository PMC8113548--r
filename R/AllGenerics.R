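## Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for CranioGuide objects
#' @description Small accessor generics: vertices/faces of a mesh, rotation
#'   and translation of a rigid transform, distances of a deviation report.
#' @param x an object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("sourceFrame", function(x) standardGeneric("sourceFrame"))
#' @rdname accessors
#' @export
setGeneric("targetFrame", function(x) standardGeneric("targetFrame"))
#' @rdname accessors
#' @export
setGeneric("planePoint", function(x) standardGeneric("planePoint"))
#' @rdname accessors
#' @export
setGeneric("planeNormal", function(x) standardGeneric("planeNormal"))
#' @rdname accessors
#' @export
setGeneric("landmarkNames", function(x) standardGeneric("landmarkNames"))
#' @rdname accessors
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))
#' @rdname accessors
#' @export
setGeneric("plannedSurface", function(x) standardGeneric("plannedSurface"))
#' @rdname accessors
#' @export
setGeneric("resectionFaces", function(x) standardGeneric("resectionFaces"))
#' @rdname accessors
#' @export
setGeneric("excessMap", function(x) standardGeneric("excessMap"))
#' @rdname accessors
#' @export
setGeneric("sourcePoints", function(x) standardGeneric("sourcePoints"))
#' @rdname accessors
#' @export
setGeneric("targetPoints", function(x) standardGeneric("targetPoints"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("caseMeans", function(x) standardGeneric("caseMeans"))
#' @rdname accessors
#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))
#' @rdname accessors
#' @export
setGeneric("grandSD", function(x) standardGeneric("grandSD"))

## -- mesh accessors ---------------------------------------------------------

#' @rdname accessors
setMethod("vertices", "TriMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("faces", "TriMesh", function(x) x@faces)
#' @rdname accessors
setMethod("vertexLabels", "TriMesh", function(x) x@vertexLabels)
#' @rdname accessors
setMethod("nVertices", "TriMesh", function(x) nrow(x@vertices))
#' @rdname accessors
setMethod("nFaces", "TriMesh", function(x) nrow(x@faces))

## -- transform / plane accessors -------------------------------------------

#' @rdname accessors
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @rdname accessors
setMethod("translation", "RigidTransform", function(x) x@translation)
#' @rdname accessors
setMethod("sourceFrame", "RigidTransform", function(x) x@sourceFrame)
#' @rdname accessors
setMethod("targetFrame", "RigidTransform", function(x) x@targetFrame)
#' @rdname accessors
setMethod("planePoint", "Plane", function(x) x@point)
#' @rdname accessors
setMethod("planeNormal", "Plane", function(x) x@normal)

## -- landmark / plan accessors ----------------------------------------------

#' @rdname accessors
setMethod("landmarkNames", "LandmarkSet", function(x) rownames(x@points))
#' @rdname accessors
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)
#' @rdname accessors
setMethod("plannedSurface", "PlanModel", function(x) x@plannedSurface)
#' @rdname accessors
setMethod("resectionFaces", "PlanModel", function(x) x@resectionFaces)
#' @rdname accessors
setMethod("excessMap", "PlanModel", function(x) x@excessMap)

## -- correspondence / report accessors --------------------------------------

#' @rdname accessors
setMethod("sourcePoints", "CorrespondenceSet", function(x) x@source)
#' @rdname accessors
setMethod("targetPoints", "CorrespondenceSet", function(x) x@target)
#' @rdname accessors
setMethod("distances", "DeviationReport", function(x) x@distances)
#' @rdname accessors
setMethod("caseId", "DeviationReport", function(x) x@caseId)
#' @rdname accessors
setMethod("caseMeans", "AggregateReport", function(x) x@caseMeans)
#' @rdname accessors
setMethod("grandMean", "AggregateReport", function(x) x@grandMean)
#' @rdname accessors
setMethod("grandSD", "AggregateReport", function(x) x@grandSD)

## -- show methods -----------------------------------------------------------

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces", nVertices(object),
              nFaces(object)))
  if (length(object@vertexLabels)) {
    tab <- table(object@vertexLabels)
    cat(sprintf("; labels: %s",
                paste(sprintf("%s(%d)", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform %s -> %s: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              object@sourceFrame, object@targetFrame, ang * 180 / pi,
              object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane through (%.3f, %.3f, %.3f) with normal (%.4f, %.4f, %.4f)\n",
              object@point[1], object@point[2], object@point[3],
              object@normal[1], object@normal[2], object@normal[3]))
})

setMethod("show", "LandmarkSet", function(object) {
  info <- .splitLandmarks(object)
  cat(sprintf("LandmarkSet: %d landmarks (%d midline, %d left/right pairs)\n",
              nrow(object@points), nrow(info$midline), length(info$pairStems)))
})

setMethod("show", "PlanModel", function(object) {
  ex <- object@excessMap[object@excessMap > 0]
  cat(sprintf("PlanModel (%s side): %d resection faces, max excess %.2f mm, excess volume %.1f mm^3\n",
              object@affectedSide, length(object@resectionFaces),
              if (length(ex)) max(ex) else 0, excessVolume(object)))
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet: %d point pairs\n", nrow(object@source)))
})

setMethod("show", "FrameGraph", function(object) {
  cat(sprintf("FrameGraph: frames {%s}, %d static edges, %d tracked edges\n",
              paste(object@frames, collapse = ", "),
              length(object@staticEdges), length(object@trackedEdges)))
})

setMethod("show", "DeviationReport", function(object) {
  d <- object@distances
  cat(sprintf("DeviationReport [%s]: n = %d, min %.4f, max %.4f, mean %.3f +/- %.3f mm\n",
              object@caseId, length(d), min(d), max(d), mean(d),
              sqrt(mean((d - mean(d))^2))))
})

setMethod("show", "AggregateReport", function(object) {
  cat(sprintf("AggregateReport: %d cases, mean +/- SD = %.3f +/- %.3f mm\n",
              length(object@caseMeans), object@grandMean, object@grandSD))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: semi-axes (%.0f, %.0f, %.0f) mm, subdiv %d, lesion %s h=%.1f mm, seed %d\n",
              object@semiAxes[1], object@semiAxes[2], object@semiAxes[3],
              object@subdivisions, object@lesionSide, object@lesionHeight,
              object@seed))
})

setMethod("show", "SimulatedProcedure", function(object) {
  cat(sprintf("SimulatedProcedure: residual %.2f +/- %.2f mm, %d pose samples, seed %d\n",
              object@residualMean, object@residualSd,
              length(unique(object@poseStream$time_s)), object@seed))
})
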