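## Central S4 classes. All geometry is in millimetres, image space unless a
## frame name says otherwise. Validity methods enforce the structural
## invariants; numerical invariants (outward orientation, group laws) are
## exercised by the test-suite on phantom data.

.checkPoints3 <- function(x, what) {
  if (!is.matrix(x) || ncol(x) != 3L)
    return(sprintf("%s must be an n x 3 matrix", what))
  if (nrow(x) > 0 && !all(is.finite(x)))
    return(sprintf("%s contains non-finite coordinates", what))
  NULL
}

#' Triangulated surface mesh
#'
#' A triangulated surface in image space (millimetres): an \code{n x 3} vertex
#' matrix, an \code{m x 3} face matrix of 1-based vertex indices, and optional
#' per-vertex region labels (e.g. \code{"surgical_area"}, \code{"unchanged"}).
#' Use [triMesh()] to construct one; construction welds duplicate vertices and
#' drops degenerate faces.
#'
#' @slot vertices numeric matrix, one row per vertex (mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot vertexLabels character vector of length 0 or \code{nrow(vertices)}.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexLabels = "character"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            vertexLabels = character(0)),
  validity = function(object) {
    msgs <- character(0)
    m <- .checkPoints3(object@vertices, "vertices")
    if (!is.null(m)) msgs <- c(msgs, m)
    f <- object@faces
    if (!is.matrix(f) || ncol(f) != 3L)
      msgs <- c(msgs, "faces must be an m x 3 matrix")
    else if (nrow(f) > 0) {
      if (any(f < 1L) || any(f > nrow(object@vertices)))
        msgs <- c(msgs, "face indices out of range")
    }
    nl <- length(object@vertexLabels)
    if (nl != 0L && nl != nrow(object@vertices))
      msgs <- c(msgs, "vertexLabels must be empty or one per vertex")
    if (length(msgs)) msgs else TRUE
  })

#' Rigid transform between two named coordinate frames
#'
#' Rotation (proper orthonormal 3x3) plus translation (mm), mapping points
#' expressed in \code{sourceFrame} into \code{targetFrame}:
#' \eqn{p' = R p + t}. Construct with [rigidTransform()].
#'
#' @slot rotation 3x3 rotation matrix, \eqn{R^T R = I}, \eqn{\det R = +1}.
#' @slot translation numeric length-3, mm.
#' @slot sourceFrame,targetFrame frame names.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 sourceFrame = "character", targetFrame = "character"),
  prototype(rotation = diag(3), translation = c(0, 0, 0),
            sourceFrame = "a", targetFrame = "b"),
  validity = function(object) {
    R <- object@rotation
    msgs <- character(0)
    if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
      return("rotation must be a finite 3 x 3 matrix")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msgs <- c(msgs, "rotation is not orthonormal (R'R != I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
      msgs <- c(msgs, "rotation must be proper (det = +1 within 1e-9)")
    if (length(object@translation) != 3L || !all(is.finite(object@translation)))
      msgs <- c(msgs, "translation must be a finite length-3 vector")
    if (length(object@sourceFrame) != 1L || length(object@targetFrame) != 1L)
      msgs <- c(msgs, "frame names must be single strings")
    if (length(msgs)) msgs else TRUE
  })

#' Oriented plane
#'
#' A plane given by a point on it and a unit normal. The midsagittal plane
#' fitted by [fitMidsagittalPlane()] has its normal oriented from the left
#' towards the right anatomical side.
#'
#' @slot point numeric length-3, a point on the plane (mm).
#' @slot normal unit normal vector.
#' @export
setClass("Plane",
  representation(point = "numeric", normal = "numeric"),
  prototype(point = c(0, 0, 0), normal = c(1, 0, 0)),
  validity = function(object) {
    if (length(object@point) != 3L || !all(is.finite(object@point)))
      return("point must be a finite length-3 vector")
    if (length(object@normal) != 3L || !all(is.finite(object@normal)))
      return("normal must be a finite length-3 vector")
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-12)
      return("normal must be unit length within 1e-12")
    TRUE
  })

#' Named anatomical landmarks
#'
#' Named 3D points (mm). Midline landmarks carry plain names
#' (\code{"nasion"}, \code{"basion"}, ...); bilateral pairs use the suffixes
#' \code{"_left"} / \code{"_right"} on a common stem
#' (\code{"zygion_left"}, \code{"zygion_right"}). Plane fitting requires at
#' least 3 midline landmarks or at least 3 complete left/right pairs.
#'
#' @slot points numeric matrix with rownames = landmark names.
#' @export
setClass("LandmarkSet",
  representation(points = "matrix"),
  prototype(points = matrix(numeric(0), 0, 3)),
  validity = function(object) {
    m <- .checkPoints3(object@points, "points")
    if (!is.null(m)) return(m)
    nm <- rownames(object@points)
    if (nrow(object@points) > 0 && (is.null(nm) || anyDuplicated(nm)))
      return("landmark names must be present and unique")
    TRUE
  })

#' Virtual recontouring plan
#'
#' Output of [buildPlan()]: the mirrored target surface over the affected
#' side, the resection region on the pre-operative mesh (faces whose bone
#' must be removed), the midsagittal plane used for mirroring, and the
#' per-vertex excess bone thickness (mm, zero outside the region).
#'
#' @slot plannedSurface [TriMesh-class] mirrored target restricted to the
#'   resection region's neighbourhood.
#' @slot preop the pre-operative [TriMesh-class] the plan refers to.
#' @slot resectionFaces integer indices of pre-op faces to be recontoured.
#' @slot sourcePlane the [Plane-class] used for mirroring.
#' @slot excessMap numeric, per pre-op vertex excess thickness (mm, >= 0).
#' @slot affectedSide \code{"left"} or \code{"right"}.
#' @export
setClass("PlanModel",
  representation(plannedSurface = "TriMesh", preop = "TriMesh",
                 resectionFaces = "integer", sourcePlane = "Plane",
                 excessMap = "numeric", affectedSide = "character"),
  validity = function(object) {
    msgs <- character(0)
    npre <- nrow(object@preop@vertices)
    if (length(object@excessMap) != npre)
      msgs <- c(msgs, "excessMap must have one value per pre-op vertex")
    else if (any(object@excessMap < 0))
      msgs <- c(msgs, "excessMap must be non-negative")
    nf <- nrow(object@preop@faces)
    if (length(object@resectionFaces) &&
        (any(object@resectionFaces < 1L) || any(object@resectionFaces > nf)))
      msgs <- c(msgs, "resectionFaces out of range")
    if (!object@affectedSide %in% c("left", "right"))
      msgs <- c(msgs, "affectedSide must be 'left' or 'right'")
    if (length(msgs)) msgs else TRUE
  })

#' Ordered point correspondences
#'
#' Paired source/target points (mm) for rigid registration and for
#' paired-point deviation measurement.
#'
#' @slot source,target numeric n x 3 matrices, row i of each paired.
#' @export
setClass("CorrespondenceSet",
  representation(source = "matrix", target = "matrix"),
  prototype(source = matrix(numeric(0), 0, 3),
            target = matrix(numeric(0), 0, 3)),
  validity = function(object) {
    m <- .checkPoints3(object@source, "source")
    if (!is.null(m)) return(m)
    m <- .checkPoints3(object@target, "target")
    if (!is.null(m)) return(m)
    if (nrow(object@source) != nrow(object@target))
      return("source and target must have the same number of points")
    if (anyDuplicated(object@source) > 0)
      return("duplicated source points")
    TRUE
  })

#' Drill-tip calibration
#'
#' Fixed offset of the drill tip expressed in the drill DRF frame (mm).
#' Pivot calibration itself is out of scope; the offset is an input.
#'
#' @slot offset numeric length-3, |offset| < 500 mm.
#' @export
setClass("TipCalibration",
  representation(offset = "numeric"),
  prototype(offset = c(0, 0, 0)),
  validity = function(object) {
    if (length(object@offset) != 3L || !all(is.finite(object@offset)))
      return("offset must be a finite length-3 vector")
    if (sqrt(sum(object@offset^2)) >= 500)
      return("tip offset magnitude must be < 500 mm")
    TRUE
  })

#' Coordinate-frame graph
#'
#' Named frames (conventionally \code{TRACKER}, \code{PATIENT_DRF},
#' \code{DRILL_DRF}, \code{IMAGE}) connected by static rigid edges and by
#' time-stamped tracked edges (pose tracks). [resolveFrames()] composes a
#' path between any two connected frames, interpolating tracked edges.
#'
#' @slot frames character vector of frame names.
#' @slot staticEdges list of [RigidTransform-class].
#' @slot trackedEdges list of pose tracks (see [poseTrack()]).
#' @export
setClass("FrameGraph",
  representation(frames = "character", staticEdges = "list",
                 trackedEdges = "list"),
  prototype(frames = character(0), staticEdges = list(),
            trackedEdges = list()))

#' Guidance configuration
#'
#' The two-state rendering rule: the model is shown GREEN while the drill tip
#' is more than \code{threshold} (default 1 mm) from the planned surface and
#' RED once the remaining distance is at or below it. An optional hysteresis
#' band (default 0, i.e. the literal two-rule logic) suppresses chatter.
#'
#' @slot threshold mm, > 0; boundary value classifies RED.
#' @slot hysteresis mm, >= 0; half-width of the optional hysteresis band.
#' @export
setClass("GuidanceConfig",
  representation(threshold = "numeric", hysteresis = "numeric"),
  prototype(threshold = 1.0, hysteresis = 0.0),
  validity = function(object) {
    if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
        object@threshold <= 0)
      return("threshold must be a single positive number (mm)")
    if (length(object@hysteresis) != 1L || !is.finite(object@hysteresis) ||
        object@hysteresis < 0)
      return("hysteresis must be a single non-negative number (mm)")
    TRUE
  })

#' Per-case deviation report
#'
#' Paired-point distances (mm) between the planned and post-operative
#' surfaces for one case, with min/max/mean and population SD, the
#' per-case row of the accuracy table.
#'
#' @slot distances numeric, per-pair distances (mm).
#' @slot caseId case identifier.
#' @export
setClass("DeviationReport",
  representation(distances = "numeric", caseId = "character"),
  validity = function(object) {
    if (length(object@distances) < 1L || !all(is.finite(object@distances)))
      return("distances must be a non-empty finite numeric vector")
    if (length(object@caseId) != 1L)
      return("caseId must be a single string")
    TRUE
  })

#' Cross-case aggregate report
#'
#' Grand mean and population SD (divide by n) of the per-case mean
#' deviations, the convention that reproduces the published cross-patient
#' aggregate from the published per-case means.
#'
#' @slot caseMeans per-case mean deviations (mm).
#' @slot grandMean,grandSD aggregate statistics (mm).
#' @export
setClass("AggregateReport",
  representation(caseMeans = "numeric", grandMean = "numeric",
                 grandSD = "numeric"),
  validity = function(object) {
    if (length(object@caseMeans) < 1L || !all(is.finite(object@caseMeans)))
      return("caseMeans must be a non-empty finite numeric vector")
    gm <- mean(object@caseMeans)
    gs <- sqrt(mean((object@caseMeans - gm)^2))
    if (abs(object@grandMean - gm) > 1e-12 || abs(object@grandSD - gs) > 1e-12)
      return("grandMean/grandSD inconsistent with caseMeans")
    TRUE
  })

#' Synthetic phantom specification
#'
#' Parameters of the skull-like phantom: an ellipsoid (semi-axes in mm)
#' meshed as a subdivided icosahedron, with a unilateral Gaussian lesion
#' bump of known height and footprint, plus landmark and fiducial placement.
#' The base mesh is exactly bilaterally symmetric about the plane x = 0
#' (x is the left(-)/right(+) axis).
#'
#' @slot semiAxes ellipsoid semi-axes (mm), length 3.
#' @slot subdivisions icosphere subdivision level (3 gives 1280 faces).
#' @slot lesionSide \code{"left"} or \code{"right"}.
#' @slot lesionCenter unit direction of the bump centre on the sphere.
#' @slot lesionHeight bump height (mm, > 0 for a lesion; 0 = healthy).
#' @slot lesionRadius Gaussian footprint sigma expressed as an angle scale.
#' @slot nFiducials number of fiducial markers placed on the unchanged side.
#' @slot seed integer seed fixing all randomness downstream.
#' @export
setClass("PhantomSpec",
  representation(semiAxes = "numeric", subdivisions = "integer",
                 lesionSide = "character", lesionCenter = "numeric",
                 lesionHeight = "numeric", lesionRadius = "numeric",
                 nFiducials = "integer", seed = "integer"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
      msgs <- c(msgs, "semiAxes must be 3 positive numbers (mm)")
    if (object@subdivisions < 3L)
      msgs <- c(msgs, "resolution too coarse: subdivisions >= 3 required (>= 1000 faces)")
    if (!object@lesionSide %in% c("left", "right"))
      msgs <- c(msgs, "lesionSide must be 'left' or 'right'")
    if (object@lesionHeight < 0)
      msgs <- c(msgs, "lesionHeight must be >= 0")
    if (object@lesionRadius <= 0)
      msgs <- c(msgs, "lesionRadius must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' Simulated procedure with full ground truth
#'
#' Everything needed to exercise registration, guidance and evaluation
#' without hardware: the simulated post-operative mesh, a scripted noisy
#' drill pose stream, the ground-truth frame transforms, the injected
#' residual error field, and the unchanged-region correspondences.
#'
#' @slot postop simulated post-operative [TriMesh-class] (in post-op space).
#' @slot poseStream data.frame pose stream (time_s, frame, qw..qz, tx..tz).
#' @slot groundTruth list of ground-truth quantities (transforms, tip
#'   trajectory, per-vertex residuals, ...).
#' @slot unchangedCorrespondences [CorrespondenceSet-class] on the
#'   unchanged region, plan space to post-op space.
#' @slot residualMean,residualSd injected residual field statistics (mm).
#' @slot noise list of noise parameters (translation sd mm, rotation sd
#'   deg, fiducial sd mm).
#' @slot seed integer seed.
#' @export
setClass("SimulatedProcedure",
  representation(postop = "TriMesh", poseStream = "data.frame",
                 groundTruth = "list",
                 unchangedCorrespondences = "CorrespondenceSet",
                 residualMean = "numeric", residualSd = "numeric",
                 noise = "list", seed = "integer"))
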