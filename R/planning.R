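## Virtual planning: midsagittal plane fit, mirroring, resection plan and
## excess-volume estimate.

## Split a LandmarkSet into midline landmarks and left/right pairs.
## Pairs use the "_left"/"_right" suffix convention on a common stem.
.splitLandmarks <- function(landmarks) {
  pts <- landmarks@points
  nm <- rownames(pts)
  isL <- grepl("_left$", nm)
  isR <- grepl("_right$", nm)
  stemsL <- sub("_left$", "", nm[isL])
  stemsR <- sub("_right$", "", nm[isR])
  stems <- intersect(stemsL, stemsR)
  left <- pts[match(paste0(stems, "_left"), nm), , drop = FALSE]
  right <- pts[match(paste0(stems, "_right"), nm), , drop = FALSE]
  midline <- pts[!(isL | isR), , drop = FALSE]
  list(midline = midline, left = left, right = right, pairStems = stems)
}

#' Fit the midsagittal plane to anatomical landmarks
#'
#' Single least-squares problem combining midline landmarks and bilateral
#' pairs: the plane minimizes the squared distances of midline landmarks
#' (and pair midpoints) to the plane plus the squared off-normal components
#' of the left-to-right pair axes. Closed form: the normal is the
#' eigenvector of \eqn{S_{on} - S_{axis}} with the smallest eigenvalue,
#' where \eqn{S_{on}} is the scatter of the on-plane points about their
#' centroid and \eqn{S_{axis}} the scatter of the pair difference vectors.
#' The normal is oriented from the left towards the right anatomical side
#' (using the pair axes when present, the +x image axis convention
#' otherwise).
#'
#' @param landmarks a [LandmarkSet-class] with >= 3 midline landmarks or
#'   >= 3 complete left/right pairs.
#' @return a [Plane-class].
#' @export
fitMidsagittalPlane <- function(landmarks) {
  sp <- .splitLandmarks(landmarks)
  nPairs <- length(sp$pairStems)
  nMid <- nrow(sp$midline)
  if (nMid < 3L && nPairs < 3L)
    stop("insufficient landmarks: need >= 3 midline landmarks or >= 3 left/right pairs")
  onPlane <- sp$midline
  if (nPairs > 0)
    onPlane <- rbind(onPlane, (sp$left + sp$right) / 2)
  q <- colMeans(onPlane)
  Son <- crossprod(sweep(onPlane, 2, q))
  M <- Son
  D <- NULL
  if (nPairs > 0) {
    D <- sp$right - sp$left
    M <- M - crossprod(D)
  }
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- rev(e$values)              # ascending
  vec <- e$vectors[, 3L]           # smallest eigenvalue
  scale <- max(abs(e$values), 1)
  if ((ev[2] - ev[1]) < 1e-9 * scale)
    stop("collinear or rank-deficient landmark configuration: midsagittal plane is not unique")
  n <- vec / sqrt(sum(vec^2))
  if (nPairs > 0) {
    if (sum(colMeans(D) * n) < 0) n <- -n
  } else if (n[which.max(abs(n))] < 0) n <- -n
  new("Plane", point = as.numeric(q), normal = as.numeric(n))
}

#' Reflect points across a plane
#' @param points length-3 vector or n x 3 matrix.
#' @param plane a [Plane-class].
#' @return reflected points, same shape (Householder map
#'   \eqn{p - 2((p - q)\cdot n)\, n}).
#' @export
reflectPoints <- function(points, plane) {
  n <- plane@normal; q <- plane@point
  if (is.null(dim(points))) {
    return(points - 2 * sum((points - q) * n) * n)
  }
  h <- sweep(points, 2, q) %*% n
  points - 2 * as.vector(h) %o% n
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex by the Householder map and flips the face winding
#' so that normals remain consistently outward (a reflection alone would
#' turn them inward).
#'
#' @param mesh a [TriMesh-class].
#' @param plane a [Plane-class].
#' @return the mirrored [TriMesh-class].
#' @export
mirrorAcrossPlane <- function(mesh, plane) {
  new("TriMesh", vertices = reflectPoints(mesh@vertices, plane),
      faces = mesh@faces[, c(1L, 3L, 2L), drop = FALSE],
      vertexLabels = mesh@vertexLabels)
}

#' Build the recontouring plan by contralateral mirroring
#'
#' The healthy contralateral half is mirrored across the midsagittal plane
#' onto the affected side; the excess map is the per-vertex outward distance
#' from the pre-operative surface to the mirrored (target) surface, clamped
#' at zero, measured by nearest-point projection. The resection region is
#' the set of affected-side faces all of whose vertices exceed
#' \code{threshold} of excess; the planned surface is the mirrored surface
#' restricted to the neighbourhood of that region. Vertices of the returned
#' plan's pre-op mesh are labelled \code{"surgical_area"} /
#' \code{"unchanged"}.
#'
#' @param preop pre-operative [TriMesh-class].
#' @param plane midsagittal [Plane-class] (normal oriented left to right).
#' @param affectedSide \code{"left"} or \code{"right"}.
#' @param threshold excess (mm) above which a vertex is counted as lesion;
#'   default 0.5 mm, below typical mirroring/segmentation noise.
#' @return a [PlanModel-class]. Empty resection region raises a warning
#'   ("no excess found"), not an error.
#' @export
buildPlan <- function(preop, plane, affectedSide = c("right", "left"),
                      threshold = 0.5) {
  affectedSide <- match.arg(affectedSide)
  sideSign <- if (affectedSide == "right") 1 else -1
  V <- preop@vertices
  h <- as.vector(sweep(V, 2, plane@point) %*% plane@normal)
  if (all(sideSign * h <= 0))
    stop("plane does not separate the mesh: no vertices on the affected side")
  affectedVerts <- sideSign * h > 0
  mirrored <- mirrorAcrossPlane(preop, plane)

  excess <- numeric(nrow(V))
  idx <- which(affectedVerts)
  excess[idx] <- pmax(0, signedDistance(V[idx, , drop = FALSE], mirrored))

  F <- preop@faces
  over <- excess > threshold
  faceAffected <- matrix(sideSign * h[F] > 0, ncol = 3)
  regionFaces <- which(rowSums(matrix(over[F], ncol = 3)) == 3L &
                         rowSums(faceAffected) == 3L)

  labs <- rep("unchanged", nrow(V))
  if (length(regionFaces))
    labs[unique(as.vector(F[regionFaces, ]))] <- "surgical_area"
  preopLab <- new("TriMesh", vertices = V, faces = F, vertexLabels = labs)

  if (!length(regionFaces)) {
    warning("no excess found: resection region is empty")
    planned <- new("TriMesh")
  } else {
    regionMesh <- subMesh(preopLab, regionFaces)
    edges <- sqrt(rowSums((V[F[, 1], , drop = FALSE] -
                             V[F[, 2], , drop = FALSE])^2))
    margin <- max(excess) + 3 * stats::median(edges)
    cen <- faceCentroids(mirrored)
    cenSide <- as.vector(sweep(cen, 2, plane@point) %*% plane@normal)
    near <- which(sideSign * cenSide > 0)
    d <- closestPointOnMesh(cen[near, , drop = FALSE], regionMesh)$distance
    planned <- subMesh(mirrored, near[d <= margin])
    ## label planned vertices by whether they project into the resection
    ## region, so the evaluation sampler can stay inside the surgical area
    proj <- closestPointOnMesh(planned@vertices, preopLab)
    planned@vertexLabels <- ifelse(proj$face %in% regionFaces,
                                   "surgical_area", "unchanged")
  }
  new("PlanModel", plannedSurface = planned, preop = preopLab,
      resectionFaces = as.integer(regionFaces), sourcePlane = plane,
      excessMap = excess, affectedSide = affectedSide)
}

#' Excess lesion volume of a plan
#'
#' Prism summation of the excess thickness over the resection region: each
#' region vertex contributes its excess times one third of the area of its
#' incident region faces. The empty region gives 0.
#'
#' @param plan a [PlanModel-class].
#' @return excess volume in mm^3 (non-negative).
#' @export
excessVolume <- function(plan) {
  rf <- plan@resectionFaces
  if (!length(rf)) return(0)
  F <- plan@preop@faces[rf, , drop = FALSE]
  a <- .triAreas(plan@preop@vertices, F) / 3
  sum(a * (plan@excessMap[F[, 1]] + plan@excessMap[F[, 2]] +
             plan@excessMap[F[, 3]]))
}
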