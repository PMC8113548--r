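## TriMesh construction, differential quantities, and distance queries.

#' Construct a triangulated surface mesh
#'
#' Cleans on construction: vertices closer than \code{weldTolerance} are
#' welded (STL files routinely duplicate vertices per facet) and faces whose
#' area falls below \code{areaTolerance} are dropped, along with repeated
#' vertex indices within a face.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param vertexLabels optional character vector, one label per vertex.
#' @param weldTolerance vertices within this distance are merged (mm).
#' @param areaTolerance faces with smaller area are dropped (mm^2).
#' @return a [TriMesh-class].
#' @examples
#' m <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'              rbind(c(1, 2, 3)))
#' nFaces(m)
#' @export
triMesh <- function(vertices, faces, vertexLabels = character(0),
                    weldTolerance = 1e-6, areaTolerance = 1e-12) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) && weldTolerance > 0) {
    key <- paste(round(vertices[, 1] / weldTolerance),
                 round(vertices[, 2] / weldTolerance),
                 round(vertices[, 3] / weldTolerance))
    first <- !duplicated(key)
    remap <- match(key, key[first])
    if (any(!first)) {
      vertices <- vertices[first, , drop = FALSE]
      if (length(vertexLabels)) vertexLabels <- vertexLabels[first]
      faces[] <- remap[faces]
    }
  }
  if (nrow(faces)) {
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    faces <- faces[!dup, , drop = FALSE]
    if (nrow(faces)) {
      a <- .triAreas(vertices, faces)
      faces <- faces[a >= areaTolerance, , drop = FALSE]
    }
  }
  new("TriMesh", vertices = vertices, faces = faces,
      vertexLabels = as.character(vertexLabels))
}

.triAreas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-face and per-vertex mesh quantities
#'
#' \code{faceNormals} returns outward unit normals (right-hand rule on the
#' winding), \code{faceAreas} triangle areas (mm^2), \code{faceCentroids}
#' triangle centroids, \code{vertexAreas} one third of the incident face
#' area per vertex (sums to the total surface area), and
#' \code{vertexNormals} angle-weighted unit vertex normals.
#'
#' @param mesh a [TriMesh-class].
#' @return matrix or numeric vector as described.
#' @export
faceNormals <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' @rdname faceNormals
#' @export
faceAreas <- function(mesh) .triAreas(mesh@vertices, mesh@faces)

#' @rdname faceNormals
#' @export
faceCentroids <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' @rdname faceNormals
#' @export
vertexAreas <- function(mesh) {
  a <- faceAreas(mesh) / 3
  va <- numeric(nVertices(mesh))
  for (j in 1:3) {
    s <- tapply(a, mesh@faces[, j], sum)
    idx <- as.integer(names(s))
    va[idx] <- va[idx] + as.numeric(s)
  }
  va
}

#' @rdname faceNormals
#' @export
vertexNormals <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  fn <- faceNormals(mesh)
  vn <- matrix(0, nrow(V), 3)
  for (j in 1:3) {
    i0 <- F[, j]; i1 <- F[, (j %% 3) + 1]; i2 <- F[, ((j + 1) %% 3) + 1]
    e1 <- V[i1, , drop = FALSE] - V[i0, , drop = FALSE]
    e2 <- V[i2, , drop = FALSE] - V[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      sqrt(rowSums(e1^2) * rowSums(e2^2))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    w <- ang * fn
    for (k in 1:3) {
      s <- tapply(w[, k], i0, sum)
      idx <- as.integer(names(s))
      vn[idx, k] <- vn[idx, k] + as.numeric(s)
    }
  }
  vn / sqrt(rowSums(vn^2))
}

#' Signed volume enclosed by a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed mesh with consistently outward normals.
#'
#' @param mesh a closed [TriMesh-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Closest point on a mesh
#'
#' Exact closest point over all triangles (exhaustive scan with an exact
#' bounding-box prune, so results equal the brute-force answer).
#'
#' @param points query point (length-3) or n x 3 matrix (mm).
#' @param mesh a non-empty [TriMesh-class].
#' @return a list with \code{point} (n x 3 closest points), \code{distance}
#'   (mm) and \code{face} (1-based index of the nearest face).
#' @export
closestPointOnMesh <- function(points, mesh) {
  if (nFaces(mesh) == 0L) stop("empty mesh")
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else points
  .cgClosestPoints(pts, mesh@vertices, mesh@faces)
}

#' Signed distance to a mesh surface
#'
#' Magnitude equals the closest-point distance; the sign is taken from the
#' angle-weighted pseudonormal of the closest surface feature: positive on
#' the outward-normal side (drill has not yet reached the planned surface),
#' negative past it.
#'
#' @inheritParams closestPointOnMesh
#' @return numeric vector of signed distances (mm).
#' @export
signedDistance <- function(points, mesh) {
  if (nFaces(mesh) == 0L) stop("empty mesh")
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else points
  .cgSignedDistances(pts, mesh@vertices, mesh@faces)$signed
}

#' Nearest line-mesh intersection along given directions
#'
#' Intersects the two-sided line through each origin along its direction with
#' the mesh and returns the signed parameter \code{t} of the hit nearest in
#' \code{|t|}, up to \code{maxAbsT}. Used to pair points along surface
#' normals.
#'
#' @param origins,directions n x 3 matrices (directions need not be unit).
#' @param mesh a [TriMesh-class].
#' @param maxAbsT search cutoff on \code{|t|} (mm for unit directions).
#' @return list with \code{t} (signed, NA on miss), \code{hit} (logical)
#'   and \code{face}.
#' @export
lineMeshIntersect <- function(origins, directions, mesh, maxAbsT = Inf) {
  if (nFaces(mesh) == 0L) stop("empty mesh")
  .cgLineMeshNearest(origins, directions, mesh@vertices, mesh@faces, maxAbsT)
}

#' Extract a sub-mesh by face indices
#'
#' Keeps the selected faces and the vertices they reference; labels follow.
#' No welding or area filtering is re-applied.
#'
#' @param mesh a [TriMesh-class].
#' @param faceIndices integer indices of faces to keep.
#' @return a [TriMesh-class].
#' @export
subMesh <- function(mesh, faceIndices) {
  F <- mesh@faces[faceIndices, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nVertices(mesh))
  remap[used] <- seq_along(used)
  labs <- if (length(mesh@vertexLabels)) mesh@vertexLabels[used] else character(0)
  new("TriMesh", vertices = mesh@vertices[used, , drop = FALSE],
      faces = matrix(remap[F], ncol = 3), vertexLabels = labs)
}

#' Faces lying entirely in the surgical area
#'
#' Indices of faces all of whose vertices carry the \code{"surgical_area"}
#' label; empty when the mesh is unlabelled.
#'
#' @param mesh a labelled [TriMesh-class].
#' @return integer face indices.
#' @export
surgicalAreaFaces <- function(mesh) {
  if (!length(mesh@vertexLabels)) return(integer(0))
  inReg <- mesh@vertexLabels == "surgical_area"
  which(rowSums(matrix(inReg[mesh@faces], ncol = 3)) == 3L)
}

#' Apply a rigid transform to a mesh
#' @param mesh a [TriMesh-class].
#' @param T a [RigidTransform-class].
#' @return the transformed mesh (labels preserved).
#' @export
transformMesh <- function(mesh, T) {
  new("TriMesh", vertices = applyTransform(T, mesh@vertices),
      faces = mesh@faces, vertexLabels = mesh@vertexLabels)
}
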