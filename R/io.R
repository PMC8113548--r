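## File formats: ASCII STL/OBJ/PLY meshes, landmark and correspondence JSON,
## pose-stream CSV. All text-based, mm units throughout.

#' Read a surface mesh from file
#'
#' Supports ASCII STL, Wavefront OBJ (v/f records, polygon faces fan-
#' triangulated) and ASCII PLY. The mesh is cleaned on load (vertex welding,
#' degenerate-face removal) via [triMesh()].
#'
#' @param path file path; format inferred from the extension.
#' @return a [TriMesh-class].
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .readSTL(path),
    obj = .readOBJ(path),
    ply = .readPLY(path),
    stop("unsupported mesh format: ", ext))
}

#' Write a surface mesh to file
#'
#' ASCII STL, OBJ or PLY depending on the extension. For PLY an optional
#' per-vertex scalar (e.g. an excess-thickness or deviation map) is stored
#' as a \code{quality} property.
#'
#' @param mesh a [TriMesh-class].
#' @param path output path (.stl, .obj or .ply).
#' @param vertexScalar optional numeric, one value per vertex (PLY only).
#' @return invisibly, \code{path}.
#' @export
writeMesh <- function(mesh, path, vertexScalar = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .writeSTL(mesh, path),
    obj = .writeOBJ(mesh, path),
    ply = .writePLY(mesh, path, vertexScalar),
    stop("unsupported mesh format: ", ext))
  invisible(path)
}

.readSTL <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found; only ASCII STL is supported")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  nf <- nrow(nums) / 3
  triMesh(nums, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

.writeSTL <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  n <- faceNormals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (f in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[f, 1], n[f, 2], n[f, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- V[F[f, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) == 3L) idx
    else do.call(rbind, lapply(2:(length(idx) - 1), function(k)
      c(idx[1], idx[k], idx[k + 1])))   # fan triangulation
  }))
  triMesh(V, F)
}

.writeOBJ <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  endh <- grep("^end_header", lines)[1]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", lines, value = TRUE)[1]))
  vlines <- lines[(endh + 1):(endh + nv)]
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x)
    as.numeric(x[1:3])))
  flines <- lines[(endh + nv + 1):(endh + nv + nf)]
  F <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
    k <- as.integer(x[1])
    as.integer(x[2:(1 + k)])[1:3] + 1L
  }))
  triMesh(V, F)
}

.writePLY <- function(mesh, path, vertexScalar = NULL) {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (!is.null(vertexScalar)) {
    stopifnot(length(vertexScalar) == nrow(V))
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(vertexScalar))
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  else
    writeLines(sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3],
                       vertexScalar), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

## -- landmarks ---------------------------------------------------------------

#' Read / write landmark sets
#'
#' Landmarks are stored as a JSON object \code{{name: [x, y, z], ...}} in mm.
#'
#' @param path JSON file path.
#' @return \code{readLandmarks}: a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- do.call(rbind, lst)
  rownames(pts) <- names(lst)
  landmarkSet(pts)
}

#' @rdname readLandmarks
#' @param landmarks a [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  pts <- landmarkPoints(landmarks)
  lst <- lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ]))
  names(lst) <- rownames(pts)
  jsonlite::write_json(lst, path, digits = NA)
  invisible(path)
}

#' Construct a landmark set
#' @param points numeric n x 3 matrix with rownames = landmark names.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(points) new("LandmarkSet", points = points)

## -- correspondences ---------------------------------------------------------

#' Construct / read / write correspondence sets
#'
#' On disk a correspondence set is a JSON array of
#' \code{{"source": [x,y,z], "target": [x,y,z]}} pairs (mm).
#'
#' @param source,target n x 3 matrices of paired points.
#' @return a [CorrespondenceSet-class].
#' @export
correspondenceSet <- function(source, target) {
  new("CorrespondenceSet", source = source, target = target)
}

#' @rdname correspondenceSet
#' @param path JSON file path.
#' @export
readCorrespondences <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  correspondenceSet(asMat(lst$source), asMat(lst$target))
}

#' @rdname correspondenceSet
#' @param corr a [CorrespondenceSet-class].
#' @export
writeCorrespondences <- function(corr, path) {
  src <- lapply(seq_len(nrow(corr@source)), function(i) as.numeric(corr@source[i, ]))
  tgt <- lapply(seq_len(nrow(corr@target)), function(i) as.numeric(corr@target[i, ]))
  jsonlite::write_json(list(source = src, target = tgt), path, digits = NA)
  invisible(path)
}

## -- rigid transforms --------------------------------------------------------

#' Read / write a rigid transform as JSON
#'
#' Serialized as unit quaternion \code{(qw, qx, qy, qz)} plus translation
#' (mm) with the frame names, the same convention as the pose-stream CSV.
#'
#' @param path JSON file path.
#' @return \code{readTransform}: a [RigidTransform-class].
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrixFromQuaternion(c(x$qw, x$qx, x$qy, x$qz)),
                 c(x$tx, x$ty, x$tz),
                 source = x$source_frame, target = x$target_frame)
}

#' @rdname readTransform
#' @param transform a [RigidTransform-class].
#' @param extra named list of extra scalar fields to store (e.g. an FRE).
#' @export
writeTransform <- function(transform, path, extra = list()) {
  q <- quaternionFromMatrix(transform@rotation)
  t <- transform@translation
  jsonlite::write_json(
    c(list(source_frame = transform@sourceFrame,
           target_frame = transform@targetFrame,
           qw = q[1], qx = q[2], qy = q[3], qz = q[4],
           tx = t[1], ty = t[2], tz = t[3]), extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## -- pose streams ------------------------------------------------------------

#' Read / write tracked pose streams
#'
#' CSV dialect with columns \code{time_s, frame, qw, qx, qy, qz, tx, ty, tz}
#' (quaternion + translation in mm), one row per tracked frame per sample.
#' Each row is the pose of \code{frame} expressed in the tracker frame.
#'
#' @param path CSV file path.
#' @return \code{readPoseStream}: a data.frame in the dialect above.
#' @export
readPoseStream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "frame", "qw", "qx", "qy", "qz", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("pose stream must have columns ", paste(need, collapse = ", "))
  df[order(df$time_s), , drop = FALSE]
}

#' @rdname readPoseStream
#' @param stream a pose-stream data.frame.
#' @export
writePoseStream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}
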