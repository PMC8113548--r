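# Independent pure-R oracles and shared fixtures.

# Point-segment distance (independent of the compiled kernel).
pointSegDist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

# Brute-force point-triangle distance: distance to the supporting plane if
# the foot lies inside the triangle (2D barycentric test), else the minimum
# edge-segment distance. A different algorithm from the production kernel.
cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

pointTriDist <- function(p, a, b, c) {
  n <- cross3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  dmin <- min(pointSegDist(p, a, b), pointSegDist(p, b, c),
              pointSegDist(p, c, a))
  if (nn < 1e-30) return(dmin)
  n <- n / nn
  h <- sum((p - a) * n)
  foot <- p - h * n
  # barycentric coordinates of the foot
  v0 <- b - a; v1 <- c - a; v2 <- foot - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) min(abs(h), dmin) else dmin
}

bruteForceMeshDistance <- function(p, mesh) {
  V <- vertices(mesh); F <- faces(mesh)
  min(vapply(seq_len(nrow(F)), function(f)
    pointTriDist(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ]), numeric(1)))
}

# Rectangular flat patch in the z = 0 plane, normals pointing +z.
flatPatch <- function(width = 40, n = 8, z = 0) {
  xs <- seq(-width / 2, width / 2, length.out = n + 1)
  V <- as.matrix(expand.grid(x = xs, y = xs))
  V <- cbind(V, z)
  idx <- function(i, j) (j - 1) * (n + 1) + i
  F <- NULL
  for (j in seq_len(n)) for (i in seq_len(n))
    F <- rbind(F, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  triMesh(V, F)
}

sphereMesh <- function(radius = 1, subdivisions = 2L) {
  ico <- icosphere(subdivisions)
  triMesh(radius * ico$vertices, ico$faces)
}

# Shared lesion phantom + plan (built once per test run).
.fixtures <- new.env()
sharedPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- makePhantom(phantomSpec(seed = 7))
  .fixtures$phantom
}
sharedPlan <- function() {
  if (is.null(.fixtures$plan)) {
    ph <- sharedPhantom()
    .fixtures$plan <- buildPlan(ph$mesh, fitMidsagittalPlane(ph$landmarks),
                                "right", threshold = 0.5)
  }
  .fixtures$plan
}

# Identity-chain pose stream whose drill "tip" IS the drill DRF origin,
# descending linearly in z over a flat patch.
linearApproachStream <- function(z0 = 5, z1 = 0, nSamples = 101) {
  times <- seq(0, 1, length.out = nSamples)
  z <- z0 + (z1 - z0) * times
  rbind(
    data.frame(time_s = times, frame = "DRILL_DRF", qw = 1, qx = 0, qy = 0,
               qz = 0, tx = 0, ty = 0, tz = z),
    data.frame(time_s = times, frame = "PATIENT_DRF", qw = 1, qx = 0,
               qy = 0, qz = 0, tx = 0, ty = 0, tz = 0))
}
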