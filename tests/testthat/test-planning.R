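test_that("midsagittal plane fit recovers exact and jittered planes", {
  # three midline points exactly in x = 0
  lm <- landmarkSet(rbind(a = c(0, 10, 0), b = c(0, 0, 10), c = c(0, -5, 3)))
  pl <- fitMidsagittalPlane(lm)
  expect_equal(abs(planeNormal(pl)), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(abs(planePoint(pl)[1]), 1e-9)

  # perfectly mirrored pairs give x = 0 with zero residual and a normal
  # oriented left -> right (+x)
  prs <- rbind(p_left = c(-1, 4, 2), p_right = c(1, 4, 2),
               q_left = c(-3, 0, 7), q_right = c(3, 0, 7),
               r_left = c(-2, -5, 1), r_right = c(2, -5, 1))
  pl2 <- fitMidsagittalPlane(landmarkSet(prs))
  expect_equal(planeNormal(pl2), c(1, 0, 0), tolerance = 1e-9)

  # jittered pairs on a known plane: normal within 2 degrees of truth
  set.seed(12)
  base <- cbind(runif(10, 20, 60), runif(10, -60, 60), runif(10, -40, 40))
  pts <- NULL
  for (i in 1:10) {
    pts <- rbind(pts, c(-base[i, 1], base[i, 2], base[i, 3]) + rnorm(3, sd = 0.5),
                 base[i, ] + rnorm(3, sd = 0.5))
    rownames(pts)[(2 * i - 1):(2 * i)] <- paste0("lm", i, c("_left", "_right"))
  }
  pl3 <- fitMidsagittalPlane(landmarkSet(pts))
  ang <- acos(min(1, abs(sum(planeNormal(pl3) * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 2)

  # degenerate configurations are refused
  expect_error(fitMidsagittalPlane(landmarkSet(rbind(a = c(0, 0, 0),
                                                     b = c(0, 1, 0)))),
               "insufficient")
  expect_error(fitMidsagittalPlane(
    landmarkSet(rbind(a = c(0, 0, 0), b = c(0, 1, 0), c = c(0, 2, 0)))),
    "collinear|rank")
})

test_that("plane fit is covariant under a rigid motion of all landmarks", {
  ph <- sharedPhantom()
  pl0 <- fitMidsagittalPlane(ph$landmarks)
  set.seed(31)
  T <- randomRigidTransform()
  moved <- landmarkSet({
    m <- applyTransform(T, landmarkPoints(ph$landmarks))
    rownames(m) <- landmarkNames(ph$landmarks)
    m
  })
  pl1 <- fitMidsagittalPlane(moved)
  expect_equal(planeNormal(pl1),
               as.vector(rotation(T) %*% planeNormal(pl0)),
               tolerance = 1e-9)
  # the transformed original plane point still lies on the fitted plane
  offset <- sum((applyTransform(T, planePoint(pl0)) - planePoint(pl1)) *
                  planeNormal(pl1))
  expect_lt(abs(offset), 1e-6)
})

test_that("mirroring is an involutive isometry that preserves volume", {
  ph <- sharedPhantom()
  pl <- fitMidsagittalPlane(ph$landmarks)
  m <- ph$mesh

  onplane <- planePoint(pl)
  expect_equal(reflectPoints(onplane, pl), onplane)

  mm <- mirrorAcrossPlane(m, pl)
  back <- mirrorAcrossPlane(mm, pl)
  expect_lt(max(abs(vertices(back) - vertices(m))), 1e-12)

  set.seed(4)
  idx <- sample(nVertices(m), 40)
  expect_lt(max(abs(dist(vertices(mm)[idx, ]) - dist(vertices(m)[idx, ]))),
            1e-9)
  # winding flip keeps the signed volume positive (normals stay outward)
  expect_equal(meshVolume(mm), meshVolume(m), tolerance = 1e-9)
})

test_that("a symmetric phantom yields an empty resection region", {
  healthy <- makePhantom(phantomSpec(lesionHeight = 0, subdivisions = 3L,
                                     seed = 2))
  pl <- fitMidsagittalPlane(healthy$landmarks)
  expect_warning(plan <- buildPlan(healthy$mesh, pl, "right", 0.5),
                 "no excess")
  expect_length(resectionFaces(plan), 0)
  expect_true(all(excessMap(plan) == 0))
  expect_equal(excessVolume(plan), 0)
})

test_that("a 6 mm lesion bump is recovered with the right height and footprint", {
  ph <- sharedPhantom()
  plan <- sharedPlan()
  expect_lt(abs(max(excessMap(plan)) - 6), 0.5)
  expect_true(all(excessMap(plan) >= 0))
  # excess vanishes away from the resection region
  regionVerts <- unique(as.vector(faces(plan@preop)[resectionFaces(plan), ]))
  offRegion <- setdiff(which(excessMap(plan) > 0.75), regionVerts)
  expect_lt(length(offRegion), 0.02 * length(regionVerts))
  # footprint Dice against ground-truth lesion faces
  inter <- length(intersect(ph$lesionFaces, resectionFaces(plan)))
  dice <- 2 * inter / (length(ph$lesionFaces) + length(resectionFaces(plan)))
  expect_gte(dice, 0.9)
  # the planned surface lies on or inside the pre-op surface over the region
  surg <- which(vertexLabels(plannedSurface(plan)) == "surgical_area")
  sd_ <- signedDistance(vertices(plannedSurface(plan))[surg, ], plan@preop)
  expect_lt(max(sd_), 0.3)
})

test_that("excess volume integrates a slab exactly and scales with bump height", {
  # uniform 2 mm excess over a 10 x 10 mm patch -> 200 mm^3
  patch <- flatPatch(width = 10, n = 5, z = 0)
  plan <- new("PlanModel", plannedSurface = patch, preop = patch,
              resectionFaces = seq_len(nFaces(patch)),
              sourcePlane = new("Plane"),
              excessMap = rep(2, nVertices(patch)), affectedSide = "right")
  expect_lt(abs(excessVolume(plan) - 200) / 200, 0.05)

  # halving the bump height roughly halves the excess volume
  ph6 <- sharedPhantom()
  v6 <- excessVolume(sharedPlan())
  ph3 <- makePhantom(phantomSpec(lesionHeight = 3, seed = 7))
  pl3 <- buildPlan(ph3$mesh, fitMidsagittalPlane(ph3$landmarks), "right", 0.5)
  v3 <- excessVolume(pl3)
  expect_lt(abs(v3 / v6 - 0.5), 0.15)
})

test_that("buildPlan refuses a plane that does not separate the mesh", {
  ph <- sharedPhantom()
  farPlane <- new("Plane", point = c(500, 0, 0), normal = c(1, 0, 0))
  expect_error(buildPlan(ph$mesh, farPlane, "right"), "does not separate")
})
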