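test_that("a lesion-free phantom is bilaterally symmetric", {
  ph <- makePhantom(phantomSpec(lesionHeight = 0, subdivisions = 3L,
                                seed = 1))
  m <- ph$mesh
  refl <- vertices(m)
  refl[, 1] <- -refl[, 1]
  # every reflected vertex coincides with a mesh vertex
  d <- closestPointOnMesh(refl, m)$distance
  expect_lt(max(d), 1e-9)
  expect_true(all(vertexLabels(m) == "unchanged"))
  expect_gt(meshVolume(m), 0)   # closed and outward-oriented
})

test_that("the lesion bump has the specified height", {
  ph <- sharedPhantom()           # 6 mm bump
  m <- ph$mesh
  expect_equal(max(ph$displacement), 6, tolerance = 0.05)
  # asymmetry against the mirror image is within 0.5 mm of the bump height
  pl <- new("Plane", point = c(0, 0, 0), normal = c(1, 0, 0))
  mirrored <- mirrorAcrossPlane(m, pl)
  d <- closestPointOnMesh(vertices(m), mirrored)$distance
  expect_lt(abs(max(d) - 6), 0.5)
  # lesion labels sit where the true displacement exceeds 0.5 mm
  expect_identical(vertexLabels(m) == "surgical_area", ph$displacement > 0.5)
})

test_that("phantom generation is deterministic per seed", {
  a <- makePhantom(phantomSpec(seed = 42, subdivisions = 3L))
  b <- makePhantom(phantomSpec(seed = 42, subdivisions = 3L))
  expect_identical(vertices(a$mesh), vertices(b$mesh))
  expect_identical(a$fiducials, b$fiducials)
  c_ <- makePhantom(phantomSpec(seed = 43, subdivisions = 3L))
  expect_false(identical(a$fiducials, c_$fiducials))
  expect_error(makePhantom(phantomSpec(subdivisions = 2L)), "coarse")
})

test_that("landmarks are exactly midline or exactly mirrored", {
  ph <- sharedPhantom()
  pts <- landmarkPoints(ph$landmarks)
  mid <- pts[!grepl("_left$|_right$", rownames(pts)), ]
  expect_true(all(mid[, 1] == 0))
  lefts <- pts[grepl("_left$", rownames(pts)), ]
  rights <- pts[grepl("_right$", rownames(pts)), ]
  expect_equal(unname(lefts[, 1]), unname(-rights[, 1]))
  expect_equal(unname(lefts[, 2:3]), unname(rights[, 2:3]))
})

test_that("zero residual and zero noise reproduce the plan exactly", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan, residualMean = 0,
                            residualSd = 0,
                            noise = list(transSd = 0, rotSd = 0, fidSd = 0),
                            nSamples = 30L, seed = 2)
  # the post-op surgical region coincides with the planned surface
  postPlan <- proc@groundTruth$postopInPlanSpace
  rv <- proc@groundTruth$regionVertices
  d <- closestPointOnMesh(vertices(postPlan)[rv, ], plannedSurface(plan))$distance
  expect_lt(max(d), 1e-9)
  # and the evaluation pipeline reports near-zero deviations
  rep <- evaluateProcedure(plan, proc, n = 200, seed = 8)
  expect_lt(deviationSummary(rep)["mean"], 0.05)
})

test_that("pose noise has the requested statistics and leaves input untouched", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan,
                            noise = list(transSd = 0, rotSd = 0, fidSd = 0),
                            nSamples = 5000L, seed = 3)
  clean <- proc@groundTruth$cleanStream
  # sd 0 returns the identical stream
  expect_identical(addPoseNoise(clean, 0, 0), clean)
  noisy <- addPoseNoise(clean, transSd = 0.3, rotSd = 0, seed = 11)
  resid <- c(noisy$tx - clean$tx, noisy$ty - clean$ty, noisy$tz - clean$tz)
  expect_lt(abs(sd(resid) / 0.3 - 1), 0.05)   # n = 30,000 draws
  expect_lt(abs(mean(resid)), 0.01)
  # different seeds, different streams, same statistics
  noisy2 <- addPoseNoise(clean, transSd = 0.3, rotSd = 0, seed = 12)
  expect_false(identical(noisy$tx, noisy2$tx))
  resid2 <- c(noisy2$tx - clean$tx, noisy2$ty - clean$ty,
              noisy2$tz - clean$tz)
  expect_lt(abs(sd(resid2) / 0.3 - 1), 0.05)
})

test_that("one seed fixes the whole simulated procedure", {
  plan <- sharedPlan()
  a <- simulateProcedure(sharedPhantom(), plan, nSamples = 40L, seed = 19)
  b <- simulateProcedure(sharedPhantom(), plan, nSamples = 40L, seed = 19)
  expect_identical(vertices(a@postop), vertices(b@postop))
  expect_identical(a@poseStream, b@poseStream)
  expect_identical(targetPoints(a@unchangedCorrespondences),
                   targetPoints(b@unchangedCorrespondences))
})
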