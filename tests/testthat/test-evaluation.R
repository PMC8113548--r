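test_that("deviation statistics match hand computations", {
  # all-zero distances
  P <- matrix(runif(9, -5, 5), ncol = 3)
  rep0 <- deviationStats(correspondenceSet(P, P), case = "zero")
  s0 <- deviationSummary(rep0)
  expect_equal(unname(s0[c("min", "max", "mean", "sd")]), c(0, 0, 0, 0))

  # distances {1, 2, 3}: mean 2, population sd sqrt(2/3)
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  tgt <- src + cbind(c(1, 2, 3), 0, 0)
  rep1 <- deviationStats(correspondenceSet(src, tgt), case = "hand")
  s1 <- deviationSummary(rep1)
  expect_equal(unname(s1["min"]), 1)
  expect_equal(unname(s1["max"]), 3)
  expect_equal(unname(s1["mean"]), 2)
  expect_equal(unname(s1["sd"]), 0.8165, tolerance = 1e-4)

  # permutation invariance
  perm <- c(3, 1, 2)
  rep2 <- deviationStats(correspondenceSet(src[perm, ], tgt[perm, ]))
  expect_equal(sort(distances(rep2)), sort(distances(rep1)))
  expect_equal(deviationSummary(rep2)[c("min", "max", "mean", "sd")],
               s1[c("min", "max", "mean", "sd")])
})

test_that("cross-case aggregation uses the population-SD convention", {
  agg <- aggregateCases(c(1.277, 1.218, 1.525, 1.861, 1.326))
  expect_equal(grandMean(agg), mean(c(1.277, 1.218, 1.525, 1.861, 1.326)))
  expect_equal(round(grandSD(agg), 3), 0.234)
  # the sample-SD convention would NOT reproduce the published aggregate
  expect_equal(round(sd(c(1.277, 1.218, 1.525, 1.861, 1.326)), 3), 0.261)

  expect_equal(grandSD(aggregateCases(2.2)), 0)
  expect_equal(grandSD(aggregateCases(rep(1.3, 4))), 0)
  expect_equal(grandMean(aggregateCases(rep(1.3, 4))), 1.3)
  expect_error(aggregateCases(numeric(0)), "no cases")
})

test_that("paired points across parallel planes all measure the gap", {
  planned <- flatPatch(width = 20, n = 6, z = 0)
  postop <- flatPatch(width = 30, n = 6, z = 0.7)
  pairs <- samplePairedPoints(planned, postop, n = 200, seed = 3)
  expect_equal(attr(pairs, "nMissed"), 0)
  d <- distances(deviationStats(pairs))
  expect_lt(max(abs(d - 0.7)), 1e-9)
  # identical surfaces give identically zero distances
  same <- samplePairedPoints(planned, planned, n = 100, seed = 3)
  expect_lt(max(distances(deviationStats(same))), 1e-9)
  # misses beyond the cutoff are counted and warned about
  far <- flatPatch(width = 30, n = 6, z = 50)
  expect_warning(expect_error(
    samplePairedPoints(planned, far, n = 50, seed = 3, cutoff = 10),
    "no paired points"), NA)
})

test_that("post-op alignment recovers displacements from unchanged regions", {
  ph <- sharedPhantom()
  plan <- sharedPlan()
  mesh <- plan@preop
  # identical meshes, exact fiducials: identity within 1e-9
  corr <- correspondenceSet(ph$fiducials, ph$fiducials)
  T0 <- alignPostop(mesh, mesh, corr)
  expect_lt(max(abs(rotation(T0) - diag(3))), 1e-9)
  expect_lt(max(abs(translation(T0))), 1e-9)

  # known rigid motion, 6 unchanged-region pairs
  set.seed(40)
  Ttrue <- randomRigidTransform(maxTranslation = 20, source = "plan",
                                target = "postop")
  moved <- transformMesh(mesh, Ttrue)
  corr2 <- correspondenceSet(ph$fiducials, applyTransform(Ttrue, ph$fiducials))
  T1 <- alignPostop(moved, mesh, corr2)
  expect_lt(max(abs(rotation(T1) - rotation(Ttrue))), 1e-6)
  expect_lt(max(abs(translation(T1) - translation(Ttrue))), 1e-6)

  # surgical-area change does not disturb the unchanged-region alignment
  proc <- simulateProcedure(ph, plan,
                            noise = list(transSd = 0, rotSd = 0, fidSd = 0),
                            nSamples = 40L, seed = 23)
  T2 <- alignPostop(proc@postop, mesh, proc@unchangedCorrespondences,
                    refine = TRUE)
  E <- composeTransforms(T2,
                         invertTransform(proc@groundTruth$planToPostop))
  unchangedIdx <- which(vertexLabels(mesh) == "unchanged")
  pts <- vertices(mesh)[unchangedIdx[1:100], ]
  expect_lt(max(sqrt(rowSums((applyTransform(E, pts) - pts)^2))), 0.05)

  # correspondences on the surgical area trigger a warning
  surg <- vertices(mesh)[which(vertexLabels(mesh) == "surgical_area")[1:6], ]
  expect_warning(alignPostop(mesh, mesh, correspondenceSet(surg, surg)),
                 "surgical area")
})

test_that("reports are invariant under a common rigid motion of both meshes", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan, seed = 6)
  # refine = FALSE keeps the alignment a pure Kabsch fit, which conjugates
  # exactly under a rigid motion of the post-op space
  rep1 <- evaluateProcedure(plan, proc, n = 300, seed = 50, refine = FALSE)

  set.seed(60)
  T <- randomRigidTransform(source = "postop", target = "postop2")
  proc2 <- proc
  proc2@postop <- transformMesh(proc@postop, T)
  proc2@unchangedCorrespondences <- correspondenceSet(
    sourcePoints(proc@unchangedCorrespondences),
    applyTransform(T, targetPoints(proc@unchangedCorrespondences)))
  rep2 <- evaluateProcedure(plan, proc2, n = 300, seed = 50, refine = FALSE)
  s1 <- deviationSummary(rep1)
  s2 <- deviationSummary(rep2)
  expect_equal(unname(s2["mean"]), unname(s1["mean"]), tolerance = 1e-6)
  expect_equal(unname(s2["sd"]), unname(s1["sd"]), tolerance = 1e-6)
})

test_that("doubling the sample size leaves the mean stable", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan, seed = 14)
  repA <- evaluateProcedure(plan, proc, n = 250, seed = 71)
  repB <- evaluateProcedure(plan, proc, n = 500, seed = 72)
  sA <- deviationSummary(repA)
  sB <- deviationSummary(repB)
  se <- sA["sd"] / sqrt(sA["n"])
  expect_lt(abs(sA["mean"] - sB["mean"]), 2 * (se + sB["sd"] / sqrt(sB["n"])))
})

test_that("deviation reports serialize and the heatmap export runs", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan, seed = 3)
  rep <- evaluateProcedure(plan, proc, n = 200, seed = 31)
  js <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  writeDeviationReport(rep, js, csv)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  s <- deviationSummary(rep)
  expect_equal(got$mean_mm, unname(s["mean"]))
  expect_equal(nrow(read.csv(csv)), unname(s["n"]))
  ply <- tempfile(fileext = ".ply")
  d <- exportDeviationHeatmap(plannedSurface(plan), plan@preop, ply)
  expect_true(file.exists(ply))
  expect_length(d, nVertices(plannedSurface(plan)))
})
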