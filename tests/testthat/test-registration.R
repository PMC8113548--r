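test_that("paired-point registration recovers exact correspondences", {
  set.seed(8)
  P <- matrix(runif(30, -60, 60), ncol = 3)
  # identical clouds give the identity with zero FRE
  fit0 <- pairedPointRegister(correspondenceSet(P, P))
  expect_lt(max(abs(rotation(fit0$transform) - diag(3))), 1e-12)
  expect_lt(fit0$fre, 1e-12)
  # known rigid motion, 10 points, exact recovery
  T <- randomRigidTransform()
  fit <- pairedPointRegister(correspondenceSet(P, applyTransform(T, P)))
  expect_lt(max(abs(rotation(fit$transform) - rotation(T))), 1e-9)
  expect_lt(max(abs(translation(fit$transform) - translation(T))), 1e-9)
  expect_lt(fit$fre, 1e-9)
})

test_that("noisy correspondences give a bounded FRE and accurate rotation", {
  set.seed(21)
  P <- matrix(runif(24, -60, 60), ncol = 3)   # n = 8
  T <- randomRigidTransform()
  Q <- applyTransform(T, P) + matrix(rnorm(24, sd = 0.3), ncol = 3)
  fit <- pairedPointRegister(correspondenceSet(P, Q))
  expect_gt(fit$fre, 0.15)
  expect_lt(fit$fre, 0.6)
  rotErr <- rotationAngle(t(rotation(T)) %*% rotation(fit$transform))
  expect_lt(rotErr * 180 / pi, 1)
})

test_that("the Kabsch fit is optimal and equivariant", {
  set.seed(13)
  P <- matrix(runif(36, -50, 50), ncol = 3)
  T <- randomRigidTransform()
  Q <- applyTransform(T, P) + matrix(rnorm(36, sd = 0.5), ncol = 3)
  corr <- correspondenceSet(P, Q)
  fit <- pairedPointRegister(corr)
  # no random rigid candidate beats the closed-form optimum
  for (k in 1:50) {
    cand <- randomRigidTransform()
    freCand <- sqrt(mean(rowSums((applyTransform(cand, P) - Q)^2)))
    expect_gte(freCand, fit$fre - 1e-12)
  }
  # pre-rotating both clouds conjugates the solution, same FRE
  Rot <- rigidTransform(rotationAboutY(0.7), c(0, 0, 0))
  fit2 <- pairedPointRegister(
    correspondenceSet(applyTransform(Rot, P), applyTransform(Rot, Q)))
  expect_equal(fit2$fre, fit$fre, tolerance = 1e-9)
  expect_lt(max(abs(rotation(fit2$transform) -
                      rotation(Rot) %*% rotation(fit$transform) %*%
                        t(rotation(Rot)))), 1e-9)
})

test_that("collinear source points are rejected", {
  P <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(pairedPointRegister(correspondenceSet(P, P)), "collinear")
})

test_that("ICP converges on sampled points and recovers a 5 mm / 5 deg motion", {
  ph <- sharedPhantom()
  mesh <- ph$mesh
  set.seed(77)
  src <- vertices(mesh)[sample(nVertices(mesh), 250), ]
  # source sampled from the target, identity start: RMS collapses
  fit0 <- icpRefine(src, mesh)
  expect_lt(fit0$rms, 1e-6)
  # known 5 mm / 5 degree displacement
  axis <- rnorm(3)
  Ttrue <- rigidTransform(rotationAxisAngle(axis, 5 * pi / 180),
                          c(3, -3, 2.5), "source", "target")  # |t| ~ 5 mm
  moved <- applyTransform(invertTransform(Ttrue), src)
  fit <- icpRefine(moved, mesh, maxIter = 300L)
  E <- composeTransforms(fit$transform, invertTransform(Ttrue))
  expect_lt(rotationAngle(rotation(E)) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(translation(E)^2)), 0.1)
  # RMS history is monotone non-increasing
  expect_true(all(diff(fit$rmsHistory) <= 1e-12))
  expect_true(all(diff(fit0$rmsHistory) <= 1e-12))
})

test_that("frame resolution composes, inverts and interpolates correctly", {
  g <- frameGraph()
  g <- addStaticEdge(g, rigidTransform(rotationAboutZ(0.3), c(1, 2, 3),
                                       "PATIENT_DRF", "IMAGE"))
  tr <- poseTrack("DRILL_DRF", "TRACKER", c(0, 1),
                  rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                  rbind(c(0, 0, 0), c(0, 0, 10)))
  g <- addTrackedEdge(g, tr)
  g <- addStaticEdge(g, rigidTransform(diag(3), c(5, 0, 0),
                                       "PATIENT_DRF", "TRACKER"))

  expect_equal(rotation(resolveFrames(g, "TRACKER", "TRACKER")), diag(3))

  # path symmetry: resolve(a, b) == invert(resolve(b, a))
  Tab <- resolveFrames(g, "DRILL_DRF", "IMAGE", at = 0.25)
  Tba <- resolveFrames(g, "IMAGE", "DRILL_DRF", at = 0.25)
  E <- composeTransforms(Tab, Tba)
  expect_lt(max(abs(rotation(E) - diag(3))), 1e-12)
  expect_lt(max(abs(translation(E))), 1e-9)

  # linear interpolation midway between two translations
  Tmid <- resolveFrames(g, "DRILL_DRF", "TRACKER", at = 0.5)
  expect_equal(translation(Tmid), c(0, 0, 5))
  expect_error(resolveFrames(g, "DRILL_DRF", "TRACKER", at = 2),
               "outside")
  g2 <- frameGraph(c("A", "B"))
  expect_error(resolveFrames(g2, "A", "B"), "not connected")
})

test_that("the drill tip maps through the full frame chain exactly", {
  # all edges identity: the tip offset is the image-space position
  g <- frameGraph()
  g <- addStaticEdge(g, identityTransform("PATIENT_DRF", "IMAGE"))
  tr <- poseTrack("DRILL_DRF", "TRACKER", c(0, 1),
                  rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                  rbind(c(0, 0, 0), c(0, 0, 0)))
  g <- addTrackedEdge(g, tr)
  g <- addStaticEdge(g, identityTransform("PATIENT_DRF", "TRACKER"))
  expect_equal(drillTipInImage(g, tipCalibration(c(0, 0, 100)), 0.5),
               c(0, 0, 100))

  # simulator ground truth is reproduced exactly in the noise-free limit
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan,
                            noise = list(transSd = 0, rotSd = 0, fidSd = 0),
                            nSamples = 60L, seed = 5)
  gt <- proc@groundTruth
  run <- processPoseStream(proc@poseStream, plan, gt$patientToImage,
                           tipCalibration(gt$tipOffset))
  expect_lt(max(abs(as.matrix(run$samples[, c("tip_x", "tip_y", "tip_z")]) -
                      gt$tipTrajectoryImage)), 1e-9)
})

test_that("tip error under tracking noise matches first-order propagation", {
  plan <- sharedPlan()
  proc <- simulateProcedure(sharedPhantom(), plan,
                            noise = list(transSd = 0.2, rotSd = 0,
                                         fidSd = 0),
                            nSamples = 1000L, seed = 17)
  gt <- proc@groundTruth
  run <- processPoseStream(proc@poseStream, plan, gt$patientToImage,
                           tipCalibration(gt$tipOffset))
  err <- as.matrix(run$samples[, c("tip_x", "tip_y", "tip_z")]) -
    gt$tipTrajectoryImage
  rms <- sqrt(mean(rowSums(err^2)))
  expect_gt(rms, 0.1)
  expect_lt(rms, 0.8)
})
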