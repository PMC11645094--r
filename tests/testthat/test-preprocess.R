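test_that("GRF/CoP derivation: symmetry, statics and moment balance", {
  # equal constant corner forces: GRF = 4F/m, CoP pinned at the centre
  F <- matrix(170, 50, 4)
  out <- deriveGrfCop(F, mass = 68.2, subtractInitial = FALSE)
  expect_equal(unname(out[, "grf_norm"]), rep(4 * 170 / 68.2, 50))
  expect_equal(max(abs(out[, c("cop_x", "cop_y")])), 0)

  # static stand at body weight: grf_norm ~ g within 1%
  r <- generateRepetition(testParticipant(), "Squat", 0, seed = 3,
                          rotations = identityRotations(), noise = FALSE)
  out <- deriveGrfCop(r@boardForces, 68.2)
  expect_equal(unname(out[1, "grf_norm"]), 9.80665, tolerance = 0.01)
  expect_equal(unname(out[1, c("cop_x", "cop_y")]), c(0, 0))

  # all weight on the right-side sensors: mediolateral CoP at +half spacing
  Fr <- cbind(0, matrix(300, 20, 1), 0, matrix(300, 20, 1))  # FR, BR loaded
  out <- deriveGrfCop(Fr, 61.2, boardDims = c(0.433, 0.238),
                      subtractInitial = FALSE)
  expect_equal(unname(out[, "cop_y"]), rep(0.433 / 2, 20))
  expect_equal(max(abs(out[, "cop_x"])), 0)

  expect_error(deriveGrfCop(matrix(1, 30, 4), 70), "unloaded board")
  expect_error(deriveGrfCop(F, mass = 0), "mass")
})

test_that("T-pose calibration recovers tilt misalignments", {
  rot <- fatlat:::sessionMisalignments(42)
  tp <- fatlat:::generateTpose(rot, seed = 5)
  for (s in 1:3) {
    Rhat <- estimateTposeRotation(tp, sensor = s)
    expect_equal(det(Rhat), 1, tolerance = 1e-9)
    expect_equal(crossprod(Rhat), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # rotated mean acceleration aligns with the world vertical (< 2 deg)
    g <- Rhat %*% colMeans(tp[, (s - 1) * 6 + (1:3)])
    ang <- acos(g[3] / sqrt(sum(g^2))) * 180 / pi
    expect_lt(ang, 2)
    # and the estimate inverts the true tilt
    err <- Rhat %*% t(solve(rot[[s]]))
    expect_equal(err %*% t(err), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  }

  # already world-aligned sensor: identity within tolerance
  tpId <- fatlat:::generateTpose(identityRotations(), seed = 6)
  Rhat <- estimateTposeRotation(tpId, sensor = 2)
  expect_equal(Rhat, diag(3), tolerance = 0.02)

  # a 90-degree tilt about a horizontal axis is recovered exactly
  R90 <- fatlat:::rotationAboutAxis(c(1, 0, 0), pi / 2)
  tp90 <- fatlat:::generateTpose(list(R90, diag(3), diag(3)), seed = 7)
  Rhat <- estimateTposeRotation(tp90, sensor = 1)
  g <- Rhat %*% colMeans(tp90[, 1:3])
  expect_equal(as.vector(g), c(0, 0, 9.80665), tolerance = 0.02)

  # moving window rejected
  bad <- tp
  bad[, 4:6] <- bad[, 4:6] + 1
  expect_error(estimateTposeRotation(bad, sensor = 1), "non-static")
  expect_error(estimateTposeRotation(tp[1:10, 1:6]), "too short")
})

test_that("gravity removal and height normalization", {
  static <- matrix(rep(c(0, 0, 9.80665), each = 40), 40, 3)
  expect_equal(max(abs(removeGravityNormalize(static, 1.75))), 0)

  a <- sin(seq(0, 4 * pi, length.out = 40))
  acc <- static; acc[, 3] <- acc[, 3] + a
  out <- removeGravityNormalize(acc, 1.75)
  expect_equal(out[, 3], a / 1.75)
  out2 <- removeGravityNormalize(acc, 3.5)
  expect_equal(out2[, 3], out[, 3] / 2)
  expect_error(removeGravityNormalize(acc, 0), "height")
})

test_that("zero-phase Butterworth: DC gain, cutoff attenuation, idempotence", {
  expect_equal(lowpassFilter(rep(3, 200), fs = 60), rep(3, 200),
               tolerance = 1e-9)

  t <- seq(0, 20, by = 1 / 60)
  mid <- 400:800
  x15 <- sin(2 * pi * 15 * t)
  ratio15 <- max(abs(lowpassFilter(x15, fs = 60)[mid]))
  expect_equal(ratio15, 0.5, tolerance = 0.02)

  x25 <- sin(2 * pi * 25 * t)
  expect_lt(max(abs(lowpassFilter(x25, fs = 60)[mid])), 0.05)

  # pass band idempotence: refiltering a 1 Hz tone changes it < 0.5%
  x1 <- sin(2 * pi * 1 * t)
  f1 <- lowpassFilter(x1, fs = 60)
  f2 <- lowpassFilter(f1, fs = 60)
  expect_lt(max(abs(f2[mid] - f1[mid])) / max(abs(f1[mid])), 0.005)

  expect_error(lowpassFilter(x15, fs = 30), "Nyquist")
  expect_error(lowpassFilter(rep(1, 10), fs = 60), "too short")
})

test_that("segmentation contracts on constructed streams", {
  expect_equal(nrow(segmentRepetitions(rep(0, 600))), 0)

  burst <- c(rep(0, 120), rep(2, 90), rep(0, 120))
  iv <- segmentRepetitions(burst, fs = 60, threshold = 0.5)
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv[1, "start"] - 120), 10)

  # two bursts separated by less than the quiet gap merge into one
  two <- c(rep(0, 120), rep(2, 60), rep(0, 24), rep(2, 60), rep(0, 120))
  expect_equal(nrow(segmentRepetitions(two, fs = 60, threshold = 0.5,
                                       minQuietGap = 0.6, smoothWindow = 0.1)), 1)
  expect_equal(nrow(segmentRepetitions(two, fs = 60, threshold = 0.5,
                                       minQuietGap = 0.2, smoothWindow = 0.1)), 2)
})

test_that("cubic-spline resampling to the 192-frame grid", {
  t60 <- seq(0, 2, by = 1 / 60)
  ramp <- 3 * t60 - 1
  out <- resampleRepetition(t60, ramp)
  expect_equal(nrow(out), 192)
  grid <- seq(0, 2, length.out = 192)
  expect_lt(max(abs(out[, 1] - (3 * grid - 1))), 1e-9)
  expect_equal(out[1, 1], ramp[1])            # endpoints preserved
  expect_equal(out[192, 1], ramp[length(ramp)])

  s <- sin(2 * pi * t60)
  out <- resampleRepetition(t60, s)
  expect_lt(max(abs(out[, 1] - sin(2 * pi * grid))), 1e-4)

  # 30 Hz and 60 Hz channels land on one shared grid
  t30 <- seq(0, 2, by = 1 / 30)
  o30 <- resampleRepetition(t30, sin(2 * pi * t30), span = c(0, 2))
  o60 <- resampleRepetition(t60, sin(2 * pi * t60), span = c(0, 2))
  expect_lt(max(abs(o30 - o60)), 2e-3)

  expect_error(resampleRepetition(1:3, c(1, 2, 3)), ">= 4 samples")
})

test_that("per-type standardization: pooled moments, hand oracle, inverse", {
  coh <- smallCohortA()
  se <- assembleDataset(coh, "DB2")
  ids <- participants(coh)$id
  st <- computeStandardization(se, ids, fold = "0")
  seStd <- standardizeDataset(se, st)

  types <- S4Vectors::metadata(se)$channelTypes
  for (tp in unique(types)) {
    vals <- unlist(lapply(names(types)[types == tp],
                          function(ch) assay(seStd, ch)))
    expect_equal(mean(vals), 0, tolerance = 1e-10)
    expect_equal(sd(vals), 1, tolerance = 1e-10)
  }

  # hand-computed oracle on 5 values of a held-out channel
  x5 <- assay(se, "grf_norm")[1:5, 1]
  z5 <- assay(seStd, "grf_norm")[1:5, 1]
  expect_equal(z5, (x5 - st@mu[["grf"]]) / st@sigma[["grf"]], tolerance = 1e-12)

  # x == mu everywhere maps to zero
  expect_equal((st@mu[["acc"]] - st@mu[["acc"]]) / st@sigma[["acc"]], 0)

  # inverse transform restores the input exactly
  back <- unstandardizeDataset(seStd, st)
  expect_equal(assay(back, "cop_x"), assay(se, "cop_x"), tolerance = 1e-12)

  # standardizing twice is refused; degenerate sigma is named
  expect_error(computeStandardization(seStd, ids), "already standardized")
})

test_that("dataset assembly: variant channel counts, labels, CoP zeroing", {
  coh <- smallCohortA()
  counts <- c(DB0 = 3, DB1 = 9, DB2 = 21, DB3 = 6, DB4 = 18)
  for (db in names(counts)) {
    se <- assembleDataset(coh, db, participantIds = "A01")
    expect_equal(length(SummarizedExperiment::assayNames(se)),
                 unname(counts[db]))
    expect_equal(ncol(se), 40)          # 4 exercises x 1 set x 10 reps
    expect_equal(nrow(se), 192)
  }

  se <- assembleDataset(coh, "DB0")
  expect_equal(ncol(se), 80)            # 2 participants
  Y <- oneHotLabels(se)
  expect_true(all(rowSums(Y) == 1))
  sq <- colData(se)$exercise == "Squat"
  expect_true(all(Y[sq, "Squat"] == 1))
  expect_equal(colnames(Y), c("Squat", "LungeLeft", "LungeRight", "PlankJumpIn"))

  # CoP channels start at exactly (0, 0) for every repetition
  expect_equal(max(abs(assay(se, "cop_x")[1, ])), 0)
  expect_equal(max(abs(assay(se, "cop_y")[1, ])), 0)
})
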