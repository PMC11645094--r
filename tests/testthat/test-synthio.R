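test_that("cohort generation counts, determinism and config validation", {
  cfg <- cohortConfig(nGroupA = 0, nGroupB = 1, setsRange = c(3, 3))
  coh <- generateCohort(cfg, seed = 7)
  # 3 sets x 10 reps x 4 exercises
  expect_equal(nrow(cohortManifest(coh)@index), 120)
  expect_true(all(table(cohortManifest(coh)@index$rep) == 12))

  coh2 <- generateCohort(cfg, seed = 7)
  r1 <- getRepetition(coh, "B01", "Squat", 1, 3)
  r2 <- getRepetition(coh2, "B01", "Squat", 1, 3)
  expect_identical(r1@imu, r2@imu)
  expect_identical(r1@boardForces, r2@boardForces)

  expect_error(cohortConfig(nGroupA = 0, nGroupB = 0), "at least one")
  expect_error(cohortConfig(nGroupB = 1, setsRange = c(0, 0)), ">= 2")
  expect_error(fatigueProfile(amplitudeDrift = -0.1), ">= 0")
})

test_that("written cohorts round-trip losslessly and are byte-identical", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- cohortConfig(nGroupA = 1, nGroupB = 0)
  generateCohort(cfg, seed = 5, dir = dir1)
  generateCohort(cfg, seed = 5, dir = dir2)
  f1 <- file.path(dir1, "data/A01/Squat/set0_rep0.csv")
  expect_identical(readLines(f1),
                   readLines(file.path(dir2, "data/A01/Squat/set0_rep0.csv")))

  back <- readCohort(dir1)
  orig <- generateCohort(cfg, seed = 5)
  rr <- getRepetition(back, "A01", "Squat", 0, 0)
  expect_equal(rr@imu, getRepetition(orig, "A01", "Squat", 0, 0)@imu,
               tolerance = 1e-12)
  expect_equal(rr@boardForces,
               getRepetition(orig, "A01", "Squat", 0, 0)@boardForces,
               tolerance = 1e-12)
})

test_that("manifest errors are specific: missing file, duplicate key", {
  dir <- withr::local_tempdir()
  generateCohort(cohortConfig(nGroupA = 1, nGroupB = 0), seed = 5, dir = dir)
  unlink(file.path(dir, "data/A01/LungeLeft/set0_rep2.csv"))
  err <- tryCatch(readCohort(dir), error = identity)
  expect_s3_class(err, "fatlat_missing_file")
  expect_match(conditionMessage(err), "A01/LungeLeft/0/2")

  # duplicate key in the manifest index
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  mf$index <- rbind(mf$index, mf$index[1, ])
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  err <- tryCatch(readCohort(dir), error = identity)
  expect_s3_class(err, "fatlat_schema")
  expect_match(conditionMessage(err), "duplicate")
})

test_that("templates obey physics: force balance, mirror symmetry, scaling", {
  p <- testParticipant()
  idr <- identityRotations()

  # standing phase: corner forces sum to body weight (noise off, 1%)
  r <- generateRepetition(p, "Squat", 0, seed = 3, rotations = idr,
                          noise = FALSE)
  expect_equal(sum(r@boardForces[1, ]), 68.2 * 9.80665, tolerance = 0.01)
  expect_true(all(r@boardForces >= 0))

  # lunge left = lunge right with the mediolateral axis negated
  rl <- generateRepetition(p, "LungeLeft", 0, seed = 3, rotations = idr,
                           noise = FALSE)
  rr <- generateRepetition(p, "LungeRight", 0, seed = 3, rotations = idr,
                           noise = FALSE)
  mir <- fatlat:::mirrorImuColumns()
  expect_equal(rl@imu[, mir], -rr@imu[, mir], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rl@imu[, -mir], rr@imu[, -mir], tolerance = 1e-12,
               ignore_attr = TRUE)
  gl <- deriveGrfCop(rl@boardForces, 68.2, subtractInitial = FALSE)
  gr <- deriveGrfCop(rr@boardForces, 68.2, subtractInitial = FALSE)
  expect_equal(gl[, "cop_y"], -gr[, "cop_y"], tolerance = 1e-12)
  expect_equal(gl[, "cop_x"], gr[, "cop_x"], tolerance = 1e-12)

  # amplitude drift parameterization: peak dynamic amplitude ratio 1 + drift
  prof <- fatigueProfile(amplitudeDrift = 0.2, noiseGrowth = 0,
                         timingJitter = 0, swayGrowth = 0, tremorGain = 0)
  r0 <- generateRepetition(p, "Squat", 0, seed = 3, profile = prof,
                           rotations = idr, noise = FALSE)
  r1 <- generateRepetition(p, "Squat", 1, seed = 3, profile = prof,
                           rotations = idr, noise = FALSE)
  amp0 <- max(abs(r0@imu[, 1]))
  amp1 <- max(abs(r1@imu[, 1]))
  expect_equal(amp1 / amp0, 1.2, tolerance = 1e-9)

  expect_error(generateRepetition(p, "Burpee", 0, seed = 1), "unknown exercise")
  expect_error(generateRepetition(p, "Squat", 1.5, seed = 1), "fatigueFraction")
})

test_that("null fatigue profile yields exchangeable sets; injected drift is monotone", {
  p <- testParticipant()
  idr <- identityRotations()

  # null model: per-channel mean absolute amplitude comparable across sets
  nullSetStat <- function(setSeed) {
    reps <- lapply(1:10, function(i) {
      generateRepetition(p, "Squat", 0, seed = setSeed * 100 + i,
                         profile = nullFatigueProfile(), rotations = idr)
    })
    mean(vapply(reps, function(r) mean(abs(r@imu[, 1])), numeric(1)))
  }
  stats <- vapply(1:6, nullSetStat, numeric(1))
  expect_lt(diff(range(stats)) / mean(stats), 0.08)

  # sway growth alone -> CoP dispersion grows with fatigue fraction
  prof <- fatigueProfile(amplitudeDrift = 0, noiseGrowth = 0,
                         timingJitter = 0, swayGrowth = 3, tremorGain = 0)
  copSD <- vapply(c(0, 0.5, 1), function(phi) {
    disp <- vapply(1:8, function(i) {
      r <- generateRepetition(p, "Squat", phi, seed = 400 + i,
                              profile = prof, rotations = idr)
      gc <- deriveGrfCop(r@boardForces, 68.2)
      sd(gc[, "cop_y"])
    }, numeric(1))
    mean(disp)
  }, numeric(1))
  expect_true(all(diff(copSD) > 0))

  # tremor is confined to 8-12 Hz: it must survive the 15 Hz low-pass
  proft <- fatigueProfile(amplitudeDrift = 0, noiseGrowth = 0,
                          timingJitter = 0, swayGrowth = 0, tremorGain = 2)
  r0 <- generateRepetition(p, "Squat", 0, seed = 9, profile = proft,
                           rotations = idr)
  r1 <- generateRepetition(p, "Squat", 1, seed = 9, profile = proft,
                           rotations = idr)
  hp <- function(x) {
    f <- lowpassFilter(x, fs = 60)      # tremor band passes the filter
    sp <- Mod(fft(f))[seq_along(f)]
    frq <- (seq_along(f) - 1) * 60 / length(f)
    sum(sp[frq >= 8 & frq <= 12])
  }
  expect_gt(hp(r1@imu[, 1]), 2 * hp(r0@imu[, 1]))
})

test_that("concatenated streams carry recoverable repetition supports", {
  p <- testParticipant()
  reps <- lapply(1:10, function(i) {
    generateRepetition(p, "Squat", 0, seed = 600 + i,
                       rotations = identityRotations())
  })
  cc <- concatenateRepetitions(reps, seed = 4)
  iv <- segmentRepetitions(cc$stream, fs = cc$fs, threshold = 0.5)
  expect_equal(nrow(iv), 10)
  expect_true(all(abs(iv[, "start"] - cc$intervals[, "start"]) <= 3 |
                  iv[, "start"] >= cc$intervals[, "start"]))
  # every detected interval sits inside (a slightly padded) true support
  pad <- 5
  expect_true(all(iv[, "start"] >= cc$intervals[, "start"] - pad))
  expect_true(all(iv[, "end"] <= cc$intervals[, "end"] + pad))
})
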