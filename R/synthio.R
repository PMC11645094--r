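# Synthetic cohort generator and cohort file format.
#
# The generator emulates the statistical structure of an exhaustion protocol:
# four lower-body exercises recorded by a balance board (4 vertical corner
# forces, 30 Hz) and three IMUs (hip + both forearms, 3-axis accelerometer +
# 3-axis gyroscope, 60 Hz), performed in sets of 10 repetitions by a
# non-fatigued group (A) and a repeated-sets-to-exhaustion group (B).
# Activity-specific waveforms are sums of low-frequency harmonics under a
# smooth envelope; participants carry random amplitude/duration effects, and
# a FatigueProfile injects parametric drift as the fatigue fraction grows.

#' Canonical IMU channel names
#'
#' 18 channels: for each sensor (hip, lfa = left forearm, rfa = right
#' forearm), 3-axis acceleration then 3-axis angular velocity.  World axes:
#' x anteroposterior (+forward), y mediolateral (+right), z up.
#'
#' @return character vector of length 18.
#' @export
imuChannelNames <- function() {
  sensors <- c("hip", "lfa", "rfa")
  as.vector(vapply(sensors, function(s) {
    c(paste0(s, "_acc_", c("x", "y", "z")),
      paste0(s, "_gyr_", c("x", "y", "z")))
  }, character(6)))
}

#' @rdname imuChannelNames
#' @export
boardChannelNames <- function() c("force_FL", "force_FR", "force_BL", "force_BR")

# Column indices of mediolateral-sensitive IMU channels: acc_y and the
# angular velocities about the horizontal axes x and z.  Negating these (plus
# CoP_y) mirrors a movement about the sagittal plane.
mirrorImuColumns <- function() {
  base <- c(2L, 4L, 6L)  # acc_y, gyr_x, gyr_z within one sensor block
  as.vector(outer(base, c(0L, 6L, 12L), `+`))
}

BASE_DURATION <- c(Squat = 2.0, LungeLeft = 2.0, LungeRight = 2.0,
                   PlankJumpIn = 1.5)

# Deterministic harmonic template for the 18 IMU channels of one exercise.
# Amplitudes/phases are drawn once from a fixed per-exercise seed so each
# exercise has a distinct spectrum and asymmetry; LungeLeft is never drawn --
# it is the mediolateral mirror of LungeRight (see generateRepetition).
imuTemplateParams <- function(exercise) {
  tplEx <- if (exercise == "LungeLeft") "LungeRight" else exercise
  seed <- c(Squat = 101L, LungeRight = 103L, PlankJumpIn = 107L)[[tplEx]]
  withSeed(seed, {
    A <- matrix(runif(18 * 3, 0.4, 1.6), 18, 3)
    P <- matrix(runif(18 * 3, 0, 2 * pi), 18, 3)
    list(A = A, P = P)
  })
}

# Relative weight of harmonics k = 1..3 per exercise (distinct spectra).
harmonicWeights <- function(exercise) {
  switch(if (exercise == "LungeLeft") "LungeRight" else exercise,
    Squat       = c(1.0, 0.35, 0.10),
    LungeRight  = c(1.0, 0.60, 0.20),
    PlankJumpIn = c(0.45, 1.0, 0.55))
}

# Per-channel physical scale: hip moves less than the forearms; gyro in rad/s.
channelScales <- function() {
  rep(c(rep(2.0, 3), rep(1.2, 3),    # hip acc / gyr
        rep(3.2, 3), rep(1.8, 3),    # left forearm
        rep(3.2, 3), rep(1.8, 3)),   # right forearm
      length.out = 18)
}

# Dynamic (gravity-free, world-frame) IMU template at phase u in [0, 1].
# Returns a length(u) x 18 matrix.  Envelope sin(pi u)^2 guarantees rest at
# the repetition boundaries so segmentation has true quiet support.
imuTemplate <- function(exercise, u) {
  pars <- imuTemplateParams(exercise)
  w <- harmonicWeights(exercise)
  env <- sin(pi * u)^2
  out <- matrix(0, length(u), 18)
  for (k in 1:3) {
    ph <- outer(2 * pi * k * u, rep(1, 18)) +
      matrix(pars$P[, k], length(u), 18, byrow = TRUE)
    out <- out + sin(ph) *
      matrix(w[k] * pars$A[, k], length(u), 18, byrow = TRUE)
  }
  out <- out * env * matrix(channelScales(), length(u), 18, byrow = TRUE)
  if (exercise == "LungeLeft") out[, mirrorImuColumns()] <- -out[, mirrorImuColumns()]
  colnames(out) <- imuChannelNames()
  out
}

# Dynamic fraction of the total vertical force at phase u (0 at u = 0, 1).
grfShape <- function(exercise, u) {
  env <- sin(pi * u)^2
  switch(if (exercise == "LungeLeft") "LungeRight" else exercise,
    Squat       = -0.25 * env + 0.12 * sin(2 * pi * u) * env,
    LungeRight  = -0.18 * env + 0.08 * sin(4 * pi * u) * env,
    PlankJumpIn = -0.75 * exp(-((u - 0.45) / 0.10)^2) +
                   0.55 * exp(-((u - 0.72) / 0.06)^2))
}

# Centre-of-pressure excursion (m) at phase u: columns x (anteroposterior),
# y (mediolateral, +right).  Zero at u = 0 by construction.
copShape <- function(exercise, u) {
  env <- sin(pi * u)^2
  base <- switch(if (exercise == "LungeLeft") "LungeRight" else exercise,
    Squat       = cbind(x = 0.035 * env, y = 0.004 * sin(2 * pi * u) * env),
    LungeRight  = cbind(x = 0.045 * env, y = 0.050 * env),
    PlankJumpIn = cbind(x = -0.055 * env, y = 0.008 * sin(2 * pi * u) * env))
  if (exercise == "LungeLeft") base[, "y"] <- -base[, "y"]
  base
}

# Distribute a total vertical force over the 4 corners of the board so that
# force and moment balance reproduce (F, CoP).  Corners at x = +/- a
# (anteroposterior), y = +/- b (mediolateral); columns FL, FR, BL, BR.
cornerForces <- function(F, copX, copY, boardDims) {
  b <- boardDims[1] / 2  # mediolateral half-width
  a <- boardDims[2] / 2  # anteroposterior half-depth
  copX <- pmin(pmax(copX, -a), a)
  copY <- pmin(pmax(copY, -b), b)
  cbind(force_FL = F / 4 * (1 + copX / a) * (1 - copY / b),
        force_FR = F / 4 * (1 + copX / a) * (1 + copY / b),
        force_BL = F / 4 * (1 - copX / a) * (1 - copY / b),
        force_BR = F / 4 * (1 - copX / a) * (1 + copY / b))
}

# Fixed sensor-to-world misalignment for one (participant, exercise) session:
# a pure tilt (rotation about a horizontal axis) so that a single static
# gravity observation identifies it.  SD 5 degrees, capped at 15.
sessionMisalignments <- function(seed) {
  withSeed(seed, {
    lapply(1:3, function(i) {
      theta <- runif(1, 0, 2 * pi)
      ang <- max(min(rnorm(1, 0, 5 * pi / 180), 15 * pi / 180), -15 * pi / 180)
      rotationAboutAxis(c(cos(theta), sin(theta), 0), ang)
    })
  })
}

# Static T-pose calibration window: sensor-frame gravity reading + noise.
generateTpose <- function(rotations, durationS = 1.0, fs = 60, seed = 1) {
  n <- round(durationS * fs)
  withSeed(seed, {
    out <- matrix(0, n, 18)
    for (s in 1:3) {
      gSens <- crossprod(rotations[[s]], c(0, 0, GRAVITY))  # R^T g
      accCols <- (s - 1) * 6 + (1:3)
      gyrCols <- (s - 1) * 6 + (4:6)
      out[, accCols] <- matrix(gSens, n, 3, byrow = TRUE) +
        matrix(rnorm(n * 3, 0, 0.03), n, 3)
      out[, gyrCols] <- matrix(rnorm(n * 3, 0, 0.005), n, 3)
    }
    colnames(out) <- imuChannelNames()
    out
  })
}

#' Generate one synthetic repetition
#'
#' Builds the raw sensor streams for a single repetition of one exercise:
#' activity-specific harmonic templates scaled by the participant's random
#' effects, perturbed according to the fatigue fraction and
#' [FatigueProfile-class], projected into each sensor's (misaligned) frame,
#' and sampled at the native rates (board 30 Hz, IMU 60 Hz).
#'
#' @param participant one-row data.frame with columns id, mass_kg, height_m,
#'   amplitudeFactor, durationFactor (see [participants()]).
#' @param exercise one of Squat, LungeLeft, LungeRight, PlankJumpIn.
#' @param fatigueFraction fatigue level in `[0, 1]`.
#' @param seed integer RNG seed for this repetition.
#' @param profile a [FatigueProfile-class].
#' @param setIndex,repIndex 0-based indices recorded in the object.
#' @param boardDims board sensor rectangle, c(mediolateral, anteroposterior)
#'   in metres.
#' @param rotations optional list of 3 sensor-to-world rotation matrices (one
#'   per IMU); defaults to session misalignments derived from `seed`.
#' @param tpose optional precomputed T-pose window matrix.
#' @param noise logical; FALSE disables all stochastic components (template
#'   inspection and physics checks).
#' @return a [RawRepetition-class].
#' @examples
#' p <- data.frame(id = "A01", mass_kg = 70, height_m = 1.75,
#'                 amplitudeFactor = 1, durationFactor = 1)
#' rep1 <- generateRepetition(p, "Squat", 0, seed = 1, profile = nullFatigueProfile())
#' @export
generateRepetition <- function(participant, exercise, fatigueFraction, seed,
                               profile = fatigueProfile(),
                               setIndex = 0L, repIndex = 0L,
                               boardDims = c(0.433, 0.238),
                               rotations = NULL, tpose = NULL,
                               noise = TRUE) {
  assertExercise(exercise)
  validObject(profile)
  if (fatigueFraction < 0 || fatigueFraction > 1) {
    stop("fatigueFraction must be in [0, 1]", call. = FALSE)
  }
  phi <- fatigueFraction
  mass <- participant$mass_kg
  dur <- BASE_DURATION[[exercise]] * participant$durationFactor

  n60 <- round(dur * 60)
  n30 <- round(dur * 30)
  t60 <- (seq_len(n60) - 1) / 60
  t30 <- (seq_len(n30) - 1) / 30

  if (is.null(rotations)) {
    rotations <- sessionMisalignments(childSeed(seed, "misalign"))
  }

  withSeed(seed, {
    # per-repetition stochastic modifiers -----------------------------------
    jitter <- if (noise) rnorm(1, 0, profile@timingJitter * phi) else 0
    repScale <- if (noise) 1 + rnorm(1, 0, 0.04 * (1 + profile@noiseGrowth * phi)) else 1
    amp <- participant$amplitudeFactor * (1 + profile@amplitudeDrift * phi) * repScale

    u60 <- pmin(pmax(t60 / dur - jitter, 0), 1)
    u30 <- pmin(pmax(t30 / dur - jitter, 0), 1)

    # board ----------------------------------------------------------------
    Ftot <- mass * GRAVITY * (1 + amp * grfShape(exercise, u30))
    cop <- copShape(exercise, u30) * amp
    swaySD <- 0.004 * (1 + profile@swayGrowth * phi)
    if (noise) {
      for (ax in 1:2) {
        f <- runif(3, 0.2, 1.2); ph <- runif(3, 0, 2 * pi)
        cj <- rnorm(3, 0, swaySD)
        cop[, ax] <- cop[, ax] +
          colSums(cj * t(sin(outer(u30, 2 * pi * f) +
                             matrix(ph, n30, 3, byrow = TRUE))))
      }
    }
    forces <- cornerForces(pmax(Ftot, 0), cop[, 1], cop[, 2], boardDims)
    if (noise) {
      forces <- forces + matrix(
        rnorm(n30 * 4, 0, 1.5 * (1 + profile@noiseGrowth * phi)), n30, 4)
      forces <- pmax(forces, 0)
    }
    colnames(forces) <- boardChannelNames()

    # IMU ------------------------------------------------------------------
    dyn <- imuTemplate(exercise, u60) * amp
    if (noise && profile@tremorGain * phi > 0) {
      for (s in 1:3) {
        fTr <- runif(1, 8, 12); phTr <- runif(3, 0, 2 * pi)
        accCols <- (s - 1) * 6 + (1:3)
        gains <- runif(3, 0.5, 1) * profile@tremorGain * phi
        dyn[, accCols] <- dyn[, accCols] +
          sin(outer(2 * pi * fTr * t60, rep(1, 3)) +
              matrix(phTr, n60, 3, byrow = TRUE)) *
          matrix(gains, n60, 3, byrow = TRUE)
      }
    }
    imu <- matrix(0, n60, 18)
    for (s in 1:3) {
      accCols <- (s - 1) * 6 + (1:3)
      gyrCols <- (s - 1) * 6 + (4:6)
      accWorld <- dyn[, accCols]
      accWorld[, 3] <- accWorld[, 3] + GRAVITY  # specific force of gravity
      imu[, accCols] <- accWorld %*% rotations[[s]]      # (R^T a)^T rows
      imu[, gyrCols] <- dyn[, gyrCols] %*% rotations[[s]]
    }
    if (noise) {
      nsd <- 1 + profile@noiseGrowth * phi
      accIdx <- as.vector(outer(1:3, (0:2) * 6, `+`))
      gyrIdx <- as.vector(outer(4:6, (0:2) * 6, `+`))
      imu[, accIdx] <- imu[, accIdx] + matrix(rnorm(n60 * 9, 0, 0.08 * nsd), n60, 9)
      imu[, gyrIdx] <- imu[, gyrIdx] + matrix(rnorm(n60 * 9, 0, 0.02 * nsd), n60, 9)
    }
    colnames(imu) <- imuChannelNames()

    if (is.null(tpose)) {
      tpose <- generateTpose(rotations, seed = childSeed(seed, "tpose"))
    }

    new("RawRepetition",
        participantId = participant$id, exercise = exercise,
        setIndex = as.integer(setIndex), repIndex = as.integer(repIndex),
        boardTime = t30, boardForces = forces,
        imuTime = t60, imu = imu, tpose = tpose,
        rates = c(board = 30, imu = 60))
  })
}

#' Cohort generator configuration
#'
#' Defaults reflect the study protocol the generator emulates: 20 group-A
#' participants (one set of 10 repetitions per exercise, no fatigue) and 10
#' group-B participants performing repeated sets until exhaustion, with the
#' number of sets drawn uniformly from `setsRange` per exercise.
#'
#' @param nGroupA,nGroupB group sizes (either may be 0, not both).
#' @param setsRange integer range (min, max) of group-B set counts.
#' @param repsPerSet repetitions per set (10 in the protocol).
#' @param profile a [FatigueProfile-class] applied to group B.
#' @param boardDims board sensor rectangle c(mediolateral, anteroposterior), m.
#' @return list of class "cohortConfig".
#' @export
cohortConfig <- function(nGroupA = 20L, nGroupB = 10L, setsRange = c(5L, 15L),
                         repsPerSet = 10L, profile = fatigueProfile(),
                         boardDims = c(0.433, 0.238)) {
  if (nGroupA < 0 || nGroupB < 0 || nGroupA + nGroupB < 1) {
    stop("need at least one participant", call. = FALSE)
  }
  if (length(setsRange) != 2L || setsRange[1] > setsRange[2]) {
    stop("setsRange must be c(min, max) with min <= max", call. = FALSE)
  }
  if (nGroupB > 0 && setsRange[1] < 2L) {
    stop("group B set counts must be >= 2 (zero/one sets rejected)", call. = FALSE)
  }
  if (repsPerSet < 1L) stop("repsPerSet must be >= 1", call. = FALSE)
  validObject(profile)
  structure(list(nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
                 setsRange = as.integer(setsRange),
                 repsPerSet = as.integer(repsPerSet),
                 profile = profile, boardDims = boardDims),
            class = "cohortConfig")
}

# Draw participant metadata.  Mass/height distributions follow the cohort
# the generator emulates (group A: 66.6 +/- 9.1 kg, 1.739 +/- 0.07 m;
# group B: 68.2 +/- 13.3 kg, 1.755 +/- 0.07 m).
sampleParticipants <- function(config, seed) {
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(config$nGroupA)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("A%02d", i), group = "A",
        mass_kg = max(rnorm(1, 66.6, 9.1), 45),
        height_m = max(rnorm(1, 1.739, 0.07), 1.5),
        amplitudeFactor = exp(rnorm(1, 0, 0.10)),
        durationFactor = exp(rnorm(1, 0, 0.05)))
    }
    for (i in seq_len(config$nGroupB)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("B%02d", i), group = "B",
        mass_kg = max(rnorm(1, 68.2, 13.3), 45),
        height_m = max(rnorm(1, 1.755, 0.07), 1.5),
        amplitudeFactor = exp(rnorm(1, 0, 0.10)),
        durationFactor = exp(rnorm(1, 0, 0.05)))
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic cohort
#'
#' Produces the full collection of [RawRepetition-class] objects plus a
#' [CohortManifest-class].  Group-A repetitions are generated at fatigue
#' fraction 0; a group-B repetition in set `i` of `S` is generated at
#' fraction `i / (S - 1)`, so the final set represents complete fatigue.
#' Every stochastic element is derived from `seed` through stable per-key
#' child seeds: the same (config, seed) always yields an identical cohort.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer master seed.
#' @param dir optional directory; when given the cohort is also written to
#'   disk via [writeCohort()].
#' @return a [Cohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nGroupA = 1, nGroupB = 0), seed = 1)
#' coh
#' @export
generateCohort <- function(config, seed, dir = NULL) {
  if (!inherits(config, "cohortConfig")) {
    stop("config must come from cohortConfig()", call. = FALSE)
  }
  seed <- as.integer(seed)
  parts <- sampleParticipants(config, childSeed(seed, "participants"))

  setsRows <- list(); idxRows <- list(); tposeRows <- list()
  repetitions <- list(); tposes <- list()

  for (p in seq_len(nrow(parts))) {
    part <- parts[p, , drop = FALSE]
    for (ex in EXERCISES) {
      nSets <- if (part$group == "A") 1L else {
        withSeed(childSeed(seed, part$id, ex, "nsets"), {
          rng <- config$setsRange
          if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
        })
      }
      setsRows[[length(setsRows) + 1L]] <- data.frame(
        participant = part$id, exercise = ex, nSets = nSets)
      sessKey <- paste(part$id, ex, sep = "/")
      rot <- sessionMisalignments(childSeed(seed, part$id, ex, "misalign"))
      tp <- generateTpose(rot, seed = childSeed(seed, part$id, ex, "tpose"))
      tposes[[sessKey]] <- tp
      tposeRows[[length(tposeRows) + 1L]] <- data.frame(
        participant = part$id, exercise = ex,
        path = file.path("data", part$id, ex, "tpose.csv"))
      for (si in seq_len(nSets) - 1L) {
        phi <- if (part$group == "A" || nSets == 1L) 0 else si / (nSets - 1L)
        for (ri in seq_len(config$repsPerSet) - 1L) {
          key <- paste(part$id, ex, si, ri, sep = "/")
          rr <- generateRepetition(
            part, ex, phi, seed = childSeed(seed, part$id, ex, si, ri),
            profile = config$profile, setIndex = si, repIndex = ri,
            boardDims = config$boardDims, rotations = rot, tpose = tp)
          repetitions[[key]] <- rr
          idxRows[[length(idxRows) + 1L]] <- data.frame(
            participant = part$id, exercise = ex, set = si, rep = ri,
            path = file.path("data", part$id, ex,
                             sprintf("set%d_rep%d.csv", si, ri)))
        }
      }
    }
  }

  manifest <- new("CohortManifest",
    schemaVersion = "1.0",
    participants = parts,
    sets = do.call(rbind, setsRows),
    index = do.call(rbind, idxRows),
    tposeIndex = do.call(rbind, tposeRows),
    config = list(nGroupA = config$nGroupA, nGroupB = config$nGroupB,
                  setsRange = config$setsRange, repsPerSet = config$repsPerSet,
                  boardDims = config$boardDims,
                  profile = list(amplitudeDrift = config$profile@amplitudeDrift,
                                 noiseGrowth = config$profile@noiseGrowth,
                                 timingJitter = config$profile@timingJitter,
                                 swayGrowth = config$profile@swayGrowth,
                                 tremorGain = config$profile@tremorGain)),
    seed = seed)
  validObject(manifest)

  cohort <- new("Cohort", manifest = manifest, repetitions = repetitions,
                tposes = tposes, dir = "")
  if (!is.null(dir)) {
    writeCohort(cohort, dir)
    cohort@dir <- dir
  }
  cohort
}

# ---------------------------------------------------------------------------
# On-disk cohort format: manifest.json + one CSV per repetition.  Rows run on
# the IMU grid; the four board columns (native 30 Hz) are NA-padded past
# their own length.  Headers carry units.

repCsvHeader <- function() {
  c("t_board_s", paste0(boardChannelNames(), "_N"), "t_imu_s",
    vapply(imuChannelNames(), function(ch) {
      paste0(ch, if (grepl("_acc_", ch)) "_mps2" else "_radps")
    }, character(1), USE.NAMES = FALSE))
}

writeRepetitionCsv <- function(rr, path) {
  n60 <- length(rr@imuTime); n30 <- length(rr@boardTime)
  pad <- function(v) c(v, rep(NA_real_, n60 - n30))
  tab <- data.table::data.table(
    t_board = pad(rr@boardTime),
    fFL = pad(rr@boardForces[, 1]), fFR = pad(rr@boardForces[, 2]),
    fBL = pad(rr@boardForces[, 3]), fBR = pad(rr@boardForces[, 4]),
    t_imu = rr@imuTime)
  for (j in seq_len(18)) tab[[paste0("c", j)]] <- rr@imu[, j]
  data.table::setnames(tab, repCsvHeader())
  data.table::fwrite(tab, path)
}

condStop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "fatlatError")))
}

#' Write a cohort to disk
#'
#' Layout: `dir/manifest.json` plus
#' `dir/data/<participant>/<exercise>/set<k>_rep<j>.csv` (tabular text, one
#' column per channel with units in the header, one timestamp column per
#' native rate) and a `tpose.csv` per session.
#'
#' @param cohort a [Cohort-class] with repetitions in memory.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  m <- cohort@manifest
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(m@index))) {
    row <- m@index[i, ]
    key <- paste(row$participant, row$exercise, row$set, row$rep, sep = "/")
    rr <- cohort@repetitions[[key]]
    if (is.null(rr)) condStop("fatlat_missing_file", "missing repetition in memory: ", key)
    path <- file.path(dir, row$path)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeRepetitionCsv(rr, path)
  }
  for (i in seq_len(nrow(m@tposeIndex))) {
    row <- m@tposeIndex[i, ]
    tp <- cohort@tposes[[paste(row$participant, row$exercise, sep = "/")]]
    path <- file.path(dir, row$path)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tab <- data.table::as.data.table(tp)
    data.table::fwrite(tab, path)
  }
  manifestList <- list(
    schema_version = m@schemaVersion, seed = m@seed, config = m@config,
    participants = m@participants, sets = m@sets,
    index = m@index, tpose_index = m@tposeIndex)
  jsonlite::write_json(manifestList, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort directory
#'
#' Parses and validates `manifest.json` (every indexed file must exist;
#' repetition keys must be unique) and returns a [Cohort-class].  With
#' `lazy = TRUE` (default) repetition payloads are loaded on demand through
#' [getRepetition()].
#'
#' @param dir cohort directory written by [writeCohort()].
#' @param lazy load repetition files on demand rather than eagerly.
#' @return a [Cohort-class].
#' @export
readCohort <- function(dir, lazy = TRUE) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) condStop("fatlat_missing_file", "missing file: manifest.json")
  raw <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("schema_version", "participants", "sets", "index")
  if (!all(need %in% names(raw))) {
    condStop("fatlat_schema", "schema mismatch: manifest lacks ",
             paste(setdiff(need, names(raw)), collapse = ", "))
  }
  idx <- as.data.frame(raw$index)
  key <- paste(idx$participant, idx$exercise, idx$set, idx$rep)
  if (any(duplicated(key))) {
    condStop("fatlat_schema", "schema mismatch: duplicate repetition key ",
             key[duplicated(key)][1])
  }
  for (i in seq_len(nrow(idx))) {
    if (!file.exists(file.path(dir, idx$path[i]))) {
      condStop("fatlat_missing_file", "missing file for key ",
               paste(idx$participant[i], idx$exercise[i], idx$set[i],
                     idx$rep[i], sep = "/"), ": ", idx$path[i])
    }
  }
  manifest <- new("CohortManifest",
    schemaVersion = as.character(raw$schema_version),
    participants = as.data.frame(raw$participants),
    sets = as.data.frame(raw$sets),
    index = idx,
    tposeIndex = as.data.frame(raw$tpose_index),
    config = if (is.null(raw$config)) list() else raw$config,
    seed = if (is.null(raw$seed)) NA_integer_ else as.integer(raw$seed))
  validObject(manifest)
  cohort <- new("Cohort", manifest = manifest, repetitions = list(),
                tposes = list(), dir = dir)
  if (!lazy) {
    for (i in seq_len(nrow(idx))) {
      cohort@repetitions[[key[i]]] <- getRepetition(
        cohort, idx$participant[i], idx$exercise[i], idx$set[i], idx$rep[i])
    }
    cohort@repetitions <- cohort@repetitions[
      paste(idx$participant, idx$exercise, idx$set, idx$rep, sep = "/")]
    names(cohort@repetitions) <- paste(idx$participant, idx$exercise,
                                       idx$set, idx$rep, sep = "/")
    for (i in seq_len(nrow(manifest@tposeIndex))) {
      r <- manifest@tposeIndex[i, ]
      cohort@tposes[[paste(r$participant, r$exercise, sep = "/")]] <-
        readTpose(cohort, r$participant, r$exercise)
    }
  }
  cohort
}

readTpose <- function(cohort, participant, exercise) {
  k <- paste(participant, exercise, sep = "/")
  if (!is.null(cohort@tposes[[k]])) return(cohort@tposes[[k]])
  row <- cohort@manifest@tposeIndex
  row <- row[row$participant == participant & row$exercise == exercise, ]
  if (!nrow(row)) condStop("fatlat_missing_file", "missing file: tpose for ", k)
  tp <- as.matrix(data.table::fread(file.path(cohort@dir, row$path[1])))
  colnames(tp) <- imuChannelNames()
  tp
}

#' Fetch one repetition from a cohort
#'
#' Returns the in-memory object when present, otherwise reads and validates
#' the backing CSV (sampling-rate check included).
#'
#' @param cohort a [Cohort-class].
#' @param participant,exercise,set,rep repetition key (0-based set/rep).
#' @return a [RawRepetition-class].
#' @export
getRepetition <- function(cohort, participant, exercise, set, rep) {
  key <- paste(participant, exercise, set, rep, sep = "/")
  if (!is.null(cohort@repetitions[[key]])) return(cohort@repetitions[[key]])
  idx <- cohort@manifest@index
  row <- idx[idx$participant == participant & idx$exercise == exercise &
             idx$set == set & idx$rep == rep, ]
  if (!nrow(row)) condStop("fatlat_missing_file", "missing file for key ", key)
  path <- file.path(cohort@dir, row$path[1])
  if (!file.exists(path)) {
    condStop("fatlat_missing_file", "missing file for key ", key, ": ", row$path[1])
  }
  tab <- data.table::fread(path)
  if (!identical(names(tab), repCsvHeader())) {
    condStop("fatlat_schema", "schema mismatch in ", row$path[1])
  }
  tImu <- tab[["t_imu_s"]]
  tBoard <- tab[["t_board_s"]]; tBoard <- tBoard[!is.na(tBoard)]
  rateOk <- function(t, fs) {
    length(t) < 2 || abs(1 / stats::median(diff(t)) - fs) < 0.01
  }
  if (!rateOk(tBoard, 30) || !rateOk(tImu, 60)) {
    condStop("fatlat_rate", "rate mismatch in ", row$path[1],
             " (expected 30 Hz board / 60 Hz IMU)")
  }
  forces <- as.matrix(tab[seq_along(tBoard), 2:5])
  colnames(forces) <- boardChannelNames()
  imu <- as.matrix(tab[, 7:24])
  colnames(imu) <- imuChannelNames()
  new("RawRepetition",
      participantId = participant, exercise = exercise,
      setIndex = as.integer(set), repIndex = as.integer(rep),
      boardTime = tBoard, boardForces = forces,
      imuTime = tImu, imu = imu,
      tpose = readTpose(cohort, participant, exercise),
      rates = c(board = 30, imu = 60))
}

#' Concatenate repetitions into a continuous activity stream
#'
#' Joins the repetitions with quiet gaps of 1-2 s (sensor noise only) and
#' returns the hip/forearm acceleration-magnitude activity signal
#' `| ||acc|| - g |` together with the ground-truth repetition support
#' intervals (half-open, 0-based).  This exercises the movement/stillness
#' segmentation without emulating video-assisted boundary refinement.
#'
#' @param reps list of [RawRepetition-class].
#' @param gapRange quiet-gap duration range in seconds.
#' @param seed integer seed for gap durations and gap noise.
#' @return list with `stream` (numeric), `fs` (60), and `intervals`
#'   (matrix with columns start, end).
#' @export
concatenateRepetitions <- function(reps, gapRange = c(1, 2), seed = 1) {
  fs <- 60
  withSeed(seed, {
    pieces <- list(); intervals <- NULL; cursor <- 0L
    gapPiece <- function(n) abs(rnorm(n, 0, 0.06))
    pieces[[1]] <- gapPiece(round(runif(1, gapRange[1], gapRange[2]) * fs))
    cursor <- length(pieces[[1]])
    for (rr in reps) {
      accIdx <- as.vector(outer(1:3, (0:2) * 6, `+`))
      mag <- sqrt(rowSums(rr@imu[, accIdx[1:3], drop = FALSE]^2))
      act <- abs(mag - GRAVITY)
      pieces[[length(pieces) + 1L]] <- act
      intervals <- rbind(intervals, c(cursor, cursor + length(act)))
      cursor <- cursor + length(act)
      gap <- gapPiece(round(runif(1, gapRange[1], gapRange[2]) * fs))
      pieces[[length(pieces) + 1L]] <- gap
      cursor <- cursor + length(gap)
    }
    colnames(intervals) <- c("start", "end")
    list(stream = unlist(pieces), fs = fs, intervals = intervals)
  })
}
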