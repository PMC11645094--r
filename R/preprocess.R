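# Preprocessing: raw sensor streams -> standardized 192-frame matrices.
#
# Fixed stage order: T-pose calibration -> gravity removal / height
# normalization -> GRF/CoP derivation -> 15 Hz zero-phase low-pass at the
# native rate -> (segmentation for continuous streams) -> cubic-spline
# resampling to 192 frames -> per-type standardization.  Every stage is pure.

N_FRAMES <- 192L

#' Channels of each database variant
#'
#' DB0: board only (GRF + CoP); DB1: board + hip IMU; DB2: board + all three
#' IMUs; DB3: hip IMU only; DB4: all three IMUs.  Channel order is fixed:
#' board channels first (grf_norm, cop_x, cop_y), then IMU sensors in the
#' order hip, left forearm, right forearm (acceleration before angular
#' velocity within a sensor).
#'
#' @param databaseId one of "DB0".."DB4".
#' @return character vector of channel names.
#' @examples
#' length(databaseChannels("DB2"))  # 21
#' @export
databaseChannels <- function(databaseId) {
  board <- c("grf_norm", "cop_x", "cop_y")
  imu <- imuChannelNames()
  hip <- imu[1:6]
  switch(databaseId,
    DB0 = board,
    DB1 = c(board, hip),
    DB2 = c(board, imu),
    DB3 = hip,
    DB4 = imu,
    stop("unknown database id '", databaseId, "'", call. = FALSE))
}

# Signal type of each channel, used for pooled per-type standardization.
channelTypes <- function(channels) {
  vapply(channels, function(ch) {
    if (ch == "grf_norm") "grf"
    else if (startsWith(ch, "cop_")) "cop"
    else if (grepl("_acc_", ch)) "acc"
    else if (grepl("_gyr_", ch)) "gyr"
    else stop("unknown channel '", ch, "'", call. = FALSE)
  }, character(1))
}

#' Derive normalized GRF and centre of pressure from corner forces
#'
#' `grf_norm = sum(F) / mass` (N/kg); CoP from corner-force moment balance
#' over the sensor rectangle, with the first-frame value subtracted so the
#' trajectory starts at (0, 0) (removes initial-stance bias).
#'
#' @param forces T x 4 matrix of corner forces (N), columns FL, FR, BL, BR.
#' @param mass participant mass (kg), > 0.
#' @param boardDims c(mediolateral, anteroposterior) sensor spacing (m).
#' @param subtractInitial subtract the first-frame CoP (default TRUE).
#' @param forceFloor minimum total force (N) for a valid CoP sample.
#' @param maxUnloadedFraction error if more than this fraction of frames is
#'   below `forceFloor`.
#' @return T x 3 matrix with columns grf_norm, cop_x (anteroposterior, m),
#'   cop_y (mediolateral, m).
#' @export
deriveGrfCop <- function(forces, mass, boardDims = c(0.433, 0.238),
                         subtractInitial = TRUE, forceFloor = 50,
                         maxUnloadedFraction = 0.1) {
  if (mass <= 0) stop("mass must be > 0", call. = FALSE)
  Ftot <- rowSums(forces)
  unloaded <- Ftot < forceFloor
  if (mean(unloaded) > maxUnloadedFraction) {
    stop("unloaded board: ", round(100 * mean(unloaded)),
         "% of frames below the ", forceFloor, " N floor", call. = FALSE)
  }
  b <- boardDims[1] / 2; a <- boardDims[2] / 2
  Fsafe <- pmax(Ftot, forceFloor)
  # moment balance: x weights +a for front corners, y weights +b for right
  copX <- (a * (forces[, 1] + forces[, 2]) - a * (forces[, 3] + forces[, 4])) / Fsafe
  copY <- (b * (forces[, 2] + forces[, 4]) - b * (forces[, 1] + forces[, 3])) / Fsafe
  if (subtractInitial) {
    copX <- copX - copX[1]
    copY <- copY - copY[1]
  }
  cbind(grf_norm = Ftot / mass, cop_x = copX, cop_y = copY)
}

#' Estimate the sensor-to-world rotation from a static T-pose window
#'
#' During the T-pose all body segments are assumed aligned with the world
#' frame, so each accelerometer should read pure gravity (0, 0, +g).  The
#' estimate is the minimal rotation taking the measured mean specific-force
#' direction to the world vertical; applied to the streams it restores the
#' world frame up to an (unobservable) rotation about the vertical.
#'
#' @param tpose T x 6 matrix (acc xyz, gyr xyz) of one sensor, or a T x 18
#'   window from which one sensor is selected via `sensor`.
#' @param sensor sensor index 1..3 when `tpose` has 18 columns.
#' @param gyroThreshold maximum mean gyro norm (rad/s) for the window to
#'   count as static.
#' @param minSamples minimum window length (0.5 s at 60 Hz by default).
#' @return 3 x 3 rotation matrix `R` such that `world = meas %*% t(R)` for
#'   row-vector samples.
#' @export
estimateTposeRotation <- function(tpose, sensor = 1L, gyroThreshold = 0.2,
                                  minSamples = 30L) {
  if (ncol(tpose) == 18L) {
    tpose <- tpose[, (sensor - 1L) * 6L + (1:6), drop = FALSE]
  }
  if (ncol(tpose) != 6L) stop("tpose must have 6 (or 18) columns", call. = FALSE)
  if (nrow(tpose) < minSamples) {
    stop("T-pose window too short: need >= ", minSamples, " samples", call. = FALSE)
  }
  gyroNorm <- mean(sqrt(rowSums(tpose[, 4:6, drop = FALSE]^2)))
  if (gyroNorm > gyroThreshold) {
    stop("non-static T-pose window (mean gyro norm ", signif(gyroNorm, 3),
         " rad/s > ", gyroThreshold, ")", call. = FALSE)
  }
  g <- colMeans(tpose[, 1:3, drop = FALSE])
  gn <- g / sqrt(sum(g^2))
  z <- c(0, 0, 1)
  cosA <- sum(gn * z)
  if (cosA > 1 - 1e-12) return(diag(3))
  if (cosA < -1 + 1e-12) return(rotationAboutAxis(c(1, 0, 0), pi))
  axis <- c(gn[2] * z[3] - gn[3] * z[2],
            gn[3] * z[1] - gn[1] * z[3],
            gn[1] * z[2] - gn[2] * z[1])
  rotationAboutAxis(axis, acos(cosA))
}

#' Apply I2S calibration to IMU streams
#'
#' Rotates all three sensors' acceleration and angular-velocity streams into
#' the world frame using per-sensor rotations estimated from the T-pose.
#'
#' @param imu T x 18 sensor-frame matrix (canonical channel order).
#' @param rotations list of 3 rotation matrices from
#'   [estimateTposeRotation()].
#' @return T x 18 world-frame matrix.
#' @export
applyCalibration <- function(imu, rotations) {
  out <- imu
  for (s in 1:3) {
    accCols <- (s - 1) * 6 + (1:3)
    gyrCols <- (s - 1) * 6 + (4:6)
    R <- rotations[[s]]
    out[, accCols] <- imu[, accCols, drop = FALSE] %*% t(R)
    out[, gyrCols] <- imu[, gyrCols, drop = FALSE] %*% t(R)
  }
  out
}

#' Remove gravity and normalize acceleration by body height
#'
#' Subtracts the constant gravity specific force (0, 0, +g) in the world
#' frame and divides by the participant's height, yielding dynamic
#' acceleration in (m/s^2)/m.
#'
#' @param worldAcc T x 3 world-frame accelerometer matrix.
#' @param height participant height (m), > 0.
#' @return T x 3 matrix.
#' @export
removeGravityNormalize <- function(worldAcc, height) {
  if (height <= 0) stop("height must be > 0", call. = FALSE)
  worldAcc[, 3] <- worldAcc[, 3] - GRAVITY
  worldAcc / height
}

#' Zero-phase low-pass Butterworth filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, squared
#' magnitude response: gain 0.5 at the cutoff).  Signals are extended by odd
#' reflection before filtering so short biomechanics records keep clean
#' edges.
#'
#' @param x numeric vector or T x C matrix (columns filtered independently).
#' @param fs sampling rate (Hz); must exceed `2 * cutoff`.
#' @param cutoff cutoff frequency (Hz), default 15.
#' @param order filter order, default 4.
#' @return filtered signal, same shape as `x`.
#' @export
lowpassFilter <- function(x, fs, cutoff = 15, order = 4) {
  if (fs <= 2 * cutoff) {
    stop("Nyquist violation: fs = ", fs, " Hz must exceed 2 * cutoff = ",
         2 * cutoff, " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2))
  pad <- 3L * (length(bf$b) - 1L) * 2L
  filt1 <- function(v) {
    n <- length(v)
    if (n <= pad) {
      stop("signal too short to filter: length ", n, " <= required padding ",
           pad, call. = FALSE)
    }
    # odd-reflection padding; the edge level is subtracted before each pass
    # so the zero-initial-condition transient acts on a zero-mean edge
    # (constants pass through exactly: DC gain 1)
    ext <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
             2 * v[n] - rev(v[(n - pad):(n - 1)]))
    fwd <- as.numeric(signal::filter(bf, ext - ext[1])) + ext[1]
    rev_ <- rev(fwd)
    bwd <- rev(as.numeric(signal::filter(bf, rev_ - rev_[1])) + rev_[1])
    bwd[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

#' Segment repetitions from a continuous activity stream
#'
#' Detects periods of movement in a gravity-free acceleration-magnitude
#' stream: the signal is smoothed with a moving RMS window, thresholded, and
#' supra-threshold runs separated by less than `minQuietGap` are merged.
#' Returns half-open, 0-based sample intervals.
#'
#' @param stream numeric activity signal (e.g. `| ||acc|| - g |`).
#' @param fs sampling rate (Hz).
#' @param threshold movement threshold on the smoothed signal (stream units).
#' @param minQuietGap minimum stillness between repetitions (s).
#' @param minDuration minimum repetition duration (s); shorter bursts are
#'   discarded.
#' @param smoothWindow RMS smoothing window (s).
#' @return integer matrix with columns start, end (possibly 0 rows).
#' @export
segmentRepetitions <- function(stream, fs = 60, threshold = 0.5,
                               minQuietGap = 0.5, minDuration = 0.3,
                               smoothWindow = 0.25) {
  n <- length(stream)
  w <- max(1L, round(smoothWindow * fs))
  kernel <- rep(1 / w, w)
  sm <- sqrt(pmax(stats::filter(stream^2, kernel, sides = 2), 0))
  sm[is.na(sm)] <- 0
  active <- sm > threshold
  if (!any(active)) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(as.vector(active))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive
  # merge runs separated by quiet gaps shorter than minQuietGap
  gapN <- round(minQuietGap * fs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1L < gapN) {
      merged[nrow(merged), 2] <- runs[i, 2]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= round(minDuration * fs)
  merged <- merged[keep, , drop = FALSE]
  out <- cbind(start = merged[, 1] - 1L, end = merged[, 2])  # half-open 0-based
  storage.mode(out) <- "integer"
  out
}

#' Resample channels onto the fixed 192-frame grid
#'
#' Each channel is independently cubic-spline interpolated onto 192
#' uniformly spaced points spanning the repetition interval; endpoints are
#' preserved exactly.  Channels sampled at different native rates land on
#' the same output grid.
#'
#' @param time numeric sample times (s), increasing, length >= 4.
#' @param channels numeric vector or T x C matrix on that time grid.
#' @param nOut output frames (default 192).
#' @param span optional c(t0, t1) interval; defaults to range(time).
#' @return `nOut` x C matrix.
#' @export
resampleRepetition <- function(time, channels, nOut = N_FRAMES, span = NULL) {
  if (is.vector(channels)) channels <- matrix(channels, ncol = 1)
  if (length(time) != nrow(channels)) {
    stop("time and channels lengths differ", call. = FALSE)
  }
  if (length(time) < 4L) {
    stop("cubic spline interpolation needs >= 4 samples, got ", length(time),
         call. = FALSE)
  }
  if (is.null(span)) span <- range(time)
  grid <- seq(span[1], span[2], length.out = nOut)
  out <- apply(channels, 2, function(v) {
    stats::spline(time, v, xout = grid, method = "fmm")$y
  })
  dimnames(out) <- list(NULL, colnames(channels))
  out
}

# Full native-rate -> 192-frame pipeline for one repetition.
# Returns a 192 x length(channels) matrix in the requested database layout.
preprocessRepetition <- function(rr, mass, height, databaseId,
                                 boardDims = c(0.433, 0.238)) {
  channels <- databaseChannels(databaseId)
  needBoard <- any(startsWith(channels, "grf")) || any(startsWith(channels, "cop"))
  needImu <- any(grepl("_acc_|_gyr_", channels))
  dur <- max(tail(rr@imuTime, 1), tail(rr@boardTime, 1))
  cols <- list()

  if (needBoard) {
    gc3 <- deriveGrfCop(rr@boardForces, mass, boardDims, subtractInitial = TRUE)
    # at 30 Hz the 15 Hz cutoff sits at Nyquist: the record carries no
    # representable content above the cutoff, so the low-pass is an identity
    # and is skipped for that rate
    if (rr@rates[["board"]] > 2 * 15) {
      gc3 <- lowpassFilter(gc3, fs = rr@rates[["board"]])
    }
    gc3 <- resampleRepetition(rr@boardTime, gc3, span = c(0, dur))
    gc3[, "cop_x"] <- gc3[, "cop_x"] - gc3[1, "cop_x"]
    gc3[, "cop_y"] <- gc3[, "cop_y"] - gc3[1, "cop_y"]
    for (ch in c("grf_norm", "cop_x", "cop_y")) cols[[ch]] <- gc3[, ch]
  }
  if (needImu) {
    rots <- lapply(1:3, function(s) estimateTposeRotation(rr@tpose, sensor = s))
    world <- applyCalibration(rr@imu, rots)
    for (s in 1:3) {
      accCols <- (s - 1) * 6 + (1:3)
      world[, accCols] <- removeGravityNormalize(
        world[, accCols, drop = FALSE], height)
    }
    world <- lowpassFilter(world, fs = rr@rates[["imu"]])
    world <- resampleRepetition(rr@imuTime, world, span = c(0, dur))
    colnames(world) <- imuChannelNames()
    for (ch in intersect(channels, imuChannelNames())) cols[[ch]] <- world[, ch]
  }
  missing <- setdiff(channels, names(cols))
  if (length(missing)) {
    stop("missing modality for database ", databaseId, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- do.call(cbind, cols[channels])
  colnames(X) <- channels
  X
}

#' Assemble a processed dataset from a cohort
#'
#' Runs the full preprocessing pipeline on every repetition of a cohort and
#' returns a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one 192 x R assay per channel (R = repetitions), `colData` columns
#' `participant`, `group`, `exercise`, `set`, `rep`, and metadata recording
#' the database variant and channel types.  Labels are one-hot over the
#' canonical activity order (Squat, LungeLeft, LungeRight, PlankJumpIn);
#' see [oneHotLabels()].
#'
#' @param cohort a [Cohort-class].
#' @param databaseId one of "DB0".."DB4".
#' @param participantIds optional subset of participants.
#' @param stats optional [StandardizationStats-class]; when supplied the
#'   assays are standardized in place.
#' @return a `SummarizedExperiment`.
#' @export
assembleDataset <- function(cohort, databaseId, participantIds = NULL,
                            stats = NULL) {
  channels <- databaseChannels(databaseId)
  m <- cohort@manifest
  idx <- m@index
  if (!is.null(participantIds)) {
    idx <- idx[idx$participant %in% participantIds, , drop = FALSE]
  }
  if (!nrow(idx)) stop("no repetitions selected", call. = FALSE)
  boardDims <- if (!is.null(m@config$boardDims)) {
    as.numeric(m@config$boardDims)
  } else c(0.433, 0.238)

  mats <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    row <- idx[i, ]
    rr <- getRepetition(cohort, row$participant, row$exercise, row$set, row$rep)
    part <- m@participants[m@participants$id == row$participant, ]
    mats[[i]] <- preprocessRepetition(rr, part$mass_kg, part$height_m,
                                      databaseId, boardDims)
  }
  assays <- lapply(seq_along(channels), function(j) {
    vapply(mats, function(X) X[, j], numeric(N_FRAMES))
  })
  names(assays) <- channels
  cd <- S4Vectors::DataFrame(
    participant = idx$participant,
    group = m@participants$group[match(idx$participant, m@participants$id)],
    exercise = factor(idx$exercise, levels = EXERCISES),
    set = idx$set, rep = idx$rep)
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
  S4Vectors::metadata(se) <- list(databaseId = databaseId,
                                  channelTypes = channelTypes(channels),
                                  standardized = FALSE)
  if (!is.null(stats)) se <- standardizeDataset(se, stats)
  se
}

#' One-hot activity labels of a processed dataset
#'
#' @param se a `SummarizedExperiment` from [assembleDataset()].
#' @return R x 4 binary matrix, columns in canonical activity order.
#' @export
oneHotLabels <- function(se) {
  ex <- SummarizedExperiment::colData(se)$exercise
  out <- matrix(0L, length(ex), length(EXERCISES),
                dimnames = list(NULL, EXERCISES))
  out[cbind(seq_along(ex), as.integer(ex))] <- 1L
  out
}

#' Compute per-type standardization statistics
#'
#' Pools all frames of all channels of each signal type (grf, cop, acc, gyr)
#' over the selected training repetitions and records the global mean and SD
#' per type.  Statistics must come from the training split of the
#' non-fatigued group only; the fold id and subject ids are stored as
#' provenance.
#'
#' @param se a `SummarizedExperiment` from [assembleDataset()] (not yet
#'   standardized).
#' @param trainIds participant ids of the fold's training split.
#' @param fold fold identifier string.
#' @return a [StandardizationStats-class].
#' @export
computeStandardization <- function(se, trainIds, fold = "0") {
  if (isTRUE(S4Vectors::metadata(se)$standardized)) {
    stop("dataset is already standardized", call. = FALSE)
  }
  sel <- SummarizedExperiment::colData(se)$participant %in% trainIds
  if (!any(sel)) stop("no training repetitions in dataset", call. = FALSE)
  types <- S4Vectors::metadata(se)$channelTypes
  mu <- c(); sigma <- c()
  for (t in unique(types)) {
    vals <- unlist(lapply(names(types)[types == t], function(ch) {
      SummarizedExperiment::assay(se, ch)[, sel]
    }), use.names = FALSE)
    s <- stats::sd(vals)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate type (sigma = 0): ", t, call. = FALSE)
    }
    mu[t] <- mean(vals); sigma[t] <- s
  }
  new("StandardizationStats", mu = mu, sigma = sigma, fold = as.character(fold),
      trainSubjects = as.character(trainIds))
}

#' Standardize / unstandardize a processed dataset
#'
#' Applies `z = (x - mu_t) / sigma_t` per channel according to its signal
#' type.  `unstandardizeDataset()` inverts the transform exactly.
#'
#' @param se a `SummarizedExperiment` from [assembleDataset()].
#' @param stats a [StandardizationStats-class].
#' @return the transformed `SummarizedExperiment`.
#' @export
standardizeDataset <- function(se, stats) {
  types <- S4Vectors::metadata(se)$channelTypes
  miss <- setdiff(unique(types), names(stats@mu))
  if (length(miss)) {
    stop("stats lack types: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (ch in names(types)) {
    t <- types[[ch]]
    SummarizedExperiment::assay(se, ch) <-
      (SummarizedExperiment::assay(se, ch) - stats@mu[[t]]) / stats@sigma[[t]]
  }
  md <- S4Vectors::metadata(se)
  md$standardized <- TRUE
  md$statsProvenance <- stats@fold
  S4Vectors::metadata(se) <- md
  se
}

#' @rdname standardizeDataset
#' @export
unstandardizeDataset <- function(se, stats) {
  types <- S4Vectors::metadata(se)$channelTypes
  for (ch in names(types)) {
    t <- types[[ch]]
    SummarizedExperiment::assay(se, ch) <-
      SummarizedExperiment::assay(se, ch) * stats@sigma[[t]] + stats@mu[[t]]
  }
  md <- S4Vectors::metadata(se)
  md$standardized <- FALSE
  md$statsProvenance <- NULL
  S4Vectors::metadata(se) <- md
  se
}

# Processed dataset -> 192 x channels x R array (model input layout).
datasetArray <- function(se) {
  channels <- names(S4Vectors::metadata(se)$channelTypes)
  R <- ncol(se)
  arr <- array(0, c(N_FRAMES, length(channels), R))
  for (j in seq_along(channels)) {
    arr[, j, ] <- SummarizedExperiment::assay(se, channels[j])
  }
  arr
}
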