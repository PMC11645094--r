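# Central S4 classes.  Heavy tabular payloads are kept as plain data.frames
# inside the objects; validity methods enforce the structural invariants the
# downstream stages rely on.

#' Parametric fatigue drift profile
#'
#' Encodes how the synthetic generator perturbs repetitions as a participant
#' approaches exhaustion.  Every field is a non-negative rate per unit of
#' fatigue fraction (0 = fresh, 1 = complete fatigue); an all-zero profile
#' yields a stationary null cohort in which no set differs statistically from
#' any other.
#'
#' @slot amplitudeDrift fractional increase of movement amplitude at full
#'   fatigue (dimensionless, e.g. 0.15 = +15%).
#' @slot noiseGrowth multiplicative growth of sensor/motor noise SD at full
#'   fatigue (dimensionless).
#' @slot timingJitter SD of the phase perturbation at full fatigue, as a
#'   fraction of the repetition duration.
#' @slot swayGrowth fractional growth of centre-of-pressure wander dispersion
#'   at full fatigue (dimensionless).
#' @slot tremorGain amplitude of an 8-12 Hz tremor component added to the
#'   accelerometer channels at full fatigue (m/s^2).
#' @export
setClass("FatigueProfile",
  representation(
    amplitudeDrift = "numeric",
    noiseGrowth    = "numeric",
    timingJitter   = "numeric",
    swayGrowth     = "numeric",
    tremorGain     = "numeric"
  )
)

setValidity("FatigueProfile", function(object) {
  vals <- c(object@amplitudeDrift, object@noiseGrowth, object@timingJitter,
            object@swayGrowth, object@tremorGain)
  if (length(vals) != 5L || anyNA(vals)) {
    return("all five fields must be scalar and non-missing")
  }
  if (any(vals < 0)) return("fatigue profile fields must be >= 0")
  TRUE
})

#' Construct a [FatigueProfile-class]
#'
#' Defaults describe the fatigue condition the generator emulates for the
#' exhaustion-protocol group: a moderate (+15%) amplitude drift, a 60%
#' growth of motor noise, mild timing jitter, an 80% growth of postural
#' sway and a 0.4 m/s^2 tremor component at complete fatigue.  Pass all
#' zeros (see [nullFatigueProfile()]) for the stationary null model.
#'
#' @param amplitudeDrift,noiseGrowth,timingJitter,swayGrowth,tremorGain
#'   non-negative scalars; see [FatigueProfile-class].
#' @return a `FatigueProfile` object.
#' @examples
#' fatigueProfile()
#' nullFatigueProfile()
#' @export
fatigueProfile <- function(amplitudeDrift = 0.15, noiseGrowth = 0.6,
                           timingJitter = 0.03, swayGrowth = 0.8,
                           tremorGain = 0.4) {
  new("FatigueProfile",
      amplitudeDrift = amplitudeDrift, noiseGrowth = noiseGrowth,
      timingJitter = timingJitter, swayGrowth = swayGrowth,
      tremorGain = tremorGain)
}

#' @rdname fatigueProfile
#' @export
nullFatigueProfile <- function() fatigueProfile(0, 0, 0, 0, 0)

setMethod("show", "FatigueProfile", function(object) {
  cat("FatigueProfile: amplitudeDrift=", object@amplitudeDrift,
      " noiseGrowth=", object@noiseGrowth,
      " timingJitter=", object@timingJitter,
      " swayGrowth=", object@swayGrowth,
      " tremorGain=", object@tremorGain, "\n", sep = "")
})

#' One raw exercise repetition
#'
#' Multichannel raw streams for a single repetition: four balance-board
#' vertical corner forces (N, 30 Hz) and three IMUs (hip, left forearm,
#' right forearm), each providing 3-axis acceleration (m/s^2) and 3-axis
#' angular velocity (rad/s) at 60 Hz in the sensor frame, plus the static
#' T-pose calibration window recorded for the session.
#'
#' @slot participantId character.
#' @slot exercise one of Squat, LungeLeft, LungeRight, PlankJumpIn.
#' @slot setIndex,repIndex 0-based integers.
#' @slot boardTime numeric, seconds (30 Hz grid).
#' @slot boardForces T30 x 4 matrix, columns FL, FR, BL, BR (front/back x
#'   left/right corner), Newtons, non-negative.
#' @slot imuTime numeric, seconds (60 Hz grid).
#' @slot imu T60 x 18 matrix, sensor-frame streams in the canonical channel
#'   order (see [imuChannelNames()]).
#' @slot tpose T x 18 matrix, static calibration window at 60 Hz.
#' @slot rates named numeric, board and imu sampling rates (Hz).
#' @export
setClass("RawRepetition",
  representation(
    participantId = "character",
    exercise      = "character",
    setIndex      = "integer",
    repIndex      = "integer",
    boardTime     = "numeric",
    boardForces   = "matrix",
    imuTime       = "numeric",
    imu           = "matrix",
    tpose         = "matrix",
    rates         = "numeric"
  )
)

setValidity("RawRepetition", function(object) {
  if (!object@exercise %in% EXERCISES) return("unknown exercise")
  if (!identical(sort(names(object@rates)), c("board", "imu"))) {
    return("rates must be named 'board' and 'imu'")
  }
  if (ncol(object@boardForces) != 4L) return("boardForces must have 4 columns")
  if (nrow(object@boardForces) != length(object@boardTime)) {
    return("boardForces rows must match boardTime length")
  }
  if (ncol(object@imu) != 18L) return("imu must have 18 columns")
  if (nrow(object@imu) != length(object@imuTime)) {
    return("imu rows must match imuTime length")
  }
  if (any(object@boardForces < 0)) return("board forces must be >= 0")
  TRUE
})

setMethod("show", "RawRepetition", function(object) {
  cat("RawRepetition ", object@participantId, "/", object@exercise,
      " set ", object@setIndex, " rep ", object@repIndex,
      ": ", length(object@boardTime), " board frames @",
      object@rates[["board"]], " Hz, ",
      length(object@imuTime), " IMU frames @", object@rates[["imu"]],
      " Hz\n", sep = "")
})

#' Cohort manifest
#'
#' Index of a cohort: participant metadata, per-exercise set counts, the
#' (participant, exercise, set, rep) -> file mapping used by the on-disk
#' format, and the generator configuration when the cohort is synthetic.
#'
#' @slot schemaVersion character.
#' @slot participants data.frame with columns id, group ("A"/"B"), mass_kg,
#'   height_m, amplitudeFactor, durationFactor.
#' @slot sets data.frame with columns participant, exercise, nSets.
#' @slot index data.frame with columns participant, exercise, set, rep, path.
#' @slot tposeIndex data.frame with columns participant, exercise, path.
#' @slot config list, generator settings (empty for ingested data).
#' @slot seed integer master seed (NA for ingested data).
#' @export
setClass("CohortManifest",
  representation(
    schemaVersion = "character",
    participants  = "data.frame",
    sets          = "data.frame",
    index         = "data.frame",
    tposeIndex    = "data.frame",
    config        = "list",
    seed          = "integer"
  )
)

setValidity("CohortManifest", function(object) {
  p <- object@participants
  need <- c("id", "group", "mass_kg", "height_m")
  if (!all(need %in% names(p))) {
    return(paste("participants must have columns:", paste(need, collapse = ", ")))
  }
  if (any(duplicated(p$id))) return("duplicate participant ids")
  if (any(p$mass_kg <= 0)) return("participant mass must be > 0")
  if (any(p$height_m <= 0)) return("participant height must be > 0")
  if (!all(p$group %in% c("A", "B"))) return("group must be 'A' or 'B'")
  s <- object@sets
  if (nrow(s)) {
    grp <- p$group[match(s$participant, p$id)]
    if (any(grp == "A" & s$nSets != 1L)) {
      return("group A participants must have exactly 1 set per exercise")
    }
    if (any(grp == "B" & s$nSets < 2L)) {
      return("group B participants must have >= 2 sets per exercise")
    }
  }
  idx <- object@index
  if (nrow(idx)) {
    key <- paste(idx$participant, idx$exercise, idx$set, idx$rep)
    if (any(duplicated(key))) {
      return(paste("duplicate repetition key:", key[duplicated(key)][1]))
    }
  }
  TRUE
})

setMethod("show", "CohortManifest", function(object) {
  cat("CohortManifest (schema ", object@schemaVersion, "): ",
      nrow(object@participants), " participants (",
      sum(object@participants$group == "A"), " A / ",
      sum(object@participants$group == "B"), " B), ",
      nrow(object@index), " repetitions indexed\n", sep = "")
})

#' In-memory cohort
#'
#' A [CohortManifest-class] plus the repetition payloads.  When read lazily
#' from disk the `repetitions` list is empty and [getRepetition()] loads
#' files on demand via the `dir` slot.
#'
#' @slot manifest a [CohortManifest-class].
#' @slot repetitions named list of [RawRepetition-class] keyed
#'   "participant/exercise/set/rep".
#' @slot tposes named list of T x 18 matrices keyed "participant/exercise".
#' @slot dir character, backing directory ("" when purely in-memory).
#' @export
setClass("Cohort",
  representation(
    manifest    = "CohortManifest",
    repetitions = "list",
    tposes      = "list",
    dir         = "character"
  )
)

setMethod("show", "Cohort", function(object) {
  cat("Cohort: ", nrow(object@manifest@index), " repetitions, ",
      length(object@repetitions), " in memory",
      if (nzchar(object@dir)) paste0(", backed by ", object@dir), "\n",
      sep = "")
})

#' Per-type standardization statistics
#'
#' Global mean and SD per signal type (grf, cop, acc, gyr), pooled over all
#' frames and channels of that type in the training split of one fold.
#' Only training-split data from the non-fatigued group may enter these
#' statistics (leakage guard).
#'
#' @slot mu,sigma named numerics over signal types; `sigma > 0`.
#' @slot fold character fold identifier.
#' @slot trainSubjects character vector of training subject ids.
#' @export
setClass("StandardizationStats",
  representation(
    mu            = "numeric",
    sigma         = "numeric",
    fold          = "character",
    trainSubjects = "character"
  )
)

setValidity("StandardizationStats", function(object) {
  if (!identical(names(object@mu), names(object@sigma))) {
    return("mu and sigma must cover the same types")
  }
  if (any(object@sigma <= 0)) {
    return(paste("degenerate type (sigma <= 0):",
                 paste(names(object@sigma)[object@sigma <= 0], collapse = ", ")))
  }
  TRUE
})

setMethod("show", "StandardizationStats", function(object) {
  cat("StandardizationStats (fold ", object@fold, "):\n", sep = "")
  for (t in names(object@mu)) {
    cat("  ", t, ": mu=", signif(object@mu[[t]], 5),
        " sigma=", signif(object@sigma[[t]], 5), "\n", sep = "")
  }
})

#' Latent prior layout
#'
#' One isotropic Gaussian mode per activity in the 2-D latent plane.  By
#' default the four modes sit equally spaced on a circle of radius `radius`
#' with shared SD `s`.
#'
#' @slot centers 4 x 2 matrix of mode centres, rows named by activity.
#' @slot s positive scalar, shared isotropic SD.
#' @export
setClass("PriorLayout",
  representation(centers = "matrix", s = "numeric")
)

setValidity("PriorLayout", function(object) {
  if (ncol(object@centers) != 2L) return("centers must be K x 2")
  if (is.null(rownames(object@centers))) return("centers rows must be named")
  d <- as.matrix(stats::dist(object@centers))
  diag(d) <- Inf
  if (any(d < 1e-9)) return("mode centers must be pairwise distinct")
  if (length(object@s) != 1L || object@s <= 0) return("s must be a positive scalar")
  TRUE
})

#' Construct a [PriorLayout-class]
#'
#' @param radius circle radius for the default equally spaced layout.
#' @param s shared isotropic mode SD.
#' @param classes activity names, in canonical order.
#' @return a `PriorLayout` object.
#' @examples
#' priorLayout()
#' @export
priorLayout <- function(radius = 4, s = 1, classes = EXERCISES) {
  k <- length(classes)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(radius * cos(ang), radius * sin(ang))
  rownames(centers) <- classes
  colnames(centers) <- c("z1", "z2")
  new("PriorLayout", centers = centers, s = s)
}

setMethod("show", "PriorLayout", function(object) {
  cat("PriorLayout: ", nrow(object@centers), " modes, s=", object@s, "\n",
      sep = "")
  print(round(object@centers, 3))
})

#' Trained adversarial autoencoder
#'
#' Holds the architecture description, learned parameters (restored to the
#' epoch with the lowest mean validation KL divergence), the latent prior,
#' the standardization provenance the model expects its inputs to carry, and
#' the per-epoch training history.
#'
#' @slot spec list, architecture description (see [aaeModelSpec()]).
#' @slot params list, parameter tree of the selected epoch.
#' @slot prior a [PriorLayout-class].
#' @slot statsProvenance character, id of the [StandardizationStats-class]
#'   used to standardize training inputs.
#' @slot history data.frame with one row per epoch (losses, per-activity
#'   validation KL, mean KL, phase "train"/"fine-tune").
#' @slot selectedEpoch integer, argmin of mean validation KL over the
#'   base-training epochs.
#' @export
setClass("TrainedAAE",
  representation(
    spec            = "list",
    params          = "list",
    prior           = "PriorLayout",
    statsProvenance = "character",
    history         = "data.frame",
    selectedEpoch   = "integer"
  )
)

setMethod("show", "TrainedAAE", function(object) {
  h <- object@history
  base <- h[h$phase == "train", , drop = FALSE]
  cat("TrainedAAE (", object@spec$variant, "): ", nrow(base),
      " training epochs, selected epoch ", object@selectedEpoch,
      if (nrow(base)) paste0(" (mean val KL ",
        signif(base$meanKL[object@selectedEpoch], 4), ")"),
      ", ", sum(h$phase == "fine-tune"), " fine-tune epochs\n", sep = "")
})

#' @describeIn TrainedAAE-class training history accessor
#' @param object a `TrainedAAE`.
#' @export
trainingHistory <- function(object) {
  stopifnot(is(object, "TrainedAAE"))
  object@history
}

#' @describeIn PriorLayout-class mode-centre accessor
#' @param object a `PriorLayout` or `TrainedAAE`.
#' @export
priorCenters <- function(object) {
  if (is(object, "TrainedAAE")) object <- object@prior
  stopifnot(is(object, "PriorLayout"))
  object@centers
}

#' @describeIn CohortManifest-class participant metadata accessor
#' @param object a `CohortManifest` or `Cohort`.
#' @export
participants <- function(object) {
  if (is(object, "Cohort")) object <- object@manifest
  stopifnot(is(object, "CohortManifest"))
  object@participants
}

#' @describeIn Cohort-class manifest accessor
#' @param object a `Cohort`.
#' @export
cohortManifest <- function(object) {
  stopifnot(is(object, "Cohort"))
  object@manifest
}
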