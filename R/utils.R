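# Internal helpers shared across modules.

#' Deterministic child seed from a master seed and a key string
#'
#' Cohort generation derives one RNG seed per (participant, exercise, set,
#' repetition) so that any sub-collection can be regenerated reproducibly
#' without replaying the whole cohort.  A simple polynomial string hash over
#' a 31-bit prime field keeps seeds stable across platforms and R versions
#' (no dependence on serialization internals).
#'
#' @param master integer master seed.
#' @param ... character or numeric key components, concatenated with "/".
#' @return integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
childSeed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  p <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- as.numeric(master) %% p
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% p
  }
  as.integer(h %% (p - 2L) + 1L)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Canonical activity order used everywhere (one-hot columns, prior modes).
EXERCISES <- c("Squat", "LungeLeft", "LungeRight", "PlankJumpIn")

assertExercise <- function(exercise) {
  if (length(exercise) != 1L || !exercise %in% EXERCISES) {
    stop("unknown exercise '", paste(exercise, collapse = ","),
         "'; expected one of: ", paste(EXERCISES, collapse = ", "),
         call. = FALSE)
  }
  exercise
}

# Stable content hash of an R object (for config provenance / resume checks).
configHash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  p <- 2147483647
  h <- 7
  for (code in utf8ToInt(as.character(json))) h <- (h * 131 + code) %% p
  sprintf("%08x", as.integer(h))
}

# 3-D rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotationAboutAxis <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

GRAVITY <- 9.80665  # m/s^2
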