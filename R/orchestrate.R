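# End-to-end experiment driver: fold construction, per-fold training and
# fine-tuning, encoding of the fatigue group, index and trend computation,
# assessment tables, and the latent-space / trend figures.

#' User-independent cross-validation folds
#'
#' Partitions the non-fatigued group's subjects into K disjoint validation
#' blocks of near-equal size; each fold trains on the remaining subjects.
#' The fatigue group never enters training or validation.
#'
#' @param subjectIds group-A subject ids.
#' @param K number of folds (>= 2, <= number of subjects).
#' @param seed integer seed for the shuffle.
#' @return list of K lists with elements `fold`, `train`, `val`.
#' @examples
#' makeFolds(sprintf("A%02d", 1:20), K = 4, seed = 1)[[1]]
#' @export
makeFolds <- function(subjectIds, K, seed = 1L) {
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (K > length(subjectIds)) {
    stop("K = ", K, " exceeds the number of subjects (", length(subjectIds),
         ")", call. = FALSE)
  }
  shuffled <- withSeed(seed, sample(subjectIds))
  blocks <- split(shuffled, rep(seq_len(K), length.out = length(shuffled)))
  lapply(seq_len(K), function(k) {
    list(fold = k - 1L, train = sort(setdiff(subjectIds, blocks[[k]])),
         val = sort(blocks[[k]]))
  })
}

#' Experiment configuration
#'
#' @param databases database variants to run ("DB0".."DB4").
#' @param variants model variants ("Res-SSAAE", "Cond-SSAAE").
#' @param K number of cross-validation folds.
#' @param cohort a [cohortConfig()] for simulation, or a directory of an
#'   existing cohort.
#' @param maxEpochs,batchSize,lr training settings (see [trainAAE()]).
#' @param fineTuneEpochs fine-tuning epochs on the fatigue group.
#' @param prior a [PriorLayout-class].
#' @param alpha significance level for the assessment counters.
#' @param figures write latent-space and trend figures.
#' @return list of class "experimentConfig".
#' @export
experimentConfig <- function(databases = "DB4",
                             variants = "Res-SSAAE",
                             K = 4L,
                             cohort = cohortConfig(),
                             maxEpochs = 300L, batchSize = 64L, lr = 1e-4,
                             fineTuneEpochs = 10L,
                             prior = priorLayout(),
                             alpha = 0.05,
                             figures = FALSE) {
  stopifnot(all(databases %in% paste0("DB", 0:4)),
            all(variants %in% c("Res-SSAAE", "Cond-SSAAE")))
  structure(list(databases = databases, variants = variants, K = as.integer(K),
                 cohort = cohort, maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 fineTuneEpochs = as.integer(fineTuneEpochs), prior = prior,
                 alpha = alpha, figures = figures),
            class = "experimentConfig")
}

# serializable view of a config (for hashing / provenance)
configForHash <- function(config, seed) {
  ser <- config
  ser$prior <- list(centers = unname(config$prior@centers), s = config$prior@s)
  if (inherits(ser$cohort, "cohortConfig")) {
    pr <- ser$cohort$profile
    ser$cohort$profile <- c(pr@amplitudeDrift, pr@noiseGrowth, pr@timingJitter,
                            pr@swayGrowth, pr@tremorGain)
  }
  ser$seed <- seed
  ser
}

# Cache helper: run `fun` producing `path` unless it already exists with a
# matching config hash (resumable pipelines).
cachedStage <- function(path, hash, resume, fun) {
  hashFile <- paste0(path, ".hash")
  if (resume && file.exists(path) && file.exists(hashFile) &&
      identical(readLines(hashFile, warn = FALSE)[1], hash)) {
    return(FALSE)  # cache hit
  }
  fun()
  writeLines(hash, hashFile)
  TRUE
}

#' Run the full fatigue-assessment experiment
#'
#' For every database x variant x fold: computes fold standardization
#' statistics from the group-A training split, trains the model on group A
#' (KL-selected checkpoint), fine-tunes on group B, encodes all group-B
#' repetitions, computes the per-set cluster indices, and fits the trend
#' regressions; finally aggregates the fold-level and ensemble significance
#' counters per database x variant.  All randomness derives from `seed`.
#' Stages whose outputs already exist with a matching configuration hash are
#' skipped when `resume = TRUE`.
#'
#' @param config an [experimentConfig()].
#' @param outDir output directory (created).
#' @param seed master seed.
#' @param resume skip stages with up-to-date outputs.
#' @param verbose print stage progress.
#' @return invisibly, a list with the assessment table (data.frame) and the
#'   paths of all written artifacts.
#' @export
runExperiment <- function(config, outDir, seed = 1L, resume = TRUE,
                          verbose = TRUE) {
  stopifnot(inherits(config, "experimentConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  hash <- configHash(configForHash(config, seed))

  # resolved config copy for provenance
  jsonlite::write_json(configForHash(config, seed),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  # --- cohort ------------------------------------------------------------
  if (inherits(config$cohort, "cohortConfig")) {
    say("simulating cohort (seed ", seed, ")")
    cohort <- generateCohort(config$cohort, seed = childSeed(seed, "cohort"))
  } else {
    say("reading cohort from ", config$cohort)
    cohort <- readCohort(config$cohort)
  }
  parts <- participants(cohort)
  groupA <- parts$id[parts$group == "A"]
  groupB <- parts$id[parts$group == "B"]
  if (!length(groupA) || !length(groupB)) {
    stop("experiment needs both a group A and a group B", call. = FALSE)
  }
  folds <- makeFolds(groupA, config$K, seed = childSeed(seed, "folds"))

  latDir <- file.path(outDir, "latents")
  dir.create(latDir, showWarnings = FALSE)
  figDir <- file.path(outDir, "figures")
  if (config$figures) dir.create(figDir, showWarnings = FALSE)

  allRecords <- list(); artifacts <- character()
  assessRows <- list()

  for (db in config$databases) {
    seAll <- assembleDataset(cohort, db)  # unstandardized, all participants
    for (variant in config$variants) {
      recs <- list()
      for (f in folds) {
        tag <- sprintf("%s_%s_fold%d", db, variant, f$fold)
        latPath <- file.path(latDir, paste0(tag, ".csv"))
        ran <- cachedStage(latPath, hash, resume, function() {
          say("  ", tag, ": train + encode")
          stats <- computeStandardization(
            seAll[, colData(seAll)$participant %in% f$train],
            trainIds = f$train, fold = as.character(f$fold))
          seStd <- standardizeDataset(seAll, stats)
          seTrain <- seStd[, colData(seStd)$participant %in% f$train]
          seVal <- seStd[, colData(seStd)$participant %in% f$val]
          seB <- seStd[, colData(seStd)$participant %in% groupB]
          spec <- aaeModelSpec(length(databaseChannels(db)), variant)
          model <- trainAAE(spec, seTrain, seVal, prior = config$prior,
                            lr = config$lr, batchSize = config$batchSize,
                            maxEpochs = config$maxEpochs,
                            seed = childSeed(seed, db, variant, f$fold, "train"))
          model <- fineTune(model, seB, epochs = config$fineTuneEpochs,
                            lr = config$lr / 10, batchSize = config$batchSize,
                            seed = childSeed(seed, db, variant, f$fold, "ft"))
          lat <- encodeDataset(model, seB)
          lat$fold <- f$fold; lat$variant <- variant; lat$database <- db
          valLat <- encodeDataset(model, seVal)
          acc <- latentAccuracy(as.matrix(valLat[, c("z1", "z2")]),
                                valLat$exercise, config$prior)
          attr(lat, "valAccuracy") <- acc
          data.table::fwrite(lat, latPath)
          writeLines(as.character(acc), paste0(latPath, ".acc"))
          if (config$figures) {
            p <- plotLatentSpace(lat, config$prior, accuracy = acc)
            ggplot2::ggsave(file.path(figDir, paste0("latent_", tag, ".png")),
                            p, width = 6, height = 5, dpi = 120)
          }
        })
        if (!ran) say("  ", tag, ": cache hit")
        lat <- as.data.frame(data.table::fread(latPath))
        recs[[tag]] <- indexTable(lat)
        artifacts <- c(artifacts, latPath)
      }
      records <- do.call(rbind, recs)
      idxPath <- file.path(outDir, sprintf("indices_%s_%s.csv", db, variant))
      data.table::fwrite(records, idxPath)
      asmt <- assessment(records, alpha = config$alpha)
      trendPath <- file.path(outDir, sprintf("trends_%s_%s.csv", db, variant))
      data.table::fwrite(asmt$trends, trendPath)
      if (config$figures) {
        p <- plotTrendGrid(records)
        ggplot2::ggsave(file.path(figDir, sprintf("trends_%s_%s.png", db, variant)),
                        p, width = 10, height = 8, dpi = 120)
      }
      assessRows[[paste(db, variant)]] <- data.frame(
        database = db, variant = variant,
        p_value_counter = asmt$counter, counter_total = asmt$counterTotal,
        p_value_ensemble = asmt$ensemble, ensemble_total = asmt$ensembleTotal)
      allRecords[[paste(db, variant)]] <- records
      artifacts <- c(artifacts, idxPath, trendPath)
    }
  }

  assessTable <- do.call(rbind, assessRows)
  rownames(assessTable) <- NULL
  jsonlite::write_json(assessTable, file.path(outDir, "assessment.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  data.table::fwrite(assessTable, file.path(outDir, "assessment.csv"))
  say("assessment written to ", file.path(outDir, "assessment.json"))
  invisible(list(assessment = assessTable, records = allRecords,
                 artifacts = c(artifacts, file.path(outDir, "assessment.json"))))
}

#' Save / load a trained model
#'
#' Serializes the parameter tree with a JSON sidecar describing the
#' architecture, prior and provenance (human-inspectable).
#'
#' @param model a [TrainedAAE-class].
#' @param path file path (.rds; sidecar written as `path.json`).
#' @return `path` (save) or the model (load).
#' @export
saveAAE <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(variant = model@spec$variant, nChannels = model@spec$nChannels,
         selectedEpoch = model@selectedEpoch,
         statsProvenance = model@statsProvenance,
         prior = list(centers = model@prior@centers, s = model@prior@s)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveAAE
#' @export
loadAAE <- function(path) readRDS(path)

LATENT_COLORS <- c(LungeRight = "#2ca02c", LungeLeft = "#d62728",
                   PlankJumpIn = "#1f77b4", Squat = "#9467bd")

#' Latent-space scatter plot
#'
#' One panel of latent points colored by activity (lunge right green, lunge
#' left red, plank jump-in blue, squat purple), with the prior modes marked
#' and the latent accuracy annotated.
#'
#' @param latents data.frame with columns z1, z2, exercise.
#' @param prior a [PriorLayout-class].
#' @param accuracy optional accuracy to annotate (fraction).
#' @param file optional output file (written via [ggplot2::ggsave()]).
#' @return a ggplot object.
#' @export
plotLatentSpace <- function(latents, prior = priorLayout(), accuracy = NULL,
                            file = NULL) {
  present <- intersect(names(LATENT_COLORS), unique(latents$exercise))
  if (length(present) < length(unique(latents$exercise))) {
    warning("classes without a colour mapping are dropped from the legend",
            call. = FALSE)
  }
  if (length(setdiff(names(LATENT_COLORS), present))) {
    warning("empty class(es) suppressed from legend: ",
            paste(setdiff(names(LATENT_COLORS), present), collapse = ", "),
            call. = FALSE)
  }
  centers <- as.data.frame(priorCenters(prior))
  p <- ggplot2::ggplot(latents, ggplot2::aes(x = .data$z1, y = .data$z2,
                                             color = .data$exercise)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = centers,
                        ggplot2::aes(x = .data$z1, y = .data$z2),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::scale_color_manual(values = LATENT_COLORS, breaks = present) +
    ggplot2::labs(x = "z1", y = "z2", color = "activity") +
    ggplot2::theme_minimal()
  if (!is.null(accuracy)) {
    p <- p + ggplot2::ggtitle(sprintf("latent accuracy: %.2f%%", 100 * accuracy))
  }
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 120)
  p
}

#' Trend regression grid
#'
#' Standardized index values against completion percentage, one panel per
#' (exercise, index) cell with the fitted line and slope / R-squared /
#' p-value annotation (significant cells in green, others in red).
#'
#' @param records data.frame from [indexTable()] (one database x variant;
#'   folds pooled via the ensemble average).
#' @param alpha significance level for the annotation colour.
#' @return a ggplot object.
#' @export
plotTrendGrid <- function(records, alpha = 0.05) {
  std <- standardizePerParticipant(foldEnsembleRecords(records))
  tt <- trendTable(foldEnsembleRecords(records), alpha = alpha)
  tt$label <- sprintf("b=%.3f R2=%.2f p=%.3g", tt$slope, tt$r2, tt$p_value)
  tt$sig <- ifelse(tt$significant, "significant", "n.s.")
  ggplot2::ggplot(std, ggplot2::aes(x = .data$completion, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, color = "black") +
    ggplot2::geom_text(data = tt, ggplot2::aes(label = .data$label,
                                               color = .data$sig),
                       x = 50, y = Inf, vjust = 1.4, size = 2.6,
                       inherit.aes = FALSE) +
    ggplot2::scale_color_manual(values = c(significant = "#2ca02c",
                                           n.s. = "#d62728")) +
    ggplot2::facet_grid(exercise ~ index) +
    ggplot2::labs(x = "completion (%)", y = "standardized index",
                  color = NULL) +
    ggplot2::theme_minimal()
}
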