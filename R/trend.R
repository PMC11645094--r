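# Completion-normalized trend regressions over cluster indices.
#
# Index values are standardized within each participant's series (indices
# live on participant-specific scales), set position is expressed as a
# percentage of completion of the whole session (last set = 100%), and one
# ordinary least-squares regression is fitted per (exercise, index) cell by
# pooling standardized values over participants.  Counts of significant
# slopes across cross-validation folds (out of K x 4 x 4) and across
# fold-averaged indices (out of 4 x 4) summarize each database x variant.

#' Percentage of completion of a set within a session
#'
#' `100 * setIndex / (totalSets - 1)`: the first set maps to 0% and the
#' final (exhaustion) set to 100%, making participants with different set
#' counts comparable.
#'
#' @param setIndex 0-based set index (vectorized).
#' @param totalSets total number of sets in the session (>= 2).
#' @return percentage in `[0, 100]`.
#' @examples
#' completionPercentage(2, 5)  # 50
#' @export
completionPercentage <- function(setIndex, totalSets) {
  if (any(totalSets < 2L)) {
    stop("totalSets must be >= 2 to define a completion percentage",
         call. = FALSE)
  }
  if (any(setIndex < 0L) || any(setIndex >= totalSets)) {
    stop("setIndex must satisfy 0 <= setIndex < totalSets", call. = FALSE)
  }
  100 * setIndex / (totalSets - 1)
}

# series grouping key columns present in an index-record table
.seriesCols <- function(records) {
  intersect(c("database", "variant", "fold", "participant", "exercise",
              "index"), names(records))
}

#' Standardize index records within each participant's series
#'
#' Z-scores the values of every (participant, exercise, index) series
#' (separately per fold/variant/database when those columns are present)
#' across its sets.  Flagged/missing records are dropped first;
#' zero-variance series are dropped with a warning rather than aborting.
#' A `completion` column (percentage, from the series' total set count) is
#' added.
#'
#' @param records data.frame from [indexTable()].
#' @return standardized records with a `completion` column.
#' @export
standardizePerParticipant <- function(records) {
  records <- records[!is.na(records$value), , drop = FALSE]
  if (!nrow(records)) return(records)

  # total sets per (participant, exercise): sets are shared across indices
  totKey <- paste(records$participant, records$exercise)
  totalSets <- tapply(records$set, totKey, max) + 1L
  records$completion <- completionPercentage(
    records$set, as.integer(totalSets[totKey]))

  key <- do.call(paste, records[.seriesCols(records)])
  mu <- tapply(records$value, key, mean)
  s <- tapply(records$value, key, stats::sd)
  degenerate <- !is.finite(s[key]) | s[key] <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " record(s) in zero-variance series dropped",
            call. = FALSE)
  }
  records <- records[!degenerate, , drop = FALSE]
  key <- key[!degenerate]
  records$value <- (records$value - mu[key]) / s[key]
  rownames(records) <- NULL
  records
}

#' Ordinary least-squares trend of an index on completion percentage
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, coefficient of
#' determination and the two-sided t-test p-value on the slope.
#'
#' @param x completion percentages (>= 3 values, not constant).
#' @param y standardized index values.
#' @return one-row data.frame: slope, intercept, r2, p_value, n_points.
#' @export
fitTrend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 points for a regression", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x: trend undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r2 = sm$r.squared, p_value = sm$coefficients[2, 4],
             n_points = length(x))
}

#' Per-cell trend regressions
#'
#' Standardizes the records per participant, then fits one pooled OLS
#' regression of standardized index value on completion percentage per
#' (exercise, index) cell, separately for each database / variant / fold
#' present.  Regressions never mix exercises or indices; cells whose data
#' are insufficient (fewer than 3 points or constant completion) are
#' returned with `NA` statistics.
#'
#' @param records data.frame from [indexTable()].
#' @param alpha significance level recorded in the `significant` column.
#' @return data.frame of trend results, one row per regression cell.
#' @export
trendTable <- function(records, alpha = 0.05) {
  std <- standardizePerParticipant(records)
  cellCols <- setdiff(.seriesCols(std), "participant")
  key <- do.call(paste, c(std[cellCols], sep = "\r"))
  rows <- lapply(unique(key), function(k) {
    sub <- std[key == k, , drop = FALSE]
    res <- tryCatch(fitTrend(sub$completion, sub$value),
                    error = function(e) {
                      data.frame(slope = NA_real_, intercept = NA_real_,
                                 r2 = NA_real_, p_value = NA_real_,
                                 n_points = nrow(sub))
                    })
    cbind(sub[1, cellCols, drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}

# Average raw index values across folds -> one "ensemble" record set.
foldEnsembleRecords <- function(records) {
  if (!"fold" %in% names(records)) {
    records$fold <- "ensemble"
    return(records)
  }
  keyCols <- setdiff(names(records), c("fold", "value", "flag"))
  key <- do.call(paste, c(records[keyCols], sep = "\r"))
  agg <- tapply(records$value, key, function(v) mean(v, na.rm = TRUE))
  first <- !duplicated(key)
  out <- records[first, keyCols, drop = FALSE]
  out$value <- as.numeric(agg[key[first]])
  out$value[is.nan(out$value)] <- NA_real_
  out$fold <- "ensemble"
  out$flag <- NA_character_
  rownames(out) <- NULL
  out
}

#' Assessment summary: significant-regression counters
#'
#' Reproduces the two bookkeeping summaries of the analysis: the p-value
#' counter (number of significant fold-level regressions out of
#' K folds x 4 exercises x 4 indices) and the p-value ensemble (the index
#' values are first averaged across the K folds per (participant, exercise,
#' set, index), then regressed, giving 4 x 4 = 16 regressions).  Raw
#' p-values are compared to `alpha`; optionally a Benjamini-Hochberg
#' correction can be applied first (off by default, matching the raw-count
#' convention).
#'
#' @param records data.frame from [indexTable()] covering all folds of one
#'   database x variant (a `fold` column distinguishes folds).
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return list with elements `counter`, `counterTotal`, `ensemble`,
#'   `ensembleTotal`, `trends` (fold-level regressions) and
#'   `ensembleTrends`.
#' @export
assessment <- function(records, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  trends <- trendTable(records, alpha = alpha)
  ens <- trendTable(foldEnsembleRecords(records), alpha = alpha)
  flagSig <- function(tt) {
    p <- tt$p_value
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    !is.na(p) & p < alpha
  }
  trends$significant <- flagSig(trends)
  ens$significant <- flagSig(ens)
  list(counter = sum(trends$significant),
       counterTotal = nrow(trends),
       ensemble = sum(ens$significant),
       ensembleTotal = nrow(ens),
       trends = trends,
       ensembleTrends = ens)
}
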