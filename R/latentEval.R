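# Cluster-drift indices over per-set latent clusters.
#
# Each set of 10 repetitions of one activity forms a cluster of 10 2-D
# latent points.  Four indices track how clusters drift away from the first
# set as fatigue accumulates: silhouette and Davies-Bouldin of set i versus
# set 0, the 95% confidence-ellipse area of set i, and the Euclidean
# distance between the centroids of set i and set 0.

#' Two-cluster silhouette score
#'
#' Mean silhouette over the pooled points of the two clusters under the
#' 2-cluster labelling with Euclidean distances: for each point,
#' `s = (b - a) / max(a, b)` where `a` is the mean distance to the other
#' members of its own cluster and `b` the mean distance to the other
#' cluster.  Coincident clusters give 0; well-separated tight clusters
#' approach 1.
#'
#' @param clusterI,cluster0 N x 2 matrices (N >= 2 each).
#' @return value in `[-1, 1]`.
#' @export
silhouettePair <- function(clusterI, cluster0) {
  if (nrow(clusterI) < 2L || nrow(cluster0) < 2L) {
    stop("each cluster needs >= 2 points", call. = FALSE)
  }
  pts <- rbind(clusterI, cluster0)
  lab <- rep(1:2, c(nrow(clusterI), nrow(cluster0)))
  D <- as.matrix(stats::dist(pts))
  s <- vapply(seq_len(nrow(pts)), function(i) {
    own <- lab == lab[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- mean(D[i, lab != lab[i]])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Two-cluster Davies-Bouldin index
#'
#' With exactly two clusters the average-of-maximum-similarities form of the
#' index reduces to the single ratio `(S_i + S_0) / d(c_i, c_0)`, where `S`
#' is the mean Euclidean distance of a cluster's points to its own centroid.
#' Lower values mean tighter, better-separated clusters.  For three or more
#' clusters use [daviesBouldin()].
#'
#' @param clusterI,cluster0 N x 2 matrices.
#' @param eps minimum centroid separation; below it the index is undefined.
#' @return value >= 0.
#' @export
daviesBouldinPair <- function(clusterI, cluster0, eps = 1e-9) {
  ci <- colMeans(clusterI); c0 <- colMeans(cluster0)
  d <- sqrt(sum((ci - c0)^2))
  if (d <= eps) {
    stop("coincident centroids: Davies-Bouldin undefined", call. = FALSE)
  }
  Si <- mean(sqrt(rowSums(sweep(clusterI, 2, ci)^2)))
  S0 <- mean(sqrt(rowSums(sweep(cluster0, 2, c0)^2)))
  (Si + S0) / d
}

#' General Davies-Bouldin index
#'
#' Standard form for any number of clusters: the mean over clusters of the
#' maximum pairwise similarity `(S_i + S_j) / d(c_i, c_j)`.  Equals
#' [daviesBouldinPair()] when exactly two clusters are given.
#'
#' @param points N x 2 matrix.
#' @param labels cluster labels, length N (>= 2 distinct values).
#' @return value >= 0.
#' @export
daviesBouldin <- function(points, labels) {
  labs <- unique(labels)
  if (length(labs) < 2L) stop("need >= 2 clusters", call. = FALSE)
  cents <- t(vapply(labs, function(l) {
    colMeans(points[labels == l, , drop = FALSE])
  }, numeric(ncol(points))))
  S <- vapply(seq_along(labs), function(i) {
    p <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(p, 2, cents[i, ])^2)))
  }, numeric(1))
  mean(vapply(seq_along(labs), function(i) {
    max(vapply(seq_along(labs)[-i], function(j) {
      d <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      if (d <= 1e-9) stop("coincident centroids: Davies-Bouldin undefined",
                          call. = FALSE)
      (S[i] + S[j]) / d
    }, numeric(1)))
  }, numeric(1)))
}

#' Area of the 95% confidence ellipse of a cluster
#'
#' Assuming the points follow a bivariate normal distribution, the ellipse
#' containing a `coverage` fraction of the probability mass has area
#' `pi * q * sqrt(det(S))`, where `q` is the chi-square quantile with 2
#' degrees of freedom at the coverage level and `S` the sample covariance.
#'
#' @param cluster N x 2 matrix (N >= 3).
#' @param coverage probability mass of the ellipse (default 0.95).
#' @param regularize add `epsilon * I` to a singular sample covariance
#'   instead of failing.
#' @param epsilon ridge used when `regularize = TRUE`.
#' @return area (squared latent units).
#' @export
ellipseArea <- function(cluster, coverage = 0.95, regularize = FALSE,
                        epsilon = 1e-8) {
  if (nrow(cluster) < 3L) {
    stop("need >= 3 points for a covariance estimate", call. = FALSE)
  }
  S <- stats::cov(cluster)
  dS <- det(S)
  if (dS <= 0) {
    if (!regularize) {
      stop("singular covariance (collinear points); set regularize = TRUE",
           call. = FALSE)
    }
    S <- S + epsilon * diag(2)
    dS <- det(S)
  }
  pi * stats::qchisq(coverage, df = 2) * sqrt(dS)
}

#' Euclidean distance between two cluster centroids
#'
#' @param clusterI,cluster0 non-empty N x 2 matrices.
#' @return value >= 0.
#' @export
centroidDistance <- function(clusterI, cluster0) {
  stopifnot(nrow(clusterI) >= 1L, nrow(cluster0) >= 1L)
  sqrt(sum((colMeans(clusterI) - colMeans(cluster0))^2))
}

#' Per-set cluster index table
#'
#' Computes, for every (participant, exercise) series of latent set
#' clusters, the 95% confidence-ellipse area of each set and the three
#' comparative indices (silhouette, Davies-Bouldin, centroid distance) of
#' each set `i >= 1` against set 0.  Degenerate cases (coincident centroids,
#' singular covariance) yield `NA` values flagged with a reason rather than
#' aborting; downstream regressions drop flagged records.
#'
#' @param latents data.frame with columns participant, exercise, set, rep,
#'   z1, z2 (e.g. from [encodeDataset()]), and optionally fold / variant
#'   columns, which are carried through.
#' @return tidy data.frame with columns participant, exercise, set, index,
#'   value, flag (plus carried columns); one row per (set, index) record.
#' @export
indexTable <- function(latents) {
  need <- c("participant", "exercise", "set", "z1", "z2")
  if (!all(need %in% names(latents))) {
    stop("latents must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  carry <- intersect(c("fold", "variant", "database"), names(latents))
  out <- list()
  for (pid in unique(latents$participant)) {
    for (ex in unique(latents$exercise[latents$participant == pid])) {
      sub <- latents[latents$participant == pid & latents$exercise == ex, ]
      sets <- sort(unique(sub$set))
      if (!0 %in% sets) {
        stop("missing set 0 for ", pid, "/", ex, call. = FALSE)
      }
      clusters <- lapply(sets, function(s) {
        as.matrix(sub[sub$set == s, c("z1", "z2")])
      })
      names(clusters) <- as.character(sets)
      c0 <- clusters[["0"]]
      emit <- function(set, index, value, flag = NA_character_) {
        row <- data.frame(participant = pid, exercise = ex, set = set,
                          index = index, value = value, flag = flag)
        for (cc in carry) row[[cc]] <- sub[[cc]][1]
        out[[length(out) + 1L]] <<- row
      }
      for (s in sets) {
        cl <- clusters[[as.character(s)]]
        area <- tryCatch(ellipseArea(cl, regularize = TRUE),
                         error = function(e) NA_real_)
        emit(s, "ellipse_area", area,
             if (is.na(area)) "degenerate_covariance" else NA_character_)
        if (s == 0) next
        sil <- tryCatch(silhouettePair(cl, c0), error = function(e) NA_real_)
        emit(s, "silhouette", sil,
             if (is.na(sil)) "too_few_points" else NA_character_)
        db <- tryCatch(daviesBouldinPair(cl, c0), error = function(e) NA_real_)
        emit(s, "davies_bouldin", db,
             if (is.na(db)) "coincident_centroids" else NA_character_)
        emit(s, "centroid_distance", centroidDistance(cl, c0))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
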