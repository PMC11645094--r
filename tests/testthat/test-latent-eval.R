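test_that("silhouette: degeneracies, limits and a fixed toy oracle", {
  # fully degenerate clusters (every point at one location): a = b = 0 -> 0
  pt <- matrix(1, 4, 2)
  expect_equal(silhouettePair(pt, pt), 0)
  # coincident but internally spread point sets score <= 0 under the
  # standard definition (the opposite cluster contains each point's copy)
  a <- matrix(c(0, 1, 0, 0, 0, 1), 3, 2)
  expect_lte(silhouettePair(a, a), 0)

  set.seed(1)
  tight1 <- randomCluster(10, c(0, 0), 0.01)
  tight2 <- randomCluster(10, c(100, 0), 0.01)
  expect_gt(silhouettePair(tight1, tight2), 0.95)

  # brute-force per-point silhouette of two fixed 3-point clusters
  c1 <- matrix(c(0, 1, 0, 0, 0, 1), 3, 2)
  c2 <- matrix(c(10, 11, 10, 10, 10, 11), 3, 2)
  pts <- rbind(c1, c2); lab <- rep(1:2, each = 3)
  sBrute <- mean(vapply(1:6, function(i) {
    d <- sqrt(rowSums(sweep(pts, 2, pts[i, ])^2))
    aI <- mean(d[lab == lab[i]][-match(i, which(lab == lab[i]))])
    bI <- mean(d[lab != lab[i]])
    (bI - aI) / max(aI, bI)
  }, numeric(1)))
  expect_equal(silhouettePair(c1, c2), sBrute, tolerance = 1e-12)

  expect_error(silhouettePair(c1[1, , drop = FALSE], c2), ">= 2")
})

test_that("Davies-Bouldin: closed cases, invariance, general form", {
  z <- matrix(0, 4, 2); o <- matrix(rep(c(3, 4), each = 4), 4, 2)
  expect_equal(daviesBouldinPair(z, o), 0)  # zero scatter

  # S_i = S_0 = 1, centroid distance 2 -> exactly 1
  sq <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4, 2)  # mean dist to centroid = 1
  expect_equal(daviesBouldinPair(sq, sweep(sq, 2, c(2, 0), `+`)), 1)

  set.seed(2)
  ca <- randomCluster(8, c(0, 0)); cb <- randomCluster(8, c(5, 1))
  expect_equal(daviesBouldinPair(2 * ca, 2 * cb), daviesBouldinPair(ca, cb),
               tolerance = 1e-12)

  # the >= 3 cluster form reduces to the pair ratio for two clusters
  pts <- rbind(ca, cb); lab <- rep(1:2, each = 8)
  expect_equal(daviesBouldin(pts, lab), daviesBouldinPair(ca, cb),
               tolerance = 1e-12)

  expect_error(daviesBouldinPair(ca, ca), "coincident")
})

test_that("confidence-ellipse area: chi-square quantile and scaling", {
  # identity sample covariance -> area pi * qchisq(.95, 2)
  base <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4, 2)
  S <- cov(base)                         # diagonal, 2/3 I
  white <- base %*% diag(1 / sqrt(diag(S)))
  expect_equal(cov(white), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ellipseArea(white), pi * qchisq(0.95, 2), tolerance = 1e-12)
  expect_equal(ellipseArea(white), 18.8227, tolerance = 1e-4)

  set.seed(3)
  cl <- randomCluster(30, c(2, 1))
  expect_equal(ellipseArea(3 * cl), 9 * ellipseArea(cl), tolerance = 1e-9)

  collinear <- cbind(1:5, 2 * (1:5))
  expect_error(ellipseArea(collinear), "singular")
  expect_gt(ellipseArea(collinear, regularize = TRUE), 0)
  expect_error(ellipseArea(cl[1:2, ]), ">= 3")
})

test_that("centroid distance basics", {
  a <- matrix(0, 5, 2)
  b <- sweep(matrix(0, 5, 2), 2, c(3, 4), `+`)
  expect_equal(centroidDistance(a, a), 0)
  expect_equal(centroidDistance(a, b), 5)
  shift <- c(-2, 7)
  expect_equal(centroidDistance(sweep(a, 2, shift, `+`),
                                sweep(b, 2, shift, `+`)), 5)
})

test_that("all four indices respect rigid motions of the latent plane", {
  set.seed(4)
  ci <- randomCluster(10, c(1, 2)); c0 <- randomCluster(10, c(-2, 0))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(x) x %*% R
  mv <- function(x) sweep(x, 2, c(5, -3), `+`)
  expect_equal(silhouettePair(rot(mv(ci)), rot(mv(c0))),
               silhouettePair(ci, c0), tolerance = 1e-10)
  expect_equal(daviesBouldinPair(rot(mv(ci)), rot(mv(c0))),
               daviesBouldinPair(ci, c0), tolerance = 1e-10)
  expect_equal(ellipseArea(rot(mv(ci))), ellipseArea(ci), tolerance = 1e-10)
  expect_equal(centroidDistance(rot(mv(ci)), rot(mv(c0))),
               centroidDistance(ci, c0), tolerance = 1e-10)
})

test_that("index table: record counts, degeneracy flags, programmed drift", {
  # 5 sets of 10 points -> 5 ellipse + 4 x 3 comparative = 17 records
  set.seed(5)
  lat <- do.call(rbind, lapply(0:4, function(s) {
    data.frame(participant = "B01", exercise = "Squat", set = s, rep = 0:9,
               z1 = rnorm(10, s), z2 = rnorm(10))
  }))
  tab <- indexTable(lat)
  expect_equal(nrow(tab), 17)
  expect_equal(sum(tab$index == "ellipse_area"), 5)
  expect_false(any(tab$set == 0 & tab$index != "ellipse_area"))

  # all sets identical point clouds: distances 0, silhouettes 0, DB flagged
  one <- randomCluster(10, c(0, 0))
  same <- do.call(rbind, lapply(0:2, function(s) {
    data.frame(participant = "B01", exercise = "Squat", set = s, rep = 0:9,
               z1 = one[, 1], z2 = one[, 2])
  }))
  tabS <- indexTable(same)
  expect_true(all(tabS$value[tabS$index == "centroid_distance"] == 0))
  expect_true(all(tabS$value[tabS$index == "silhouette"] <= 0))
  expect_true(all(is.na(tabS$value[tabS$index == "davies_bouldin"])))
  expect_true(all(tabS$flag[tabS$index == "davies_bouldin"] ==
                  "coincident_centroids"))

  # programmed linear centroid drift -> strictly increasing distances
  drift <- do.call(rbind, lapply(0:4, function(s) {
    data.frame(participant = "B01", exercise = "Squat", set = s, rep = 0:9,
               z1 = one[, 1] + s, z2 = one[, 2])
  }))
  d <- indexTable(drift)
  d <- d[d$index == "centroid_distance", ]
  expect_true(all(diff(d$value[order(d$set)]) > 0))

  expect_error(indexTable(lat[lat$set > 0, ]), "missing set 0")
})
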