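# The network engine is hand-written, so its backward passes are validated
# against finite differences and its convolution against a naive oracle.

test_that("conv1d matches a naive direct-convolution oracle", {
  set.seed(3)
  Tn <- 12L; B <- 3L; Cin <- 2L; Cout <- 4L; k <- 5L
  X <- array(rnorm(Tn * Cin * B), c(Tn, Cin, B))
  P <- fatlat:::nnConvInit(Cin, Cout, k)
  out <- fatlat:::nnConvF(fatlat:::arrToMat(X), P, Tn, B)$out
  out3 <- fatlat:::matToArr(out, Tn, B)

  pad <- (k - 1) %/% 2
  naive <- array(0, c(Tn, Cout, B))
  for (b in 1:B) for (o in 1:Cout) for (t in 1:Tn) {
    acc <- P$b[o]
    for (dk in 1:k) for (ci in 1:Cin) {
      ts <- t + dk - 1 - pad
      xv <- if (ts >= 1 && ts <= Tn) X[ts, ci, b] else 0
      acc <- acc + xv * P$W[(dk - 1) * Cin + ci, o]
    }
    naive[t, o, b] <- acc
  }
  expect_equal(out3, naive, tolerance = 1e-12)
})

test_that("pool/upsample/flatten round-trips and shapes", {
  set.seed(4)
  Tn <- 8L; B <- 2L; C <- 3L
  X <- array(rnorm(Tn * C * B), c(Tn, C, B))
  Xm <- fatlat:::arrToMat(X)

  p <- fatlat:::nnPoolF(Xm, Tn, B)
  expect_equal(nrow(p$out), Tn / 2 * B)
  pool3 <- fatlat:::matToArr(p$out, Tn / 2L, B)
  expect_equal(pool3[1, , ], pmax(X[1, , ], X[2, , ]))

  u <- fatlat:::nnUpF(Xm, Tn, B)
  up3 <- fatlat:::matToArr(u$out, 2L * Tn, B)
  expect_equal(up3[1, , ], X[1, , ])
  expect_equal(up3[2, , ], X[1, , ])
  # upsample backward sums the duplicated frames
  expect_equal(fatlat:::nnUpB(u$out), 2 * Xm)

  fl <- fatlat:::nnFlatF(Xm, Tn, B)
  expect_equal(dim(fl$out), c(Tn * C, B))
  expect_equal(fatlat:::nnFlatB(fl$out, fl$cache), Xm)
  uf <- fatlat:::nnUnflatF(fl$out, Tn, C)
  expect_equal(uf$out, Xm)
})

test_that("backpropagation matches finite differences through the full model", {
  spec <- aaeModelSpec(nChannels = 3, variant = "Cond-SSAAE",
                       convChannels = c(4L, 5L, 6L), denseUnits = 7L,
                       discUnits = 9L, embeddingDim = 2L, nFrames = 16L,
                       dropout = 0)        # dropout off: deterministic loss
  set.seed(1)
  P <- fatlat:::initAAEParams(spec, seed = 2)
  B <- 5L
  X <- array(rnorm(16 * 3 * B), c(16, 3, B))
  Xt <- fatlat:::arrToMat(X)
  y <- sample(1:4, B, replace = TRUE)
  Y <- fatlat:::oneHot(y, 4)

  lossRecon <- function(P) {
    Xin <- fatlat:::encInput(X, y, P, spec)
    ef <- fatlat:::encForward(Xin, P$enc, spec, training = TRUE)
    zin <- rbind(ef$z, P$emb[, y, drop = FALSE])
    df <- fatlat:::decForward(zin, P$dec, spec, training = TRUE)
    mean((df$out - Xt)^2)
  }
  Xin <- fatlat:::encInput(X, y, P, spec)
  ef <- fatlat:::encForward(Xin, P$enc, spec, training = TRUE)
  zin <- rbind(ef$z, P$emb[, y, drop = FALSE])
  df <- fatlat:::decForward(zin, P$dec, spec, training = TRUE)
  db <- fatlat:::decBackward(2 * (df$out - Xt) / length(Xt), P$dec, df$cache)
  eb <- fatlat:::encBackward(db$dZin[1:2, , drop = FALSE], P$enc, ef$cache)
  dEmb <- db$dZin[-(1:2), , drop = FALSE] +
    fatlat:::embGradFromInput(eb$dX, spec, B)
  ana <- list(enc = eb$grads, dec = db$grads,
              emb = fatlat:::scatterEmb(dEmb, y, dim(P$emb)))

  # scan whole leaves; median relative error must be tiny (individual
  # entries can disagree when a +/-h step crosses a ReLU/max-pool kink)
  h <- 1e-6
  checkLeaf <- function(top, path) {
    g <- ana[[top]]; for (nm in path) g <- g[[nm]]
    idx <- seq_along(g)
    if (length(idx) > 25) { set.seed(7); idx <- sample(idx, 25) }
    rel <- vapply(idx, function(i) {
      Pp <- P; Pm <- P
      leaf <- function(Q, d) {
        path2 <- c(top, path)
        ref <- Q
        for (nm in path2[-length(path2)]) ref <- ref[[nm]]
        # modify by rebuilding the nested list
        assignNested <- function(node, keys, val) {
          if (!length(keys)) return(val)
          node[[keys[1]]] <- assignNested(node[[keys[1]]], keys[-1], val)
          node
        }
        x <- ref[[path2[length(path2)]]]
        x[i] <- x[i] + d
        assignNested(Q, path2, x)
      }
      num <- (lossRecon(leaf(P, h)) - lossRecon(leaf(P, -h))) / (2 * h)
      abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-7)
    }, numeric(1))
    stats::median(rel)
  }
  expect_lt(checkLeaf("enc", c("b1", "c1", "W")), 1e-5)
  expect_lt(checkLeaf("enc", c("b2", "proj", "W")), 1e-5)
  expect_lt(checkLeaf("enc", c("b3", "bn2", "gamma")), 1e-5)
  expect_lt(checkLeaf("enc", c("d2", "W")), 1e-5)
  expect_lt(checkLeaf("dec", c("d1", "W")), 1e-5)
  # (conv biases feeding batch norm have an exactly-zero gradient -- the
  # normalization absorbs them -- so weight leaves are checked instead)
  expect_lt(checkLeaf("dec", c("b1", "c2", "W")), 1e-5)
  expect_lt(checkLeaf("dec", c("head", "W")), 1e-5)
  expect_lt(checkLeaf("emb", character(0)), 1e-5)
})

test_that("discriminator gradients and cross-entropy at chance level", {
  spec <- aaeModelSpec(nChannels = 3, convChannels = c(4L, 5L, 6L),
                       denseUnits = 7L, discUnits = 9L, nFrames = 16L,
                       dropout = 0)
  set.seed(2)
  P <- fatlat:::initAAEParams(spec, seed = 3)
  B <- 6L
  z <- matrix(rnorm(2 * B), 2, B)
  Y <- fatlat:::oneHot(sample(1:4, B, replace = TRUE), 4)

  lossD <- function(P) {
    f <- fatlat:::discForward(rbind(z, Y), P$disc, spec, training = TRUE)
    mean(fatlat:::softplus(-f$logits))
  }
  f <- fatlat:::discForward(rbind(z, Y), P$disc, spec, training = TRUE)
  a <- 1 / (1 + exp(-f$logits))
  g <- fatlat:::discBackward((a - 1) / B, P$disc, f$cache)$grads
  h <- 1e-6
  num <- vapply(seq_along(g$d1$W)[1:20], function(i) {
    Pp <- P; Pp$disc$d1$W[i] <- Pp$disc$d1$W[i] + h
    Pm <- P; Pm$disc$d1$W[i] <- Pm$disc$d1$W[i] - h
    (lossD(Pp) - lossD(Pm)) / (2 * h)
  }, numeric(1))
  expect_equal(num, as.vector(g$d1$W)[1:20], tolerance = 1e-5)

  # with a zeroed output layer the discriminator is exactly at chance:
  # binary cross-entropy of ln 2 per sample on balanced real/fake input
  P$disc$d3$W[] <- 0; P$disc$d3$b[] <- 0
  fR <- fatlat:::discForward(rbind(z, Y), P$disc, spec, training = TRUE)
  lD <- mean(fatlat:::softplus(-fR$logits)) + mean(fatlat:::softplus(fR$logits))
  expect_equal(lD, 2 * log(2), tolerance = 1e-12)
})
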