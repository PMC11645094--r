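# Semi-supervised and conditional adversarial autoencoders.
#
# Both variants share the backbone: a 1-D residual convolutional encoder
# (16/32/64 channels, kernel 5x1, max-pool 2x1 between blocks, dense 128,
# linear 2-unit latent), a symmetric decoder with a linear reconstruction
# head, and a discriminator of two 512-unit sigmoid dense layers operating
# on latent codes paired with the one-hot activity label.  Semi-supervision
# enters through the adversarial phase: the "real" latent samples shown to
# the discriminator are drawn from the prior mode of each item's own label,
# so fooling the discriminator pulls every activity toward its own Gaussian
# mode.  The conditional variant additionally feeds a learned label
# embedding to the encoder (as extra input channels) and decoder.

#' Architecture description for the adversarial autoencoder
#'
#' @param nChannels number of input channels (the database variant's n).
#' @param variant "Res-SSAAE" (semi-supervised) or "Cond-SSAAE" (adds the
#'   activity-label embedding as conditional input).
#' @param convChannels output channels of the three residual blocks.
#' @param denseUnits width of the dense layer before the latent layer.
#' @param latentDim latent dimension (2 throughout the analysis).
#' @param kernel convolution kernel length (5).
#' @param dropout dropout rate (0.1).
#' @param discUnits discriminator hidden width (512).
#' @param embeddingDim label-embedding width for the conditional variant.
#' @param nFrames input frames, divisible by 8 (three pooling stages).
#' @param classes activity names.
#' @return list of class "aaeModelSpec".
#' @export
aaeModelSpec <- function(nChannels, variant = c("Res-SSAAE", "Cond-SSAAE"),
                         convChannels = c(16L, 32L, 64L), denseUnits = 128L,
                         latentDim = 2L, kernel = 5L, dropout = 0.1,
                         discUnits = 512L, embeddingDim = 8L,
                         nFrames = N_FRAMES, classes = EXERCISES) {
  variant <- match.arg(variant)
  if (nFrames %% 8L != 0L) {
    stop("nFrames must be divisible by 8 (three 2x1 pooling stages)",
         call. = FALSE)
  }
  structure(list(nChannels = as.integer(nChannels), variant = variant,
                 convChannels = as.integer(convChannels),
                 denseUnits = as.integer(denseUnits),
                 latentDim = as.integer(latentDim), kernel = as.integer(kernel),
                 dropout = dropout, discUnits = as.integer(discUnits),
                 embeddingDim = as.integer(embeddingDim),
                 nFrames = as.integer(nFrames), classes = classes),
            class = "aaeModelSpec")
}

initAAEParams <- function(spec, seed = 1) {
  withSeed(seed, {
    k <- spec$kernel
    cc <- spec$convChannels
    cin <- spec$nChannels +
      if (spec$variant == "Cond-SSAAE") spec$embeddingDim else 0L
    t3 <- spec$nFrames %/% 8L
    flat <- t3 * cc[3]
    dz <- spec$latentDim +
      if (spec$variant == "Cond-SSAAE") spec$embeddingDim else 0L
    P <- list(
      enc = list(
        b1 = nnResInit(cin, cc[1], k),
        b2 = nnResInit(cc[1], cc[2], k),
        b3 = nnResInit(cc[2], cc[3], k),
        d1 = nnDenseInit(flat, spec$denseUnits),
        bnD = nnBnInit(spec$denseUnits),
        d2 = nnDenseInit(spec$denseUnits, spec$latentDim, scale = 0.05)),
      dec = list(
        d1 = nnDenseInit(dz, spec$denseUnits),
        bn1 = nnBnInit(spec$denseUnits),
        d2 = nnDenseInit(spec$denseUnits, flat),
        bn2 = nnBnInit(flat),
        b1 = nnResInit(cc[3], cc[2], k),
        b2 = nnResInit(cc[2], cc[1], k),
        b3 = nnResInit(cc[1], cc[1], k),
        head = nnConvInit(cc[1], spec$nChannels, k)),
      disc = list(
        d1 = nnDenseInit(spec$latentDim + length(spec$classes), spec$discUnits),
        bn1 = nnBnInit(spec$discUnits),
        d2 = nnDenseInit(spec$discUnits, spec$discUnits),
        bn2 = nnBnInit(spec$discUnits),
        d3 = nnDenseInit(spec$discUnits, 1L)))
    if (spec$variant == "Cond-SSAAE") {
      P$emb <- matrix(rnorm(spec$embeddingDim * length(spec$classes), 0, 0.5),
                      spec$embeddingDim, length(spec$classes))
    }
    P
  })
}

# Assemble the encoder input matrix (T*B, C [+E]) from a (T, C, B) batch
# array, appending the broadcast label embedding for Cond-SSAAE.
encInput <- function(X, labels, P, spec) {
  Xm <- arrToMat(X)
  if (spec$variant != "Cond-SSAAE") return(Xm)
  Tn <- dim(X)[1]; B <- dim(X)[3]
  embRows <- t(P$emb[, labels, drop = FALSE])[rep(seq_len(B), each = Tn), ,
                                              drop = FALSE]
  cbind(Xm, embRows)
}

encForward <- function(Xin, P, spec, training) {
  drp <- spec$dropout
  Tn <- spec$nFrames
  B <- nrow(Xin) %/% Tn
  r1 <- nnResF(Xin, P$b1, training, drp, Tn, B); P$b1 <- r1$P
  p1 <- nnPoolF(r1$out, Tn, B)
  r2 <- nnResF(p1$out, P$b2, training, drp, Tn %/% 2L, B); P$b2 <- r2$P
  p2 <- nnPoolF(r2$out, Tn %/% 2L, B)
  r3 <- nnResF(p2$out, P$b3, training, drp, Tn %/% 4L, B); P$b3 <- r3$P
  p3 <- nnPoolF(r3$out, Tn %/% 4L, B)
  fl <- nnFlatF(p3$out, Tn %/% 8L, B)
  h <- nnDenseF(fl$out, P$d1)
  bn <- nnBnF2(h$out, P$bnD, training); P$bnD <- bn$P
  re <- nnReluF(bn$out)
  dr <- nnDropF(re$out, drp, training)
  z <- nnDenseF(dr$out, P$d2)
  list(z = z$out, P = P,
       cache = list(r1 = r1$cache, p1 = p1$cache, r2 = r2$cache,
                    p2 = p2$cache, r3 = r3$cache, p3 = p3$cache,
                    fl = fl$cache, h = h$cache, bn = bn$cache,
                    re = re$cache, dr = dr$cache, z = z$cache))
}

encBackward <- function(dZ, P, cache) {
  z <- nnDenseB(dZ, P$d2, cache$z)
  ddr <- nnDropB(z$dX, cache$dr)
  dre <- nnReluB(ddr, cache$re)
  bn <- nnBnB2(dre, P$bnD, cache$bn)
  h <- nnDenseB(bn$dX, P$d1, cache$h)
  dfl <- nnFlatB(h$dX, cache$fl)
  dp3 <- nnPoolB(dfl, cache$p3)
  r3 <- nnResB(dp3, P$b3, cache$r3)
  dp2 <- nnPoolB(r3$dX, cache$p2)
  r2 <- nnResB(dp2, P$b2, cache$r2)
  dp1 <- nnPoolB(r2$dX, cache$p1)
  r1 <- nnResB(dp1, P$b1, cache$r1)
  list(dX = r1$dX,
       grads = list(b1 = r1$grads, b2 = r2$grads, b3 = r3$grads,
                    d1 = h$grads, bnD = bn$grads, d2 = z$grads))
}

decForward <- function(zin, P, spec, training) {
  drp <- spec$dropout
  t3 <- spec$nFrames %/% 8L
  cc <- spec$convChannels
  h1 <- nnDenseF(zin, P$d1)
  b1 <- nnBnF2(h1$out, P$bn1, training); P$bn1 <- b1$P
  re1 <- nnReluF(b1$out)
  dr1 <- nnDropF(re1$out, drp, training)
  h2 <- nnDenseF(dr1$out, P$d2)
  b2 <- nnBnF2(h2$out, P$bn2, training); P$bn2 <- b2$P
  re2 <- nnReluF(b2$out)
  dr2 <- nnDropF(re2$out, drp, training)
  B <- ncol(zin)
  uf <- nnUnflatF(dr2$out, t3, cc[3])
  u1 <- nnUpF(uf$out, t3, B)
  rb1 <- nnResF(u1$out, P$b1, training, drp, 2L * t3, B); P$b1 <- rb1$P
  u2 <- nnUpF(rb1$out, 2L * t3, B)
  rb2 <- nnResF(u2$out, P$b2, training, drp, 4L * t3, B); P$b2 <- rb2$P
  u3 <- nnUpF(rb2$out, 4L * t3, B)
  rb3 <- nnResF(u3$out, P$b3, training, drp, 8L * t3, B); P$b3 <- rb3$P
  out <- nnConvF(rb3$out, P$head, 8L * t3, B)
  list(out = out$out, P = P,
       cache = list(h1 = h1$cache, b1 = b1$cache, re1 = re1$cache,
                    dr1 = dr1$cache, h2 = h2$cache, b2 = b2$cache,
                    re2 = re2$cache, dr2 = dr2$cache, uf = uf$cache,
                    rb1 = rb1$cache, rb2 = rb2$cache, rb3 = rb3$cache,
                    head = out$cache))
}

decBackward <- function(dOut, P, cache) {
  hd <- nnConvB(dOut, P$head, cache$head)
  rb3 <- nnResB(hd$dX, P$b3, cache$rb3)
  du3 <- nnUpB(rb3$dX)
  rb2 <- nnResB(du3, P$b2, cache$rb2)
  du2 <- nnUpB(rb2$dX)
  rb1 <- nnResB(du2, P$b1, cache$rb1)
  du1 <- nnUpB(rb1$dX)
  dflat <- nnUnflatB(du1, cache$uf)
  ddr2 <- nnDropB(dflat, cache$dr2)
  dre2 <- nnReluB(ddr2, cache$re2)
  b2 <- nnBnB2(dre2, P$bn2, cache$b2)
  h2 <- nnDenseB(b2$dX, P$d2, cache$h2)
  ddr1 <- nnDropB(h2$dX, cache$dr1)
  dre1 <- nnReluB(ddr1, cache$re1)
  b1 <- nnBnB2(dre1, P$bn1, cache$b1)
  h1 <- nnDenseB(b1$dX, P$d1, cache$h1)
  list(dZin = h1$dX,
       grads = list(d1 = h1$grads, bn1 = b1$grads, d2 = h2$grads,
                    bn2 = b2$grads, b1 = rb1$grads, b2 = rb2$grads,
                    b3 = rb3$grads, head = hd$grads))
}

discForward <- function(zy, P, spec, training) {
  drp <- spec$dropout
  h1 <- nnDenseF(zy, P$d1)
  b1 <- nnBnF2(h1$out, P$bn1, training); P$bn1 <- b1$P
  s1 <- nnSigF(b1$out)
  dr1 <- nnDropF(s1$out, drp, training)
  h2 <- nnDenseF(dr1$out, P$d2)
  b2 <- nnBnF2(h2$out, P$bn2, training); P$bn2 <- b2$P
  s2 <- nnSigF(b2$out)
  dr2 <- nnDropF(s2$out, drp, training)
  u <- nnDenseF(dr2$out, P$d3)
  list(logits = u$out, P = P,
       cache = list(h1 = h1$cache, b1 = b1$cache, s1 = s1$cache,
                    dr1 = dr1$cache, h2 = h2$cache, b2 = b2$cache,
                    s2 = s2$cache, dr2 = dr2$cache, u = u$cache))
}

discBackward <- function(dU, P, cache) {
  u <- nnDenseB(dU, P$d3, cache$u)
  ddr2 <- nnDropB(u$dX, cache$dr2)
  ds2 <- nnSigB(ddr2, cache$s2)
  b2 <- nnBnB2(ds2, P$bn2, cache$b2)
  h2 <- nnDenseB(b2$dX, P$d2, cache$h2)
  ddr1 <- nnDropB(h2$dX, cache$dr1)
  ds1 <- nnSigB(ddr1, cache$s1)
  b1 <- nnBnB2(ds1, P$bn1, cache$b1)
  h1 <- nnDenseB(b1$dX, P$d1, cache$h1)
  list(dZy = h1$dX,
       grads = list(d1 = h1$grads, bn1 = b1$grads, d2 = h2$grads,
                    bn2 = b2$grads, d3 = u$grads))
}

oneHot <- function(labels, nClasses) {
  out <- matrix(0, nClasses, length(labels))
  out[cbind(labels, seq_along(labels))] <- 1
  out
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Sample latent points from an activity's prior mode
#'
#' @param prior a [PriorLayout-class].
#' @param class activity name (a row of the prior's centres).
#' @param count number of draws.
#' @param seed integer seed.
#' @return count x 2 matrix.
#' @examples
#' samplePrior(priorLayout(), "Squat", 5, seed = 1)
#' @export
samplePrior <- function(prior, class, count, seed) {
  if (!class %in% rownames(prior@centers)) {
    stop("unknown class '", class, "'", call. = FALSE)
  }
  mu <- prior@centers[class, ]
  withSeed(seed, {
    cbind(z1 = rnorm(count, mu[1], prior@s), z2 = rnorm(count, mu[2], prior@s))
  })
}

#' Closed-form KL divergence of a latent cluster from its prior mode
#'
#' Fits a Gaussian (sample mean, sample covariance) to the points of one
#' activity and returns `KL(N(m, S) || N(mu_c, s^2 I))` in nats using the
#' closed form for two Gaussians.  A ridge `epsilon * I` is added when the
#' sample covariance is near-singular.
#'
#' @param points N x 2 matrix of latent points (N >= 3).
#' @param class activity name.
#' @param prior a [PriorLayout-class].
#' @param epsilon covariance regularizer used only when needed.
#' @return KL divergence (nats).
#' @export
klToPrior <- function(points, class, prior, epsilon = 1e-6) {
  if (nrow(points) < 3L) {
    stop("need >= 3 points to fit a Gaussian, got ", nrow(points), call. = FALSE)
  }
  mu1 <- prior@centers[class, ]
  s2 <- prior@s^2
  m <- colMeans(points)
  S <- stats::cov(points)
  if (!is.finite(det(S)) || det(S) < epsilon^2) S <- S + epsilon * diag(2)
  d <- 2
  delta <- m - mu1
  0.5 * (sum(diag(S)) / s2 + sum(delta^2) / s2 - d +
         d * log(s2) - determinant(S, logarithm = TRUE)$modulus[1])
}

#' Latent-space accuracy
#'
#' Fraction of latent points whose nearest prior mode (Euclidean distance)
#' is the mode of their true activity.
#'
#' @param z N x 2 matrix of latent points.
#' @param labels activity names (character or factor), length N.
#' @param prior a [PriorLayout-class].
#' @return fraction in `[0, 1]`.
#' @export
latentAccuracy <- function(z, labels, prior) {
  stopifnot(nrow(z) >= 1L)
  centers <- prior@centers
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) -
    2 * z %*% t(centers) +
    outer(rep(1, nrow(z)), rowSums(centers^2))
  pred <- rownames(centers)[max.col(-d2, ties.method = "first")]
  mean(pred == as.character(labels))
}

# Deterministic (inference-mode) encoding of a (T, C, B) array.
encodeArray <- function(params, spec, X, labels = NULL, chunk = 512L) {
  B <- dim(X)[3]
  if (spec$variant == "Cond-SSAAE" && is.null(labels)) {
    stop("Cond-SSAAE requires the activity label to encode", call. = FALSE)
  }
  out <- matrix(0, B, spec$latentDim)
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    Xin <- encInput(X[, , idx, drop = FALSE], labels[idx], params, spec)
    out[idx, ] <- t(encForward(Xin, params$enc, spec, training = FALSE)$z)
  }
  colnames(out) <- c("z1", "z2")
  out
}

#' Encode a processed dataset into the latent plane
#'
#' Runs the encoder in inference mode (dropout off, batch normalization
#' using running statistics), so encoding is deterministic and independent
#' of batching.  The conditional variant requires the activity labels, which
#' are taken from the dataset's `colData`.
#'
#' @param model a [TrainedAAE-class].
#' @param se standardized `SummarizedExperiment` from [assembleDataset()].
#' @return data.frame with columns participant, exercise, set, rep, z1, z2.
#' @export
encodeDataset <- function(model, se) {
  checkProvenance(model, se)
  X <- datasetArray(se)
  labels <- as.integer(SummarizedExperiment::colData(se)$exercise)
  z <- encodeArray(model@params, model@spec, X, labels)
  cd <- SummarizedExperiment::colData(se)
  data.frame(participant = cd$participant,
             exercise = as.character(cd$exercise),
             set = cd$set, rep = cd$rep, z1 = z[, 1], z2 = z[, 2])
}

checkProvenance <- function(model, se) {
  prov <- S4Vectors::metadata(se)$statsProvenance
  if (is.null(prov) || !isTRUE(S4Vectors::metadata(se)$standardized)) {
    stop("dataset must be standardized before encoding/training", call. = FALSE)
  }
  if (length(model@statsProvenance) && model@statsProvenance != prov) {
    stop("standardization provenance mismatch: model expects fold '",
         model@statsProvenance, "', data carry fold '", prov, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

# One full pass over the training batches (recon / discriminator / generator
# phases per batch).  Mutates nothing: returns updated params + optimizer
# state + mean losses.
aaeEpoch <- function(P, opt, X, labels, spec, prior, lr, batchSize) {
  B <- dim(X)[3]
  perm <- sample.int(B)
  nb <- 0L
  losses <- c(recon = 0, disc = 0, gen = 0)
  nClasses <- length(spec$classes)
  centers <- prior@centers

  for (start in seq(1L, B, by = batchSize)) {
    idx <- perm[start:min(start + batchSize - 1L, B)]
    if (length(idx) < 2L) next   # batch norm needs >= 2 samples
    nb <- nb + 1L
    Xb <- X[, , idx, drop = FALSE]
    Xt <- arrToMat(Xb)                    # reconstruction target
    yb <- labels[idx]
    nB <- length(idx)
    Y <- oneHot(yb, nClasses)

    # --- phase 1: reconstruction -----------------------------------------
    Xin <- encInput(Xb, yb, P, spec)
    ef <- encForward(Xin, P$enc, spec, training = TRUE); P$enc <- ef$P
    zin <- if (spec$variant == "Cond-SSAAE") {
      rbind(ef$z, P$emb[, yb, drop = FALSE])
    } else ef$z
    df <- decForward(zin, P$dec, spec, training = TRUE); P$dec <- df$P
    resid <- df$out - Xt
    lRec <- mean(resid^2)
    if (!is.finite(lRec)) {
      stop("non-finite reconstruction loss at batch ", nb,
           " (consider a lower learning rate)", call. = FALSE)
    }
    db <- decBackward(2 * resid / length(resid), P$dec, df$cache)
    dZ <- db$dZin[seq_len(spec$latentDim), , drop = FALSE]
    eb <- encBackward(dZ, P$enc, ef$cache)
    grads <- list(enc = eb$grads, dec = db$grads)
    if (spec$variant == "Cond-SSAAE") {
      dEmb <- db$dZin[-seq_len(spec$latentDim), , drop = FALSE] +
        embGradFromInput(eb$dX, spec, nB)
      grads$emb <- scatterEmb(dEmb, yb, dim(P$emb))
    }
    opt$tAE <- opt$tAE + 1L
    for (part in intersect(names(grads), c("enc", "dec", "emb"))) {
      r <- adamStep(P[[part]], grads[[part]], opt$ae[[part]], lr, opt$tAE)
      P[[part]] <- r$p; opt$ae[[part]] <- r$s
    }
    losses["recon"] <- losses["recon"] + lRec

    # --- phase 2: discriminator ------------------------------------------
    zPrior <- centers[yb, , drop = FALSE] +
      matrix(rnorm(2 * nB, 0, prior@s), nB, 2)
    Xin <- encInput(Xb, yb, P, spec)
    zFake <- encForward(Xin, P$enc, spec, training = TRUE)$z  # detached
    fR <- discForward(rbind(t(zPrior), Y), P$disc, spec, TRUE); P$disc <- fR$P
    fF <- discForward(rbind(zFake, Y), P$disc, spec, TRUE); P$disc <- fF$P
    aR <- 1 / (1 + exp(-fR$logits)); aF <- 1 / (1 + exp(-fF$logits))
    lDisc <- mean(softplus(-fR$logits)) + mean(softplus(fF$logits))
    bR <- discBackward((aR - 1) / nB, P$disc, fR$cache)
    bF <- discBackward(aF / nB, P$disc, fF$cache)
    opt$tD <- opt$tD + 1L
    r <- adamStep(P$disc, gradAdd(bR$grads, bF$grads), opt$disc, lr, opt$tD)
    P$disc <- r$p; opt$disc <- r$s
    losses["disc"] <- losses["disc"] + lDisc

    # --- phase 3: generator (encoder fools the discriminator) ------------
    Xin <- encInput(Xb, yb, P, spec)
    ef <- encForward(Xin, P$enc, spec, training = TRUE); P$enc <- ef$P
    fG <- discForward(rbind(ef$z, Y), P$disc, spec, TRUE)  # disc state frozen
    aG <- 1 / (1 + exp(-fG$logits))
    lGen <- mean(softplus(-fG$logits))
    bG <- discBackward((aG - 1) / nB, P$disc, fG$cache)
    dZ <- bG$dZy[seq_len(spec$latentDim), , drop = FALSE]
    eb <- encBackward(dZ, P$enc, ef$cache)
    gradsG <- list(enc = eb$grads)
    if (spec$variant == "Cond-SSAAE") {
      gradsG$emb <- scatterEmb(embGradFromInput(eb$dX, spec, nB), yb, dim(P$emb))
    }
    opt$tAE <- opt$tAE + 1L
    for (part in names(gradsG)) {
      r <- adamStep(P[[part]], gradsG[[part]], opt$ae[[part]], lr, opt$tAE)
      P[[part]] <- r$p; opt$ae[[part]] <- r$s
    }
    losses["gen"] <- losses["gen"] + lGen
  }
  list(P = P, opt = opt, losses = losses / max(nb, 1L))
}

# gradient wrt the embedding block of the encoder input: sum over frames
embGradFromInput <- function(dXin, spec, B) {
  E <- spec$embeddingDim
  C <- ncol(dXin)
  Tn <- nrow(dXin) %/% B
  block <- dXin[, (C - E + 1L):C, drop = FALSE]
  t(rowsum(block, rep(seq_len(B), each = Tn)))
}

scatterEmb <- function(dEmbPerItem, labels, dimEmb) {
  out <- matrix(0, dimEmb[1], dimEmb[2])
  for (b in seq_along(labels)) {
    out[, labels[b]] <- out[, labels[b]] + dEmbPerItem[, b]
  }
  out
}

# Mean validation KL across activities (activities with < 3 points are
# excluded with a warning).
validationKL <- function(P, spec, prior, Xval, labelsVal) {
  z <- encodeArray(P, spec, Xval, labelsVal)
  kls <- setNames(rep(NA_real_, length(spec$classes)), spec$classes)
  for (ci in seq_along(spec$classes)) {
    sel <- labelsVal == ci
    if (sum(sel) < 3L) {
      warning("validation activity '", spec$classes[ci],
              "' has < 3 points; excluded from mean KL", call. = FALSE)
      next
    }
    kls[ci] <- klToPrior(z[sel, , drop = FALSE], spec$classes[ci], prior)
  }
  kls
}

#' Train an adversarial autoencoder
#'
#' Alternates three phases per batch: (1) reconstruction (encoder + decoder
#' minimize mean squared error), (2) regularization (the discriminator
#' learns to tell prior samples, drawn from each item's labelled mode, from
#' encoder outputs, both paired with the one-hot label), (3) the encoder is
#' updated to fool the discriminator.  After each epoch the validation set
#' is encoded, the KL divergence to the prior is computed per activity, and
#' the parameters of the epoch with the lowest mean validation KL are
#' retained (early-stopping by checkpoint).
#'
#' @param spec an [aaeModelSpec()].
#' @param trainSe,valSe standardized subject-disjoint
#'   `SummarizedExperiment`s from [assembleDataset()].
#' @param prior a [PriorLayout-class].
#' @param lr Adam learning rate (default 1e-4).
#' @param batchSize mini-batch size (default 64).
#' @param maxEpochs training epoch budget (default 300).
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and prior draws.
#' @param verbose print per-epoch losses.
#' @return a [TrainedAAE-class].
#' @export
trainAAE <- function(spec, trainSe, valSe, prior = priorLayout(),
                     lr = 1e-4, batchSize = 64L, maxEpochs = 300L,
                     seed = 1L, verbose = FALSE) {
  trainIds <- unique(SummarizedExperiment::colData(trainSe)$participant)
  valIds <- unique(SummarizedExperiment::colData(valSe)$participant)
  if (length(intersect(trainIds, valIds))) {
    stop("train and validation sets must be subject-disjoint", call. = FALSE)
  }
  prov <- S4Vectors::metadata(trainSe)$statsProvenance
  if (is.null(prov)) stop("training data must be standardized", call. = FALSE)

  X <- datasetArray(trainSe)
  labels <- as.integer(SummarizedExperiment::colData(trainSe)$exercise)
  Xval <- datasetArray(valSe)
  labelsVal <- as.integer(SummarizedExperiment::colData(valSe)$exercise)

  P <- initAAEParams(spec, seed = childSeed(seed, "init"))
  opt <- list(ae = list(enc = adamInit(P$enc), dec = adamInit(P$dec),
                        emb = if (!is.null(P$emb)) adamInit(P$emb)),
              disc = adamInit(P$disc), tAE = 0L, tD = 0L)

  hist <- list()
  best <- list(kl = Inf, P = deepCopyParams(P), epoch = 0L)
  withSeed(childSeed(seed, "loop"), {
    for (epoch in seq_len(maxEpochs)) {
      r <- aaeEpoch(P, opt, X, labels, spec, prior, lr, batchSize)
      P <- r$P; opt <- r$opt
      kls <- validationKL(P, spec, prior, Xval, labelsVal)
      meanKL <- mean(kls, na.rm = TRUE)
      hist[[epoch]] <- data.frame(
        epoch = epoch, phase = "train", recon = r$losses[["recon"]],
        disc = r$losses[["disc"]], gen = r$losses[["gen"]],
        t(setNames(kls, paste0("kl_", spec$classes))), meanKL = meanKL)
      if (is.finite(meanKL) && meanKL < best$kl) {
        best <- list(kl = meanKL, P = deepCopyParams(P), epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  recon %.4f  disc %.4f  gen %.4f  KL %.3f",
                        epoch, r$losses[["recon"]], r$losses[["disc"]],
                        r$losses[["gen"]], meanKL))
      }
    }
  })
  new("TrainedAAE", spec = unclass(spec), params = best$P, prior = prior,
      statsProvenance = as.character(prov),
      history = do.call(rbind, hist), selectedEpoch = best$epoch)
}

#' Fine-tune a trained model on the fatigue group
#'
#' Runs the same three-phase loop for a fixed number of epochs (default 10)
#' at a learning rate ten times lower than the base one, starting from the
#' selected checkpoint.  No epoch selection is applied; the final parameters
#' are kept and the history rows are flagged as "fine-tune".
#'
#' @param model a [TrainedAAE-class].
#' @param se standardized dataset of the fatigue group (same fold statistics
#'   as the model; enforced).
#' @param epochs fine-tuning epochs (default 10).
#' @param lr learning rate (default base 1e-4 divided by 10).
#' @param batchSize mini-batch size.
#' @param seed integer seed.
#' @return the updated [TrainedAAE-class].
#' @export
fineTune <- function(model, se, epochs = 10L, lr = 1e-5, batchSize = 64L,
                     seed = 1L) {
  checkProvenance(model, se)
  if (epochs == 0L) return(model)
  spec <- model@spec
  X <- datasetArray(se)
  labels <- as.integer(SummarizedExperiment::colData(se)$exercise)
  P <- deepCopyParams(model@params)
  opt <- list(ae = list(enc = adamInit(P$enc), dec = adamInit(P$dec),
                        emb = if (!is.null(P$emb)) adamInit(P$emb)),
              disc = adamInit(P$disc), tAE = 0L, tD = 0L)
  hist <- list()
  prior <- model@prior
  withSeed(childSeed(seed, "finetune"), {
    for (epoch in seq_len(epochs)) {
      r <- aaeEpoch(P, opt, X, labels, spec, prior, lr, batchSize)
      P <- r$P; opt <- r$opt
      hist[[epoch]] <- data.frame(
        epoch = epoch, phase = "fine-tune", recon = r$losses[["recon"]],
        disc = r$losses[["disc"]], gen = r$losses[["gen"]],
        t(setNames(rep(NA_real_, length(spec$classes)),
                   paste0("kl_", spec$classes))), meanKL = NA_real_)
    }
  })
  model@params <- P
  model@history <- rbind(model@history, do.call(rbind, hist))
  model
}

#' Reconstruct a processed dataset (inference mode)
#'
#' @param model a [TrainedAAE-class].
#' @param se standardized dataset.
#' @return array (frames x channels x repetitions) of reconstructions.
#' @export
reconstructDataset <- function(model, se) {
  checkProvenance(model, se)
  spec <- model@spec
  X <- datasetArray(se)
  labels <- as.integer(SummarizedExperiment::colData(se)$exercise)
  B <- dim(X)[3]
  out <- array(0, dim(X))
  for (start in seq(1L, B, by = 256L)) {
    idx <- start:min(start + 255L, B)
    Xin <- encInput(X[, , idx, drop = FALSE], labels[idx], model@params, spec)
    z <- encForward(Xin, model@params$enc, spec, training = FALSE)$z
    zin <- if (spec$variant == "Cond-SSAAE") {
      rbind(z, model@params$emb[, labels[idx], drop = FALSE])
    } else z
    rec <- decForward(zin, model@params$dec, spec, training = FALSE)$out
    out[, , idx] <- matToArr(rec, spec$nFrames, length(idx))
  }
  out
}
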