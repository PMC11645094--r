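# Minimal neural-network engine for the adversarial autoencoder.
#
# Written for this package: the stack has no deep-learning framework and the
# encoder/decoder/discriminator are the heart of the method, so forward and
# backward passes are implemented directly with BLAS-backed matrix algebra.
#
# Tensor conventions:
#   * convolutional feature maps: matrix (T*B, C) -- frames x batch flattened
#     row-major in t-within-b order (row r = t + (b-1)*T), channels in
#     columns.  Time shifts are then row gathers and batch norm over (T, B)
#     is a plain column operation, which keeps the R overhead tiny.
#   * dense activations: matrix (F, B).
# Conv1d uses shifted-gather im2col + GEMM with same-padding; backprop
# formulas are the standard ones and are validated against finite
# differences in the tests.  Parameter trees are nested lists; leaves named
# rm/rv (batch-norm running stats) are state, not trainable, and are skipped
# by Adam.

# row-gather indices for a time shift; rows beyond the series map to a zero
# row appended at position T*B + 1
.shiftIdx <- function(Tn, B, offset) {
  src <- rep(seq_len(Tn), B) + offset
  idx <- src + rep((seq_len(B) - 1L) * Tn, each = Tn)
  idx[src < 1L | src > Tn] <- Tn * B + 1L
  idx
}

nnConvInit <- function(cin, cout, k = 5L, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (k * cin))
  list(W = matrix(rnorm(k * cin * cout, 0, scale), k * cin, cout),
       b = rep(0, cout), k = k)
}

nnConvF <- function(Xm, P, Tn, B) {
  k <- P$k
  M <- if (k == 1L) Xm else .convIm2col(Xm, Tn, B, k)
  Y <- .addColwise(M %*% P$W, P$b)
  list(out = Y, cache = list(M = M, Tn = Tn, B = B, Cin = ncol(Xm), k = k))
}

nnConvB <- function(dY, P, cache) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, P$W)
  dX <- if (cache$k == 1L) dM else {
    .convCol2im(dM, cache$Tn, cache$B, cache$Cin, cache$k)
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

nnBnInit <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), rm = rep(0, C), rv = rep(1, C))
}

# Batch norm over a samples-in-rows matrix (N, C); updates running stats
# when training.  Conv maps are already (T*B, C); dense layers pass t(X).
nnBnF <- function(Xm, P, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    st <- .bnColStats(Xm)
    mu <- st$mu; v <- st$v
    n <- nrow(Xm)
    P$rm <- (1 - momentum) * P$rm + momentum * mu
    P$rv <- (1 - momentum) * P$rv + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- P$rm; v <- P$rv
  }
  istd <- 1 / sqrt(v + eps)
  r <- .bnApply(Xm, P$gamma, P$beta, mu, istd)
  list(out = r$Y,
       cache = list(xhat = r$xhat, istd = istd, training = training),
       P = P)
}

nnBnB <- function(dY, P, cache) {
  if (cache$training) {
    r <- .bnBackward(dY, cache$xhat, P$gamma, cache$istd)
    list(dX = r$dX, grads = list(gamma = r$dgamma, beta = r$dbeta))
  } else {
    N <- nrow(dY)
    list(dX = dY * rep(P$gamma * cache$istd, each = N),
         grads = list(gamma = colSums(dY * cache$xhat), beta = colSums(dY)))
  }
}

# dense-layer batch norm: activations are (F, B), stats over the batch
nnBnF2 <- function(X, P, training) {
  r <- nnBnF(t(X), P, training)
  list(out = t(r$out), cache = r$cache, P = r$P)
}

nnBnB2 <- function(dY, P, cache) {
  r <- nnBnB(t(dY), P, cache)
  list(dX = t(r$dX), grads = r$grads)
}

# (T, C, B) array -> (T*B, C) conv-map matrix (t-within-b row order)
arrToMat <- function(X3) {
  d <- dim(X3)
  X <- aperm(X3, c(1, 3, 2))
  dim(X) <- c(d[1] * d[3], d[2])
  X
}

matToArr <- function(Xm, Tn, B) {
  X <- Xm
  dim(X) <- c(Tn, B, ncol(Xm))
  aperm(X, c(1, 3, 2))
}

nnReluF <- function(X) {
  Y <- if (is.matrix(X)) .reluFwd(X) else pmax(X, 0)
  list(out = Y, cache = Y)
}
nnReluB <- function(dY, cache) {
  if (is.matrix(dY)) .reluBwd(dY, cache) else dY * (cache > 0)
}

nnSigF <- function(X) {
  Y <- 1 / (1 + exp(-X))
  list(out = Y, cache = Y)
}
nnSigB <- function(dY, cache) dY * cache * (1 - cache)

nnDropF <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  r <- .dropoutFwd(X, p)
  list(out = r$Y, cache = r$mask)
}
nnDropB <- function(dY, cache) if (is.null(cache)) dY else .elemMul(dY, cache)

# max-pool 2x1 along frames: rows with odd/even t within each series
nnPoolF <- function(Xm, Tn, B) {
  odd <- .shiftIdx(Tn, B, 0L)[rep(c(TRUE, FALSE), length.out = Tn * B)]
  X1 <- Xm[odd, , drop = FALSE]
  X2 <- Xm[odd + 1L, , drop = FALSE]
  mask <- X1 >= X2
  list(out = pmax(X1, X2),
       cache = list(mask = mask, odd = odd, Tn = Tn, B = B))
}

nnPoolB <- function(dY, cache) {
  dX <- matrix(0, cache$Tn * cache$B, ncol(dY))
  dX[cache$odd, ] <- dY * cache$mask
  dX[cache$odd + 1L, ] <- dY * !cache$mask
  dX
}

# nearest-neighbour x2 upsample along frames
nnUpF <- function(Xm, Tn, B) {
  tp <- rep(seq_len(2L * Tn), B)
  idx <- ceiling(tp / 2) + rep((seq_len(B) - 1L) * Tn, each = 2L * Tn)
  list(out = Xm[idx, , drop = FALSE], cache = NULL)
}

nnUpB <- function(dY) {
  n2 <- nrow(dY)
  dY[seq(1L, n2, 2L), , drop = FALSE] + dY[seq(2L, n2, 2L), , drop = FALSE]
}

nnDenseInit <- function(fin, fout, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / fin)
  list(W = matrix(rnorm(fout * fin, 0, scale), fout, fin), b = rep(0, fout))
}

nnDenseF <- function(X, P) list(out = P$W %*% X + P$b, cache = X)

nnDenseB <- function(dY, P, cache) {
  list(dX = crossprod(P$W, dY),
       grads = list(W = tcrossprod(dY, cache), b = rowSums(dY)))
}

# (T*B, C) conv map  <->  (T*C, B) dense features
nnFlatF <- function(Xm, Tn, B) {
  X <- Xm
  dim(X) <- c(Tn, B, ncol(Xm))
  X <- aperm(X, c(1, 3, 2))
  dim(X) <- c(Tn * ncol(Xm), B)
  list(out = X, cache = list(Tn = Tn, B = B, C = ncol(Xm)))
}

nnFlatB <- function(dY, cache) {
  dim(dY) <- c(cache$Tn, cache$C, cache$B)
  dY <- aperm(dY, c(1, 3, 2))
  dim(dY) <- c(cache$Tn * cache$B, cache$C)
  dY
}

nnUnflatF <- function(X, Tn, C) {
  B <- ncol(X)
  dim(X) <- c(Tn, C, B)
  X <- aperm(X, c(1, 3, 2))
  dim(X) <- c(Tn * B, C)
  list(out = X, cache = list(Tn = Tn, B = B, C = C))
}

nnUnflatB <- function(dY, cache) {
  dim(dY) <- c(cache$Tn, cache$B, cache$C)
  dY <- aperm(dY, c(1, 3, 2))
  dim(dY) <- c(cache$Tn * cache$C, cache$B)
  dY
}

# fused batch-norm + ReLU (training/eval) used inside residual blocks
nnBnReluF <- function(Xm, P, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    st <- .bnColStats(Xm)
    mu <- st$mu; v <- st$v
    n <- nrow(Xm)
    P$rm <- (1 - momentum) * P$rm + momentum * mu
    P$rv <- (1 - momentum) * P$rv + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- P$rm; v <- P$rv
  }
  istd <- 1 / sqrt(v + eps)
  r <- .bnApplyRelu(Xm, P$gamma, P$beta, mu, istd)
  list(out = r$Y,
       cache = list(xhat = r$xhat, istd = istd, Y = r$Y, training = training),
       P = P)
}

nnBnReluB <- function(dY, P, cache) {
  stopifnot(cache$training)
  r <- .bnReluBackward(dY, cache$Y, cache$xhat, P$gamma, cache$istd)
  list(dX = r$dX, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# ---- residual block -------------------------------------------------------

nnResInit <- function(cin, cout, k = 5L) {
  P <- list(c1 = nnConvInit(cin, cout, k), bn1 = nnBnInit(cout),
            c2 = nnConvInit(cout, cout, k), bn2 = nnBnInit(cout))
  if (cin != cout) {
    # identity skips are used wherever shapes allow; a 1x1 projection is
    # unavoidable at channel transitions
    P$proj <- nnConvInit(cin, cout, 1L)
    P$bnp <- nnBnInit(cout)
  }
  P
}

nnResF <- function(Xm, P, training, dropout, Tn, B) {
  c1 <- nnConvF(Xm, P$c1, Tn, B)
  br <- nnBnReluF(c1$out, P$bn1, training); P$bn1 <- br$P
  d1 <- nnDropF(br$out, dropout, training)
  c2 <- nnConvF(d1$out, P$c2, Tn, B)
  b2 <- nnBnF(c2$out, P$bn2, training); P$bn2 <- b2$P
  if (!is.null(P$proj)) {
    cp <- nnConvF(Xm, P$proj, Tn, B)
    bp <- nnBnF(cp$out, P$bnp, training); P$bnp <- bp$P
    skip <- bp$out
    skipCache <- list(cp = cp$cache, bp = bp$cache)
  } else {
    skip <- Xm
    skipCache <- NULL
  }
  ro <- .addRelu(b2$out, skip)
  list(out = ro, P = P,
       cache = list(c1 = c1$cache, br = br$cache,
                    d1 = d1$cache, c2 = c2$cache, b2 = b2$cache,
                    ro = ro, skip = skipCache))
}

nnResB <- function(dY, P, cache) {
  dSum <- .reluBwd(dY, cache$ro)
  b2 <- nnBnB(dSum, P$bn2, cache$b2)
  c2 <- nnConvB(b2$dX, P$c2, cache$c2)
  dd1 <- nnDropB(c2$dX, cache$d1)
  br <- nnBnReluB(dd1, P$bn1, cache$br)
  c1 <- nnConvB(br$dX, P$c1, cache$c1)
  dX <- c1$dX
  grads <- list(c1 = c1$grads, bn1 = br$grads, c2 = c2$grads, bn2 = b2$grads)
  if (!is.null(P$proj)) {
    bp <- nnBnB(dSum, P$bnp, cache$skip$bp)
    cp <- nnConvB(bp$dX, P$proj, cache$skip$cp)
    dX <- dX + cp$dX
    grads$proj <- cp$grads
    grads$bnp <- bp$grads
  } else {
    dX <- dX + dSum
  }
  list(dX = dX, grads = grads)
}

# ---- Adam over parameter trees -------------------------------------------

STATE_LEAVES <- c("rm", "rv", "k")

adamInit <- function(params) {
  walk <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, walk)
      names(out) <- names(x)
      out
    } else list(m = x * 0, v = x * 0)
  }
  walk(params)
}

adamStep <- function(params, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, s) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% STATE_LEAVES) next
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else {
      # leaves are updated in place (buffers owned by the optimizer loop)
      .adamLeaf(p, s$m, s$v, g, lr, beta1, beta2, eps, bc1, bc2)
      list(p = p, s = s)
    }
  }
  walk(params, grads, state)
}

# fresh copies of every numeric leaf: checkpoints and fine-tuning must not
# alias the buffers the in-place optimizer keeps mutating
deepCopyParams <- function(P) {
  rapply(P, function(x) if (is.numeric(x)) x + 0 else x, how = "replace")
}

# elementwise sum of two same-shape gradient trees (NULL-tolerant)
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in union(names(a), names(b))) a[[nm]] <- gradAdd(a[[nm]], b[[nm]])
    a
  } else a + b
}

`%||%` <- function(a, b) if (is.null(a)) b else a
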