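test_that("prior sampling: limits, CLT bound, determinism", {
  pr <- priorLayout(radius = 4, s = 1)
  expect_equal(dim(priorCenters(pr)), c(4, 2))

  tiny <- priorLayout(radius = 4, s = 1e-12)
  z <- samplePrior(tiny, "Squat", 5, seed = 1)
  expect_equal(z, matrix(rep(priorCenters(tiny)["Squat", ], each = 5), 5, 2),
               tolerance = 1e-9, ignore_attr = TRUE)

  z <- samplePrior(pr, "LungeLeft", 1e4, seed = 2)
  mu <- priorCenters(pr)["LungeLeft", ]
  expect_lt(max(abs(colMeans(z) - mu)), 4 / 100)

  expect_identical(samplePrior(pr, "Squat", 50, seed = 3),
                   samplePrior(pr, "Squat", 50, seed = 3))
  expect_error(samplePrior(pr, "Jog", 1, seed = 1), "unknown class")
})

test_that("closed-form Gaussian KL against analytic values", {
  pr <- priorLayout(radius = 4, s = 1)
  mu <- priorCenters(pr)["Squat", ]

  # construct points whose sample mean / covariance are exactly controlled
  set.seed(4)
  raw <- matrix(rnorm(60), 30, 2)
  raw <- sweep(raw, 2, colMeans(raw))
  white <- raw %*% solve(chol(cov(raw)))       # sample cov exactly I
  atPrior <- sweep(white, 2, mu, `+`)
  expect_equal(klToPrior(atPrior, "Squat", pr), 0, tolerance = 1e-9)

  shifted <- sweep(white, 2, mu + c(1, 0), `+`)  # KL = ||delta||^2 / 2
  expect_equal(klToPrior(shifted, "Squat", pr), 0.5, tolerance = 1e-9)

  wide <- sweep(white * sqrt(2), 2, mu, `+`)     # cov = 2I
  expect_equal(klToPrior(wide, "Squat", pr),
               0.5 * (2 * 2 - 2 - log(4)), tolerance = 1e-9)

  expect_error(klToPrior(white[1:2, ], "Squat", pr), ">= 3")
})

test_that("latent accuracy is nearest-prior-mode classification", {
  pr <- priorLayout()
  ctr <- priorCenters(pr)
  labels <- rownames(ctr)
  expect_equal(latentAccuracy(ctr, labels, pr), 1)
  expect_equal(latentAccuracy(ctr, rev(labels), pr), 0)

  # two modes at (+-4, 0): accuracy equals the sign-agreement fraction
  pr2 <- new("PriorLayout",
             centers = matrix(c(4, -4, 0, 0), 2, 2,
                              dimnames = list(c("R", "L"), c("z1", "z2"))),
             s = 1)
  z <- cbind(c(1, 1, -1, -1, 1), 0)
  lab <- c("R", "L", "L", "L", "R")
  expect_equal(latentAccuracy(z, lab, pr2), 4 / 5)
})

test_that("inference-mode encoding is deterministic and batch-invariant", {
  coh <- smallCohortA()
  se <- assembleDataset(coh, "DB0")
  st <- computeStandardization(se, participants(coh)$id, fold = "f0")
  seStd <- standardizeDataset(se, st)

  spec <- aaeModelSpec(3, "Res-SSAAE")
  model <- new("TrainedAAE", spec = unclass(spec),
               params = fatlat:::initAAEParams(spec, seed = 8),
               prior = priorLayout(), statsProvenance = "f0",
               history = data.frame(), selectedEpoch = 0L)

  z1 <- encodeDataset(model, seStd)
  z2 <- encodeDataset(model, seStd)
  expect_identical(z1, z2)
  single <- encodeDataset(model, seStd[, 5])
  expect_equal(unlist(single[, c("z1", "z2")]), unlist(z1[5, c("z1", "z2")]),
               tolerance = 1e-12)

  # conditional variant refuses to encode without labels
  specC <- aaeModelSpec(3, "Cond-SSAAE")
  pc <- fatlat:::initAAEParams(specC, seed = 8)
  X <- fatlat:::datasetArray(seStd)
  expect_error(fatlat:::encodeArray(pc, specC, X, labels = NULL),
               "activity label")

  # provenance guard
  st2 <- computeStandardization(se, participants(coh)$id[1], fold = "f1")
  seOther <- standardizeDataset(se, st2)
  expect_error(encodeDataset(model, seOther), "provenance mismatch")
  expect_error(encodeDataset(model, se), "standardized")
})

test_that("training contracts on a tiny run; fine-tuning contracts", {
  coh <- smallCohortA()                  # 2 subjects, group A
  se <- assembleDataset(coh, "DB0")
  ids <- participants(coh)$id
  st <- computeStandardization(se, ids[1], fold = "0")
  seStd <- standardizeDataset(se, st)
  seTr <- seStd[, colData(seStd)$participant == ids[1]]
  seVal <- seStd[, colData(seStd)$participant == ids[2]]

  spec <- aaeModelSpec(3, "Res-SSAAE")
  model <- trainAAE(spec, seTr, seVal, maxEpochs = 3, batchSize = 32,
                    lr = 1e-3, seed = 5)
  h <- trainingHistory(model)
  expect_equal(nrow(h), 3)
  expect_equal(model@selectedEpoch, which.min(h$meanKL))
  expect_true(all(c("recon", "disc", "gen", "meanKL") %in% names(h)))

  # same seed reproduces the training trajectory exactly
  model2 <- trainAAE(spec, seTr, seVal, maxEpochs = 3, batchSize = 32,
                     lr = 1e-3, seed = 5)
  expect_equal(trainingHistory(model2)$recon, h$recon, tolerance = 1e-12)

  expect_error(trainAAE(spec, seStd, seVal, maxEpochs = 1),
               "subject-disjoint")

  # fine-tuning: 0 epochs is the identity; k epochs appends k flagged rows
  expect_identical(fineTune(model, seTr, epochs = 0L), model)
  ft <- fineTune(model, seTr, epochs = 2L, seed = 6)
  hf <- trainingHistory(ft)
  expect_equal(sum(hf$phase == "fine-tune"), 2)
  expect_equal(ft@selectedEpoch, model@selectedEpoch)
  # original model untouched by the fine-tune (no aliasing)
  expect_equal(model@params$enc$d2$W, model2@params$enc$d2$W,
               tolerance = 1e-12)
})

test_that("reconstruction error of a trained model beats its initialization", {
  folds <- foldModels()
  model <- folds$models[[1]]
  seVal <- folds$seStd[, colData(folds$seStd)$participant %in%
                         folds$valIds[[1]]]
  X <- fatlat:::datasetArray(seVal)
  recT <- reconstructDataset(model, seVal)
  untrained <- new("TrainedAAE", spec = model@spec,
                   params = fatlat:::initAAEParams(
                     structure(model@spec, class = "aaeModelSpec"), seed = 99),
                   prior = model@prior,
                   statsProvenance = model@statsProvenance,
                   history = data.frame(), selectedEpoch = 0L)
  recU <- reconstructDataset(untrained, seVal)
  expect_lt(mean((recT - X)^2), mean((recU - X)^2))
})

test_that("adversarial regularization shapes the validation latent space", {
  folds <- foldModels()
  model <- folds$models[[1]]
  h <- trainingHistory(model)
  h <- h[h$phase == "train", ]
  # KL early stopping: the selected epoch's mean KL never exceeds epoch 1's
  expect_lte(h$meanKL[model@selectedEpoch], h$meanKL[1])

  # prior recovery: per-activity validation means land near their modes
  seVal <- folds$seStd[, colData(folds$seStd)$participant %in%
                         folds$valIds[[1]]]
  lat <- encodeDataset(model, seVal)
  ctr <- priorCenters(model@prior)
  for (ex in rownames(ctr)) {
    zc <- as.matrix(lat[lat$exercise == ex, c("z1", "z2")])
    expect_lt(sqrt(sum((colMeans(zc) - ctr[ex, ])^2)), 2.5)
  }
})
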