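test_that("the default architecture realises the documented shape chain", {
  cfg <- ModelConfig()
  expect_equal(cfg@vocabSize, 65L)
  expect_equal(flattenedDim(cfg), 298L * 2L * 128L)
  expect_equal(flattenedDim(cfg), 76288L)
  model <- buildModel(cfg, seed = 1)
  p <- model@params
  # embedding output per sequence: 298 x 64 (stored as 64 x 65 lookup)
  expect_equal(dim(p$embedding), c(64L, 65L))
  # Bi-LSTM per-position output width: 2 * 128 = 256
  expect_equal(nrow(p$lstm_fwd_Wx), 4L * 128L)
  expect_equal(nrow(p$lstm_bwd_Wx), 4L * 128L)
  # FC1 consumes the 76288-wide flattened vector
  expect_equal(dim(p$fc1_W), c(128L, 76288L))
  expect_equal(dim(p$fc2_W), c(1L, 128L))
  # forward-pass probe on the full default geometry
  X <- matrix(sample(0:64, 3 * 298, replace = TRUE), 3, 298)
  probs <- forwardProbs(model, X)
  expect_length(probs, 3)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- ModelConfig(vocabSize = 10, embedDim = 4, hiddenDim = 3,
                     seqLen = 8, fc1Dim = 5)
  model <- buildModel(cfg, seed = 2)
  expect_equal(parameterCount(model), parameterCount(cfg))
  expect_equal(parameterCount(buildModel(ModelConfig(), seed = 1)),
               parameterCount(ModelConfig()))
})

test_that("the compiled forward pass matches a pure-R reference", {
  cfg <- ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                     seqLen = 12, fc1Dim = 6)
  model <- buildModel(cfg, seed = 42)
  set.seed(43)
  X <- matrix(sample(0:8, 6 * 12, replace = TRUE), 6, 12)
  got <- forwardProbs(model, X)
  want <- referenceForward(model@params, X, cfg@leakySlope)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("forward output is deterministic and validates its input", {
  cfg <- ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                     seqLen = 12, fc1Dim = 6)
  model <- buildModel(cfg, seed = 7)
  X <- matrix(sample(0:8, 2 * 12, replace = TRUE), 2, 12)
  Xdup <- X[c(1, 1, 2), ]
  probs <- forwardProbs(model, Xdup)
  expect_identical(probs[1], probs[2])
  expect_error(forwardProbs(model, X[, 1:11]), "does not match seq_len")
  bad <- X; bad[1, 1] <- 9L
  expect_error(forwardProbs(model, bad), "indices must lie")
})

test_that("initialisation is deterministic given the seed", {
  a <- buildModel(ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                              seqLen = 12, fc1Dim = 6), seed = 5)
  b <- buildModel(ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                              seqLen = 12, fc1Dim = 6), seed = 5)
  expect_identical(a@params, b@params)
})

test_that("binary cross-entropy matches its closed form and is monotone", {
  expect_equal(bceLoss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-12)
  # brute-force formula evaluation on random instances
  set.seed(51)
  for (i in 1:10) {
    y <- rbinom(20, 1, 0.5)
    p <- runif(20, 0.01, 0.99)
    expect_equal(bceLoss(y, p),
                 mean(-(y * log(p) + (1 - y) * log(1 - p))),
                 tolerance = 1e-12)
  }
  # perfect prediction gives (clipped) near-zero, non-negative loss
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-5)
  expect_gte(bceLoss(c(1, 0), c(1, 0)), 0)
  # strictly decreasing in p for y = 1
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p) bceLoss(1, p), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(bceLoss(c(1, 0), 0.5), "equal length")
})

test_that("prediction thresholds at >= with ties classed positive", {
  cfg <- ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                     seqLen = 12, fc1Dim = 6)
  model <- buildModel(cfg, seed = 11)
  X <- matrix(sample(0:8, 4 * 12, replace = TRUE), 4, 12)
  pred <- predictModel(model, X, threshold = 0.5)
  expect_equal(pred$label, as.integer(pred$prob >= 0.5))
  # exact tie at the threshold is positive
  tie <- predictModel(model, X, threshold = pred$prob[1])
  expect_equal(tie$label[1], 1L)
  # threshold above 1 yields all negatives
  expect_true(all(predictModel(model, X, threshold = 1.01)$label == 0L))
})

test_that("checkpoints round-trip the model", {
  cfg <- ModelConfig(vocabSize = 9, embedDim = 5, hiddenDim = 4,
                     seqLen = 12, fc1Dim = 6)
  model <- buildModel(cfg, seed = 3)
  f <- withr::local_tempfile(fileext = ".ckpt")
  saveModelCheckpoint(model, f)
  back <- loadModelCheckpoint(f)
  X <- matrix(sample(0:8, 2 * 12, replace = TRUE), 2, 12)
  expect_identical(forwardProbs(model, X), forwardProbs(back, X))
  expect_equal(back@config@hiddenDim, 4L)
})
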