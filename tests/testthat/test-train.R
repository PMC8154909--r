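# Fold splitting, optimizer plumbing, learning sanity at tiny scale.

test_that("fold splitting partitions the data with balanced sizes", {
  f <- splitFolds(10, 5, seed = 3)
  sizes <- vapply(f, function(x) length(x$validation), 0L)
  expect_equal(sizes, rep(2L, 5))
  expect_setequal(unlist(lapply(f, `[[`, "validation")), 1:10)
  for (x in f) {
    expect_length(intersect(x$train, x$validation), 0)
    expect_setequal(c(x$train, x$validation), 1:10)
  }
  # the published cohort size splits 7152 train / 1787-1788 validation
  f5 <- splitFolds(8939, 5, seed = 1)
  sz <- sort(vapply(f5, function(x) length(x$validation), 0L))
  expect_equal(sz, c(1787L, 1788L, 1788L, 1788L, 1788L))
  expect_equal(length(f5[[5]]$train), 8939L - length(f5[[5]]$validation))
  # deterministic given seed
  expect_identical(splitFolds(100, 4, seed = 9), splitFolds(100, 4, seed = 9))
  expect_error(splitFolds(3, 5), "folds")
  expect_error(splitFolds(10, 1), "folds")
})

test_that("stratified folds preserve class balance", {
  strata <- rep(c(0, 1), c(30, 10))
  f <- splitFolds(40, 4, seed = 2, strata = strata)
  for (x in f)
    expect_equal(sum(strata[x$validation]), 2.5, tolerance = 0.3)
})

test_that("zero epochs leave the network untouched", {
  ds <- smallPopulation(8)
  net <- buildNetwork(deskArchitecture(), seed = 31)
  fit <- fitNetwork(net, ds, measurements(ds)$qrs,
                    trainConfig("qrs", epochs = 0))
  expect_identical(fit$net@layers, net@layers)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("a constant-label task converges to the constant", {
  ds <- smallPopulation(24)
  net <- buildNetwork(deskArchitecture(nResidualModules = 1), seed = 7)
  y <- rep(135, 24)
  fit <- fitNetwork(net, ds, y, trainConfig("qrs", epochs = 4,
                                            batchSize = 8, seed = 5))
  p <- predictEcg(fit$net, ds)
  expect_lt(mae(p, y), 1)
})

test_that("training is reproducible given the seed", {
  ds <- smallPopulation(16)
  y <- measurements(ds)$rAmp
  cfg <- trainConfig("rAmp", epochs = 2, batchSize = 8, seed = 77)
  f1 <- fitNetwork(buildNetwork(cfg$arch, seed = 9), ds, y, cfg)
  f2 <- fitNetwork(buildNetwork(cfg$arch, seed = 9), ds, y, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$net@layers, f2$net@layers)
})

test_that("augmentation shifts the signal but never the labels", {
  ds <- smallPopulation(6)
  arch <- deskArchitecture()
  arr <- ecgradcam:::prepareInputArray(ds, arch)
  y <- measurements(ds)$qrs
  yBefore <- y + 0
  shifts <- c(-20L, 0L, 10L, 5L, -3L, 15L)
  sh <- ecgradcam:::shiftBatch(arr, shifts)
  # each record is circularly shifted by its own amount
  for (j in seq_along(shifts)) {
    n <- dim(arr)[2]
    idx <- ((seq_len(n) - 1L - shifts[j]) %% n) + 1L
    expect_equal(sh[, , j], arr[, idx, j])
  }
  fitNetwork(buildNetwork(arch, seed = 1), ds, y,
             trainConfig("qrs", epochs = 1, batchSize = 6))
  expect_identical(y, yBefore)
})

test_that("validation error falls with more training on an easy task", {
  # labels are a pure amplitude readout, learnable by construction
  ds <- smallPopulation(60)
  y <- measurements(ds)$rAmp
  arch <- deskArchitecture(nResidualModules = 1)
  va <- 49:60; tr <- 1:48
  arrTr <- ecgradcam:::prepareInputArray(ds[tr], arch)
  arrVa <- ecgradcam:::prepareInputArray(ds[va], arch)
  maes <- vapply(c(0, 4, 16), function(ep) {
    fit <- fitNetwork(buildNetwork(arch, seed = 11), arrTr, y[tr],
                      trainConfig("rAmp", epochs = ep, batchSize = 16,
                                  seed = 3))
    mae(predictEcg(fit$net, arrVa), y[va])
  }, numeric(1))
  expect_lt(maes[2], maes[1])
  expect_lt(maes[3], maes[2])
})

test_that("injected predictors short-circuit training in cross-validation", {
  ds <- smallPopulation(30)
  # a perfect oracle scores zero error in every fold
  cfg <- trainConfig("qt", folds = 3, seed = 2,
                     predictor = function(trd, vad, ytr, yva) yva)
  cv <- crossValidate(ds, cfg)
  expect_equal(cv$folds$mae, rep(0, 3))
  expect_equal(cv$report$mae, 0)
  # the ZeroR predictor reproduces zeroR() of the validation labels
  cfgZ <- trainConfig("qt", folds = 3, seed = 2,
                      predictor = function(trd, vad, ytr, yva)
                        rep(mean(yva), length(yva)))
  cvZ <- crossValidate(ds, cfgZ)
  y <- measurements(ds)$qt
  folds <- splitFolds(30, 3, seed = 2)
  for (i in 1:3)
    expect_equal(cvZ$folds$mae[i],
                 unname(zeroR(y[folds[[i]]$validation])["mae"]))
})

test_that("cross-validation guards degenerate inputs", {
  ds <- smallPopulation(30)
  m <- measurements(ds); m$sex <- 0L
  dsBad <- new("EcgDataset", records = records(ds),
               fiducials = fiducials(ds), measurements = m,
               spec = ds@spec)
  expect_error(crossValidate(dsBad, trainConfig("sex", folds = 2)),
               "class")
})

test_that("divergence aborts with a diagnostic", {
  ds <- smallPopulation(8)
  cfg <- trainConfig("rAmp", epochs = 2, batchSize = 4)
  net <- buildNetwork(cfg$arch, seed = 2)
  net@layers[[1]]$W[1, 1] <- Inf  # poisoned weights -> non-finite loss
  expect_error(fitNetwork(net, ds, measurements(ds)$rAmp, cfg),
               "diverged")
})
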