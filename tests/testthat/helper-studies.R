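# Desk-scale trained study artifacts shared between the acceptance
# blocks and the study-level tests. Filled lazily on first use (four
# models, several minutes of training) and cached for the rest of the
# test run; every seed is fixed so the artifacts are one reproducible
# experiment.

accCache <- new.env(parent = emptyenv())

accArtifacts <- function() {
  if (!is.null(accCache$done)) return(accCache)
  dsReg <- generatePopulation(populationSpec(seed = 2101), 2000, "median")
  mReg <- measurements(dsReg)
  arch <- deskArchitecture()
  folds <- splitFolds(2000, 5, seed = 11)
  tr <- folds[[1]]$train; va <- folds[[1]]$validation
  arrTr <- ecgradcam:::prepareInputArray(dsReg[tr], arch)
  arrVa <- ecgradcam:::prepareInputArray(dsReg[va], arch)
  nets <- list()
  for (cfg in list(list(task = "qrs", ep = 12), list(task = "rAmp", ep = 10),
                   list(task = "tAmp", ep = 10))) {
    fit <- fitNetwork(buildNetwork(arch, seed = 501), arrTr,
                      mReg[[cfg$task]][tr],
                      trainConfig(cfg$task, epochs = cfg$ep,
                                  batchSize = 64, seed = 77))
    nets[[cfg$task]] <- fit$net
  }
  dsSex <- generatePopulation(populationSpec(seed = 2102), 800, "median")
  mSex <- measurements(dsSex)
  foldsS <- splitFolds(800, 5, seed = 11, strata = mSex$sex)
  archC <- deskArchitecture(head = "classification")
  fitS <- fitNetwork(buildNetwork(archC, seed = 501),
                     ecgradcam:::prepareInputArray(dsSex[foldsS[[1]]$train],
                                                   archC),
                     mSex$sex[foldsS[[1]]$train],
                     trainConfig("sex", epochs = 18, batchSize = 64,
                                 seed = 77))
  nets$sex <- fitS$net
  accCache$dsReg <- dsReg; accCache$mReg <- mReg
  accCache$va <- va; accCache$arrVa <- arrVa
  accCache$dsSex <- dsSex; accCache$mSex <- mSex
  accCache$vaS <- foldsS[[1]]$validation; accCache$foldsS <- foldsS
  accCache$nets <- nets
  accCache$done <- TRUE
  accCache
}

# mean P/QRS/T-window localization over held-out records for one model
windowScores <- function(net, ds, idx, n = 25) {
  idx <- idx[seq_len(min(n, length(idx)))]
  sc <- vapply(idx, function(i) {
    fid <- fiducials(ds)[[i]]
    # an identically zero rectified map is legitimate (scores 0)
    mm <- suppressWarnings(perLeadMaps(net, records(ds)[[i]]))
    amax <- (which.max(averagedMap(mm)) - 1) * 1000 /
      sampleRate(records(ds)[[i]])
    qrsWin <- c(fid@qrsOn, fid@qrsOff)
    c(P = localizationScore(mm, c(fid@pOn, fid@pOff)),
      QRS = localizationScore(mm, qrsWin),
      T = localizationScore(mm, c(2 * fid@tPeak - fid@tOff, fid@tOff)),
      qrsFrac = diff(qrsWin) / (ncol(perLead(mm)) * 2),
      hitQRS = as.numeric(amax >= qrsWin[1] && amax <= qrsWin[2]))
  }, numeric(5))
  rowMeans(sc)
}
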