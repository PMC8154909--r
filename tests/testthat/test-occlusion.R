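# Wave blanking: interpolation oracle, idempotence, locality.

test_that("blanked segments follow the per-lead linear interpolation", {
  # endpoints 0 and 10 LSB over 11 samples -> interior 1..9
  v <- matrix(0L, 12, 600)
  v[, 101] <- 0L; v[, 111] <- 10L
  v[, 102:110] <- 55L  # arbitrary wave content to be removed
  rec <- new("ECGRecord", voltages = v, recordKind = "median")
  fid <- new("FiducialSet", pOn = 200, pOff = 222, qrsOn = 240,
             qrsOff = 300, tOff = 500, rPeak = 270, tPeak = 460,
             beatTimes = 270)
  # place the P interval over our test samples: onset 200 ms = sample 101
  fid@pOn <- 200; fid@pOff <- 220
  b <- blankWave(rec, fid, "P")
  expect_equal(unname(voltages(b)[1, 102:110]), 1:9)
  # untouched outside the open interval, endpoints preserved
  expect_identical(voltages(b)[, c(1:101, 111:600)],
                   voltages(rec)[, c(1:101, 111:600)])
})

test_that("blanking matches a per-lead scalar oracle on random records", {
  set.seed(61)
  out <- cleanMedianRecord()
  rec <- out$record; fid <- out$fiducials
  for (wave in c("P", "QRS", "T")) {
    b <- blankWave(rec, fid, wave)
    iv <- ecgradcam:::waveInterval(fid, wave)
    i0 <- ecgradcam:::msToSample(iv[1], 500)
    i1 <- ecgradcam:::msToSample(iv[2], 500)
    v <- voltages(rec)
    for (l in sample(12, 4)) {
      line <- seq(v[l, i0], v[l, i1], length.out = i1 - i0 + 1)
      expected <- sign(line) * floor(abs(line) + 0.5)
      expect_equal(unname(voltages(b)[l, i0:i1]),
                   expected, tolerance = 0)
    }
    # locality: bit-identical outside the interval
    outside <- setdiff(seq_len(600), i0:i1)
    expect_identical(voltages(b)[, outside], v[, outside])
    # idempotence
    expect_identical(voltages(blankWave(b, fid, wave)), voltages(b))
    # integers survive re-quantization
    expect_true(is.integer(voltages(b)))
  }
})

test_that("degenerate intervals behave as specified", {
  out <- cleanMedianRecord()
  fid <- out$fiducials
  # onset == offset leaves the record unchanged
  fid0 <- fid; fid0@pOff <- fid0@pOn
  expect_identical(voltages(blankWave(out$record, fid0, "P")),
                   voltages(out$record))
  # onset after offset is an error
  fidBad <- fid; fidBad@pOff <- fidBad@pOn - 10
  expect_error(blankWave(out$record, fidBad, "P"), "onset after offset")
  # fiducials outside the record are an error
  fidOut <- fid; fidOut@tOff <- 1500; fidOut@tPeak <- 1400
  expect_error(blankWave(out$record, fidOut, "T"), "outside")
})

test_that("flat leads blank to flat", {
  v <- matrix(0L, 12, 600)
  rec <- new("ECGRecord", voltages = v, recordKind = "median")
  fid <- cleanMedianRecord()$fiducials
  expect_identical(voltages(blankWave(rec, fid, "QRS")), v)
})

test_that("rhythm blanking is applied beat by beat", {
  ds <- generatePopulation(populationSpec(seed = 9, noiseSd = 0,
                                          wanderAmp = 0), 1, "rhythm")
  rec <- records(ds)[[1]]; fid <- fiducials(ds)[[1]]
  b <- blankWave(rec, fid, "QRS")
  # every in-window beat loses its R peak
  for (bt in fid@beatTimes) {
    i <- ecgradcam:::msToSample(bt, 500)
    if (i < 30 || i > 4970) next
    expect_lt(max(abs(microvolts(b)[11, (i - 5):(i + 5)])),
              max(abs(microvolts(rec)[11, (i - 5):(i + 5)])))
  }
})

test_that("a constant predictor yields identical metrics for all variants", {
  ds <- smallPopulation(10)
  net <- buildNetwork(deskArchitecture(), seed = 2)
  hi <- length(net@layers)
  net@layers[[hi]]$w <- net@layers[[hi]]$w * 0
  net@layers[[hi]]$b <- 92
  rep <- blankingStudy(list(qrs = net), ds)
  expect_equal(length(unique(rep$value)), 1L)
  expect_true(all(rep$ratio == 1))
  # the 'none' row equals plain evaluation of the same model
  expect_equal(rep$value[rep$wave == "none"],
               mae(predictEcg(net, ds), measurements(ds)$qrs))
})
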