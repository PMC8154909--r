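# Generator: beat model, fiducials, measurement, quantization, shifting.

test_that("beat waveform is the sum of its Gaussian components", {
  # degenerate: all amplitudes zero -> identically zero waveform
  expect_equal(makeBeat(toyWaveParams()), rep(0, 600))
  # a single R wave peaks at its center with its amplitude
  p <- toyWaveParams(amplitudes = c(P = 0, Q = 0, R = 1000, S = 0, T = 0),
                     centers = c(P = 100, Q = 300, R = 500, S = 700,
                                 T = 900))
  w <- makeBeat(p)
  expect_equal(max(w), 1000)
  expect_equal((which.max(w) - 1) * 2, 500)  # ms at 500 Hz
  # deterministic
  expect_identical(w, makeBeat(p))
})

test_that("non-positive width with non-zero amplitude is rejected", {
  waves <- toyWaves(amplitudes = c(P = 0, Q = 0, R = 100, S = 0, T = 0))
  waves["R", "width"] <- 0
  expect_error(new("WaveParams", waves = waves, baseline = 0,
                   leadProjection = defaultLeadProjection()),
               "width")
})

test_that("Table-1-median parameters give the exact target measurements", {
  p <- medianBeatParams()
  fid <- deriveFiducials(p)
  m <- measureBeat(fid, makeBeat(p), rr = 1000)
  expect_equal(m@qrs, 92)
  expect_equal(m@qt, 408)
  expect_equal(m@pr, 158)
  expect_equal(m@hr, 60)          # RR 1000 ms -> 60 bpm
  expect_equal(m@rAmp, 1376)
  expect_equal(m@tAmp, 346)
  expect_equal(m@stj, -5)
})

test_that("fiducial derivation is support arithmetic, exact by construction", {
  p <- medianBeatParams()
  fid <- deriveFiducials(p)
  expect_equal(fid@qrsOff - fid@qrsOn, 92)
  # zero-width limit: onset = offset = center
  waves <- toyWaves()
  waves["P", "width"] <- 0
  wp <- new("WaveParams", waves = waves, baseline = 0,
            leadProjection = defaultLeadProjection())
  f0 <- deriveFiducials(wp)
  expect_equal(f0@pOn, waves["P", "center"])
  expect_equal(f0@pOff, waves["P", "center"])
  # overlapping adjacent supports warn and clip
  waves2 <- toyWaves(widths = c(P = 60, Q = 10, R = 8, S = 10, T = 30),
                     centers = c(P = 400, Q = 520, R = 560, S = 600,
                                 T = 820))
  wp2 <- new("WaveParams", waves = waves2, baseline = 0,
             leadProjection = defaultLeadProjection())
  expect_warning(fc <- deriveFiducials(wp2), "overlap")
  expect_equal(fc@pOff, fc@qrsOn)
})

test_that("round trip: requested intervals survive generation exactly", {
  for (qt in c(364, 408, 460)) {
    p <- beatParams(pr = 140, qrs = 100, qt = qt, rAmp = 900, tAmp = 250,
                    stj = 12)
    m <- measureBeat(deriveFiducials(p), makeBeat(p), rr = 900)
    expect_equal(m@qt, qt)
    expect_equal(m@qrs, 100)
  }
})

test_that("missing fiducials give undefined measurements, not zero", {
  fid <- new("FiducialSet", pOn = NA_real_, pOff = NA_real_, qrsOn = 518.6,
             qrsOff = 610.6, tOff = 926.6, rPeak = 560, tPeak = 851.6,
             beatTimes = 560)
  m <- measureBeat(fid, makeBeat(medianBeatParams()))
  expect_true(is.na(m@pr))
  expect_false(is.na(m@qrs))
  expect_true(is.na(m@hr))  # no RR information supplied
})

test_that("quantization rounds half away from zero and round-trips", {
  expect_equal(quantizeVoltage(c(4.88, 0, 9.76)), c(1, 0, 2))
  expect_equal(quantizeVoltage(c(-4.88, -2.45)), c(-1, -1))
  set.seed(2)
  uv <- runif(2000, -3000, 3000)
  q <- quantizeVoltage(uv)
  expect_true(all(q == round(q)))
  expect_lte(max(abs(dequantizeVoltage(q) - uv)), 4.88 / 2)
})

test_that("records carry the declared shape and integer voltages", {
  out <- cleanMedianRecord()
  expect_s4_class(out$record, "ECGRecord")
  expect_identical(dim(voltages(out$record)), c(12L, 600L))
  expect_true(is.integer(voltages(out$record)))
  # derived leads obey the Einthoven/Goldberger linear relations
  mu <- microvolts(out$record)
  expect_lt(max(abs(mu["III", ] - (mu["II", ] - mu["I", ]))), 4.88 * 1.5)
  # wrong sample count is rejected
  expect_error(new("ECGRecord", voltages = voltages(out$record)[, 1:500],
                   recordKind = "median"), "600")
})

test_that("time shifting moves signal and fiducials together", {
  out <- cleanMedianRecord()
  same <- timeShiftRecord(out$record, out$fiducials, shiftMs = 0)
  expect_identical(voltages(same$record), voltages(out$record))
  sh <- timeShiftRecord(out$record, out$fiducials, shiftMs = 20)
  expect_equal(sh$fiducials@rPeak, out$fiducials@rPeak + 20)
  i <- function(ms) round(ms * 500 / 1000) + 1
  expect_equal(voltages(sh$record)[, i(sh$fiducials@rPeak)],
               voltages(out$record)[, i(out$fiducials@rPeak)])
  # intervals unchanged
  expect_equal(sh$fiducials@qrsOff - sh$fiducials@qrsOn,
               out$fiducials@qrsOff - out$fiducials@qrsOn)
  # rhythm records are refused
  rp <- generatePopulation(populationSpec(seed = 77), 1, "rhythm")
  expect_error(timeShiftRecord(records(rp)[[1]], fiducials(rp)[[1]], 10),
               "rhythm")
})

test_that("random shifts stay inside +/-40 ms with mean near zero", {
  out <- cleanMedianRecord()
  set.seed(99)
  draws <- replicate(1000,
    timeShiftRecord(out$record, out$fiducials)$shiftMs)
  expect_true(all(abs(draws) <= 40))
  expect_lt(abs(mean(draws)), 2.5)
  expect_true(all(draws * 500 / 1000 == round(draws * 500 / 1000)))
})

test_that("population generation is seeded, reproducible and labeled", {
  ds <- smallPopulation(40)
  ds2 <- generatePopulation(populationSpec(seed = 404), 40)
  expect_identical(lapply(records(ds), voltages),
                   lapply(records(ds2), voltages))
  expect_identical(measurements(ds), measurements(ds2))
  # empty population
  e <- generatePopulation(populationSpec(seed = 1), 0)
  expect_equal(length(e), 0L)
  expect_equal(nrow(measurements(e)), 0L)
})

test_that("generated records agree with their own ground truth", {
  ds <- smallPopulation(40)
  meas <- measurements(ds)
  for (i in seq_len(10)) {
    m <- measureBeat(fiducials(ds)[[i]], records(ds)[[i]],
                     rr = 60000 / meas$hr[i])
    # intervals are fiducial arithmetic: exact
    expect_equal(m@pr, meas$pr[i])
    expect_equal(m@qrs, meas$qrs[i])
    expect_equal(m@qt, meas$qt[i])
    # amplitudes read off the quantized noisy record: within noise + LSB
    tol <- 3 * ds@spec@noiseSd + ds@spec@wanderAmp + 4.88
    expect_lt(abs(m@rAmp - meas$rAmp[i]), tol)
    expect_lt(abs(m@stj - meas$stj[i]), tol)
  }
})

test_that("measurement marginals track the population targets", {
  ds <- smallPopulation(400, seed = 812)
  meas <- measurements(ds)
  tg <- gesusTargets()
  for (v in c("pr", "qrs", "qt", "hr", "rAmp", "tAmp")) {
    expect_lt(abs(median(meas[[v]]) - tg[v, "median"]),
              0.08 * (tg[v, "p95"] - tg[v, "p05"]))
  }
  expect_true(all(meas$sex %in% 0:1))
})

test_that("rhythm strips have jittered beats and HR from mean RR", {
  ds <- generatePopulation(populationSpec(seed = 5, rrJitterSd = 0.04),
                           2, "rhythm")
  fid <- fiducials(ds)[[1]]
  expect_gt(length(fid@beatTimes), 4)
  rr <- diff(fid@beatTimes)
  expect_gt(sd(rr), 0)  # jitter present
  expect_equal(measurements(ds)$hr[1], 60000 / mean(rr))
  expect_identical(dim(voltages(records(ds)[[1]])), c(12L, 5000L))
})

test_that("sexEffect = 0 produces classes identical in distribution", {
  ds <- generatePopulation(populationSpec(seed = 31, sexEffect = 0), 120)
  m <- measurements(ds)
  # the planted morphology channels must carry no class signal
  expect_gt(t.test(rWidthRight ~ sex, data = m)$p.value, 0.01)
  expect_gt(t.test(qrs ~ sex, data = m)$p.value, 0.01)
})
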