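# Population-level generation: sampling measurement targets from
# median/percentile specifications and emitting full datasets.

#' Measurement targets of the two study populations
#'
#' Median and 5th/95th percentiles for heart rate (bpm), QT/PR intervals
#' and QRS duration (ms), J-point elevation, R-peak amplitude and T-wave
#' amplitude in lead V5 (uV). `gesusTargets()` describes the training
#' population, `inter99Targets()` the replication population.
#'
#' @return data.frame with rows hr, qt, pr, qrs, stj, rAmp, tAmp and
#'   columns median, p05, p95.
#' @export
gesusTargets <- function() {
  data.frame(
    median = c(hr = 64, qt = 408, pr = 158, qrs = 92, stj = -5,
               rAmp = 1376, tAmp = 346),
    p05 = c(48, 364, 126, 76, -54, 698, 122),
    p95 = c(85, 460, 204, 118, 48, 2426, 698))
}

#' @rdname gesusTargets
#' @export
inter99Targets <- function() {
  data.frame(
    median = c(hr = 66, qt = 402, pr = 156, qrs = 90, stj = 4,
               rAmp = 1171, tAmp = 327),
    p05 = c(51, 362, 124, 76, -35, 600, 122),
    p95 = c(86, 450, 196, 110, 58, 2044, 649))
}

#' Construct a population specification
#'
#' @param targets measurement quantile table as from [gesusTargets()].
#' @param noiseSd additive white noise SD in uV (default 5 for the
#'   low-noise median-beat regime; raise for rhythm strips).
#' @param wanderAmp baseline wander amplitude in uV.
#' @param sexEffect scale of the planted sex difference (0 = identical
#'   classes).
#' @param sexQrsShiftMs between-class QRS-duration median shift (ms) at
#'   `sexEffect = 1`.
#' @param sexSlopeShiftMs how much earlier/deeper the class-1 S wave sits
#'   (ms) at `sexEffect = 1`.
#' @param rrJitterSd fractional per-beat RR jitter for rhythm strips.
#' @param kSigma fiducial support half-width in sigmas.
#' @param seed integer seed.
#' @return a [PopulationSpec-class].
#' @export
populationSpec <- function(targets = gesusTargets(), noiseSd = 5,
                           wanderAmp = 10, sexEffect = 1,
                           sexQrsShiftMs = 6, sexSlopeShiftMs = 6,
                           rrJitterSd = 0.03, kSigma = 2.5, seed = 1L) {
  new("PopulationSpec", targets = targets, noiseSd = noiseSd,
      wanderAmp = wanderAmp, sexEffect = sexEffect,
      sexQrsShiftMs = sexQrsShiftMs, sexSlopeShiftMs = sexSlopeShiftMs,
      rrJitterSd = rrJitterSd, kSigma = kSigma, seed = as.integer(seed))
}

# Split-normal sampler: reproduces the median and both tail quantiles of a
# median [p05; p95] row exactly in expectation. The two half-widths are
# (median - p05)/z95 and (p95 - median)/z95 with z95 = qnorm(0.95).
sampleSplitNormal <- function(n, med, p05, p95) {
  z <- stats::qnorm(0.95)
  sLo <- (med - p05) / z
  sHi <- (p95 - med) / z
  u <- stats::runif(n)
  q <- stats::qnorm(u)
  med + ifelse(u < 0.5, sLo * q, sHi * q)
}

# sample one record's measurement vector, redrawing until geometrically
# feasible (T wave clears the S wave, P wave fits before the QRS, ...)
sampleMeasurements <- function(targets, qrsShift = 0, maxTries = 50L) {
  for (i in seq_len(maxTries)) {
    m <- vapply(rownames(targets), function(r)
      sampleSplitNormal(1, targets[r, "median"] +
                          if (r == "qrs") qrsShift else 0,
                        targets[r, "p05"] + if (r == "qrs") qrsShift else 0,
                        targets[r, "p95"] + if (r == "qrs") qrsShift else 0),
      numeric(1))
    ok <- m["qt"] > m["qrs"] + 120 && m["pr"] > 96 && m["pr"] < 300 &&
      m["hr"] > 35 && m["hr"] < 160 && m["rAmp"] > 200 && m["qt"] < 620 &&
      m["qrs"] > 55
    if (ok) return(m)
  }
  stop("could not sample a feasible measurement vector")
}

#' Generate a synthetic study population
#'
#' Draws `n` records whose measurement marginals follow the split-normal
#' distributions implied by the population targets, with a binary sex-like
#' label. The two classes differ in R-wave downslope morphology: class 1
#' has a steeper R downslope (smaller right-hand R sigma), a slightly
#' earlier and deeper S wave, and a slightly shorter QRS duration, all
#' scaled by `sexEffect`; at `sexEffect = 0` the classes are identical in
#' distribution. Per-record morphological variability (P amplitude, Q/S
#' depth, R downslope width) is lognormal, so no single ground-truth
#' feature separates the classes perfectly.
#'
#' Generation is reproducible: the spec's seed fully determines the
#' dataset, and the caller's RNG state is left untouched.
#'
#' @param spec a [PopulationSpec-class].
#' @param n number of records (0 gives an empty dataset).
#' @param kind `"median"` or `"rhythm"`.
#' @return an [EcgDataset-class].
#' @export
generatePopulation <- function(spec, n, kind = c("median", "rhythm")) {
  kind <- match.arg(kind)
  stopifnot(is(spec, "PopulationSpec"), n >= 0)
  withSeed(spec@seed, {
    recs <- vector("list", n)
    fids <- vector("list", n)
    rows <- vector("list", n)
    eff <- spec@sexEffect
    for (i in seq_len(n)) {
      sex <- stats::rbinom(1, 1, 0.5)
      qrsShift <- (0.5 - sex) * spec@sexQrsShiftMs * eff
      m <- sampleMeasurements(spec@targets, qrsShift)
      pAmp <- 120 * exp(stats::rnorm(1, 0, 0.2))
      qFrac <- 0.08 * exp(stats::rnorm(1, 0, 0.3))
      sFrac <- 0.18 * exp(stats::rnorm(1, 0, 0.35)) *
        (1 + 0.25 * eff * sex)
      # jittered so S timing is noisy within class: without it, S time
      # would be an exact linear function of QRS duration and the probe
      # features would separate the classes perfectly
      sShift <- stats::rnorm(1, spec@sexSlopeShiftMs * eff * sex, 5)
      sShift <- min(max(sShift, -8), 0.25 * m[["qrs"]])
      rWidthRight <- 0.09 * m[["qrs"]] * exp(stats::rnorm(1, 0, 0.25))
      if (sex == 1) rWidthRight <- rWidthRight * max(0.25, 1 - 0.4 * eff)
      p <- beatParams(pr = m[["pr"]], qrs = m[["qrs"]], qt = m[["qt"]],
                      rAmp = m[["rAmp"]], tAmp = m[["tAmp"]],
                      stj = m[["stj"]], pAmp = pAmp, qFrac = qFrac,
                      sFrac = sFrac, sShiftMs = sShift,
                      rWidthRight = rWidthRight, kSigma = spec@kSigma)
      out <- synthRecord(p, kind = kind, hr = m[["hr"]],
                         noiseSd = spec@noiseSd, wanderAmp = spec@wanderAmp,
                         rrJitterSd = spec@rrJitterSd,
                         recordId = sprintf("syn%05d", i),
                         kSigma = spec@kSigma)
      recs[[i]] <- out$record
      fids[[i]] <- out$fiducials
      rows[[i]] <- data.frame(
        recordId = sprintf("syn%05d", i),
        pr = m[["pr"]], qrs = m[["qrs"]], qt = m[["qt"]], hr = out$hr,
        rAmp = m[["rAmp"]], tAmp = m[["tAmp"]], stj = m[["stj"]],
        sex = sex,
        rTime = p@waves["R", "center"], sTime = p@waves["S", "center"],
        sAmp = p@waves["S", "amplitude"],
        rWidthRight = rWidthRight)
    }
    meas <- if (n > 0) do.call(rbind, rows) else
      data.frame(recordId = character(), pr = numeric(), qrs = numeric(),
                 qt = numeric(), hr = numeric(), rAmp = numeric(),
                 tAmp = numeric(), stj = numeric(), sex = integer(),
                 rTime = numeric(), sTime = numeric(), sAmp = numeric(),
                 rWidthRight = numeric())
    rownames(meas) <- NULL
    new("EcgDataset", records = recs, fiducials = fids,
        measurements = meas, spec = spec)
  })
}
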