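# Parametric 12-lead ECG simulator with exact ground-truth fiducials.
#
# A beat is a sum of Gaussian deflections (ECGSYN-style) on a constant
# baseline; the 12 leads are scale projections of one template, with lead
# V5 as the amplitude reference. Because fiducials are defined analytically
# from the wave parameters (support boundaries at center +/- kSigma*width)
# rather than detected from the signal, every record comes with exact
# ground truth for the seven measurements.

# run expr under a seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# snap a time in ms onto the sample grid (0-based sample index convention)
snapMs <- function(ms, fs = 500) round(ms * fs / 1000) * 1000 / fs

msToSample <- function(ms, fs = 500) as.integer(round(ms * fs / 1000)) + 1L

#' Default per-lead projection factors
#'
#' Scale factors applied to the template beat to form the 12 leads. The
#' eight independent leads get physiologically plausible values with V5
#' fixed at 1 (the amplitude reference); the four derived leads follow the
#' Einthoven/Goldberger relations (III = II - I, aVR = -(I + II)/2,
#' aVL = I - II/2, aVF = II - I/2) so every record is internally
#' consistent as a true 12-lead ECG.
#'
#' @return named numeric vector of length 12.
#' @export
defaultLeadProjection <- function() {
  p <- c(I = 0.6, II = 0.8, V1 = -0.4, V2 = 0.9, V3 = 1.1, V4 = 1.15,
         V5 = 1, V6 = 0.85)
  full <- c(I = p[["I"]], II = p[["II"]],
            III = p[["II"]] - p[["I"]],
            aVR = -(p[["I"]] + p[["II"]]) / 2,
            aVL = p[["I"]] - p[["II"]] / 2,
            aVF = p[["II"]] - p[["I"]] / 2,
            p[c("V1", "V2", "V3", "V4", "V5", "V6")])
  full[ecgLeads()]
}

# Gaussian wave evaluated at times t (ms); width2 = right-hand sigma for
# asymmetric waves (R-wave downslope steepness)
waveValue <- function(t, center, width, amplitude, width2 = width) {
  if (amplitude == 0) return(numeric(length(t)))
  s <- ifelse(t < center, width, width2)
  amplitude * exp(-(t - center)^2 / (2 * s^2))
}

#' Construct beat parameters from target measurements
#'
#' Builds a [WaveParams-class] whose analytically derived fiducials and
#' measurements reproduce the requested intervals and amplitudes exactly.
#' Intervals are laid out geometrically (QRS onset at `rTime - 0.45 * qrs`,
#' wave supports `center +/- kSigma * width`); the R, T and ST-component
#' amplitudes are then solved from a 3x3 linear system so that the template
#' evaluated at the (sample-grid-snapped) R peak, T peak and J point equals
#' `rAmp`, `tAmp` and `stj` relative to baseline.
#'
#' The R wave is a split Gaussian: `rWidthRight` sets its right-hand sigma
#' and therefore the steepness of the R downslope, independently of the R
#' amplitude, S wave and QRS duration.
#'
#' @param pr,qrs,qt target intervals (ms).
#' @param rAmp,tAmp,stj target amplitudes in the reference lead (uV).
#' @param rTime R-peak time (ms from record start).
#' @param pAmp P-wave amplitude (uV).
#' @param qFrac,sFrac Q- and S-wave depth as a fraction of `rAmp`.
#' @param sShiftMs shifts the S wave this many ms earlier while widening it
#'   to keep the J point (and so the QRS duration) fixed.
#' @param rWidthRight right-hand sigma of the R wave (ms); default
#'   `0.09 * qrs` (symmetric).
#' @param baseline baseline level (uV).
#' @param kSigma support half-width in sigmas (fiducial convention).
#' @param leadProjection per-lead scale factors.
#' @param fs sampling rate (Hz), used only to snap amplitude anchor points
#'   onto the sample grid.
#' @return a [WaveParams-class] object.
#' @export
#' @examples
#' p <- beatParams(pr = 158, qrs = 92, qt = 408,
#'                 rAmp = 1376, tAmp = 346, stj = -5)
#' measureBeat(deriveFiducials(p), makeBeat(p), rr = 60000 / 64)
beatParams <- function(pr, qrs, qt, rAmp, tAmp, stj,
                       rTime = 560, pAmp = 120, qFrac = 0.08, sFrac = 0.18,
                       sShiftMs = 0, rWidthRight = 0.09 * qrs,
                       baseline = 0, kSigma = 2.5,
                       leadProjection = defaultLeadProjection(), fs = 500) {
  stopifnot(pr > 0, qrs > 0, qt > qrs, rAmp != 0)
  qrsOn <- rTime - 0.45 * qrs
  qrsOff <- qrsOn + qrs
  sigQ <- 0.11 * qrs
  sigS <- 0.11 * qrs + sShiftMs / kSigma   # widen to keep J point fixed
  cQ <- qrsOn + kSigma * sigQ
  cS <- qrsOff - kSigma * sigS
  sigR <- 0.09 * qrs
  sigP <- min(18, (pr - 4) / (2 * kSigma))
  cP <- qrsOn - pr + kSigma * sigP
  sigT <- 30
  tOff <- qrsOn + qt
  cT <- tOff - kSigma * sigT
  cST <- qrsOff + 30
  sigST <- 25
  if (cS >= cT) stop("QT too short for the T wave to clear the S wave")

  waves <- data.frame(
    center = c(cP, cQ, rTime, cS, cT, cST),
    width = c(sigP, sigQ, sigR, sigS, sigT, sigST),
    width2 = c(sigP, sigQ, rWidthRight, sigS, sigT, sigST),
    amplitude = c(pAmp, -qFrac * rAmp, 0, -sFrac * rAmp, 0, 0),
    row.names = c("P", "Q", "R", "S", "T", "ST"))

  # solve R/T/ST amplitudes so the snapped anchor samples hit the targets
  anchors <- snapMs(c(rTime, cT, qrsOff), fs)
  unknowns <- c("R", "T", "ST")
  G <- sapply(unknowns, function(w)
    waveValue(anchors, waves[w, "center"], waves[w, "width"], 1,
              waves[w, "width2"]))
  fixedPart <- rowSums(sapply(c("P", "Q", "S"), function(w)
    waveValue(anchors, waves[w, "center"], waves[w, "width"],
              waves[w, "amplitude"], waves[w, "width2"])))
  waves[unknowns, "amplitude"] <- solve(G, c(rAmp, tAmp, stj) - fixedPart)

  new("WaveParams", waves = waves, baseline = baseline,
      leadProjection = leadProjection)
}

#' Evaluate the continuous single-lead beat waveform
#'
#' Returns the reference-lead (projection 1) waveform sampled at `fs`:
#' `baseline + sum of Gaussian waves`, in microvolts. Deterministic given
#' the parameters.
#'
#' @param params a [WaveParams-class].
#' @param fs sampling rate (Hz).
#' @param durationMs record duration (ms).
#' @return numeric vector of `round(durationMs * fs / 1000)` samples.
#' @export
makeBeat <- function(params, fs = 500, durationMs = 1200) {
  stopifnot(is(params, "WaveParams"))
  w <- params@waves
  if (any(w$amplitude != 0 & w$width <= 0))
    stop("invalid parameters: non-zero amplitude with non-positive width")
  n <- round(durationMs * fs / 1000)
  t <- (seq_len(n) - 1) * 1000 / fs
  v <- rep(params@baseline, n)
  for (i in seq_len(nrow(w)))
    v <- v + waveValue(t, w$center[i], w$width[i], w$amplitude[i],
                       if ("width2" %in% names(w)) w$width2[i] else w$width[i])
  v
}

#' Derive exact fiducial points from wave parameters
#'
#' Wave onsets and offsets are the analytic support boundaries
#' `center +/- kSigma * width`; no signal processing is involved, so the
#' fiducials are exact by construction. Overlapping supports of adjacent
#' waves are clipped with a warning.
#'
#' @param params a [WaveParams-class].
#' @param kSigma support half-width in sigmas.
#' @param beatTimes R-peak times for rhythm records; defaults to the single
#'   R peak of the beat.
#' @return a [FiducialSet-class]; times in ms from record start.
#' @export
deriveFiducials <- function(params, kSigma = 2.5, beatTimes = NULL) {
  w <- params@waves
  if (any(diff(w[c("P", "Q", "R", "S", "T"), "center"]) <= 0))
    stop("wave centers must be ordered P < Q < R < S < T")
  pOn <- w["P", "center"] - kSigma * w["P", "width"]
  pOff <- w["P", "center"] + kSigma * w["P", "width"]
  qrsOn <- w["Q", "center"] - kSigma * w["Q", "width"]
  qrsOff <- w["S", "center"] + kSigma * w["S", "width"]
  tOn <- w["T", "center"] - kSigma * w["T", "width"]
  tOff <- w["T", "center"] + kSigma * w["T", "width"]
  if (pOff > qrsOn) {
    warning("P-wave support overlaps QRS onset; clipping P offset")
    pOff <- qrsOn
  }
  if (qrsOff > tOn)
    warning("QRS support overlaps T-wave onset")
  new("FiducialSet", pOn = pOn, pOff = pOff, qrsOn = qrsOn,
      qrsOff = qrsOff, tOff = tOff, rPeak = w["R", "center"],
      tPeak = w["T", "center"],
      beatTimes = if (is.null(beatTimes)) w["R", "center"] else beatTimes)
}

#' Measure intervals and amplitudes from fiducials and a waveform
#'
#' Intervals come from fiducial arithmetic (PR = QRS onset - P onset,
#' QRS = J point - QRS onset, QT = T end - QRS onset); heart rate is
#' 60000 / RR with RR the mean inter-beat interval in ms; amplitudes are
#' the waveform at the (sample-snapped) peak or J-point time minus the
#' baseline. A missing (NA) fiducial makes the dependent measurements NA,
#' never zero.
#'
#' @param fid a [FiducialSet-class].
#' @param waveform reference-lead waveform in uV (numeric vector), or an
#'   [ECGRecord-class] whose dequantized lead V5 is used.
#' @param baseline baseline level in uV.
#' @param rr RR interval in ms, used when `fid` holds fewer than two beat
#'   times (e.g. a median beat whose source rhythm is known).
#' @param fs sampling rate (Hz).
#' @return a [MeasurementSet-class].
#' @export
measureBeat <- function(fid, waveform, baseline = 0, rr = NULL, fs = 500) {
  stopifnot(is(fid, "FiducialSet"))
  if (is(waveform, "ECGRecord")) {
    fs <- sampleRate(waveform)
    waveform <- microvolts(waveform)[match("V5", ecgLeads()), ]
  }
  at <- function(ms) {
    if (is.na(ms)) return(NA_real_)
    i <- msToSample(ms, fs)
    if (i < 1L || i > length(waveform)) return(NA_real_)
    waveform[i]
  }
  rrUse <- if (length(fid@beatTimes) >= 2L) mean(diff(fid@beatTimes)) else rr
  hr <- if (is.null(rrUse) || is.na(rrUse)) NA_real_ else 60000 / rrUse
  new("MeasurementSet",
      pr = fid@qrsOn - fid@pOn,
      qrs = fid@qrsOff - fid@qrsOn,
      qt = fid@tOff - fid@qrsOn,
      hr = hr,
      rAmp = at(fid@rPeak) - baseline,
      tAmp = at(fid@tPeak) - baseline,
      stj = at(fid@qrsOff) - baseline)
}

#' Quantize microvolts to integer LSB units
#'
#' Rounds half away from zero (symmetric for negative voltages), so the
#' dequantized value is within half an LSB (2.44 uV at the default
#' resolution) of the original.
#'
#' @param uv voltages in microvolts.
#' @param lsb microvolts per least significant bit.
#' @return integer-valued numeric in LSB units.
#' @export
#' @examples
#' quantizeVoltage(c(4.88, 0, 9.76)) # 1 0 2
quantizeVoltage <- function(uv, lsb = 4.88) {
  if (any(!is.finite(uv))) stop("voltages must be finite")
  sign(uv) * floor(abs(uv) / lsb + 0.5)
}

#' @rdname quantizeVoltage
#' @param lsbUnits integer LSB values.
#' @export
dequantizeVoltage <- function(lsbUnits, lsb = 4.88) lsbUnits * lsb

# 12-lead matrix (uV) from a template waveform: baseline common to all
# leads, deflections scaled per lead
projectLeads <- function(template, baseline, leadProjection) {
  m <- outer(unname(leadProjection), template - baseline) + baseline
  rownames(m) <- ecgLeads()
  m
}

#' Synthesize a quantized 12-lead record from beat parameters
#'
#' For a median record the template beat fills the 1.2-s window; for a
#' rhythm record beats are repeated at RR intervals with per-beat
#' fractional jitter, so heart rate is only estimable from multiple beats.
#' Optional additive white noise and a slow sinusoidal baseline wander are
#' applied before quantization (both consume the caller's RNG stream).
#'
#' @param params a [WaveParams-class].
#' @param kind `"median"` or `"rhythm"`.
#' @param hr heart rate (beats/min) governing the rhythm RR intervals.
#' @param noiseSd white noise SD (uV).
#' @param wanderAmp baseline wander amplitude (uV).
#' @param rrJitterSd fractional SD of per-beat RR jitter (rhythm only).
#' @param recordId record label.
#' @param fs,lsb sampling rate and quantization step.
#' @param kSigma fiducial support convention.
#' @return list with elements `record` ([ECGRecord-class]), `fiducials`
#'   ([FiducialSet-class]) and `hr` (realized heart rate).
#' @export
synthRecord <- function(params, kind = c("median", "rhythm"), hr = 64,
                        noiseSd = 0, wanderAmp = 0, rrJitterSd = 0,
                        recordId = "", fs = 500, lsb = 4.88, kSigma = 2.5) {
  kind <- match.arg(kind)
  durationMs <- if (kind == "median") 1200 else 10000
  n <- round(durationMs * fs / 1000)
  if (kind == "median") {
    template <- makeBeat(params, fs, durationMs)
    fid <- deriveFiducials(params, kSigma)
    realizedHr <- hr
  } else {
    meanRR <- 60000 / hr
    rPeakT <- params@waves["R", "center"]
    # beat R times covering the window, start random w.r.t. the recording
    r0 <- stats::runif(1, 0, meanRR)
    rTimes <- r0
    while (rTimes[length(rTimes)] < durationMs + 2 * meanRR) {
      jit <- if (rrJitterSd > 0) stats::rnorm(1, 0, rrJitterSd) else 0
      rTimes <- c(rTimes, rTimes[length(rTimes)] + meanRR * (1 + jit))
    }
    rTimes <- c(rTimes[1] - meanRR, rTimes)
    t <- (seq_len(n) - 1) * 1000 / fs
    template <- rep(params@baseline, n)
    w <- params@waves
    for (rt in rTimes) {
      off <- rt - rPeakT
      for (i in seq_len(nrow(w)))
        template <- template +
          waveValue(t, w$center[i] + off, w$width[i], w$amplitude[i],
                    w$width2[i])
    }
    inWin <- rTimes[rTimes >= 0 & rTimes < durationMs]
    realizedHr <- 60000 / mean(diff(inWin))
    # fiducials of the first beat whose full support lies inside the record
    span <- params@waves["T", "center"] + kSigma * params@waves["T", "width"] -
      (params@waves["P", "center"] - kSigma * params@waves["P", "width"])
    first <- inWin[which(inWin - rPeakT + params@waves["P", "center"] -
                           kSigma * params@waves["P", "width"] >= 0)[1]]
    fid0 <- deriveFiducials(params, kSigma, beatTimes = inWin)
    shift <- first - rPeakT
    fid <- new("FiducialSet",
               pOn = fid0@pOn + shift, pOff = fid0@pOff + shift,
               qrsOn = fid0@qrsOn + shift, qrsOff = fid0@qrsOff + shift,
               tOff = fid0@tOff + shift, rPeak = fid0@rPeak + shift,
               tPeak = fid0@tPeak + shift, beatTimes = inWin)
  }
  m <- projectLeads(template, params@baseline, params@leadProjection)
  if (wanderAmp > 0) {
    t <- (seq_len(n) - 1) / fs
    wander <- wanderAmp * sin(2 * pi * stats::runif(1, 0.15, 0.4) * t +
                                stats::runif(1, 0, 2 * pi))
    m <- sweep(m, 2, wander, "+")
  }
  if (noiseSd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noiseSd), nrow(m))
  q <- quantizeVoltage(m, lsb)
  storage.mode(q) <- "integer"
  rec <- new("ECGRecord", voltages = q, fs = fs, lsb = lsb,
             recordKind = kind, recordId = recordId)
  list(record = rec, fiducials = fid, hr = realizedHr)
}

#' Randomly time-shift a median record and its fiducials
#'
#' Applies a circular shift by an integer number of samples drawn uniformly
#' from [-40, +40] ms (the augmentation used during training so the network
#' cannot rely on the manufacturer's fixed beat centering). Interval
#' measurements are unchanged; fiducials shift consistently with the
#' signal. Rhythm records are refused: no alignment is performed for
#' rhythm ECGs.
#'
#' @param record an [ECGRecord-class], kind `"median"`.
#' @param fid the matching [FiducialSet-class].
#' @param shiftMs shift in ms (multiple of the sample period); drawn
#'   randomly when NULL.
#' @param maxShiftMs half-range of the random shift.
#' @return list with shifted `record`, `fiducials` and the `shiftMs` used.
#' @export
timeShiftRecord <- function(record, fid, shiftMs = NULL, maxShiftMs = 40) {
  stopifnot(is(record, "ECGRecord"))
  if (recordKind(record) != "median")
    stop("time shifting applies to median beats only; no alignment is performed for rhythm records")
  fs <- sampleRate(record)
  maxS <- round(maxShiftMs * fs / 1000)
  shiftSamples <- if (is.null(shiftMs)) {
    sample.int(2L * maxS + 1L, 1L) - maxS - 1L
  } else {
    s <- shiftMs * fs / 1000
    if (abs(s - round(s)) > 1e-9)
      stop("shiftMs must be an integer number of samples")
    as.integer(round(s))
  }
  n <- ncol(voltages(record))
  idx <- ((seq_len(n) - 1L - shiftSamples) %% n) + 1L
  v <- voltages(record)[, idx, drop = FALSE]
  storage.mode(v) <- "integer"
  d <- shiftSamples * 1000 / fs
  shifted <- new("ECGRecord", voltages = v, fs = fs, lsb = record@lsb,
                 recordKind = "median", recordId = recordId(record))
  newFid <- new("FiducialSet",
                pOn = fid@pOn + d, pOff = fid@pOff + d,
                qrsOn = fid@qrsOn + d, qrsOff = fid@qrsOff + d,
                tOff = fid@tOff + d, rPeak = fid@rPeak + d,
                tPeak = fid@tPeak + d, beatTimes = fid@beatTimes + d)
  list(record = shifted, fiducials = newFid, shiftMs = d)
}
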