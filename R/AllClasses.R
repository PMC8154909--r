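#' @import methods
NULL

#' Standard 12-lead names
#'
#' Lead order used throughout the package: the three limb leads, the three
#' augmented leads, then the six precordial leads. Lead V5 (position 11) is
#' the reference lead for amplitude measurements.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' ecgLeads()
ecgLeads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Indices of the linearly independent channels of a 12-lead ECG
#'
#' A 12-lead ECG carries only 8 independent signals: leads III, aVR, aVL and
#' aVF are fixed linear combinations of leads I and II (Einthoven/Goldberger
#' relations). Returns the positions of I, II, V1--V6 in [ecgLeads()].
#'
#' @return Integer vector of length 8.
#' @export
independentLeadIndices <- function() {
  match(c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"), ecgLeads())
}

# ---- ECGRecord ---------------------------------------------------------

#' ECGRecord: a quantized 12-lead ECG
#'
#' Voltages are stored as integer multiples of the least significant bit
#' (LSB) of the analog-to-digital converter, exactly as a digital
#' electrocardiograph would deliver them. Two record shapes exist: a
#' `"median"` representative beat (1.2 s, 600 samples at 500 Hz) and a
#' `"rhythm"` strip (10 s, 5000 samples).
#'
#' @slot voltages integer matrix, 12 leads x N samples, in LSB units.
#' @slot fs sampling rate in Hz.
#' @slot lsb value of one least significant bit in microvolts.
#' @slot recordKind `"median"` or `"rhythm"`.
#' @slot recordId opaque record label.
#' @export
setClass("ECGRecord",
  representation(voltages = "matrix", fs = "numeric", lsb = "numeric",
                 recordKind = "character", recordId = "character"),
  prototype(fs = 500, lsb = 4.88, recordKind = "median", recordId = ""))

setValidity("ECGRecord", function(object) {
  v <- object@voltages
  msg <- character()
  if (nrow(v) != 12L)
    msg <- c(msg, "voltages must have 12 rows (leads)")
  if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v)))
    msg <- c(msg, "voltages must be finite integers (LSB units)")
  if (!object@recordKind %in% c("median", "rhythm"))
    msg <- c(msg, "recordKind must be 'median' or 'rhythm'")
  expected <- switch(object@recordKind, median = 600L, rhythm = 5000L, NA_integer_)
  if (!is.na(expected) && object@fs == 500 && ncol(v) != expected)
    msg <- c(msg, sprintf("a %s record at 500 Hz must have %d samples, got %d",
                          object@recordKind, expected, ncol(v)))
  if (length(msg)) msg else TRUE
})

# ---- FiducialSet -------------------------------------------------------

#' FiducialSet: ground-truth wave boundary times for one beat
#'
#' All values are milliseconds from record start. `qrsOff` is the J point.
#' `beatTimes` holds the R-peak times of every beat in a rhythm record
#' (length 1 for a median beat).
#'
#' @slot pOn,pOff P-wave onset/offset (ms).
#' @slot qrsOn QRS onset (ms).
#' @slot qrsOff QRS offset, the J point (ms).
#' @slot tOff T-wave end (ms).
#' @slot rPeak,tPeak R- and T-peak times (ms).
#' @slot beatTimes R-peak times of all beats (ms).
#' @export
setClass("FiducialSet",
  representation(pOn = "numeric", pOff = "numeric", qrsOn = "numeric",
                 qrsOff = "numeric", tOff = "numeric", rPeak = "numeric",
                 tPeak = "numeric", beatTimes = "numeric"))

setValidity("FiducialSet", function(object) {
  msg <- character()
  ord <- c(object@pOn, object@pOff, object@qrsOn, object@qrsOff, object@tOff)
  if (any(is.infinite(ord)) || any(is.nan(ord)))
    msg <- c(msg, "fiducials must not be infinite or NaN")
  else if (!anyNA(ord)) {
    # NA marks a missing fiducial (measurements become undefined, not
    # zero); equalities cover the zero-width limit where a wave's onset
    # and offset collapse onto its center
    if (!(object@pOn <= object@pOff && object@pOff <= object@qrsOn &&
          object@qrsOn <= object@qrsOff && object@qrsOff < object@tOff))
      msg <- c(msg, "fiducials must satisfy pOn <= pOff <= qrsOn <= qrsOff < tOff")
    if (any(ord < 0))
      msg <- c(msg, "fiducials must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

# ---- MeasurementSet ----------------------------------------------------

#' MeasurementSet: the seven derived ECG measurements
#'
#' Intervals in ms, heart rate in beats/min, amplitudes in microvolts
#' relative to the record baseline. `sexLabel` is an optional binary class
#' label (NA when absent).
#'
#' @slot pr,qrs,qt intervals (ms).
#' @slot hr heart rate (beats/min), 60000 / mean RR.
#' @slot rAmp,tAmp,stj amplitudes (uV): R peak, T peak, J-point elevation.
#' @slot sexLabel integer 0/1 or NA.
#' @export
setClass("MeasurementSet",
  representation(pr = "numeric", qrs = "numeric", qt = "numeric",
                 hr = "numeric", rAmp = "numeric", tAmp = "numeric",
                 stj = "numeric", sexLabel = "integer"),
  prototype(sexLabel = NA_integer_))

setValidity("MeasurementSet", function(object) {
  msg <- character()
  if (is.finite(object@qt) && is.finite(object@qrs) && object@qt <= object@qrs)
    msg <- c(msg, "QT must exceed QRS duration")
  if (is.finite(object@pr) && object@pr <= 0) msg <- c(msg, "PR must be positive")
  if (is.finite(object@hr) && object@hr <= 0) msg <- c(msg, "HR must be positive")
  if (length(msg)) msg else TRUE
})

# ---- WaveParams --------------------------------------------------------

#' WaveParams: parametric description of one beat
#'
#' A beat is a sum of Gaussian deflections, one per wave, on a constant
#' baseline. The `waves` table has one row per component with columns
#' `center` (ms), `width` (Gaussian sigma, ms) and `amplitude` (signed uV).
#' Rows "P","Q","R","S","T" are the physiological waves; an optional "ST"
#' row is a broad low component used to set the J-point elevation. The
#' 12-lead signal is `baseline + leadProjection[l] * template`.
#'
#' @slot waves data.frame with rownames P,Q,R,S,T (optionally ST) and
#'   columns center, width, amplitude.
#' @slot baseline baseline level (uV).
#' @slot leadProjection named numeric vector of 12 per-lead scale factors;
#'   V5 is 1 by convention so amplitudes are V5-referenced.
#' @export
setClass("WaveParams",
  representation(waves = "data.frame", baseline = "numeric",
                 leadProjection = "numeric"))

setValidity("WaveParams", function(object) {
  w <- object@waves
  msg <- character()
  need <- c("center", "width", "amplitude")
  if (!all(need %in% colnames(w)))
    return("waves needs columns center, width, amplitude")
  core <- c("P", "Q", "R", "S", "T")
  if (!all(core %in% rownames(w)))
    msg <- c(msg, "waves must contain rows P, Q, R, S, T")
  bad <- w$amplitude != 0 & w$width <= 0
  if (any(bad))
    msg <- c(msg, "every wave with non-zero amplitude needs width > 0")
  if (all(core %in% rownames(w))) {
    ctr <- w[core, "center"]
    if (any(diff(ctr) <= 0))
      msg <- c(msg, "wave centers must be ordered P < Q < R < S < T")
  }
  if (length(object@leadProjection) != 12L)
    msg <- c(msg, "leadProjection must have 12 entries")
  if (length(msg)) msg else TRUE
})

# ---- PopulationSpec ----------------------------------------------------

#' PopulationSpec: statistical description of a study population
#'
#' Each measurement is described by its median and 5th/95th percentiles and
#' sampled from a split-normal distribution that reproduces those three
#' quantiles exactly in expectation. `sexEffect` scales the planted
#' between-class difference: a steeper R-wave downslope (earlier, deeper S
#' wave at fixed QRS duration) plus a small QRS-duration shift, so that
#' duration alone is a weak sex predictor and downslope morphology the
#' strong one. At `sexEffect = 0` the two classes are identical in
#' distribution.
#'
#' @slot targets data.frame, rows = measurements (hr, qt, pr, qrs, stj,
#'   rAmp, tAmp), columns median, p05, p95.
#' @slot noiseSd additive white noise SD (uV).
#' @slot wanderAmp baseline wander amplitude (uV), slow sinusoid.
#' @slot sexEffect magnitude of the planted sex morphology difference.
#' @slot sexQrsShiftMs QRS-duration median shift (ms) between classes,
#'   scaled by `sexEffect`.
#' @slot sexSlopeShiftMs how much earlier the S wave sits in class 1 (ms),
#'   scaled by `sexEffect`.
#' @slot rrJitterSd per-beat fractional RR jitter for rhythm strips.
#' @slot kSigma half-width of a wave's support in units of its sigma.
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("PopulationSpec",
  representation(targets = "data.frame", noiseSd = "numeric",
                 wanderAmp = "numeric", sexEffect = "numeric",
                 sexQrsShiftMs = "numeric", sexSlopeShiftMs = "numeric",
                 rrJitterSd = "numeric", kSigma = "numeric", seed = "integer"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  need <- c("hr", "qt", "pr", "qrs", "stj", "rAmp", "tAmp")
  if (!all(need %in% rownames(object@targets)))
    msg <- c(msg, paste("targets needs rows", paste(need, collapse = ", ")))
  if (!all(c("median", "p05", "p95") %in% colnames(object@targets)))
    msg <- c(msg, "targets needs columns median, p05, p95")
  else {
    t <- object@targets
    if (any(t$p05 > t$median | t$median > t$p95))
      msg <- c(msg, "need p05 <= median <= p95 for every measurement")
  }
  if (object@noiseSd < 0 || object@wanderAmp < 0)
    msg <- c(msg, "noiseSd and wanderAmp must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---- EcgDataset --------------------------------------------------------

#' EcgDataset: a generated collection of records with ground truth
#'
#' Holds parallel lists of [ECGRecord-class] and [FiducialSet-class]
#' objects plus a measurement table with one row per record. Besides the
#' seven measurements the table carries the generator's morphology ground
#' truth (R/S timing and amplitude) used by the logistic sex probes.
#'
#' @slot records list of ECGRecord.
#' @slot fiducials list of FiducialSet.
#' @slot measurements data.frame, one row per record.
#' @slot spec the PopulationSpec that generated the data.
#' @export
setClass("EcgDataset",
  representation(records = "list", fiducials = "list",
                 measurements = "data.frame", spec = "PopulationSpec"))

setValidity("EcgDataset", function(object) {
  n <- length(object@records)
  if (length(object@fiducials) != n)
    return("records and fiducials must have equal length")
  if (nrow(object@measurements) != n)
    return("measurements must have one row per record")
  TRUE
})

# ---- ArchitectureSpec --------------------------------------------------

#' ArchitectureSpec: declarative description of the residual CNN
#'
#' The network is: conv(f1, k1) -> BN -> ReLU -> conv(f2, k2) -> BN -> ReLU
#' -> average pool (size 2) -> M residual modules -> global average pool ->
#' single-neuron head. Each residual module is conv(r1, kr) -> BN -> ReLU
#' -> conv(r2, kr) -> BN -> dropout -> add skip -> ReLU, with "same"
#' padding so the skip addition is well defined. Because the head is a
#' global average pool, the parameter count is independent of the input
#' length, and the same network accepts both median (600-sample) and rhythm
#' (5000-sample) records.
#'
#' @slot nLeads number of leads in the records fed to the network (12).
#' @slot independentLeads if TRUE the network consumes only the 8 linearly
#'   independent channels (I, II, V1--V6) of the 12-lead record.
#' @slot initialFilters,initialKernels the two initial convolutions.
#' @slot nResidualModules number of residual modules.
#' @slot residualFilters filters of the two convolutions in each module.
#' @slot residualKernel shared kernel size inside the modules.
#' @slot dropoutRate drop rate of the per-module dropout.
#' @slot poolSize size/stride of the average pool after the initial block.
#' @slot head `"regression"` (linear) or `"classification"` (logistic).
#' @export
setClass("ArchitectureSpec",
  representation(nLeads = "integer", independentLeads = "logical",
                 initialFilters = "integer", initialKernels = "integer",
                 nResidualModules = "integer", residualFilters = "integer",
                 residualKernel = "integer", dropoutRate = "numeric",
                 poolSize = "integer", head = "character"))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (length(object@initialFilters) != 2L || length(object@initialKernels) != 2L)
    msg <- c(msg, "initialFilters and initialKernels must have length 2")
  if (length(object@residualFilters) != 2L)
    msg <- c(msg, "residualFilters must have length 2")
  else if (object@residualFilters[2] != object@initialFilters[2])
    msg <- c(msg, paste("skip addition requires the module output channels to",
                        "equal the module input channels"))
  if (!object@head %in% c("regression", "classification"))
    msg <- c(msg, "head must be 'regression' or 'classification'")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

# ---- EcgNetwork --------------------------------------------------------

#' EcgNetwork: a built, differentiable residual CNN
#'
#' The constructed network: an ordered list of layer objects (convolution,
#' batch normalization, ReLU, pooling, dropout, residual bookkeeping,
#' global average pool, dense head) with explicit forward and backward
#' passes. Training state (batch-norm running statistics) lives in the
#' layer objects; functions that modify it return an updated object.
#'
#' @slot spec the [ArchitectureSpec-class] it was built from.
#' @slot layers internal list of layer objects.
#' @slot seed integer seed used for weight initialization.
#' @export
setClass("EcgNetwork",
  representation(spec = "ArchitectureSpec", layers = "list", seed = "integer"))

# ---- AttentionMap ------------------------------------------------------

#' AttentionMap: time-resolved importance of an ECG for one prediction
#'
#' ECGradCAM output: a non-negative importance value for every sample of
#' every lead, plus the lead-averaged profile (the arithmetic mean of the
#' per-lead rows). With `"unit"` normalization the maximum is 1 unless the
#' map is identically zero.
#'
#' @slot perLead 12 x N importance matrix.
#' @slot averaged length-N lead-averaged importance.
#' @slot layerName network layer the map was computed at.
#' @slot outputIndex output neuron explained.
#' @slot normalization `"raw"` or `"unit"`.
#' @export
setClass("AttentionMap",
  representation(perLead = "matrix", averaged = "numeric",
                 layerName = "character", outputIndex = "integer",
                 normalization = "character"))

setValidity("AttentionMap", function(object) {
  msg <- character()
  if (nrow(object@perLead) != 12L)
    msg <- c(msg, "perLead must have 12 rows")
  if (length(object@averaged) != ncol(object@perLead))
    msg <- c(msg, "averaged must match perLead columns")
  if (any(object@perLead < -1e-12))
    msg <- c(msg, "importance values must be non-negative")
  if (!isTRUE(all.equal(unname(colMeans(object@perLead)), unname(object@averaged),
                        tolerance = 1e-8)))
    msg <- c(msg, "averaged must equal the mean of the per-lead rows")
  if (object@normalization == "unit" && length(object@averaged)) {
    m <- max(object@perLead)
    if (m > 0 && abs(m - 1) > 1e-8)
      msg <- c(msg, "unit normalization requires max importance 1")
  }
  if (length(msg)) msg else TRUE
})
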