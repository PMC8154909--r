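# Accessor generics for the S4 containers.

#' @rdname ECGRecord-class
#' @param object,x an object.
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @rdname ECGRecord-class
#' @export
setGeneric("microvolts", function(object) standardGeneric("microvolts"))

#' @rdname ECGRecord-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname ECGRecord-class
#' @export
setGeneric("recordKind", function(object) standardGeneric("recordKind"))

#' @rdname ECGRecord-class
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @rdname EcgDataset-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname EcgDataset-class
#' @export
setGeneric("fiducials", function(object) standardGeneric("fiducials"))

#' @rdname EcgDataset-class
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname EcgNetwork-class
#' @export
setGeneric("layerNames", function(object) standardGeneric("layerNames"))

#' @rdname AttentionMap-class
#' @export
setGeneric("perLead", function(object) standardGeneric("perLead"))

#' @rdname AttentionMap-class
#' @export
setGeneric("averagedMap", function(object) standardGeneric("averagedMap"))

# ---- ECGRecord methods -------------------------------------------------

#' @rdname ECGRecord-class
#' @export
setMethod("voltages", "ECGRecord", function(object) object@voltages)

#' @describeIn ECGRecord-class dequantized signal in microvolts.
#' @export
setMethod("microvolts", "ECGRecord", function(object) object@voltages * object@lsb)

#' @rdname ECGRecord-class
#' @export
setMethod("sampleRate", "ECGRecord", function(object) object@fs)

#' @rdname ECGRecord-class
#' @export
setMethod("recordKind", "ECGRecord", function(object) object@recordKind)

#' @rdname ECGRecord-class
#' @export
setMethod("recordId", "ECGRecord", function(object) object@recordId)

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord '%s': %s beat, 12 x %d samples @ %g Hz (LSB %g uV)\n",
              object@recordId, object@recordKind, ncol(object@voltages),
              object@fs, object@lsb))
})

setMethod("show", "FiducialSet", function(object) {
  cat(sprintf(paste0("FiducialSet (ms): P [%g, %g]  QRS [%g, %g]  Toff %g",
                     "  Rpeak %g  Tpeak %g  beats %d\n"),
              object@pOn, object@pOff, object@qrsOn, object@qrsOff,
              object@tOff, object@rPeak, object@tPeak,
              length(object@beatTimes)))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf(paste0("MeasurementSet: PR %.1f ms  QRS %.1f ms  QT %.1f ms  ",
                     "HR %.1f bpm\n  Ramp %.1f uV  Tamp %.1f uV  STJ %.1f uV",
                     "  sex %s\n"),
              object@pr, object@qrs, object@qt, object@hr,
              object@rAmp, object@tAmp, object@stj,
              ifelse(is.na(object@sexLabel), "NA", object@sexLabel)))
})

#' Measurements as a one-row data.frame
#'
#' @param m a [MeasurementSet-class].
#' @return data.frame with columns pr, qrs, qt, hr, rAmp, tAmp, stj, sex.
#' @export
asMeasurementRow <- function(m) {
  stopifnot(is(m, "MeasurementSet"))
  data.frame(pr = m@pr, qrs = m@qrs, qt = m@qt, hr = m@hr,
             rAmp = m@rAmp, tAmp = m@tAmp, stj = m@stj,
             sex = as.integer(m@sexLabel))
}

# ---- EcgDataset methods ------------------------------------------------

#' @rdname EcgDataset-class
#' @export
setMethod("records", "EcgDataset", function(object) object@records)

#' @rdname EcgDataset-class
#' @export
setMethod("fiducials", "EcgDataset", function(object) object@fiducials)

#' @rdname EcgDataset-class
#' @export
setMethod("measurements", "EcgDataset", function(object) object@measurements)

#' @rdname EcgDataset-class
#' @export
setMethod("length", "EcgDataset", function(x) length(x@records))

#' @describeIn EcgDataset-class subset a dataset by record index.
#' @param i integer indices.
#' @param j,drop unused.
#' @param ... unused.
#' @export
setMethod("[", "EcgDataset", function(x, i, j, ..., drop = FALSE) {
  new("EcgDataset", records = x@records[i], fiducials = x@fiducials[i],
      measurements = x@measurements[i, , drop = FALSE], spec = x@spec)
})

setMethod("show", "EcgDataset", function(object) {
  kinds <- table(vapply(object@records, recordKind, ""))
  cat(sprintf("EcgDataset: %d records (%s)\n", length(object@records),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", ")))
  if (nrow(object@measurements)) {
    med <- vapply(object@measurements[c("pr", "qrs", "qt", "hr")],
                  stats::median, numeric(1))
    cat(sprintf("  median PR %.0f ms, QRS %.0f ms, QT %.0f ms, HR %.0f bpm\n",
                med["pr"], med["qrs"], med["qt"], med["hr"]))
  }
})

# ---- Network / map methods ---------------------------------------------

#' @rdname EcgNetwork-class
#' @export
setMethod("layerNames", "EcgNetwork", function(object) {
  nm <- vapply(object@layers, function(l) l$name %||% "", "")
  nm[nzchar(nm)]
})

setMethod("show", "EcgNetwork", function(object) {
  s <- object@spec
  cnt <- countParameters(object, includeNontrainable = TRUE)
  cat(sprintf(paste0("EcgNetwork: %d-channel input, %d residual modules ",
                     "(kernel %d), %s head\n  %s parameters ",
                     "(%s trainable)\n"),
              networkInputChannels(s), s@nResidualModules, s@residualKernel,
              s@head, format(cnt, big.mark = ","),
              format(countParameters(object, includeNontrainable = FALSE),
                     big.mark = ",")))
})

setMethod("show", "AttentionMap", function(object) {
  cat(sprintf(paste0("AttentionMap at '%s' (%s): 12 x %d, peak importance ",
                     "at sample %d\n"),
              object@layerName, object@normalization, ncol(object@perLead),
              which.max(object@averaged)))
})

#' @rdname AttentionMap-class
#' @export
setMethod("perLead", "AttentionMap", function(object) object@perLead)

#' @rdname AttentionMap-class
#' @export
setMethod("averagedMap", "AttentionMap", function(object) object@averaged)

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf(paste0("ArchitectureSpec: initial conv %d(k%d) -> %d(k%d), ",
                     "pool %d, %d x residual [%d, %d](k%d), dropout %.2f, ",
                     "%s head, %d-lead input%s\n"),
              object@initialFilters[1], object@initialKernels[1],
              object@initialFilters[2], object@initialKernels[2],
              object@poolSize, object@nResidualModules,
              object@residualFilters[1], object@residualFilters[2],
              object@residualKernel, object@dropoutRate, object@head,
              object@nLeads,
              if (object@independentLeads) " (8 independent channels)" else ""))
})

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec targets (median [p05; p95]):\n")
  t <- object@targets
  for (r in rownames(t))
    cat(sprintf("  %-5s %g [%g; %g]\n", r, t[r, "median"], t[r, "p05"],
                t[r, "p95"]))
  cat(sprintf("  noise SD %g uV, wander %g uV, sex effect %g, seed %d\n",
              object@noiseSd, object@wanderAmp, object@sexEffect, object@seed))
})

# internal convenience
`%||%` <- function(a, b) if (is.null(a)) b else a
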