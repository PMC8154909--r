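# Wave-blanking occlusion: remove the P, QRS or T wave by lead-specific
# linear interpolation and quantify how much each model's predictions
# degrade.

waveInterval <- function(fid, wave) {
  switch(wave,
    P = c(fid@pOn, fid@pOff),
    QRS = c(fid@qrsOn, fid@qrsOff),
    T = c(2 * fid@tPeak - fid@tOff, fid@tOff),  # symmetric T onset
    stop("wave must be one of 'P', 'QRS', 'T'"))
}

#' Blank a wave by lead-specific linear interpolation
#'
#' Replaces the samples strictly between the wave's onset and offset, in
#' every lead independently, by the straight line joining that lead's
#' values at the onset and offset samples; the endpoints and everything
#' outside the wave are untouched, and the interpolated segment is
#' re-quantized so the record stays integer-valued. The operation is
#' idempotent and, for a rhythm record, is applied beat by beat at every
#' R-peak time.
#'
#' @param record an [ECGRecord-class].
#' @param fid the record's [FiducialSet-class].
#' @param wave `"P"`, `"QRS"` or `"T"`.
#' @return a blanked [ECGRecord-class].
#' @export
blankWave <- function(record, fid, wave = c("P", "QRS", "T")) {
  wave <- match.arg(wave)
  iv <- waveInterval(fid, wave)
  if (anyNA(iv)) stop("missing fiducials for wave ", wave)
  if (iv[1] > iv[2]) stop("wave onset after offset")
  fs <- sampleRate(record)
  v <- voltages(record)
  n <- ncol(v)
  offsets <- if (recordKind(record) == "rhythm")
    fid@beatTimes - fid@rPeak else 0
  for (off in offsets) {
    i0 <- msToSample(iv[1] + off, fs)
    i1 <- msToSample(iv[2] + off, fs)
    if (recordKind(record) == "rhythm") {
      if (i1 > n || i0 < 1L) next   # beat truncated by the record edge
    } else if (i0 < 1L || i1 > n) {
      stop("fiducials outside the record")
    }
    if (i1 - i0 < 2L) next          # no interior samples
    line <- matrix(0, nrow(v), i1 - i0 + 1L)
    for (l in seq_len(nrow(v)))
      line[l, ] <- seq(v[l, i0], v[l, i1], length.out = i1 - i0 + 1L)
    interior <- 2:(ncol(line) - 1L)
    v[, (i0 + 1L):(i1 - 1L)] <- sign(line[, interior]) *
      floor(abs(line[, interior]) + 0.5)
  }
  storage.mode(v) <- "integer"
  new("ECGRecord", voltages = v, fs = fs, lsb = record@lsb,
      recordKind = recordKind(record), recordId = recordId(record))
}

#' Blank one wave across a whole dataset
#'
#' @param dataset an [EcgDataset-class].
#' @param wave `"P"`, `"QRS"`, `"T"`, or `"none"` (returns the dataset
#'   unchanged).
#' @return an [EcgDataset-class] with every record blanked.
#' @export
blankDataset <- function(dataset, wave) {
  if (wave == "none") return(dataset)
  recs <- mapply(blankWave, records(dataset), fiducials(dataset),
                 MoreArgs = list(wave = wave), SIMPLIFY = FALSE)
  new("EcgDataset", records = recs, fiducials = fiducials(dataset),
      measurements = measurements(dataset), spec = dataset@spec)
}

#' Wave-blanking study
#'
#' Evaluates each task's model(s) on the unmodified dataset and on each
#' blanked variant, reporting the error (MAE) or accuracy per condition
#' with the ratio to the unblanked baseline. When a task has several
#' models (one per fold) the metric is reported as mean with SD across
#' models.
#'
#' @param models named list, task -> [EcgNetwork-class] or list of
#'   networks.
#' @param dataset an [EcgDataset-class] with fiducials and labels.
#' @param waves which waves to blank.
#' @return a BlankingReport data.frame with columns task, wave, metric,
#'   value, sd, ratio.
#' @export
blankingStudy <- function(models, dataset,
                          waves = c("none", "P", "QRS", "T")) {
  stopifnot(length(names(models)) == length(models))
  meas <- measurements(dataset)
  variants <- lapply(stats::setNames(waves, waves),
                     function(w) blankDataset(dataset, w))
  rows <- list()
  for (task in names(models)) {
    if (is.null(meas[[task]])) stop("no labels for task ", task)
    y <- meas[[task]]
    nets <- models[[task]]
    if (is(nets, "EcgNetwork")) nets <- list(nets)
    metricName <- if (task == "sex") "accuracy" else "mae"
    vals <- sapply(waves, function(w) {
      per <- vapply(nets, function(nt) {
        p <- predictEcg(nt, variants[[w]])
        if (task == "sex") unname(classificationMetrics(p, y)["accuracy"])
        else mae(p, y)
      }, numeric(1))
      c(mean(per), if (length(per) > 1L) stats::sd(per) else 0)
    })
    base <- vals[1, waves == "none"]
    rows[[task]] <- data.frame(task = task, wave = waves,
                               metric = metricName, value = vals[1, ],
                               sd = vals[2, ], ratio = vals[1, ] / base)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
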