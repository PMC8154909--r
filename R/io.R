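# Plain-text record bundles: one CSV per record (columns = leads, rows =
# samples, LSB units) with a JSON sidecar holding sampling metadata,
# fiducials and measurements, plus a dataset manifest.

fidToList <- function(fid) {
  list(pOn = fid@pOn, pOff = fid@pOff, qrsOn = fid@qrsOn,
       qrsOff = fid@qrsOff, tOff = fid@tOff, rPeak = fid@rPeak,
       tPeak = fid@tPeak, beatTimes = fid@beatTimes)
}

listToFid <- function(l) {
  new("FiducialSet", pOn = l$pOn, pOff = l$pOff, qrsOn = l$qrsOn,
      qrsOff = l$qrsOff, tOff = l$tOff, rPeak = l$rPeak, tPeak = l$tPeak,
      beatTimes = as.numeric(unlist(l$beatTimes)))
}

#' Write a dataset as a plain-text bundle
#'
#' Each record becomes `<id>.csv` (12 lead columns, one row per sample,
#' integer LSB values) and `<id>.json` (fs, lsb, kind, fiducials in ms,
#' measurement row); `manifest.csv` lists every record with its labels.
#'
#' @param dataset an [EcgDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEcgBundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meas <- measurements(dataset)
  for (i in seq_along(dataset)) {
    rec <- records(dataset)[[i]]
    id <- recordId(rec)
    v <- t(voltages(rec))
    colnames(v) <- ecgLeads()
    utils::write.csv(v, file.path(dir, paste0(id, ".csv")),
                     row.names = FALSE)
    side <- list(fs = sampleRate(rec), lsb = rec@lsb,
                 recordKind = recordKind(rec),
                 fiducials = fidToList(fiducials(dataset)[[i]]),
                 measurements = as.list(meas[i, setdiff(names(meas),
                                                        "recordId")]))
    jsonlite::write_json(side, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(meas, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a bundle written by [writeEcgBundle()]
#'
#' @param dir bundle directory.
#' @return an [EcgDataset-class] (with a default [PopulationSpec-class],
#'   since the generating spec is not part of the bundle).
#' @export
readEcgBundle <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- vector("list", nrow(manifest))
  fids <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$recordId[i]
    v <- as.matrix(utils::read.csv(file.path(dir, paste0(id, ".csv"))))
    side <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                                simplifyVector = TRUE)
    m <- t(v)
    storage.mode(m) <- "integer"
    rownames(m) <- ecgLeads()
    recs[[i]] <- new("ECGRecord", voltages = m, fs = side$fs,
                     lsb = side$lsb, recordKind = side$recordKind,
                     recordId = as.character(id))
    fids[[i]] <- listToFid(side$fiducials)
  }
  new("EcgDataset", records = recs, fiducials = fids,
      measurements = manifest, spec = populationSpec())
}

#' Export an attention map as CSV
#'
#' Rows are the 12 leads plus the lead average; columns are samples.
#'
#' @param map an [AttentionMap-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAttentionCsv <- function(map, file) {
  m <- rbind(perLead(map), averaged = averagedMap(map))
  utils::write.csv(m, file, row.names = TRUE)
  invisible(file)
}
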