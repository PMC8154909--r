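# Attention-map rendering: the ECG trace colored by importance, red for
# high and blue for low.

#' Plot an ECG lead colored by attention
#'
#' Draws one lead of a record with each segment colored by the attention
#' map's importance at that sample (blue = low, red = high), the classic heat-trace
#' style rendering of an ECGradCAM map.
#'
#' @param record an [ECGRecord-class].
#' @param map an [AttentionMap-class] computed for the record.
#' @param lead lead name (default "V5").
#' @param useAveraged color by the lead-averaged importance instead of the
#'   lead's own row.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the importance vector used for coloring.
#' @export
plotAttentionMap <- function(record, map, lead = "V5", useAveraged = TRUE,
                             ...) {
  li <- match(lead, ecgLeads())
  if (is.na(li)) stop("unknown lead ", lead)
  y <- microvolts(record)[li, ]
  tms <- (seq_along(y) - 1) * 1000 / sampleRate(record)
  imp <- if (useAveraged) averagedMap(map) else perLead(map)[li, ]
  rel <- if (max(imp) > 0) imp / max(imp) else imp
  pal <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  cols <- grDevices::rgb(pal(rel), maxColorValue = 255)
  graphics::plot(tms, y, type = "n", xlab = "time (ms)",
                 ylab = sprintf("lead %s (uV)", lead), ...)
  graphics::segments(tms[-length(tms)], y[-length(y)], tms[-1], y[-1],
                     col = cols[-length(cols)], lwd = 2)
  invisible(imp)
}
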