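# ECGradCAM: gradient-weighted class activation maps for multichannel
# 1-D signals, computed at any convolutional layer, resolved per lead and
# averaged across leads.

#' Default explanation layer
#'
#' The final convolution of the last residual module: the layer whose
#' feature maps feed the prediction head, so its map shows what the
#' network attends to at the moment of prediction.
#'
#' @param net an [EcgNetwork-class].
#' @return layer name string.
#' @export
defaultExplanationLayer <- function(net) {
  sprintf("res%d_conv2", net@spec@nResidualModules)
}

# single forward + backward in evaluation mode for one record, capturing
# the feature maps and gradients at `layerName` and at the input.
# The feature maps taken for a convolution are its *rectified* unit
# output: the activation at the ReLU that completes the layer's block
# (after batch norm and, for a module-final convolution, after the skip
# addition), per the GradCAM convention of explaining post-activation
# maps. When no ReLU follows before the next convolution (e.g. a bare
# conv feeding the pooling head), the convolution output itself is used.
ecgradcamCore <- function(net, record, layerName) {
  nm <- vapply(net@layers, function(l) l$name %||% "", "")
  li <- match(layerName, nm)
  if (is.na(li)) stop("no layer named '", layerName, "'")
  if (net@layers[[li]]$kind != "conv")
    stop("'", layerName, "' is not a convolutional layer")
  kinds <- vapply(net@layers, `[[`, "", "kind")
  ai <- li
  for (j in seq(li + 1L, length.out = max(0L, length(net@layers) - li))) {
    if (kinds[j] == "relu") { ai <- j; break }
    if (kinds[j] %in% c("conv", "gap", "dense")) break
  }
  arr <- prepareInputArray(record, net@spec)
  fw <- nnForward(net@layers, arr, training = FALSE, keepCache = TRUE)
  # classification: explain the score of the *predicted* class, so maps
  # for either class show its supporting evidence (for a single-logit
  # head, class 0's score is the negated logit)
  dout <- if (net@spec@head == "classification" && fw$out < 0) -1 else 1
  bw <- nnBackward(net@layers, fw$caches, dout, captureIndices = ai)
  A <- fw$acts[[ai]]
  dA <- bw$captured[[as.character(ai)]]
  C <- dim(A)[1]
  list(A = matrix(A, C), dA = matrix(dA, C),
       dInput = matrix(bw$dInput, dim(arr)[1]),
       inputLen = dim(arr)[2], out = fw$out)
}

#' GradCAM temporal importance at a network layer
#'
#' For feature maps \eqn{A^k} at the layer, the channel weights are the
#' temporal averages \eqn{\alpha_k} of \eqn{\partial y / \partial A^k};
#' the map is \eqn{ReLU(\sum_k \alpha_k A^k(t))} at the layer's temporal
#' resolution. Deterministic: the network runs in evaluation mode. A map
#' that is zero everywhere (e.g. the output does not depend on the input)
#' is returned as zeros with a warning, not an error.
#'
#' @param net an [EcgNetwork-class].
#' @param record an [ECGRecord-class].
#' @param layerName a convolutional layer name (see [layerNames()]).
#' @param outputIndex output neuron (the networks here have one).
#' @param rectify apply the ReLU; FALSE keeps signed contributions, which
#'   can be diagnostic for regression outputs.
#' @return numeric importance vector at layer resolution.
#' @export
layerGradcam <- function(net, record, layerName = defaultExplanationLayer(net),
                         outputIndex = 1L, rectify = TRUE) {
  stopifnot(outputIndex == 1L)
  core <- ecgradcamCore(net, record, layerName)
  alpha <- rowMeans(core$dA)
  m <- colSums(core$A * alpha)
  if (rectify) m <- pmax(m, 0)
  if (all(m == 0))
    warning("attention map is identically zero (no gradient reaches the layer)")
  m
}

#' Linear upsampling of an importance profile
#'
#' Maps a layer-resolution profile onto the input resolution by linear
#' interpolation; endpoints are preserved and a constant profile stays
#' constant.
#'
#' @param map numeric vector.
#' @param targetLen target length, at least `length(map)`.
#' @return numeric vector of length `targetLen`.
#' @export
upsampleMap <- function(map, targetLen) {
  n <- length(map)
  if (n == 0L) stop("empty map")
  if (targetLen < n) stop("targetLen must be >= map length")
  if (n == 1L) return(rep(map, targetLen))
  if (targetLen == n) return(map)
  stats::approx(seq(0, 1, length.out = n), map,
                xout = seq(0, 1, length.out = targetLen))$y
}

#' Per-lead ECGradCAM attention map
#'
#' The layer-level GradCAM profile G(t) is upsampled to the input
#' resolution and distributed over leads by the normalized input-gradient
#' weights \eqn{w_l(t) = |\partial y/\partial x_l(t)| / \sum_l |\partial
#' y/\partial x_l(t)|} (uniform where all input gradients vanish), giving
#' `perLead[l, t] = G(t) * w_l(t)`. The lead average of the per-lead rows
#' is therefore proportional to G itself. With
#' `method = "saliency"` the per-lead map is instead the plain absolute
#' input gradient. When the network consumes only the 8 independent
#' channels, the four derived leads carry no separate signal and receive
#' zero weight.
#'
#' @inheritParams layerGradcam
#' @param normalization `"unit"` scales the map so its maximum is 1 (zero
#'   maps stay zero); `"raw"` keeps gradient units.
#' @param method `"ecgradcam"` (default) or `"saliency"`.
#' @return an [AttentionMap-class].
#' @export
perLeadMaps <- function(net, record, layerName = defaultExplanationLayer(net),
                        outputIndex = 1L,
                        normalization = c("unit", "raw"),
                        method = c("ecgradcam", "saliency")) {
  stopifnot(outputIndex == 1L)
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  core <- ecgradcamCore(net, record, layerName)
  N <- core$inputLen
  gAbs <- abs(core$dInput)             # [C, N]
  if (method == "saliency") {
    channelMap <- gAbs
  } else {
    alpha <- rowMeans(core$dA)
    G <- pmax(colSums(core$A * alpha), 0)
    if (all(G == 0))
      warning("attention map is identically zero")
    Gup <- upsampleMap(G, N)
    tot <- colSums(gAbs)
    w <- sweep(gAbs, 2, ifelse(tot > 0, tot, 1), "/")
    w[, tot == 0] <- 1 / nrow(gAbs)
    channelMap <- sweep(w, 2, Gup, "*")
  }
  pl <- matrix(0, 12, N, dimnames = list(ecgLeads(), NULL))
  sel <- if (net@spec@independentLeads) independentLeadIndices()
         else seq_len(net@spec@nLeads)
  pl[sel, ] <- channelMap
  if (normalization == "unit") {
    m <- max(pl)
    if (m > 0) pl <- pl / m
  }
  new("AttentionMap", perLead = pl, averaged = colMeans(pl),
      layerName = layerName, outputIndex = as.integer(outputIndex),
      normalization = normalization)
}

#' Attention maps at every residual module
#'
#' Computes the per-lead map at the final convolution of each residual
#' module, in network order, to show how the network's focus narrows from
#' the early modules to the moment of prediction.
#'
#' @inheritParams perLeadMaps
#' @return list of [AttentionMap-class], one per residual module.
#' @export
intermediateMaps <- function(net, record, outputIndex = 1L,
                             normalization = "unit") {
  lapply(seq_len(net@spec@nResidualModules), function(m)
    perLeadMaps(net, record, sprintf("res%d_conv2", m), outputIndex,
                normalization))
}

#' Fraction of attention mass inside a time window
#'
#' Quantifies localization: the share of the lead-averaged importance that
#' falls in `[t0, t1]` ms. A uniform map scores the window's length
#' fraction; an identically zero map scores 0.
#'
#' @param map an [AttentionMap-class].
#' @param windowMs numeric `c(t0, t1)` in ms from record start.
#' @param fs sampling rate of the underlying record (Hz).
#' @return fraction in `[0, 1]`.
#' @export
localizationScore <- function(map, windowMs, fs = 500) {
  stopifnot(is(map, "AttentionMap"), length(windowMs) == 2L)
  a <- averagedMap(map)
  tms <- (seq_along(a) - 1) * 1000 / fs
  idx <- tms >= windowMs[1] & tms <= windowMs[2]
  if (!any(idx)) stop("window contains no samples")
  tot <- sum(a)
  if (tot == 0) return(0)
  sum(a[idx]) / tot
}

# wave window for a task's defining feature, from a record's fiducials
taskWindow <- function(task, fid) {
  tOn <- 2 * fid@tPeak - fid@tOff
  switch(task,
    qrs = c(fid@qrsOn, fid@qrsOff),
    rAmp = c(fid@qrsOn, fid@qrsOff),
    stj = c(fid@qrsOn, fid@qrsOff + 40),
    sex = c(fid@qrsOn, fid@qrsOff),
    tAmp = c(tOn, fid@tOff),
    qt = c(fid@qrsOn, fid@tOff),
    pr = c(fid@pOn, fid@qrsOn),
    hr = c(fid@pOn, fid@tOff),
    stop("no window defined for task ", task))
}
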