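# Network construction, parameter counting and prediction.

#' Construct an architecture specification
#'
#' `fullArchitecture()` is the published residual network: two initial
#' convolutions (64 and 32 filters, kernels 8 and 3), average pooling,
#' eight residual modules of two kernel-50 convolutions (64 and 32
#' filters) with batch normalization and 50% dropout, global average
#' pooling and a single-neuron head. With its default
#' `independentLeads = TRUE` the network consumes the 8 linearly
#' independent channels of a 12-lead record (see
#' [independentLeadIndices()]); under that convention the full network has
#' exactly 1,652,993 parameters (conv biases and batch-norm moving
#' statistics included).
#'
#' `deskArchitecture()` is a reduced preset (16/8 filters, kernel 15, two
#' residual modules) whose training fits on a single CPU; it consumes all
#' 12 leads so attention maps resolve every lead directly.
#'
#' @param nLeads leads in the input records.
#' @param independentLeads feed only the 8 independent channels.
#' @param initialFilters,initialKernels,nResidualModules,residualFilters,residualKernel,dropoutRate,poolSize,head
#'   see [ArchitectureSpec-class].
#' @return an [ArchitectureSpec-class].
#' @export
architectureSpec <- function(nLeads = 12, independentLeads = FALSE,
                             initialFilters = c(64, 32),
                             initialKernels = c(8, 3),
                             nResidualModules = 8,
                             residualFilters = c(64, 32),
                             residualKernel = 50, dropoutRate = 0.5,
                             poolSize = 2,
                             head = c("regression", "classification")) {
  new("ArchitectureSpec", nLeads = as.integer(nLeads),
      independentLeads = independentLeads,
      initialFilters = as.integer(initialFilters),
      initialKernels = as.integer(initialKernels),
      nResidualModules = as.integer(nResidualModules),
      residualFilters = as.integer(residualFilters),
      residualKernel = as.integer(residualKernel),
      dropoutRate = dropoutRate, poolSize = as.integer(poolSize),
      head = match.arg(head))
}

#' @rdname architectureSpec
#' @export
fullArchitecture <- function(head = "regression", independentLeads = TRUE) {
  architectureSpec(independentLeads = independentLeads, head = head)
}

#' @rdname architectureSpec
#' @export
deskArchitecture <- function(head = "regression", nResidualModules = 2,
                             dropoutRate = 0.2) {
  architectureSpec(initialFilters = c(16, 8), initialKernels = c(8, 3),
                   nResidualModules = nResidualModules,
                   residualFilters = c(16, 8), residualKernel = 15,
                   dropoutRate = dropoutRate, head = head)
}

networkInputChannels <- function(spec) {
  if (spec@independentLeads) length(independentLeadIndices()) else spec@nLeads
}

#' Build the residual convolutional network
#'
#' Constructs the differentiable network described by an
#' [ArchitectureSpec-class]: conv-BN-ReLU x2, average pool, the residual
#' modules (conv-BN-ReLU-conv-BN-dropout-add-ReLU with "same" padding),
#' global average pooling and the single-neuron head. Weight
#' initialization is Glorot-uniform and deterministic given `seed`.
#' Because the head is a global average pool the same network accepts any
#' input length (600-sample median beats and 5000-sample rhythm strips
#' alike) and its parameter count does not depend on the length.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed integer seed for weight initialization.
#' @return an [EcgNetwork-class].
#' @export
#' @examples
#' net <- buildNetwork(fullArchitecture())
#' countParameters(net)  # 1652993
buildNetwork <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  cin <- networkInputChannels(spec)
  f <- spec@initialFilters; k <- spec@initialKernels
  rf <- spec@residualFilters; rk <- spec@residualKernel
  layers <- withSeed(seed, {
    ls <- list(
      newConvLayer("conv1", cin, f[1], k[1]), newBnLayer("bn1", f[1]),
      reluLayer(),
      newConvLayer("conv2", f[1], f[2], k[2]), newBnLayer("bn2", f[2]),
      reluLayer(),
      poolLayer(spec@poolSize))
    for (m in seq_len(spec@nResidualModules)) {
      ls <- c(ls, list(
        resBeginLayer(),
        newConvLayer(sprintf("res%d_conv1", m), rf[2], rf[1], rk),
        newBnLayer(sprintf("res%d_bn1", m), rf[1]),
        reluLayer(),
        newConvLayer(sprintf("res%d_conv2", m), rf[1], rf[2], rk),
        newBnLayer(sprintf("res%d_bn2", m), rf[2]),
        dropoutLayer(spec@dropoutRate),
        resAddLayer(),
        reluLayer()))
    }
    c(ls, list(gapLayer(), newDenseLayer("head", rf[2])))
  })
  new("EcgNetwork", spec = spec, layers = layers, seed = as.integer(seed))
}

#' Count network parameters
#'
#' Sums the sizes of all weight tensors. With
#' `includeNontrainable = TRUE` (the default, and the convention under
#' which the full architecture reports 1,652,993) the batch-normalization
#' moving mean and variance are included alongside the trainable weights,
#' as a Keras-style "total params" readout; with FALSE only trainable
#' tensors (conv kernels and biases, batch-norm gamma/beta, head weights)
#' are counted.
#'
#' @param net an [EcgNetwork-class].
#' @param includeNontrainable include batch-norm moving statistics.
#' @return integer parameter count.
#' @export
countParameters <- function(net, includeNontrainable = TRUE) {
  stopifnot(is(net, "EcgNetwork"))
  n <- 0L
  for (l in net@layers) {
    n <- n + switch(l$kind,
      conv = length(l$W) + length(l$b),
      bn = length(l$gamma) + length(l$beta) +
        if (includeNontrainable) length(l$rmean) + length(l$rvar) else 0L,
      dense = length(l$w) + 1L,
      0L)
  }
  as.integer(n)
}

# Stack records into the [C, T, B] microvolt array the network consumes,
# selecting the 8 independent channels when the spec asks for them.
prepareInputArray <- function(x, spec) {
  recs <- if (is(x, "EcgDataset")) records(x)
          else if (is(x, "ECGRecord")) list(x)
          else x
  stopifnot(length(recs) > 0L)
  sel <- if (spec@independentLeads) independentLeadIndices()
         else seq_len(spec@nLeads)
  n <- ncol(voltages(recs[[1]]))
  out <- array(0, c(length(sel), n, length(recs)))
  for (i in seq_along(recs)) {
    v <- voltages(recs[[i]])
    if (nrow(v) < max(sel))
      stop("record has fewer leads than the architecture expects")
    if (ncol(v) != n)
      stop("records in a batch must share their length")
    out[, , i] <- v[sel, , drop = FALSE] * recs[[i]]@lsb
  }
  out
}

#' Serialize an architecture specification as versioned JSON
#'
#' @param spec an [ArchitectureSpec-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeArchitectureJson <- function(spec, file) {
  stopifnot(is(spec, "ArchitectureSpec"))
  obj <- list(formatVersion = 1L,
              nLeads = spec@nLeads, independentLeads = spec@independentLeads,
              initialFilters = spec@initialFilters,
              initialKernels = spec@initialKernels,
              nResidualModules = spec@nResidualModules,
              residualFilters = spec@residualFilters,
              residualKernel = spec@residualKernel,
              dropoutRate = spec@dropoutRate, poolSize = spec@poolSize,
              head = spec@head)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeArchitectureJson
#' @export
readArchitectureJson <- function(file) {
  o <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(o$formatVersion) || o$formatVersion != 1L)
    stop("unsupported architecture format version")
  architectureSpec(nLeads = o$nLeads, independentLeads = o$independentLeads,
                   initialFilters = o$initialFilters,
                   initialKernels = o$initialKernels,
                   nResidualModules = o$nResidualModules,
                   residualFilters = o$residualFilters,
                   residualKernel = o$residualKernel,
                   dropoutRate = o$dropoutRate, poolSize = o$poolSize,
                   head = o$head)
}

#' Weight manifest of a network
#'
#' One row per weight tensor (layer name, tensor name, dimensions,
#' element count, trainable flag) for cross-checking a serialized
#' network against its architecture. Networks themselves serialize with
#' `saveRDS()`/`readRDS()` like any R object.
#'
#' @param net an [EcgNetwork-class].
#' @return data.frame.
#' @export
weightManifest <- function(net) {
  rows <- list()
  for (l in net@layers) {
    tensors <- switch(l$kind,
      conv = list(W = c(TRUE, dim(l$W)), b = c(TRUE, length(l$b))),
      bn = list(gamma = c(TRUE, length(l$gamma)),
                beta = c(TRUE, length(l$beta)),
                movingMean = c(FALSE, length(l$rmean)),
                movingVar = c(FALSE, length(l$rvar))),
      dense = list(w = c(TRUE, length(l$w)), b = c(TRUE, 1L)),
      NULL)
    if (is.null(tensors)) next
    for (tn in names(tensors)) {
      v <- tensors[[tn]]
      rows[[length(rows) + 1L]] <- data.frame(
        layer = l$name, tensor = tn,
        shape = paste(v[-1], collapse = "x"),
        size = prod(v[-1]), trainable = as.logical(v[1]))
    }
  }
  do.call(rbind, rows)
}

#' Predict with a built network
#'
#' Evaluation-mode forward pass (dropout off, batch normalization using
#' its running statistics), deterministic and batch-size invariant. For a
#' classification head the returned values are probabilities through the
#' logistic link, with the raw logits attached as attribute `"logit"`.
#'
#' @param net an [EcgNetwork-class].
#' @param x an [EcgDataset-class], list of [ECGRecord-class], single
#'   record, or a prepared `[C, T, B]` numeric array in microvolts.
#' @param batchSize records per forward chunk.
#' @return numeric vector, one value per record.
#' @export
predictEcg <- function(net, x, batchSize = 256L) {
  arr <- if (is.array(x) && length(dim(x)) == 3L) x
         else prepareInputArray(x, net@spec)
  B <- dim(arr)[3]
  out <- numeric(B)
  for (s in seq(1L, B, by = batchSize)) {
    e <- min(s + batchSize - 1L, B)
    out[s:e] <- nnForward(net@layers, arr[, , s:e, drop = FALSE],
                          training = FALSE)$out
  }
  if (net@spec@head == "classification") {
    p <- 1 / (1 + exp(-out))
    attr(p, "logit") <- out
    p
  } else out
}
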