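# Shared fixtures built in code: small wave parameter sets, records and
# hand-assembled toy networks.

# wave table with only the named waves non-zero; centers ordered P<Q<R<S<T
toyWaves <- function(amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0),
                     widths = c(P = 18, Q = 10, R = 8, S = 10, T = 30),
                     centers = c(P = 250, Q = 520, R = 560, S = 600,
                                 T = 820)) {
  data.frame(center = centers, width = widths, width2 = widths,
             amplitude = amplitudes, row.names = names(centers))
}

toyWaveParams <- function(...) {
  new("WaveParams", waves = toyWaves(...), baseline = 0,
      leadProjection = defaultLeadProjection())
}

# Table-1-median beat used across tests
medianBeatParams <- function() {
  beatParams(pr = 158, qrs = 92, qt = 408, rAmp = 1376, tAmp = 346,
             stj = -5)
}

# quick quantized median record with known ground truth, no noise
cleanMedianRecord <- function(params = medianBeatParams(), id = "fix01") {
  synthRecord(params, kind = "median", hr = 64, recordId = id)
}

# small population for pipeline tests (cached per session)
smallPopulation <- local({
  cache <- NULL
  function(n = 40, seed = 404, sexEffect = 1) {
    key <- paste(n, seed, sexEffect)
    if (!is.null(cache) && cache$key == key) return(cache$ds)
    ds <- generatePopulation(populationSpec(seed = seed,
                                            sexEffect = sexEffect), n)
    cache <<- list(key = key, ds = ds)
    ds
  }
})

# hand-assembled network: one named convolution, global average pool,
# linear head; weights supplied explicitly so maps can be hand-computed
toyConvNet <- function(W, b, headW, headB = 0, nLeads = 12) {
  cout <- nrow(W); k <- ncol(W) / nLeads
  spec <- ecgradcam:::architectureSpec(
    nLeads = nLeads, initialFilters = c(cout, cout),
    initialKernels = c(k, k), nResidualModules = 1,
    residualFilters = c(cout, cout), residualKernel = k,
    dropoutRate = 0, head = "regression")
  conv <- ecgradcam:::newConvLayer("conv1", nLeads, cout, k)
  conv$W <- W; conv$b <- b
  dense <- ecgradcam:::newDenseLayer("head", cout)
  dense$w <- headW; dense$b <- headB
  new("EcgNetwork", spec = spec,
      layers = list(conv, ecgradcam:::gapLayer(), dense), seed = 1L)
}

# direct convolution oracle: same-padded 1-D convolution written as plain
# loops, independent of the package's im2col path
convOracle <- function(x, W, b) {
  C <- nrow(x); n <- ncol(x); cout <- nrow(W); k <- ncol(W) / C
  pl <- (k - 1) %/% 2
  out <- matrix(0, cout, n)
  for (o in seq_len(cout)) {
    for (t in seq_len(n)) {
      acc <- b[o]
      for (j in seq_len(k)) {
        tt <- t + j - 1 - pl
        if (tt >= 1 && tt <= n)
          for (c in seq_len(C))
            acc <- acc + W[o, (j - 1) * C + c] * x[c, tt]
      }
      out[o, t] <- acc
    }
  }
  out
}
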