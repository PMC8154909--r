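# ECGradCAM: hand-computed oracle, invariants, lead attribution.

test_that("layerGradcam matches manual forward/backward arithmetic", {
  # one conv (known weights) -> GAP -> linear head. For this network
  # y = sum_c v_c * mean_t A_c(t), so dy/dA_c(t) = v_c / T for every t,
  # alpha_c = v_c / T and map(t) = ReLU(sum_c alpha_c A_c(t)).
  set.seed(12)
  C <- 12; k <- 3; cout <- 2
  W <- matrix(round(rnorm(cout * C * k), 2), cout)
  b <- c(0.1, -0.2)
  v <- c(1.5, -0.7)
  net <- toyConvNet(W, b, headW = v, headB = 0.3)
  rec <- cleanMedianRecord()$record
  A <- convOracle(microvolts(rec), W, b)
  T <- ncol(A)
  manual <- pmax(colSums(A * (v / T)), 0)
  got <- layerGradcam(net, rec, "conv1")
  expect_equal(got, manual, tolerance = 1e-5)
  # prediction consistency of the same toy network
  expect_equal(unname(predictEcg(net, rec)),
               sum(v * rowMeans(A)) + 0.3, tolerance = 1e-8)
})

test_that("an input-independent output yields an all-zero map with warning", {
  net <- toyConvNet(matrix(0.5, 2, 36), c(0, 0), headW = c(0, 0))
  rec <- cleanMedianRecord()$record
  expect_warning(m <- layerGradcam(net, rec, "conv1"), "zero")
  expect_equal(m, rep(0, 600))
  suppressWarnings(am <- perLeadMaps(net, rec, "conv1"))
  expect_equal(max(perLead(am)), 0)
  expect_equal(averagedMap(am), rep(0, 600))
})

test_that("upsampling is linear, endpoint-preserving and shape-checked", {
  expect_equal(upsampleMap(c(0, 1), 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(upsampleMap(c(3, 1, 4), 3), c(3, 1, 4))       # identity
  expect_equal(upsampleMap(rep(2.5, 4), 11), rep(2.5, 11))   # constant
  v <- c(0.2, 0.9, 0.4)
  expect_equal(upsampleMap(v, 9)[c(1, 9)], v[c(1, 3)])
  expect_error(upsampleMap(numeric(), 5), "empty")
})

test_that("a network reading only lead V5 attributes its mass to V5", {
  C <- 12; k <- 3; cout <- 2
  W <- matrix(0, cout, C * k)
  v5 <- match("V5", ecgLeads())
  for (j in seq_len(k)) W[, (j - 1) * C + v5] <- c(0.8, -0.5)
  net <- toyConvNet(W, c(0, 0), headW = c(1.2, 0.4))
  rec <- cleanMedianRecord()$record
  am <- perLeadMaps(net, rec, "conv1")
  mass <- rowSums(perLead(am))
  expect_gte(mass[v5] / sum(mass), 0.99)
})

test_that("attention maps satisfy their structural invariants", {
  ds <- smallPopulation(8)
  net <- buildNetwork(deskArchitecture(), seed = 21)
  for (i in c(1, 4)) {
    am <- perLeadMaps(net, records(ds)[[i]])
    expect_true(validObject(am))
    expect_true(all(perLead(am) >= 0))
    expect_equal(averagedMap(am), unname(colMeans(perLead(am))))
    expect_equal(max(perLead(am)), 1)  # unit normalization
    raw <- perLeadMaps(net, records(ds)[[i]], normalization = "raw")
    expect_equal(perLead(am), perLead(raw) / max(perLead(raw)))
  }
})

test_that("scaling the head scales raw maps but not normalized ones", {
  ds <- smallPopulation(4)
  net <- buildNetwork(deskArchitecture(), seed = 33)
  net2 <- net
  hi <- length(net@layers)
  net2@layers[[hi]]$w <- net@layers[[hi]]$w * 3
  rec <- records(ds)[[2]]
  r1 <- perLeadMaps(net, rec, normalization = "raw")
  r2 <- perLeadMaps(net2, rec, normalization = "raw")
  expect_equal(perLead(r2), perLead(r1) * 3, tolerance = 1e-8)
  u1 <- perLeadMaps(net, rec)
  u2 <- perLeadMaps(net2, rec)
  expect_equal(perLead(u2), perLead(u1), tolerance = 1e-8)
})

test_that("intermediate maps cover every residual module and end at the top", {
  ds <- smallPopulation(3)
  net <- buildNetwork(deskArchitecture(), seed = 9)
  rec <- records(ds)[[1]]
  ims <- intermediateMaps(net, rec)
  expect_length(ims, net@spec@nResidualModules)
  expect_equal(perLead(ims[[length(ims)]]),
               perLead(perLeadMaps(net, rec)))
})

test_that("localization score is the windowed share of attention mass", {
  # uniform map over 600 samples, 300-ms window at 500 Hz = 150 samples
  pl <- matrix(1 / 12, 12, 600)
  am <- new("AttentionMap", perLead = pl, averaged = colMeans(pl),
            layerName = "x", outputIndex = 1L, normalization = "raw")
  expect_equal(localizationScore(am, c(0, 1198)), 1)
  expect_equal(localizationScore(am, c(100, 398)), 150 / 600)
  # map supported entirely inside the window scores 1
  pl2 <- matrix(0, 12, 600); pl2[, 200:240] <- 1
  am2 <- new("AttentionMap", perLead = pl2, averaged = colMeans(pl2),
             layerName = "x", outputIndex = 1L, normalization = "raw")
  expect_equal(localizationScore(am2, c(390, 490)), 1)
  expect_error(localizationScore(am, c(2000, 2100)), "no samples")
})

test_that("gradients reach every named convolution (GradCAM smoke)", {
  ds <- smallPopulation(2)
  net <- buildNetwork(deskArchitecture(), seed = 14)
  for (nm in grep("conv", layerNames(net), value = TRUE)) {
    core <- ecgradcam:::ecgradcamCore(net, records(ds)[[1]], nm)
    expect_true(all(is.finite(core$dA)))
    expect_gt(max(abs(core$dA)), 0)
  }
})
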