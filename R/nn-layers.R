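# Internal neural-network engine: 1-D convolutional layers over an
# [channels x time x batch] array, with explicit forward and backward
# passes. Convolutions are computed as BLAS matrix products through an
# im2col expansion; "same" padding keeps the temporal length, which the
# residual skip additions require.
#
# Layer objects are plain lists; the exported S4 surface lives in model.R.

glorotUniform <- function(n, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  stats::runif(n, -lim, lim)
}

newConvLayer <- function(name, cin, cout, k) {
  W <- matrix(glorotUniform(cout * cin * k, cin * k, cout * k), nrow = cout)
  list(kind = "conv", name = name, W = W, b = numeric(cout),
       k = k, cin = cin, cout = cout)
}

newBnLayer <- function(name, c, momentum = 0.99, eps = 1e-3) {
  list(kind = "bn", name = name, gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

newDenseLayer <- function(name, cin) {
  list(kind = "dense", name = name,
       w = glorotUniform(cin, cin, 1), b = 0)
}

reluLayer <- function() list(kind = "relu", name = "")
poolLayer <- function(size) list(kind = "pool", name = "", size = size)
dropoutLayer <- function(rate) list(kind = "dropout", name = "", rate = rate)
resBeginLayer <- function() list(kind = "res_begin", name = "")
resAddLayer <- function() list(kind = "res_add", name = "")
gapLayer <- function() list(kind = "gap", name = "")

# im2col: [C, T, B] -> [C*k, T*B] with "same" zero padding (C++ kernel)
im2col <- function(x, k) {
  d <- dim(x)
  .im2col_cpp(x, d[1], d[2], d[3], k)
}

col2im <- function(dcol, C, T, B, k) .col2im_cpp(dcol, C, T, B, k)

convForward <- function(layer, x) {
  d <- dim(x)
  col <- im2col(x, layer$k)
  y <- layer$W %*% col + layer$b
  dim(y) <- c(layer$cout, d[2], d[3])
  list(y = y, cache = list(col = col, dims = d))
}

convBackward <- function(layer, cache, dy) {
  d <- cache$dims
  dim(dy) <- c(layer$cout, d[2] * d[3])
  dW <- tcrossprod(dy, cache$col)
  db <- rowSums(dy)
  dcol <- crossprod(layer$W, dy)
  dx <- col2im(dcol, d[1], d[2], d[3], layer$k)
  list(dx = dx, grads = list(W = dW, b = db))
}

# Batch norm over channels (first array dimension): length-C vectors
# recycle along the first dimension, so the [C, T, B] array never needs
# reshaping.
bnForward <- function(layer, x, training) {
  if (training) {
    mu <- rowMeans(x, dims = 1)
    xc <- x - mu
    v <- rowMeans(xc * xc, dims = 1)
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- xc * istd
    y <- layer$gamma * xhat + layer$beta
    layer$rmean <- layer$momentum * layer$rmean + (1 - layer$momentum) * mu
    layer$rvar <- layer$momentum * layer$rvar + (1 - layer$momentum) * v
    cache <- list(xhat = xhat, istd = istd, training = TRUE,
                  mu = mu, v = v)
  } else {
    scale <- layer$gamma / sqrt(layer$rvar + layer$eps)
    y <- scale * (x - layer$rmean) + layer$beta
    cache <- list(scale = scale, training = FALSE,
                  xhat = (x - layer$rmean) / sqrt(layer$rvar + layer$eps))
  }
  list(y = y, cache = cache, layer = layer)
}

bnBackward <- function(layer, cache, dy) {
  dgamma <- rowSums(dy * cache$xhat, dims = 1)
  dbeta <- rowSums(dy, dims = 1)
  if (cache$training) {
    M <- length(dy) / dim(dy)[1]
    dxhat <- dy * layer$gamma
    dx <- (cache$istd / M) *
      (M * dxhat - rowSums(dxhat, dims = 1) -
         cache$xhat * rowSums(dxhat * cache$xhat, dims = 1))
  } else {
    dx <- dy * cache$scale
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

poolForward <- function(layer, x) {
  d <- dim(x); s <- layer$size
  stopifnot(d[2] %% s == 0L)
  To <- d[2] %/% s
  y <- array(0, c(d[1], To, d[3]))
  for (j in seq_len(s))
    y <- y + x[, seq(j, d[2], by = s), , drop = FALSE]
  list(y = y / s, cache = d)
}

poolBackward <- function(layer, cache, dy) {
  d <- cache; s <- layer$size
  dx <- array(0, d)
  for (j in seq_len(s))
    dx[, seq(j, d[2], by = s), ] <- dy / s
  dx
}

gapForward <- function(x) {
  d <- dim(x)
  y <- colSums(aperm(x, c(2, 1, 3))) / d[2]   # [C, B]
  list(y = y, cache = d)
}

gapBackward <- function(cache, dy) {
  d <- cache
  aperm(array(dy / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
}

denseForward <- function(layer, x) {
  list(y = as.numeric(crossprod(x, layer$w)) + layer$b, cache = x)
}

denseBackward <- function(layer, cache, dy) {
  list(dx = outer(layer$w, dy),
       grads = list(w = as.numeric(cache %*% dy), b = sum(dy)))
}

# Recompute the batch-norm running statistics exactly from data: one pass
# in training mode over equal-size batches, aggregating each layer's
# per-batch moments into population moments. Momentum-based running
# averages lag badly over short training runs; this recalibration makes
# evaluation-mode behavior consistent with how activations were
# distributed during training.
recalibrateBn <- function(layers, arr, batchSize = 64L) {
  B <- dim(arr)[3]
  nb <- max(1L, B %/% batchSize)
  # dropout stays off during calibration: the statistics must describe
  # the activations the evaluation-mode network will actually see (this
  # also keeps the RNG stream untouched, so training stays reproducible)
  calib <- lapply(layers, function(l) {
    if (l$kind == "dropout") l$rate <- 0
    l
  })
  isBn <- vapply(layers, function(l) l$kind == "bn", TRUE)
  sums <- lapply(layers, function(l)
    if (l$kind == "bn") list(mu = 0, m2 = 0) else NULL)
  used <- 0L
  for (k in seq_len(nb)) {
    idx <- ((k - 1L) * batchSize + 1L):(k * batchSize)
    fw <- nnForward(calib, arr[, , idx, drop = FALSE], training = TRUE,
                    keepCache = TRUE)
    for (i in which(isBn)) {
      c <- fw$caches[[i]]
      sums[[i]]$mu <- sums[[i]]$mu + c$mu
      sums[[i]]$m2 <- sums[[i]]$m2 + c$v + c$mu^2
    }
    used <- used + 1L
  }
  for (i in which(isBn)) {
    m <- sums[[i]]$mu / used
    layers[[i]]$rmean <- m
    layers[[i]]$rvar <- pmax(sums[[i]]$m2 / used - m^2, 0)
  }
  layers
}

# Full forward pass. Returns the output, the updated layer list (batch-norm
# running statistics move during training) and, when keepCache, per-layer
# caches and activations for the backward pass / GradCAM.
nnForward <- function(layers, x, training = FALSE, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  acts <- if (keepCache) vector("list", length(layers)) else NULL
  skips <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$kind,
      conv = convForward(l, x),
      bn = bnForward(l, x, training),
      relu = list(y = pmax(x, 0), cache = NULL),
      pool = poolForward(l, x),
      dropout = if (training && l$rate > 0) {
        mask <- array((stats::runif(length(x)) >= l$rate) / (1 - l$rate), dim(x))
        list(y = x * mask, cache = mask)
      } else list(y = x, cache = NULL),
      res_begin = { skips[[length(skips) + 1L]] <- x; list(y = x, cache = NULL) },
      res_add = {
        y <- x + skips[[length(skips)]]
        skips[[length(skips)]] <- NULL
        list(y = y, cache = NULL)
      },
      gap = gapForward(x),
      dense = denseForward(l, x),
      stop("unknown layer kind: ", l$kind))
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    if (keepCache) {
      if (l$kind == "relu") r$cache <- (x > 0)
      caches[[i]] <- r$cache
      acts[[i]] <- r$y
    }
    x <- r$y
  }
  list(out = x, layers = layers, caches = caches, acts = acts)
}

# Backward pass from d(loss)/d(output). Returns per-layer parameter
# gradients, the gradient at the network input, and the gradient flowing
# into (i.e. w.r.t. the output of) every layer index in captureIndices.
nnBackward <- function(layers, caches, dout, captureIndices = integer()) {
  grads <- vector("list", length(layers))
  captured <- list()
  skipGrads <- list()
  dy <- dout
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (i %in% captureIndices)
      captured[[as.character(i)]] <- dy
    dy <- switch(l$kind,
      conv = { r <- convBackward(l, caches[[i]], dy); grads[[i]] <- r$grads; r$dx },
      bn = { r <- bnBackward(l, caches[[i]], dy); grads[[i]] <- r$grads; r$dx },
      relu = dy * caches[[i]],
      pool = poolBackward(l, caches[[i]], dy),
      dropout = if (is.null(caches[[i]])) dy else dy * caches[[i]],
      res_add = { skipGrads[[length(skipGrads) + 1L]] <- dy; dy },
      res_begin = {
        g <- dy + skipGrads[[length(skipGrads)]]
        skipGrads[[length(skipGrads)]] <- NULL
        g
      },
      gap = gapBackward(caches[[i]], dy),
      dense = { r <- denseBackward(l, caches[[i]], dy); grads[[i]] <- r$grads; r$dx })
  }
  list(grads = grads, dInput = dy, captured = captured)
}
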