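## Minimal CNN engine. Feature maps are stored as C x (h*w*n) matrices:
## each column is one spatial position (row-fastest flattening, 0-based
## j = r + c*h), samples stacked in blocks of h*w columns. 3x3 convolutions
## are computed as nine shifted GEMMs (one per kernel tap), which keeps
## memory linear in the activation size; 'same' zero padding falls out of
## restricting the tap index sets to in-range positions. Every operator has
## an explicit hand-derived backward pass, verified against finite
## differences in the test suite.

.nn_cache <- new.env(parent = emptyenv())

memo <- function(key, value_fn) {
  if (!exists(key, envir = .nn_cache)) assign(key, value_fn(), envir = .nn_cache)
  get(key, envir = .nn_cache)
}

## index vectors (1-based, single sample) for one kernel tap
conv_tap_idx <- function(h, w, stride, dilation, u, v) {
  key <- paste("tap", h, w, stride, dilation, u, v, sep = "_")
  memo(key, function() {
    ho <- h %/% stride; wo <- w %/% stride
    r_out <- 0:(ho - 1); c_out <- 0:(wo - 1)
    r_in <- r_out * stride + u * dilation
    c_in <- c_out * stride + v * dilation
    rok <- which(r_in >= 0 & r_in <= h - 1)
    cok <- which(c_in >= 0 & c_in <= w - 1)
    dst <- as.vector(outer(r_out[rok], c_out[cok] * ho, `+`)) + 1L
    src <- as.vector(outer(r_in[rok], c_in[cok] * h, `+`)) + 1L
    list(dst = dst, src = src)
  })
}

expand_idx <- function(idx, block, n) {
  if (n == 1L) return(idx)
  as.vector(outer(idx, (0:(n - 1)) * block, `+`))
}

## He-initialized conv parameters; W has dim (Cout, Cin, k, k)
conv_param <- function(cin, cout, k = 3L) {
  W <- array(stats::rnorm(cout * cin * k * k) * sqrt(2 / (k * k * cin)),
             dim = c(cout, cin, k, k))
  list(W = W, b = rep(0, cout))
}

## pack the 4-d kernel into the (Cout x 9*Cin) matrix used by the im2col
## GEMM; tap order is column offset (v) outer, row offset (u) inner, and
## must match the C++ side
conv_pack_weights <- function(W) {
  cout <- dim(W)[1]; cin <- dim(W)[2]
  W2 <- matrix(0, cout, 9L * cin)
  t_ <- 0L
  for (v in -1:1) for (u in -1:1) {
    t_ <- t_ + 1L
    W2[, ((t_ - 1L) * cin + 1L):(t_ * cin)] <- W[, , u + 2L, v + 2L]
  }
  W2
}

conv_unpack_weights <- function(W2, cout, cin) {
  W <- array(0, c(cout, cin, 3L, 3L))
  t_ <- 0L
  for (v in -1:1) for (u in -1:1) {
    t_ <- t_ + 1L
    W[, , u + 2L, v + 2L] <- W2[, ((t_ - 1L) * cin + 1L):(t_ * cin)]
  }
  W
}

conv_fwd <- function(p, x, h, w, n, stride = 1L, dilation = 1L,
                     training = TRUE) {
  k <- dim(p$W)[3]
  if (k == 1L) {
    Wm <- matrix(p$W, dim(p$W)[1], dim(p$W)[2])
    y <- Wm %*% x + p$b
    cache <- if (training) list(x = x, h = h, w = w, n = n, k = 1L) else NULL
    return(list(y = y, h = h, w = w, cache = cache))
  }
  if (stride > 1L && (h %% stride || w %% stride))
    stop("spatial dims must be divisible by the stride")
  y <- conv3_fwd_cpp(conv_pack_weights(p$W), p$b, x,
                     h, w, n, stride, dilation)
  cache <- if (training)
    list(x = x, h = h, w = w, n = n, k = 3L,
         stride = stride, dilation = dilation) else NULL
  list(y = y, h = h %/% stride, w = w %/% stride, cache = cache)
}

conv_bwd <- function(p, cache, dy) {
  if (cache$k == 1L) {
    Wm <- matrix(p$W, dim(p$W)[1], dim(p$W)[2])
    dW <- array(dy %*% t(cache$x), dim = dim(p$W))
    return(list(dx = t(Wm) %*% dy,
                dp = list(W = dW, b = rowSums(dy))))
  }
  g <- conv3_bwd_cpp(conv_pack_weights(p$W), cache$x, dy,
                     cache$h, cache$w, cache$n, cache$stride, cache$dilation)
  list(dx = g$dx,
       dp = list(W = conv_unpack_weights(g$dW2, dim(p$W)[1], dim(p$W)[2]),
                 b = as.numeric(g$db)))
}

## Pure-R reference implementation (nine shifted GEMMs); retained as an
## independent oracle for the compiled path.
conv_fwd_ref <- function(p, x, h, w, n, stride = 1L, dilation = 1L,
                         training = TRUE) {
  k <- dim(p$W)[3]
  if (k == 1L) {
    Wm <- matrix(p$W, dim(p$W)[1], dim(p$W)[2])
    y <- Wm %*% x + p$b
    cache <- if (training) list(x = x, h = h, w = w, n = n, k = 1L) else NULL
    return(list(y = y, h = h, w = w, cache = cache))
  }
  if (stride > 1L && (h %% stride || w %% stride))
    stop("spatial dims must be divisible by the stride")
  ho <- h %/% stride; wo <- w %/% stride
  cout <- dim(p$W)[1]
  y <- matrix(0, cout, ho * wo * n)
  for (u in -1:1) for (v in -1:1) {
    ti <- conv_tap_idx(h, w, stride, dilation, u, v)
    dst <- expand_idx(ti$dst, ho * wo, n)
    src <- expand_idx(ti$src, h * w, n)
    y[, dst] <- y[, dst] + p$W[, , u + 2, v + 2] %*% x[, src, drop = FALSE]
  }
  y <- y + p$b
  cache <- if (training)
    list(x = x, h = h, w = w, n = n, k = 3L,
         stride = stride, dilation = dilation) else NULL
  list(y = y, h = ho, w = wo, cache = cache)
}

conv_bwd_ref <- function(p, cache, dy) {
  if (cache$k == 1L) {
    Wm <- matrix(p$W, dim(p$W)[1], dim(p$W)[2])
    dW <- array(dy %*% t(cache$x), dim = dim(p$W))
    return(list(dx = t(Wm) %*% dy,
                dp = list(W = dW, b = rowSums(dy))))
  }
  h <- cache$h; w <- cache$w; n <- cache$n
  stride <- cache$stride; dilation <- cache$dilation
  ho <- h %/% stride; wo <- w %/% stride
  dW <- array(0, dim = dim(p$W))
  dx <- matrix(0, dim(p$W)[2], h * w * n)
  for (u in -1:1) for (v in -1:1) {
    ti <- conv_tap_idx(h, w, stride, dilation, u, v)
    dst <- expand_idx(ti$dst, ho * wo, n)
    src <- expand_idx(ti$src, h * w, n)
    dys <- dy[, dst, drop = FALSE]
    dW[, , u + 2, v + 2] <- dys %*% t(cache$x[, src, drop = FALSE])
    dx[, src] <- dx[, src] + t(p$W[, , u + 2, v + 2]) %*% dys
  }
  list(dx = dx, dp = list(W = dW, b = rowSums(dy)))
}

bn_param <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

## `state` is a mutable environment keyed by layer name holding running
## mean/var for inference mode.
bn_fwd <- function(p, x, training, state, name,
                   momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    run <- state[[name]]
    if (is.null(run)) run <- list(mean = mu, var = v)
    else run <- list(mean = (1 - momentum) * run$mean + momentum * mu,
                     var  = (1 - momentum) * run$var + momentum * v)
    state[[name]] <- run
    y <- p$gamma * xhat + p$beta
    list(y = y, cache = list(xhat = xhat, istd = istd, gamma = p$gamma))
  } else {
    run <- state[[name]]
    if (is.null(run)) run <- list(mean = rep(0, nrow(x)), var = rep(1, nrow(x)))
    y <- p$gamma * ((x - run$mean) / sqrt(run$var + eps)) + p$beta
    list(y = y, cache = NULL)
  }
}

bn_bwd <- function(cache, dy) {
  xhat <- cache$xhat
  dxhat <- dy * cache$gamma
  dx <- cache$istd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       dp = list(gamma = rowSums(dy * xhat), beta = rowSums(dy)))
}

relu_fwd <- function(x, training = TRUE) {
  mask <- x > 0
  list(y = x * mask, cache = if (training) mask else NULL)
}
relu_bwd <- function(cache, dy) dy * cache

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(y = x * keep, cache = keep)
}
dropout_bwd <- function(cache, dy) if (is.null(cache)) dy else dy * cache

maxpool2_fwd <- function(x, h, w, n, training = TRUE) {
  ho <- h %/% 2L; wo <- w %/% 2L
  idx <- lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(ab) {
    key <- paste("pool", h, w, ab[1], ab[2], sep = "_")
    single <- memo(key, function() {
      r <- 2 * (0:(ho - 1)) + ab[1]
      c_ <- 2 * (0:(wo - 1)) + ab[2]
      as.vector(outer(r, c_ * h, `+`)) + 1L
    })
    expand_idx(single, h * w, n)
  })
  m <- lapply(idx, function(i) x[, i, drop = FALSE])
  y <- pmax(m[[1]], m[[2]], m[[3]], m[[4]])
  cache <- NULL
  if (training) {
    s1 <- m[[1]] == y
    s2 <- (m[[2]] == y) & !s1
    s3 <- (m[[3]] == y) & !s1 & !s2
    s4 <- !(s1 | s2 | s3)
    cache <- list(sel = list(s1, s2, s3, s4), idx = idx,
                  h = h, w = w, n = n)
  }
  list(y = y, h = ho, w = wo, cache = cache)
}

maxpool2_bwd <- function(cache, dy) {
  dx <- matrix(0, nrow(dy), cache$h * cache$w * cache$n)
  for (k in 1:4) dx[, cache$idx[[k]]] <- dy * cache$sel[[k]]
  dx
}

## 2x bilinear upsampling as a sparse separable linear operator; the
## backward pass is its exact adjoint. Output pixel i samples source
## coordinate (i + 0.5)/2 - 0.5, edges clamped.
upsample_band <- function(h) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in 0:(2 * h - 1)) {
    k <- i %/% 2
    if (i %% 2 == 0) taps <- rbind(c(k - 1, 0.25), c(k, 0.75))
    else taps <- rbind(c(k, 0.75), c(k + 1, 0.25))
    taps[, 1] <- pmin(pmax(taps[, 1], 0), h - 1)
    ii <- c(ii, i + 1, i + 1); jj <- c(jj, taps[, 1] + 1); xx <- c(xx, taps[, 2])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * h, h))
}

upsample_op <- function(h, w) {
  memo(paste("up", h, w, sep = "_"), function() {
    M <- Matrix::kronecker(upsample_band(w), upsample_band(h))
    list(M = M, tM = Matrix::t(M))
  })
}

upsample2_fwd <- function(x, h, w, n, training = TRUE) {
  op <- upsample_op(h, w)
  blk <- h * w
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    out[[i]] <- as.matrix(x[, cols, drop = FALSE] %*% op$tM)
  }
  list(y = do.call(cbind, out), h = 2L * h, w = 2L * w,
       cache = if (training) list(h = h, w = w, n = n) else NULL)
}

upsample2_bwd <- function(cache, dy) {
  op <- upsample_op(cache$h, cache$w)
  blk <- 4L * cache$h * cache$w
  out <- vector("list", cache$n)
  for (i in seq_len(cache$n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    out[[i]] <- as.matrix(dy[, cols, drop = FALSE] %*% op$M)
  }
  do.call(cbind, out)
}

softmax_rows <- function(E) {
  E <- E - apply(E, 1, max)
  P <- exp(E)
  P / rowSums(P)
}
## dE given S = softmax_rows(E) and dS
softmax_rows_bwd <- function(S, dS) S * (dS - rowSums(dS * S))

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- Adam over nested parameter lists -------------------------------------

nl_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) nl_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

nl_zeros <- function(p) {
  if (is.list(p)) return(lapply(p, nl_zeros))
  p * 0
}

adam_init <- function(params) {
  list(m = nl_zeros(params), v = nl_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nl_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nl_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nl_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                 state$m, state$v)
  params <- nl_map2(`-`, params, upd)
  list(params = params, state = state)
}
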