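## Composite network blocks. Each block exposes *_init (parameters),
## *_fwd (returns y/h/w plus a cache) and *_bwd (returns dx plus parameter
## gradients structured like the parameters).

## ---- conv + batchnorm + relu ----------------------------------------------

cbr_init <- function(cin, cout, k = 3L) {
  list(conv = conv_param(cin, cout, k), bn = bn_param(cout))
}

cbr_fwd <- function(p, x, h, w, n, training, state, name,
                    stride = 1L, dilation = 1L) {
  cv <- conv_fwd(p$conv, x, h, w, n, stride, dilation, training)
  bn <- bn_fwd(p$bn, cv$y, training, state, name)
  rl <- relu_fwd(bn$y, training)
  list(y = rl$y, h = cv$h, w = cv$w,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

cbr_bwd <- function(p, cache, dy) {
  d1 <- relu_bwd(cache$relu, dy)
  bb <- bn_bwd(cache$bn, d1)
  cc <- conv_bwd(p$conv, cache$conv, bb$dx)
  list(dx = cc$dx, dp = list(conv = cc$dp, bn = bb$dp))
}

## ---- residual blocks (bottleneck) -----------------------------------------
## Branch: (conv3x3-BN-ReLU) x2 at the bottleneck width, then conv3x3-BN up to
## the output width; shortcut: conv3x3-BN (conv block) or identity (identity
## block); sum passed through a final ReLU. Internal width = cout /
## bottleneck_ratio.

res_block_init <- function(cin, cout, bottleneck_ratio = 4L, shortcut = TRUE) {
  m <- max(1L, cout %/% bottleneck_ratio)
  p <- list(
    c1 = cbr_init(cin, m),
    c2 = cbr_init(m, m),
    c3 = list(conv = conv_param(m, cout), bn = bn_param(cout))
  )
  if (shortcut) p$sc <- list(conv = conv_param(cin, cout), bn = bn_param(cout))
  p
}

res_block_fwd <- function(p, x, h, w, n, training, state, name, stride = 1L) {
  has_sc <- !is.null(p$sc)
  if (!has_sc && stride != 1L)
    stop("identity block requires stride 1")
  a <- cbr_fwd(p$c1, x, h, w, n, training, state, paste0(name, ".c1"),
               stride = stride)
  b <- cbr_fwd(p$c2, a$y, a$h, a$w, n, training, state, paste0(name, ".c2"))
  c3c <- conv_fwd(p$c3$conv, b$y, b$h, b$w, n, training = training)
  c3b <- bn_fwd(p$c3$bn, c3c$y, training, state, paste0(name, ".c3"))
  if (has_sc) {
    scc <- conv_fwd(p$sc$conv, x, h, w, n, stride, training = training)
    scb <- bn_fwd(p$sc$bn, scc$y, training, state, paste0(name, ".sc"))
    short <- scb$y
  } else short <- x
  s <- c3b$y + short
  rl <- relu_fwd(s, training)
  cache <- list(a = a$cache, b = b$cache, c3c = c3c$cache, c3b = c3b$cache,
                relu = rl$cache, has_sc = has_sc)
  if (has_sc) { cache$scc <- scc$cache; cache$scb <- scb$cache }
  list(y = rl$y, h = a$h, w = a$w, cache = cache)
}

res_block_bwd <- function(p, cache, dy) {
  ds <- relu_bwd(cache$relu, dy)
  b3 <- bn_bwd(cache$c3b, ds)
  c3 <- conv_bwd(p$c3$conv, cache$c3c, b3$dx)
  b2 <- cbr_bwd(p$c2, cache$b, c3$dx)
  b1 <- cbr_bwd(p$c1, cache$a, b2$dx)
  dp <- list(c1 = b1$dp, c2 = b2$dp, c3 = list(conv = c3$dp, bn = b3$dp))
  if (cache$has_sc) {
    sb <- bn_bwd(cache$scb, ds)
    sc <- conv_bwd(p$sc$conv, cache$scc, sb$dx)
    dp$sc <- list(conv = sc$dp, bn = sb$dp)
    dx <- b1$dx + sc$dx
  } else {
    dx <- b1$dx + ds
  }
  list(dx = dx, dp = dp)
}

## ---- position attention (spatial self-attention) --------------------------
## Query/key projections at C/8 channels, value at C; the N x N affinity is
## row-softmax-normalized; output = gamma * (weighted sum over positions) +
## input, with gamma a learnable scalar initialized at 0.

pam_init <- function(c) {
  cq <- max(1L, c %/% 8L)
  list(q = conv_param(c, cq, 1L), k = conv_param(c, cq, 1L),
       v = conv_param(c, c, 1L), gamma = 0)
}

pam_fwd <- function(p, x, h, w, n, training) {
  blk <- h * w
  y <- x * 0
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    X <- x[, cols, drop = FALSE]
    q <- conv_fwd(p$q, X, h, w, 1L, training = training)
    k <- conv_fwd(p$k, X, h, w, 1L, training = training)
    v <- conv_fwd(p$v, X, h, w, 1L, training = training)
    E <- crossprod(q$y, k$y)            # N x N affinities
    S <- softmax_rows(E)
    O <- v$y %*% t(S)
    y[, cols] <- p$gamma * O + X
    caches[[i]] <- if (training)
      list(q = q, k = k, v = v, S = S, O = O, X = X) else NULL
  }
  list(y = y, h = h, w = w,
       cache = if (training) list(per = caches, h = h, w = w, n = n) else NULL)
}

pam_bwd <- function(p, cache, dy) {
  blk <- cache$h * cache$w
  dx <- dy * 0
  dgamma <- 0
  dq <- dk <- dv <- NULL
  for (i in seq_len(cache$n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    cc <- cache$per[[i]]
    dyi <- dy[, cols, drop = FALSE]
    dgamma <- dgamma + sum(dyi * cc$O)
    dO <- p$gamma * dyi
    dV <- dO %*% cc$S
    dS <- crossprod(dO, cc$v$y)
    dE <- softmax_rows_bwd(cc$S, dS)
    dQ <- cc$k$y %*% t(dE)
    dK <- cc$q$y %*% dE
    gq <- conv_bwd(p$q, cc$q$cache, dQ)
    gk <- conv_bwd(p$k, cc$k$cache, dK)
    gv <- conv_bwd(p$v, cc$v$cache, dV)
    dx[, cols] <- dyi + gq$dx + gk$dx + gv$dx
    acc <- function(a, b) if (is.null(a)) b else nl_map2(`+`, a, b)
    dq <- acc(dq, gq$dp); dk <- acc(dk, gk$dp); dv <- acc(dv, gv$dp)
  }
  list(dx = dx, dp = list(q = dq, k = dk, v = dv, gamma = dgamma))
}

## ---- channel attention ----------------------------------------------------
## C x C affinity from channel-flattened features, row-softmax; output =
## gamma * (attention-weighted channel mixture) + input.

cam_init <- function() list(gamma = 0)

cam_fwd <- function(p, x, h, w, n, training) {
  blk <- h * w
  y <- x * 0
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    X <- x[, cols, drop = FALSE]
    E <- tcrossprod(X)                  # C x C
    S <- softmax_rows(E)
    O <- S %*% X
    y[, cols] <- p$gamma * O + X
    caches[[i]] <- if (training) list(X = X, S = S, O = O) else NULL
  }
  list(y = y, h = h, w = w,
       cache = if (training) list(per = caches, h = h, w = w, n = n) else NULL)
}

cam_bwd <- function(p, cache, dy) {
  blk <- cache$h * cache$w
  dx <- dy * 0
  dgamma <- 0
  for (i in seq_len(cache$n)) {
    cols <- ((i - 1) * blk + 1):(i * blk)
    cc <- cache$per[[i]]
    dyi <- dy[, cols, drop = FALSE]
    dgamma <- dgamma + sum(dyi * cc$O)
    dO <- p$gamma * dyi
    dS <- tcrossprod(dO, cc$X)
    dXa <- crossprod(cc$S, dO)
    dE <- softmax_rows_bwd(cc$S, dS)
    dXb <- (dE + t(dE)) %*% cc$X
    dx[, cols] <- dyi + dXa + dXb
  }
  list(dx = dx, dp = list(gamma = dgamma))
}

## ---- dual attention -------------------------------------------------------
## One shared conv-BN-ReLU, then position and channel attention applied to
## the same features; the two outputs are summed. With both residual scales
## at 0 the output equals twice the post-conv features.

da_init <- function(c) {
  list(pre = cbr_init(c, c), pam = pam_init(c), cam = cam_init())
}

da_fwd <- function(p, x, h, w, n, training, state, name) {
  f <- cbr_fwd(p$pre, x, h, w, n, training, state, paste0(name, ".pre"))
  yp <- pam_fwd(p$pam, f$y, h, w, n, training)
  yc <- cam_fwd(p$cam, f$y, h, w, n, training)
  list(y = yp$y + yc$y, h = h, w = w,
       cache = list(pre = f$cache, pam = yp$cache, cam = yc$cache))
}

da_bwd <- function(p, cache, dy) {
  gp <- pam_bwd(p$pam, cache$pam, dy)
  gc <- cam_bwd(p$cam, cache$cam, dy)
  gpre <- cbr_bwd(p$pre, cache$pre, gp$dx + gc$dx)
  list(dx = gpre$dx, dp = list(pre = gpre$dp, pam = gp$dp, cam = gc$dp))
}

## ---- dilated convolution block --------------------------------------------
## Three sequential 3x3 conv-BN-ReLU stages with the configured dilation
## rates; 'same' padding keeps the spatial dims.

dil_init <- function(c, rates = c(1L, 2L, 5L)) {
  if (any(rates < 1)) stop("dilation rates must be positive")
  list(d1 = cbr_init(c, c), d2 = cbr_init(c, c), d3 = cbr_init(c, c))
}

dil_fwd <- function(p, x, h, w, n, training, state, name, rates) {
  a <- cbr_fwd(p$d1, x, h, w, n, training, state, paste0(name, ".d1"),
               dilation = rates[1])
  b <- cbr_fwd(p$d2, a$y, h, w, n, training, state, paste0(name, ".d2"),
               dilation = rates[2])
  cc <- cbr_fwd(p$d3, b$y, h, w, n, training, state, paste0(name, ".d3"),
                dilation = rates[3])
  list(y = cc$y, h = h, w = w, cache = list(a = a$cache, b = b$cache, c = cc$cache))
}

dil_bwd <- function(p, cache, dy) {
  g3 <- cbr_bwd(p$d3, cache$c, dy)
  g2 <- cbr_bwd(p$d2, cache$b, g3$dx)
  g1 <- cbr_bwd(p$d1, cache$a, g2$dx)
  list(dx = g1$dx, dp = list(d1 = g1$dp, d2 = g2$dp, d3 = g3$dp))
}

#' Receptive field of a stack of dilated convolutions
#'
#' Applies the recurrence `r_out = r_in + (k - 1) * d` over the stack, so
#' rates (1, 2, 5) with 3x3 kernels give a 17 x 17 field.
#'
#' @param rates Integer vector of dilation rates.
#' @param kernel Kernel side length (default 3).
#' @return Side length of the stacked receptive field.
#' @export
dilated_receptive_field <- function(rates, kernel = 3L) {
  r <- 1L
  for (d in rates) r <- r + (kernel - 1L) * d
  r
}

## ---- decoder level --------------------------------------------------------
## Bilinear x2 upsampling, conv-BN-ReLU halving the channels, concatenation
## with the encoder skip at the same level, dropout, then a fusing
## conv-BN-ReLU.

dec_init <- function(cin, cskip, cout) {
  list(up = cbr_init(cin, cout), fuse = cbr_init(cout + cskip, cout))
}

dec_fwd <- function(p, x, h, w, skip, n, training, state, name, dropout_rate) {
  u <- upsample2_fwd(x, h, w, n, training)
  a <- cbr_fwd(p$up, u$y, u$h, u$w, n, training, state, paste0(name, ".up"))
  if (nrow(skip) < 1 || ncol(skip) != ncol(a$y))
    stop("skip connection has mismatched spatial size")
  cat_ <- rbind(a$y, skip)
  dr <- dropout_fwd(cat_, dropout_rate, training)
  f <- cbr_fwd(p$fuse, dr$y, a$h, a$w, n, training, state, paste0(name, ".fuse"))
  list(y = f$y, h = a$h, w = a$w,
       cache = list(up = u$cache, a = a$cache, drop = dr$cache, f = f$cache,
                    c_up = nrow(a$y), c_skip = nrow(skip)))
}

dec_bwd <- function(p, cache, dy) {
  gf <- cbr_bwd(p$fuse, cache$f, dy)
  dcat <- dropout_bwd(cache$drop, gf$dx)
  d_a <- dcat[seq_len(cache$c_up), , drop = FALSE]
  d_skip <- dcat[cache$c_up + seq_len(cache$c_skip), , drop = FALSE]
  ga <- cbr_bwd(p$up, cache$a, d_a)
  dx <- upsample2_bwd(cache$up, ga$dx)
  list(dx = dx, dskip = d_skip, dp = list(up = ga$dp, fuse = gf$dp))
}
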