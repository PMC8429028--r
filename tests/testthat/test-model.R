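# The compiled conv path is cross-checked against the pure-R shifted-GEMM
# reference, and the full backward pass against finite differences, so every
# architectural contract below rests on verified gradients.

test_that("compiled convolution agrees with the R reference", {
  set.seed(2)
  for (cse in list(list(s = 1L, d = 1L), list(s = 2L, d = 1L),
                   list(s = 1L, d = 2L), list(s = 1L, d = 5L))) {
    p <- eadseg:::conv_param(3, 5)
    x <- matrix(rnorm(3 * 20 * 16 * 2), 3)
    a <- eadseg:::conv_fwd(p, x, 20, 16, 2L, cse$s, cse$d)
    b <- eadseg:::conv_fwd_ref(p, x, 20, 16, 2L, cse$s, cse$d)
    expect_equal(a$y, b$y, tolerance = 1e-12)
    dy <- matrix(rnorm(length(a$y)), nrow(a$y))
    ga <- eadseg:::conv_bwd(p, a$cache, dy)
    gb <- eadseg:::conv_bwd_ref(p, b$cache, dy)
    expect_equal(ga$dx, gb$dx, tolerance = 1e-12)
    expect_equal(ga$dp$W, gb$dp$W, tolerance = 1e-12)
    expect_equal(ga$dp$b, gb$dp$b, tolerance = 1e-12)
  }
})

test_that("network gradients match finite differences", {
  set.seed(42)
  net <- build_model(tiny_model_config())
  x <- matrix(runif(3 * 16 * 16 * 2), 3)
  t_ <- matrix(rbinom(2 * 16 * 16 * 2, 1, 0.3), 2)
  loss_fn <- function(net) {
    fw <- eadseg:::model_forward(net, x, 2L, training = TRUE)
    eadseg:::bce_dice_grad(fw$logits, t_)$loss
  }
  fw <- eadseg:::model_forward(net, x, 2L, training = TRUE)
  lg <- eadseg:::bce_dice_grad(fw$logits, t_)
  g <- eadseg:::model_backward(net, fw$cache, lg$grad)
  modify <- function(lst, path, i, d) {
    if (!length(path)) { lst[i] <- lst[i] + d; return(lst) }
    lst[[path[1]]] <- modify(lst[[path[1]]], path[-1], i, d)
    lst
  }
  paths <- list(c("stem", "conv", "W"), c("enc2", "conv", "c1", "conv", "W"),
                c("enc2", "conv", "sc", "conv", "W"),
                c("enc2", "ident", "c2", "bn", "beta"),
                c("att2", "pre", "conv", "W"), c("att2", "pam", "gamma"),
                c("att2", "cam", "gamma"), c("dilated", "d2", "conv", "W"),
                c("dec1", "up", "conv", "W"), c("final", "conv", "W"),
                c("head", "W"))
  eps <- 1e-5
  for (path in paths) {
    gg <- g; pp <- net$params
    for (k in path) { gg <- gg[[k]]; pp <- pp[[k]] }
    i <- sample(length(pp), 1)
    n1 <- net; n1$params <- modify(net$params, path, i, eps)
    n2 <- net; n2$params <- modify(net$params, path, i, -eps)
    num <- (loss_fn(n1) - loss_fn(n2)) / (2 * eps)
    expect_equal(gg[i], num, tolerance = 1e-4,
                 label = paste(path, collapse = "$"))
  }
})

test_that("output shape, range and encoder downsampling follow the design", {
  cfg <- model_config(input_size = 64, base_channels = 4)
  net <- with_seed <- eadseg:::with_seed(1, build_model(cfg))
  x <- matrix(runif(3 * 64 * 64), 3)
  out <- eadseg:::model_forward(net, x, 1L)
  expect_equal(dim(out$logits), c(4L, 64L * 64L))
  probs <- eadseg:::sigmoid(out$logits)
  expect_true(all(probs >= 0 & probs <= 1))
  ## encoder halves the map at every stage, one pooling layer only
  expect_equal(model_layer_summary(net)[["max_pool"]], 1L)
  ## stage sides for a 64 input: 32, 16, 8, 4
  fw <- eadseg:::model_forward(net, x, 1L, training = TRUE)
  expect_equal(fw$h, 64L)
  expect_error(model_config(input_size = 100), "divisible")
})

test_that("residual blocks have the stated shapes and parameter ordering", {
  set.seed(5)
  p <- eadseg:::res_block_init(8, 16, bottleneck_ratio = 4, shortcut = TRUE)
  st <- new.env()
  x <- matrix(rnorm(8 * 16 * 16), 8)
  out <- eadseg:::res_block_fwd(p, x, 16, 16, 1L, TRUE, st, "t", stride = 2L)
  expect_equal(dim(out$y), c(16L, 8L * 8L))
  ## stride 1 keeps dims
  pi_ <- eadseg:::res_block_init(16, 16, shortcut = FALSE)
  out2 <- eadseg:::res_block_fwd(pi_, out$y, 8, 8, 1L, TRUE, st, "t2")
  expect_equal(dim(out2$y), dim(out$y))
  ## identity block has strictly fewer parameters (no shortcut conv)
  pc <- eadseg:::res_block_init(16, 16, shortcut = TRUE)
  expect_lt(count_parameters(pi_), count_parameters(pc))
  ## bottleneck economy: ratio 4 beats ratio 1 at equal width
  wide <- eadseg:::res_block_init(16, 16, bottleneck_ratio = 1)
  expect_lt(count_parameters(pc), count_parameters(wide))
  ## identity block limit: zeroed residual branch passes ReLU(input) through
  pz <- pi_
  pz$c3$conv$W[] <- 0; pz$c3$conv$b[] <- 0; pz$c3$bn$beta[] <- 0
  outz <- eadseg:::res_block_fwd(pz, out$y, 8, 8, 1L, FALSE, new.env(), "z")
  expect_equal(outz$y, pmax(out$y, 0), tolerance = 1e-10)
})

test_that("attention affinities are row-stochastic and gamma 0 is identity", {
  set.seed(6)
  C <- 8; h <- w <- 6
  x <- matrix(rnorm(C * h * w), C)
  pp <- eadseg:::pam_init(C)
  fw <- eadseg:::pam_fwd(pp, x, h, w, 1L, training = TRUE)
  S <- fw$cache$per[[1]]$S
  expect_equal(dim(S), c(h * w, h * w))
  expect_equal(rowSums(S), rep(1, h * w), tolerance = 1e-5)
  expect_equal(fw$y, x)                      # gamma initialized at 0

  pc <- eadseg:::cam_init()
  fc <- eadseg:::cam_fwd(pc, x, h, w, 1L, training = TRUE)
  Sc <- fc$cache$per[[1]]$S
  expect_equal(rowSums(Sc), rep(1, C), tolerance = 1e-5)
  expect_equal(fc$y, x)

  ## constant features: the attention-weighted sum over positions returns
  ## the (value-projected) constant at every position, whatever the weights
  xc <- matrix(rep(1:C, h * w), C)
  pp2 <- eadseg:::pam_init(C); pp2$gamma <- 1
  fw2 <- eadseg:::pam_fwd(pp2, xc, h, w, 1L, training = TRUE)
  O <- fw2$cache$per[[1]]$O
  v <- fw2$cache$per[[1]]$v$y
  expect_equal(O, v, tolerance = 1e-10)
  expect_lt(max(apply(O, 1, stats::sd)), 1e-10)

  ## identical channels produce identical channel-attention rows
  xi <- matrix(rnorm(h * w), 1)[rep(1, 4), ]
  fi <- eadseg:::cam_fwd(pc, rbind(xi, matrix(rnorm(2 * h * w), 2)),
                         h, w, 1L, training = TRUE)
  Si <- fi$cache$per[[1]]$S
  expect_equal(Si[1, ], Si[2, ], tolerance = 1e-12)

  ## dual attention with both scales zero doubles the shared features
  pd <- eadseg:::da_init(C)
  st <- new.env()
  fd <- eadseg:::da_fwd(pd, x, h, w, 1L, TRUE, st, "da")
  pre <- eadseg:::cbr_fwd(pd$pre, x, h, w, 1L, TRUE, new.env(), "da.pre")
  expect_equal(fd$y, 2 * pre$y, tolerance = 1e-10)
})

test_that("dilated block keeps spatial dims and has a 17x17 receptive field", {
  expect_equal(dilated_receptive_field(c(1, 2, 5)), 17L)
  expect_equal(dilated_receptive_field(c(1, 1, 1)), 7L)
  set.seed(9)
  p <- eadseg:::dil_init(4)
  st <- new.env()
  x <- matrix(rnorm(4 * 24 * 24), 4)
  out <- eadseg:::dil_fwd(p, x, 24, 24, 1L, TRUE, st, "d", c(1L, 2L, 5L))
  expect_equal(dim(out$y), dim(x))
  expect_error(eadseg:::dil_init(4, c(0, 2, 5)), "positive")
})

test_that("prediction is deterministic and thresholds behave at the bounds", {
  img <- generate_image(synthetic_config(image_size = c(32, 32), seed = 3))$image
  cfg <- model_config(input_size = 32, base_channels = 4, encoder_stages = 2,
                      attention_stages = 2)
  net <- eadseg:::with_seed(7, build_model(cfg))
  p1 <- predict_lesions(net, img)
  p2 <- predict_lesions(net, img)
  expect_identical(p1$probs, p2$probs)
  expect_true(all(unlist(p1$probs) >= 0 & unlist(p1$probs) <= 1))
  p0 <- predict_lesions(net, img, threshold = 0)
  expect_true(all(unlist(p0$masks$masks[1:4]) == 1L))
  pone <- predict_lesions(net, img, threshold = 1)
  expect_true(all(unlist(pone$masks$masks[1:4]) == 0L))
})

test_that("one small Adam step on one sample decreases the loss", {
  set.seed(12)
  net <- build_model(tiny_model_config(input_size = 32))
  gen <- generate_image(synthetic_config(image_size = c(32, 32), seed = 2))
  x <- eadseg:::images_to_batch(list(gen$image), 32)
  t_ <- eadseg:::masks_to_batch(list(gen$masks), 32, 2)
  fw <- eadseg:::model_forward(net, x, 1L, training = TRUE)
  lg <- eadseg:::bce_dice_grad(fw$logits, t_)
  g <- eadseg:::model_backward(net, fw$cache, lg$grad)
  opt <- eadseg:::adam_init(net$params)
  upd <- eadseg:::adam_step(net$params, g, opt, 1e-3)
  net2 <- net; net2$params <- upd$params
  fw2 <- eadseg:::model_forward(net2, x, 1L, training = TRUE)
  l2 <- eadseg:::bce_dice_grad(fw2$logits, t_)$loss
  expect_lt(l2, lg$loss)
})
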