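test_that("BCE+Dice loss matches a brute-force per-pixel computation", {
  set.seed(17)
  ## perfect empty prediction: loss vanishes (up to smoothing)
  z <- matrix(1e-9, 2, 50)
  t0 <- matrix(0, 2, 50)
  expect_lt(bce_dice_loss(z, t0), 1e-6)

  ## uniform 0.5 prediction on empty truth: BCE term is ln 2 per pixel
  half <- matrix(0.5, 1, 100)
  l <- bce_dice_loss(half, matrix(0, 1, 100))
  dice_term <- 1 - 1 / (50 + 1)          # smoothed dice vs empty target
  expect_equal(l, log(2) + dice_term, tolerance = 1e-12)

  ## random pair against independent summation
  for (rep in 1:5) {
    K <- sample(1:4, 1); P <- sample(20:80, 1)
    pred <- matrix(runif(K * P, 0.01, 0.99), K)
    targ <- matrix(rbinom(K * P, 1, 0.3), K)
    direct <- mean(vapply(seq_len(K), function(k) {
      p <- pred[k, ]; t_ <- targ[k, ]
      bce <- -mean(t_ * log(p) + (1 - t_) * log(1 - p))
      dice <- (2 * sum(p * t_) + 1) / (sum(p) + sum(t_) + 1)
      bce + 1 - dice
    }, numeric(1)))
    expect_equal(bce_dice_loss(pred, targ), direct, tolerance = 1e-12)
  }
  expect_error(bce_dice_loss(matrix(0.5, 2, 3), matrix(0, 3, 2)), "shape")
})

test_that("loss gradient w.r.t. logits matches finite differences", {
  set.seed(18)
  z <- matrix(rnorm(3 * 40), 3)
  t_ <- matrix(rbinom(3 * 40, 1, 0.4), 3)
  g <- eadseg:::bce_dice_grad(z, t_)
  eps <- 1e-6
  for (i in sample(length(z), 8)) {
    z1 <- z; z1[i] <- z1[i] + eps
    z2 <- z; z2[i] <- z2[i] - eps
    num <- (eadseg:::bce_dice_grad(z1, t_)$loss -
            eadseg:::bce_dice_grad(z2, t_)$loss) / (2 * eps)
    expect_equal(g$grad[i], num, tolerance = 1e-5)
  }
})

test_that("dataset split respects the 2:1 ratio and determinism", {
  items <- as.list(1:81)
  sp <- split_dataset(items, seed = 4)
  expect_length(sp$train, 54)
  expect_length(sp$test, 27)
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0)
  sp2 <- split_dataset(items, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(items, seed = 5)))
  sp3 <- split_dataset(as.list(1:3), seed = 1)
  expect_length(sp3$train, 2)
  expect_length(sp3$test, 1)
  expect_error(split_dataset(as.list(1:2)), "at least 3")
})

test_that("plateau scheduler drops the rate after 5 flat epochs, stops after 15", {
  ## improvement only at epoch 1, then a hard plateau
  losses <- c(1, rep(1, 30))
  sim <- simulate_schedule(losses, lr = 1e-4)
  expect_equal(sim$stop_epoch, 16L)
  expect_equal(sim$lr[5], 1e-4)          # still waiting
  expect_equal(sim$lr[6], 1e-5)          # first drop at epoch 6
  expect_equal(sim$lr[11], 1e-6)         # second drop five epochs later
  expect_true(all(diff(sim$lr) <= 0))    # non-increasing rate

  ## strictly decreasing loss: no drop, no stop
  sim2 <- simulate_schedule(seq(1, 0.1, length.out = 40))
  expect_true(is.na(sim2$stop_epoch))
  expect_equal(unique(sim2$lr), 1e-4)

  ## improvement resets both patience counters
  losses3 <- c(1, 1, 1, 1, 0.9, rep(0.95, 5), 0.8, rep(0.9, 16))
  sim3 <- simulate_schedule(losses3)
  expect_equal(sim3$lr[9], 1e-4)         # reset at epoch 5 kept the rate
  expect_equal(sim3$lr[10], 1e-5)        # 5 flat epochs after the reset
  expect_equal(sim3$stop_epoch, 26L)     # 15 flat epochs after epoch 11
})

test_that("training is reproducible and monitors its own loss", {
  items <- lapply(1:2, function(i) {
    g <- generate_image(synthetic_config(image_size = c(32, 32), seed = i))
    list(image = g$image, masks = g$masks)
  })
  cfg <- tiny_model_config(input_size = 32)
  net <- eadseg:::with_seed(3, build_model(cfg))
  tc <- train_config(lr = 1e-3, max_epochs = 4, seed = 9)
  f1 <- train_model(net, items, tc)
  net2 <- eadseg:::with_seed(3, build_model(cfg))
  f2 <- train_model(net2, items, tc)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-12)
  expect_equal(nrow(f1$history), 4)
  expect_true(all(diff(f1$history$lr) <= 0))
  expect_error(train_model(net, list(), tc), "empty")
  expect_error(train_config(lr_patience = 20, early_stop_patience = 15),
               "lr_patience")
})
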