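#' Combined binary cross-entropy and Dice loss
#'
#' `loss = mean over classes of ( BCE(pred, target) + 1 - Dice(pred,
#' target) )`, with BCE averaged over pixels and the Dice coefficient
#' smoothed by `smooth` in numerator and denominator so that empty masks
#' with empty predictions score a Dice of 1 (zero loss).
#'
#' @param pred Probability array/matrix; first dimension indexes classes
#'   when a matrix is given, otherwise a single class is assumed. Values in
#'   (0, 1); exact 0/1 are clipped for the log terms.
#' @param target Binary array of the same shape.
#' @param smooth Dice smoothing constant (default 1).
#' @return Nonnegative scalar loss.
#' @export
bce_dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ")
  if (!is.matrix(pred)) {
    pred <- matrix(as.numeric(pred), nrow = 1)
    target <- matrix(as.numeric(target), nrow = 1)
  }
  eps <- 1e-12
  p <- pmin(pmax(pred, eps), 1 - eps)
  bce <- rowMeans(-(target * log(p) + (1 - target) * log(1 - p)))
  dice <- (2 * rowSums(pred * target) + smooth) /
    (rowSums(pred) + rowSums(target) + smooth)
  mean(bce + (1 - dice))
}

## loss and gradient w.r.t. logits, for training. z, target: K x P.
bce_dice_grad <- function(z, target, smooth = 1) {
  K <- nrow(z); P <- ncol(z)
  p <- sigmoid(z)
  loss <- bce_dice_loss(p, target, smooth)
  ## d BCE_k / d z = (p - t) / P, then / K for the class mean
  g <- (p - target) / (P * K)
  ## Dice term: D_k = (2*S_pt + s)/(S_p + S_t + s)
  spt <- rowSums(p * target)
  sp <- rowSums(p)
  st <- rowSums(target)
  den <- sp + st + smooth
  ## d(1 - D_k)/dp = -(2*t*den - (2*spt + smooth)) / den^2
  ddice_dp <- -(2 * target * den - (2 * spt + smooth)) / den^2
  g <- g + ddice_dp * p * (1 - p) / K
  list(loss = loss, grad = g)
}

#' Per-class soft Dice coefficient
#'
#' @param pred Probability (or binary) matrix, classes in rows.
#' @param target Binary matrix of the same shape.
#' @param smooth Smoothing constant (default 1).
#' @return Numeric vector of per-class Dice coefficients.
#' @export
dice_coefficient <- function(pred, target, smooth = 1) {
  if (!is.matrix(pred)) { pred <- matrix(pred, 1); target <- matrix(target, 1) }
  (2 * rowSums(pred * target) + smooth) /
    (rowSums(pred) + rowSums(target) + smooth)
}

#' Random train/test split
#'
#' Disjoint random partition with `|train| = round(ratio * n)`; the default
#' ratio 2/3 gives the 2:1 train:test split (81 images split 54/27).
#' Deterministic for a fixed seed.
#'
#' @param items List (or vector) of dataset items.
#' @param seed Integer seed.
#' @param ratio Training fraction (default 2/3).
#' @return List with `train` and `test` subsets of `items`.
#' @export
split_dataset <- function(items, seed = 1, ratio = 2 / 3) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split")
  n_train <- round(ratio * n)
  idx <- with_seed(seed, sample.int(n))
  list(train = items[sort(idx[seq_len(n_train)])],
       test = items[sort(idx[(n_train + 1):n])])
}

#' Training configuration
#'
#' Defaults follow the training protocol: batch size 2, Adam at learning
#' rate 1e-4, the rate multiplied by `lr_factor` after `lr_patience` epochs
#' without improvement of the monitored training loss, and training stopped
#' after `early_stop_patience` epochs without improvement. Any decrease of
#' the monitored loss counts as improvement.
#'
#' @param batch_size Images per optimization step (default 2).
#' @param lr Initial Adam learning rate (default 1e-4).
#' @param lr_factor Multiplier applied on plateau (default 0.1).
#' @param lr_patience Epochs without improvement before the rate drops
#'   (default 5).
#' @param early_stop_patience Epochs without improvement before stopping
#'   (default 15); must exceed `lr_patience`.
#' @param max_epochs Hard epoch cap (default 300; early stopping usually
#'   ends training first).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 2, lr = 1e-4, lr_factor = 0.1,
                         lr_patience = 5, early_stop_patience = 15,
                         max_epochs = 300, seed = 1) {
  if (lr_patience >= early_stop_patience)
    stop("lr_patience must be smaller than early_stop_patience")
  if (batch_size < 1 || max_epochs < 1) stop("invalid batch_size/max_epochs")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

## Plateau scheduler + early stopping as a pure state machine over the
## sequence of monitored losses.
sched_init <- function(lr, factor, lr_patience, stop_patience) {
  list(lr = lr, factor = factor, lr_patience = lr_patience,
       stop_patience = stop_patience, best = Inf,
       bad_lr = 0L, bad_stop = 0L, stop = FALSE)
}

sched_step <- function(s, loss) {
  if (loss < s$best) {
    s$best <- loss
    s$bad_lr <- 0L
    s$bad_stop <- 0L
    s$improved <- TRUE
  } else {
    s$bad_lr <- s$bad_lr + 1L
    s$bad_stop <- s$bad_stop + 1L
    s$improved <- FALSE
    if (s$bad_lr >= s$lr_patience) {
      s$lr <- s$lr * s$factor
      s$bad_lr <- 0L
    }
    if (s$bad_stop >= s$stop_patience) s$stop <- TRUE
  }
  s
}

#' Simulate the learning-rate schedule on a scripted loss sequence
#'
#' Pure function of the monitored loss sequence: after `lr_patience`
#' consecutive epochs without improvement the learning rate is multiplied
#' by `factor`; after `stop_patience` epochs without improvement training
#' stops. Useful for verifying scheduler behavior without a network: a loss
#' that plateaus from epoch 1 drops the rate at epoch 6 and stops at epoch
#' 16 under the defaults.
#'
#' @param losses Numeric vector of per-epoch monitored losses.
#' @param lr Initial learning rate.
#' @param factor Plateau multiplier.
#' @param lr_patience Epochs of patience before a rate drop.
#' @param stop_patience Epochs of patience before stopping.
#' @return List with `lr` (rate in force *after* each processed epoch),
#'   `stop_epoch` (`NA` if the sequence ran out first) and `stop_reason`.
#' @export
simulate_schedule <- function(losses, lr = 1e-4, factor = 0.1,
                              lr_patience = 5, stop_patience = 15) {
  s <- sched_init(lr, factor, lr_patience, stop_patience)
  lrs <- numeric(0)
  stop_epoch <- NA_integer_
  for (e in seq_along(losses)) {
    s <- sched_step(s, losses[e])
    lrs[e] <- s$lr
    if (s$stop) { stop_epoch <- e; break }
  }
  list(lr = lrs, stop_epoch = stop_epoch,
       stop_reason = if (!is.na(stop_epoch)) "early_stop" else "exhausted")
}

#' Train the network
#'
#' Adam optimization of the combined BCE + Dice loss at the configured
#' batch size, with the reduce-on-plateau schedule and early stopping of
#' [simulate_schedule()] applied to the mean training loss per epoch. The
#' parameters achieving the best monitored loss are returned.
#'
#' @param model An `ead_model` from [build_model()].
#' @param train_set List of `list(image =, masks =)` pairs at the network
#'   input size.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss and learning rate (default FALSE).
#' @return List with `model` (best-loss parameters), `history` (data frame
#'   of epoch, loss, lr), `stop_epoch` and `stop_reason`.
#' @export
train_model <- function(model, train_set, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "ead_model"), inherits(config, "train_config"))
  if (!length(train_set)) stop("training set is empty")
  L <- model$config$input_size
  K <- model$config$num_classes
  x_all <- images_to_batch(lapply(train_set, `[[`, "image"), L)
  t_all <- masks_to_batch(lapply(train_set, `[[`, "masks"), L, K)
  n <- length(train_set)
  blk <- L * L

  opt <- adam_init(model$params)
  sch <- sched_init(config$lr, config$lr_factor,
                    config$lr_patience, config$early_stop_patience)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  best_params <- model$params
  stop_reason <- "max_epochs"
  stop_epoch <- config$max_epochs

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1, n)]
        cols <- as.vector(vapply(ids, function(i) ((i - 1) * blk + 1):(i * blk),
                                 integer(blk)))
        nb <- length(ids)
        fw <- model_forward(model, x_all[, cols, drop = FALSE], nb,
                            training = TRUE)
        lg <- bce_dice_grad(fw$logits, t_all[, cols, drop = FALSE])
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               "; try a smaller learning rate")
        grads <- model_backward(model, fw$cache, lg$grad)
        upd <- adam_step(model$params, grads, opt, sch$lr)
        model$params <- upd$params
        opt <- upd$state
        losses <- c(losses, lg$loss)
      }
      epoch_loss <- mean(losses)
      sch <- sched_step(sch, epoch_loss)
      if (sch$improved) best_params <- model$params
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss, lr = sch$lr))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  lr %.2e", epoch, epoch_loss, sch$lr))
      if (sch$stop) { stop_reason <- "early_stop"; stop_epoch <- epoch; break }
    }
  })
  model$params <- best_params
  list(model = model, history = history,
       stop_epoch = min(stop_epoch, nrow(history)),
       stop_reason = stop_reason)
}

#' Mean soft Dice of a model over a dataset
#'
#' @param model An `ead_model`.
#' @param dataset List of `list(image =, masks =)` pairs.
#' @return Mean over images of the class-averaged soft Dice coefficient.
#' @export
evaluate_dice <- function(model, dataset) {
  L <- model$config$input_size
  K <- model$config$num_classes
  mean(vapply(dataset, function(item) {
    x <- images_to_batch(list(item$image), L)
    out <- model_forward(model, x, 1L, training = FALSE)
    p <- sigmoid(out$logits)
    t_ <- masks_to_batch(list(item$masks), L, K)
    mean(dice_coefficient(p, t_))
  }, numeric(1)))
}
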