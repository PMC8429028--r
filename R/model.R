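#' Architecture configuration
#'
#' Describes the encoder-attention-decoder segmentation network: a stem
#' convolution followed by the single max-pooling of the whole network
#' produces the first feature map; each further encoder stage downsamples
#' with a stride-2 residual bottleneck block followed by an identity block,
#' doubling the channels; dual (position + channel) attention refines the
#' deepest feature maps; a three-stage dilated-convolution block sits at the
#' bottom; the decoder mirrors the encoder with bilinear upsampling, skip
#' concatenations and dropout, ending in a per-pixel multi-label sigmoid
#' head.
#'
#' @param input_size Network input side length; must be divisible by
#'   `2^encoder_stages` (default 512).
#' @param num_classes Output channels, one sigmoid map per lesion class
#'   (default 4).
#' @param base_channels Channels of the first feature map; later stages
#'   double it (default 64).
#' @param encoder_stages Number of encoder feature maps (default 4).
#' @param bottleneck_ratio Residual blocks compute internally at
#'   `out_channels / bottleneck_ratio` width (default 4).
#' @param dilation_rates Three dilation rates for the bottom block; the
#'   default (1, 2, 5) avoids the gridding artifact of equal rates.
#' @param dropout_rate Decoder dropout probability (default 0.5).
#' @param attention_stages Encoder stages whose maps pass through dual
#'   attention (default the two deepest, 3 and 4). Attention on maps larger
#'   than 64 x 64 positions is rejected: the position-attention affinity is
#'   quadratic in map area.
#' @return A validated `model_config` list.
#' @export
model_config <- function(input_size = 512, num_classes = 4,
                         base_channels = 64, encoder_stages = 4,
                         bottleneck_ratio = 4, dilation_rates = c(1, 2, 5),
                         dropout_rate = 0.5, attention_stages = c(3, 4)) {
  input_size <- as.integer(input_size)
  encoder_stages <- as.integer(encoder_stages)
  if (encoder_stages < 2) stop("encoder_stages must be at least 2")
  if (input_size %% (2^encoder_stages) != 0)
    stop(sprintf("input_size %d is not divisible by 2^%d",
                 input_size, encoder_stages))
  if (length(dilation_rates) != 3 || any(dilation_rates < 1))
    stop("dilation_rates must be three positive integers")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  if (length(attention_stages) &&
      (any(attention_stages < 1) || any(attention_stages > encoder_stages)))
    stop("attention_stages must index encoder stages")
  for (s in attention_stages) {
    side <- input_size / 2^s
    if (side > 64)
      stop(sprintf(
        "attention at stage %d would act on a %dx%d map; maps above 64x64 are not supported",
        s, side, side))
  }
  structure(list(
    input_size = input_size, in_channels = 3L,
    num_classes = as.integer(num_classes),
    base_channels = as.integer(base_channels),
    encoder_stages = encoder_stages,
    bottleneck_ratio = as.integer(bottleneck_ratio),
    dilation_rates = as.integer(dilation_rates),
    dropout_rate = dropout_rate,
    attention_stages = as.integer(sort(attention_stages))
  ), class = "model_config")
}

stage_channels <- function(config, s) config$base_channels * 2L^(s - 1L)

#' Build the segmentation network
#'
#' Instantiates all parameters (He initialization for convolutions, unit
#' gamma / zero beta for batch norm, zero attention residual scales). The
#' returned network is a plain list: `config`, `params` (nested parameter
#' list) and `state` (environment holding batch-norm running statistics).
#'
#' @param config A [model_config()].
#' @return An object of class `ead_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  S <- config$encoder_stages
  b <- config$base_channels
  params <- list(stem = cbr_init(config$in_channels, b))
  for (s in 2:S) {
    cin <- stage_channels(config, s - 1L)
    cout <- stage_channels(config, s)
    params[[paste0("enc", s)]] <- list(
      conv = res_block_init(cin, cout, config$bottleneck_ratio, shortcut = TRUE),
      ident = res_block_init(cout, cout, config$bottleneck_ratio, shortcut = FALSE)
    )
  }
  for (s in config$attention_stages)
    params[[paste0("att", s)]] <- da_init(stage_channels(config, s))
  params$dilated <- dil_init(stage_channels(config, S), config$dilation_rates)
  for (s in (S - 1):1) {
    params[[paste0("dec", s)]] <- dec_init(
      cin = stage_channels(config, s + 1L),
      cskip = stage_channels(config, s),
      cout = stage_channels(config, s)
    )
  }
  params$final <- cbr_init(b, b)
  params$head <- conv_param(b, config$num_classes, 1L)
  structure(list(config = config, params = params, state = new.env()),
            class = "ead_model")
}

#' @exportS3Method base::print
print.ead_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ead_model %dx%d -> %d classes; base %d, %d stages, attention at {%s}; %s parameters>\n",
    cfg$input_size, cfg$input_size, cfg$num_classes, cfg$base_channels,
    cfg$encoder_stages, paste(cfg$attention_stages, collapse = ","),
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param x An `ead_model` or a nested parameter list.
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(x) {
  p <- if (inherits(x, "ead_model")) x$params else x
  if (is.list(p)) return(sum(vapply(p, count_parameters, numeric(1))))
  length(p)
}

#' Layer-type census of the network graph
#'
#' @param model An `ead_model`.
#' @return Named integer vector: counts of pooling layers, strided
#'   convolutions, attention modules, dilated convolutions and upsampling
#'   steps in the computation graph.
#' @export
model_layer_summary <- function(model) {
  cfg <- model$config
  S <- cfg$encoder_stages
  c(
    max_pool = 1L,
    strided_conv = 2L * (S - 1L),      # branch + shortcut conv per downsampling block
    attention = length(cfg$attention_stages),
    dilated_conv = 3L,
    upsample = S                      # S-1 decoder levels + final upsample
  )
}

## Forward pass over a batch. x: C x (L*L*n) matrix in [0,1].
model_forward <- function(model, x, n, training = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  L <- cfg$input_size
  S <- cfg$encoder_stages
  cache <- list()

  stem <- cbr_fwd(p$stem, x, L, L, n, training, st, "stem")
  pool <- maxpool2_fwd(stem$y, L, L, n, training)
  cache$stem <- stem$cache; cache$pool <- pool$cache

  maps <- list(list(y = pool$y, h = pool$h, w = pool$w))
  for (s in 2:S) {
    prev <- maps[[s - 1L]]
    nm <- paste0("enc", s)
    cb <- res_block_fwd(p[[nm]]$conv, prev$y, prev$h, prev$w, n,
                        training, st, paste0(nm, ".conv"), stride = 2L)
    ib <- res_block_fwd(p[[nm]]$ident, cb$y, cb$h, cb$w, n,
                        training, st, paste0(nm, ".ident"))
    cache[[nm]] <- list(conv = cb$cache, ident = ib$cache)
    maps[[s]] <- list(y = ib$y, h = cb$h, w = cb$w)
  }
  for (s in cfg$attention_stages) {
    nm <- paste0("att", s)
    at <- da_fwd(p[[nm]], maps[[s]]$y, maps[[s]]$h, maps[[s]]$w, n,
                 training, st, nm)
    cache[[nm]] <- at$cache
    maps[[s]]$y <- at$y
  }
  dl <- dil_fwd(p$dilated, maps[[S]]$y, maps[[S]]$h, maps[[S]]$w, n,
                training, st, "dilated", cfg$dilation_rates)
  cache$dilated <- dl$cache
  cur <- list(y = dl$y, h = maps[[S]]$h, w = maps[[S]]$w)

  for (s in (S - 1):1) {
    nm <- paste0("dec", s)
    dc <- dec_fwd(p[[nm]], cur$y, cur$h, cur$w, maps[[s]]$y, n,
                  training, st, nm, cfg$dropout_rate)
    cache[[nm]] <- dc$cache
    cur <- list(y = dc$y, h = dc$h, w = dc$w)
  }
  up <- upsample2_fwd(cur$y, cur$h, cur$w, n, training)
  fin <- cbr_fwd(p$final, up$y, up$h, up$w, n, training, st, "final")
  head <- conv_fwd(p$head, fin$y, up$h, up$w, n, training = training)
  cache$up_final <- up$cache; cache$final <- fin$cache; cache$head <- head$cache

  list(logits = head$y, h = up$h, w = up$w,
       cache = if (training) cache else NULL)
}

## Backward pass; dlogits matches the logits layout. Returns nested grads.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  S <- cfg$encoder_stages
  g <- list()

  gh <- conv_bwd(p$head, cache$head, dlogits)
  g$head <- gh$dp
  gf <- cbr_bwd(p$final, cache$final, gh$dx)
  g$final <- gf$dp
  dcur <- upsample2_bwd(cache$up_final, gf$dx)

  dskip <- vector("list", S)
  for (s in 1:(S - 1)) {
    nm <- paste0("dec", s)
    gd <- dec_bwd(p[[nm]], cache[[nm]], dcur)
    g[[nm]] <- gd$dp
    dskip[[s]] <- gd$dskip
    dcur <- gd$dx
  }
  gdil <- dil_bwd(p$dilated, cache$dilated, dcur)
  g$dilated <- gdil$dp
  dmap <- vector("list", S)
  dmap[[S]] <- gdil$dx
  for (s in 1:(S - 1)) dmap[[s]] <- dskip[[s]]

  for (s in rev(cfg$attention_stages)) {
    nm <- paste0("att", s)
    ga <- da_bwd(p[[nm]], cache[[nm]], dmap[[s]])
    g[[nm]] <- ga$dp
    dmap[[s]] <- ga$dx
  }
  for (s in S:2) {
    nm <- paste0("enc", s)
    gi <- res_block_bwd(p[[nm]]$ident, cache[[nm]]$ident, dmap[[s]])
    gc_ <- res_block_bwd(p[[nm]]$conv, cache[[nm]]$conv, gi$dx)
    g[[nm]] <- list(conv = gc_$dp, ident = gi$dp)
    dmap[[s - 1L]] <- dmap[[s - 1L]] + gc_$dx
  }
  dpool <- maxpool2_bwd(cache$pool, dmap[[1L]])
  gs <- cbr_bwd(p$stem, cache$stem, dpool)
  g$stem <- gs$dp
  ## order grads like params
  g[names(model$params)]
}

## fundus images (list) -> input matrix C x (L*L*n), scaled to [0,1]
images_to_batch <- function(images, input_size) {
  n <- length(images)
  x <- matrix(0, 3, input_size^2 * n)
  for (i in seq_len(n)) {
    px <- images[[i]]$pixels
    if (!all(dim(px)[1:2] == input_size))
      stop(sprintf("image '%s' is %dx%d but the network expects %d",
                   images[[i]]$source_id, dim(px)[1], dim(px)[2], input_size))
    cols <- ((i - 1) * input_size^2 + 1):(i * input_size^2)
    for (ch in 1:3) x[ch, cols] <- as.vector(px[, , ch]) / 255
  }
  x
}

masks_to_batch <- function(mask_sets, input_size, num_classes = 4) {
  n <- length(mask_sets)
  t_ <- matrix(0, num_classes, input_size^2 * n)
  cls <- lesion_classes()[seq_len(num_classes)]
  for (i in seq_len(n)) {
    cols <- ((i - 1) * input_size^2 + 1):(i * input_size^2)
    for (k in seq_along(cls))
      t_[k, cols] <- as.vector(mask_sets[[i]]$masks[[cls[k]]])
  }
  t_
}

#' Predict lesion probability maps and masks for one image
#'
#' Runs the network in inference mode (no dropout, batch-norm running
#' statistics) and binarizes each class probability map at `threshold`
#' (strict `>`, so threshold 0 yields all-ones and threshold 1 all-zeros).
#'
#' @param model An `ead_model`.
#' @param image A [fundus_image()] at the network input size.
#' @param threshold Probability cut in \[0, 1\] (default 0.5).
#' @return List with `probs` (named list of H x W probability matrices) and
#'   `masks` (a [lesion_mask_set()]).
#' @export
predict_lesions <- function(model, image, threshold = 0.5) {
  stopifnot(inherits(model, "ead_model"), inherits(image, "fundus_image"))
  L <- model$config$input_size
  x <- images_to_batch(list(image), L)
  out <- model_forward(model, x, 1L, training = FALSE)
  probs <- list()
  masks <- list()
  cls <- lesion_classes()[seq_len(model$config$num_classes)]
  for (k in seq_along(cls)) {
    pm <- matrix(sigmoid(out$logits[k, ]), L, L)
    probs[[cls[k]]] <- pm
    masks[[cls[k]]] <- matrix(as.integer(pm > threshold), L, L)
  }
  list(probs = probs,
       masks = lesion_mask_set(masks, source_id = image$source_id))
}
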