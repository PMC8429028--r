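#' Augmentation configuration
#'
#' Random geometric expansion of the training set: horizontal/vertical
#' flips, per-axis scaling, translation and rotation, applied jointly to
#' image and masks. Each emitted sample uses a random subset of the enabled
#' transform families, not all of them at once. The transform families are
#' fixed; their magnitudes below are package defaults.
#'
#' @param flip_h,flip_v Enable horizontal / vertical flips (default TRUE).
#' @param scale_range Per-axis scale factor interval (default c(0.9, 1.1)).
#' @param translate_range Translation interval as a fraction of the image
#'   side (default c(-0.1, 0.1)).
#' @param rotate_range Rotation interval in degrees (default c(-15, 15)).
#' @param expansion_factor Output/input size ratio, an integer >= 1
#'   (default 5); the originals are always included.
#' @param seed Integer seed; the expansion is deterministic per seed.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_h = TRUE, flip_v = TRUE,
                           scale_range = c(0.9, 1.1),
                           translate_range = c(-0.1, 0.1),
                           rotate_range = c(-15, 15),
                           expansion_factor = 5, seed = 1) {
  if (expansion_factor < 1) stop("expansion_factor must be >= 1")
  structure(list(flip_h = flip_h, flip_v = flip_v, scale_range = scale_range,
                 translate_range = translate_range, rotate_range = rotate_range,
                 expansion_factor = as.integer(expansion_factor),
                 seed = as.integer(seed)),
            class = "augment_config")
}

## Inverse-mapping affine resampler. The forward map takes centered pixel
## coordinates (origin at the image center, (row, col) order) through
## flips/scales/rotation `A` and then adds the translation `t` (pixels).
## Out-of-bounds source positions are filled with `fill` (black).
warp_affine <- function(m, A, t, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  ctr <- c((h - 1) / 2, (w - 1) / 2)
  Ainv <- solve(A)
  ro <- rep(0:(h - 1), times = w) - ctr[1]
  co <- rep(0:(w - 1), each = h) - ctr[2]
  src_r <- Ainv[1, 1] * (ro - t[1]) + Ainv[1, 2] * (co - t[2]) + ctr[1]
  src_c <- Ainv[2, 1] * (ro - t[1]) + Ainv[2, 2] * (co - t[2]) + ctr[2]
  if (interp == "nearest") {
    r <- round(src_r); c_ <- round(src_c)
    ok <- r >= 0 & r <= h - 1 & c_ >= 0 & c_ <= w - 1
    out <- rep(fill, h * w)
    out[ok] <- m[cbind(r[ok] + 1, c_[ok] + 1)]
    return(matrix(out, h, w))
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  out <- rep(0, h * w)
  wsum <- rep(0, h * w)
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    wgt <- (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc)
    ok <- rr >= 0 & rr <= h - 1 & cc >= 0 & cc <= w - 1 & wgt > 0
    out[ok] <- out[ok] + wgt[ok] * m[cbind(rr[ok] + 1, cc[ok] + 1)]
    wsum[ok] <- wsum[ok] + wgt[ok]
  }
  inside <- wsum > 0
  out[!inside] <- fill
  matrix(out, h, w)
}

params_to_affine <- function(params) {
  th <- params$rotate * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sr <- params$scale[1] * (if (isTRUE(params$flip_v)) -1 else 1)
  sc <- params$scale[2] * (if (isTRUE(params$flip_h)) -1 else 1)
  A <- R %*% diag(c(sr, sc))
  list(A = A, t = params$translate)
}

#' Apply one fully specified geometric transform to an image/mask pair
#'
#' Flips, per-axis scales, rotation (about the image center) and
#' translation are composed into a single affine map and applied in one
#' resampling step: bilinear for the image, nearest-neighbor for the masks
#' (then re-binarized). Regions mapped from outside the frame are filled
#' with black, consistent with the fundus background. A horizontal flip
#' mirrors columns; a vertical flip mirrors rows.
#'
#' @param image A [fundus_image()].
#' @param masks A [lesion_mask_set()] aligned with `image` (or `NULL`).
#' @param params List with `flip_h`, `flip_v` (logicals), `scale` (two
#'   per-axis factors, row then column), `translate` (pixels, row then
#'   column) and `rotate` (degrees).
#' @return List with transformed `image` and `masks`.
#' @export
apply_transform <- function(image, masks, params) {
  stopifnot(inherits(image, "fundus_image"))
  af <- params_to_affine(params)
  px <- image$pixels
  out <- px
  for (ch in 1:3)
    out[, , ch] <- warp_affine(px[, , ch], af$A, af$t, "bilinear")
  out <- pmin(pmax(out, 0), 255)
  img <- fundus_image(out, source_id = image$source_id, record = image$record)
  mk <- NULL
  if (!is.null(masks)) {
    mm <- lapply(masks$masks, function(m)
      binarize_mask(warp_affine(m, af$A, af$t, "nearest")))
    mk <- lesion_mask_set(mm, source_id = masks$source_id)
  }
  list(image = img, masks = mk)
}

sample_transform_params <- function(config, size) {
  families <- c("flip_h", "flip_v", "scale", "translate", "rotate")[c(
    isTRUE(config$flip_h), isTRUE(config$flip_v), TRUE, TRUE, TRUE)]
  use <- families[stats::runif(length(families)) < 0.5]
  if (!length(use)) use <- sample(families, 1)
  params <- list(flip_h = FALSE, flip_v = FALSE, scale = c(1, 1),
                 translate = c(0, 0), rotate = 0)
  if ("flip_h" %in% use) params$flip_h <- TRUE
  if ("flip_v" %in% use) params$flip_v <- TRUE
  if ("scale" %in% use)
    params$scale <- stats::runif(2, config$scale_range[1], config$scale_range[2])
  if ("translate" %in% use)
    params$translate <- stats::runif(2, config$translate_range[1],
                                     config$translate_range[2]) * size
  if ("rotate" %in% use)
    params$rotate <- stats::runif(1, config$rotate_range[1],
                                  config$rotate_range[2])
  params
}

#' Expand a dataset by random joint geometric augmentation
#'
#' Each input pair contributes itself plus `expansion_factor - 1` randomly
#' transformed copies, so the output holds exactly
#' `length(pairs) * expansion_factor` pairs. Deterministic per seed.
#'
#' @param pairs List of `list(image =, masks =)` pairs.
#' @param config An [augment_config()].
#' @return Expanded list of pairs; augmented copies carry a `#augN` suffix
#'   on their source ids.
#' @export
augment_dataset <- function(pairs, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  with_seed(config$seed, {
    out <- vector("list", length(pairs) * config$expansion_factor)
    j <- 0L
    for (pair in pairs) {
      j <- j + 1L
      out[[j]] <- pair
      size <- image_dim(pair$image)[1]
      if (config$expansion_factor > 1L) {
        for (k in seq_len(config$expansion_factor - 1L)) {
          params <- sample_transform_params(config, size)
          tr <- apply_transform(pair$image, pair$masks, params)
          tr$image$source_id <- paste0(pair$image$source_id, "#aug", k)
          if (!is.null(tr$masks))
            tr$masks$source_id <- tr$image$source_id
          j <- j + 1L
          out[[j]] <- tr
        }
      }
    }
    out
  })
}
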