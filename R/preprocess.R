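## Geometric size normalization: crop away the black frame around the
## circular field of view, pad the short side to a square, resize to a fixed
## target (1024 by default), and carry masks through the identical transform.

resize_raster <- function(x, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  out <- EBImage::resize(x, w = h, h = w, filter = filt)
  ## EBImage returns an Image object; keep plain arrays/matrices
  out <- if (length(d) == 2L) matrix(as.numeric(out), h, w) else
    array(as.numeric(out), c(h, w, d[3]))
  out
}

#' Find the tight bounding box of non-black content
#'
#' Scans for pixels whose maximum channel intensity exceeds `threshold`
#' (default 10 on the 0-255 scale, a conservative cut for the dark frame
#' around the field of view). If nothing qualifies the full frame is
#' returned.
#'
#' @param image A [fundus_image()].
#' @param threshold Intensity threshold in \[0, 255\].
#' @return Integer vector `(row_min, row_max, col_min, col_max)`: 0-based,
#'   half-open (rows `row_min ... row_max - 1` are inside).
#' @export
find_content_box <- function(image, threshold = 10) {
  stopifnot(inherits(image, "fundus_image"))
  px <- image$pixels
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  rows <- which(apply(mx, 1, max) > threshold)
  cols <- which(apply(mx, 2, max) > threshold)
  if (!length(rows) || !length(cols))
    return(c(0L, nrow(mx), 0L, ncol(mx)))
  c(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
}

#' Normalize an image (and masks) to a fixed square size
#'
#' Crops to the content box, pads the short side symmetrically with black so
#' height equals width (an odd remainder goes to the bottom/right), then
#' resizes to `target_size` x `target_size`. Because padding happens before
#' the square resize, the cropped content keeps its aspect ratio. Masks
#' receive the identical geometric transform with nearest-neighbor
#' resampling and are re-binarized.
#'
#' @param image A [fundus_image()].
#' @param masks Optional [lesion_mask_set()] aligned with `image`.
#' @param target_size Output side length in pixels (default 1024).
#' @param threshold Black-border threshold passed to [find_content_box()].
#' @return List with `image`, `masks` (or `NULL`) and `record`, the
#'   preprocessing record needed by [invert_record()]. The record is also
#'   stored on the returned image.
#' @export
normalize_image <- function(image, masks = NULL, target_size = 1024,
                            threshold = 10) {
  stopifnot(inherits(image, "fundus_image"))
  if (!is.null(masks) && !identical(image_dim(image), mask_dim(masks)))
    stop("image and masks have different dimensions")
  d <- image_dim(image)
  box <- find_content_box(image, threshold)
  rows <- (box[1] + 1L):box[2]
  cols <- (box[3] + 1L):box[4]
  ch <- length(rows); cw <- length(cols)
  side <- max(ch, cw)
  pad_r <- side - ch; pad_c <- side - cw
  pad <- c(top = pad_r %/% 2L, bottom = pad_r - pad_r %/% 2L,
           left = pad_c %/% 2L, right = pad_c - pad_c %/% 2L)

  record <- list(
    orig_size = d,
    crop_box = box,
    pad = pad,
    padded_size = side,
    scale_factor = target_size / side,
    target_size = as.integer(target_size)
  )

  pad_and_resize <- function(x, method) {
    cropped <- if (length(dim(x)) == 3L) x[rows, cols, , drop = FALSE]
               else x[rows, cols, drop = FALSE]
    d3 <- if (length(dim(x)) == 3L) dim(x)[3] else NULL
    sq <- if (is.null(d3)) matrix(0, side, side) else array(0, c(side, side, d3))
    rr <- (pad[["top"]] + 1L):(pad[["top"]] + ch)
    cc <- (pad[["left"]] + 1L):(pad[["left"]] + cw)
    if (is.null(d3)) sq[rr, cc] <- cropped else sq[rr, cc, ] <- cropped
    resize_raster(sq, target_size, target_size, method)
  }

  out_px <- pad_and_resize(image$pixels, "bilinear")
  out_px <- pmin(pmax(out_px, 0), 255)
  out_img <- fundus_image(out_px, source_id = image$source_id, record = record)

  out_masks <- NULL
  if (!is.null(masks)) {
    mm <- lapply(masks$masks, function(m) binarize_mask(pad_and_resize(m, "nearest")))
    out_masks <- lesion_mask_set(mm, source_id = masks$source_id)
  }
  list(image = out_img, masks = out_masks, record = record)
}

#' Resize normalized image and masks to the training resolution
#'
#' @param image A normalized [fundus_image()].
#' @param masks Optional aligned [lesion_mask_set()].
#' @param train_size Side length used for network input (default 512).
#' @return List with `image` and `masks`; masks are re-binarized after the
#'   nearest-neighbor resize.
#' @export
to_train_resolution <- function(image, masks = NULL, train_size = 512) {
  stopifnot(inherits(image, "fundus_image"))
  px <- resize_raster(image$pixels, train_size, train_size, "bilinear")
  px <- pmin(pmax(px, 0), 255)
  record <- image$record
  if (!is.null(record)) record$train_size <- as.integer(train_size)
  out_img <- fundus_image(px, source_id = image$source_id, record = record)
  out_masks <- NULL
  if (!is.null(masks)) {
    mm <- lapply(masks$masks, function(m)
      binarize_mask(resize_raster(m, train_size, train_size, "nearest")))
    out_masks <- lesion_mask_set(mm, source_id = masks$source_id)
  }
  list(image = out_img, masks = out_masks)
}

#' Map a mask back to the original image geometry
#'
#' Reverses the resize, padding and crop recorded by [normalize_image()] so
#' predictions can be reported in the source image's pixel grid. Accepts a
#' mask at `target_size` or, if the record carries one, at `train_size`.
#'
#' @param record A preprocessing record.
#' @param mask Binary matrix at the normalized (or training) resolution.
#' @return Binary matrix at the original image dimensions.
#' @export
invert_record <- function(record, mask) {
  sz <- nrow(mask)
  if (!is.matrix(mask) || nrow(mask) != ncol(mask))
    stop("mask must be a square matrix")
  ok <- sz == record$target_size ||
    (!is.null(record$train_size) && sz == record$train_size)
  if (!ok)
    stop(sprintf("mask is %dx%d but the record expects %d (or train size %s)",
                 sz, sz, record$target_size,
                 if (is.null(record$train_size)) "unset" else record$train_size))
  side <- record$padded_size
  m <- binarize_mask(resize_raster(mask, side, side, "nearest"))
  pad <- record$pad
  ch <- side - pad[["top"]] - pad[["bottom"]]
  cw <- side - pad[["left"]] - pad[["right"]]
  cropped <- m[(pad[["top"]] + 1L):(pad[["top"]] + ch),
               (pad[["left"]] + 1L):(pad[["left"]] + cw), drop = FALSE]
  out <- matrix(0L, record$orig_size[1], record$orig_size[2])
  box <- record$crop_box
  out[(box[1] + 1L):box[2], (box[3] + 1L):box[4]] <- cropped
  out
}
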