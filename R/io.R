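#' Read a fundus image from disk
#'
#' Supports PNG and TIFF always, and JPEG when the `jpeg` package is
#' installed. Grayscale rasters are replicated to three identical channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @param source_id Identifier stored on the image; defaults to the file name
#'   without extension.
#' @return A [fundus_image()].
#' @export
read_image <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE))
          stop("reading JPEG requires the 'jpeg' package")
        jpeg::readJPEG(path)
      },
      stop("unsupported image format '", ext, "': ", path)
    ),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1, drop = TRUE]
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  fundus_image(round(px * 255), source_id = source_id)
}

#' Write a fundus image to disk
#'
#' PNG output is lossless: writing and re-reading reproduces the pixels
#' bit-identically (intensities are stored as 8-bit).
#'
#' @param image A [fundus_image()].
#' @param path Output path; `.png` or `.tif`/`.tiff`.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  ext <- tolower(tools::file_ext(path))
  px <- image$pixels / 255
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'")
  )
  invisible(path)
}

mask_file_name <- function(source_id, class) paste0(source_id, "_", class, ".png")

#' Read a per-class lesion mask set from a directory
#'
#' The on-disk layout is one 8-bit binary PNG per class per image, named
#' `<source_id>_<class>.png` (e.g. `img01_MA.png`). Missing class files yield
#' all-zero masks; any nonzero pixel is binarized to 1.
#'
#' @param dir Directory containing the mask files.
#' @param source_id Image identifier the masks belong to.
#' @param image Optional paired [fundus_image()] used to check dimensions.
#' @param dim Integer pair (H, W); required when `image` is `NULL` and no
#'   mask file exists.
#' @return A [lesion_mask_set()].
#' @export
read_mask_set <- function(dir, source_id, image = NULL, dim = NULL) {
  if (!is.null(image)) dim <- image_dim(image)
  masks <- list()
  for (cl in lesion_classes()) {
    f <- file.path(dir, mask_file_name(source_id, cl))
    if (file.exists(f)) {
      m <- png::readPNG(f)
      if (length(base::dim(m)) == 3L) m <- m[, , 1]
      if (!is.null(dim) && !identical(base::dim(m), as.integer(dim)))
        stop(sprintf("mask '%s' is %dx%d but the image is %dx%d",
                     basename(f), nrow(m), ncol(m), dim[1], dim[2]))
      masks[[cl]] <- binarize_mask(m)
    }
  }
  if (is.null(dim) && !length(masks))
    stop("no mask files found for '", source_id, "' and no dimensions given")
  lesion_mask_set(masks, source_id = source_id, dim = dim)
}

#' Write a lesion mask set as per-class PNG files
#'
#' @param masks A [lesion_mask_set()].
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_mask_set <- function(masks, dir) {
  stopifnot(inherits(masks, "lesion_mask_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cl in lesion_classes()) {
    f <- file.path(dir, mask_file_name(masks$source_id, cl))
    png::writePNG(masks$masks[[cl]] * 1.0, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

## 0/1 matrix of boundary pixels: foreground with at least one 4-neighbor
## outside the component (or on the image edge).
mask_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  inner <- matrix(TRUE, h, w)
  shift_and <- function(acc, dr, dc) {
    s <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    acc & (s == 1L)
  }
  inner <- shift_and(inner, 1, 0)
  inner <- shift_and(inner, -1, 0)
  inner <- shift_and(inner, 0, 1)
  inner <- shift_and(inner, 0, -1)
  (m == 1L) & !inner
}

#' Render an image with class-colored lesion contours
#'
#' Draws the boundary of every lesion in the display-color convention of
#' [class_colors()] (MA red, HE green, hard exudate blue, soft exudate
#' yellow). All-zero masks leave the image unchanged.
#'
#' @param image A [fundus_image()].
#' @param masks A [lesion_mask_set()] aligned with `image`.
#' @param path Optional PNG output path; when `NULL` the raster is only
#'   returned.
#' @return The overlay as an H x W x 3 array in \[0, 255\], invisibly when
#'   written to disk.
#' @export
write_overlay <- function(image, masks, path = NULL) {
  stopifnot(inherits(image, "fundus_image"), inherits(masks, "lesion_mask_set"))
  if (!identical(image_dim(image), mask_dim(masks)))
    stop("image and masks have different dimensions")
  out <- image$pixels
  cols <- class_colors()
  for (cl in lesion_classes()) {
    b <- mask_boundary(masks$masks[[cl]])
    if (!any(b)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[b] <- cols[[cl]][ch]
      out[, , ch] <- plane
    }
  }
  if (!is.null(path)) {
    png::writePNG(out / 255, path)
    return(invisible(out))
  }
  out
}
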