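#' Lesion class labels
#'
#' The four lesion classes segmented by the package, in canonical order:
#' microaneurysm (`MA`), hemorrhage (`HE`), hard exudate and soft exudate.
#'
#' @return Character vector of the four class labels.
#' @export
lesion_classes <- function() c("MA", "HE", "hard_exudate", "soft_exudate")

#' Display colors for the lesion classes
#'
#' Fixed convention used by all overlays: MA red, HE green, hard exudate blue,
#' soft exudate yellow.
#'
#' @return Named list of RGB triplets on the 0-255 scale.
#' @export
class_colors <- function() {
  list(
    MA           = c(255, 0, 0),
    HE           = c(0, 255, 0),
    hard_exudate = c(0, 0, 255),
    soft_exudate = c(255, 255, 0)
  )
}

#' Construct a fundus image
#'
#' A fundus image is an H x W x 3 numeric array with intensities in
#' \[0, 255\], a source identifier, and an optional preprocessing record
#' describing the geometric normalization applied to it.
#'
#' @param pixels H x W x 3 numeric array, finite, values in \[0, 255\].
#'   A plain H x W matrix is replicated to 3 identical channels.
#' @param source_id Character scalar identifying the image.
#' @param record Optional preprocessing record (see [normalize_image()]).
#' @return An object of class `fundus_image` with fields `pixels`,
#'   `source_id` and `record`.
#' @export
fundus_image <- function(pixels, source_id = "image", record = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("image must have H >= 1 and W >= 1")
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, source_id = as.character(source_id), record = record),
    class = "fundus_image"
  )
}

#' @exportS3Method base::print
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<fundus_image '%s' %dx%d%s>\n", x$source_id, d[1], d[2],
    if (is.null(x$record)) "" else " (normalized)"
  ))
  invisible(x)
}

image_dim <- function(image) dim(image$pixels)[1:2]

#' Construct a lesion mask set
#'
#' Binds one binary mask per lesion class to an image. Classes absent from
#' `masks` are filled with all-zero masks; any nonzero value counts as lesion
#' and is binarized to 1 (annotation tools vary between 1 and 255).
#'
#' @param masks Named list of H x W matrices keyed by [lesion_classes()];
#'   may be incomplete or empty.
#' @param source_id Character scalar naming the paired image.
#' @param dim Integer pair (H, W); required when `masks` is empty, otherwise
#'   inferred and checked against every supplied mask.
#' @return An object of class `lesion_mask_set` whose `masks` field holds the
#'   four aligned binary (0/1 integer) matrices.
#' @export
lesion_mask_set <- function(masks = list(), source_id = "image", dim = NULL) {
  cls <- lesion_classes()
  extra <- setdiff(names(masks), cls)
  if (length(extra)) stop("unknown lesion class: ", paste(extra, collapse = ", "))
  if (is.null(dim)) {
    if (!length(masks)) stop("dim required when no masks are supplied")
    dim <- base::dim(masks[[1]])
  }
  dim <- as.integer(dim[1:2])
  out <- vector("list", length(cls))
  names(out) <- cls
  for (cl in cls) {
    m <- masks[[cl]]
    if (is.null(m)) {
      out[[cl]] <- matrix(0L, dim[1], dim[2])
    } else {
      if (!is.matrix(m)) m <- as.matrix(m)
      if (!identical(base::dim(m), dim))
        stop(sprintf("mask '%s' is %dx%d but expected %dx%d",
                     cl, nrow(m), ncol(m), dim[1], dim[2]))
      out[[cl]] <- binarize_mask(m)
    }
  }
  structure(
    list(masks = out, source_id = as.character(source_id)),
    class = "lesion_mask_set"
  )
}

#' @exportS3Method base::print
print.lesion_mask_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  px <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<lesion_mask_set '%s' %dx%d; lesion px: %s>\n",
              x$source_id, d[1], d[2],
              paste(names(px), px, sep = "=", collapse = " ")))
  invisible(x)
}

#' Binarize a mask
#'
#' Any strictly positive value becomes 1; the operation is idempotent.
#'
#' @param m Numeric matrix.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_mask <- function(m) {
  out <- matrix(as.integer(m > 0), nrow(m), ncol(m))
  out
}

mask_dim <- function(masks) dim(masks$masks[[1]])

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
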