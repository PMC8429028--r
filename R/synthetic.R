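## Seeded generator of fundus-like images with exact per-class ground-truth
## masks: a circular bright field of view on a black frame (so the
## border-cropping pipeline has work to do), a reddish-orange background with
## smooth shading, dark curvilinear vessel-like distractors, and the four
## lesion classes with their characteristic morphology. Per-class target
## area fractions default to the IDRiD averages (fraction of the total image
## area): MA 0.10%, HE 1.03%, hard exudate 0.90%, soft exudate 0.38%.

#' Synthetic fundus image configuration
#'
#' @param image_size Integer pair (H, W); default 256 x 256.
#' @param fov_radius_fraction Field-of-view radius as a fraction of the
#'   shorter side (default 0.48).
#' @param lesions Per-class generation parameters: `radius` range in pixels,
#'   `irregularity` of the blob outline, `max_count`, and `area_fraction`,
#'   the target lesion area as a fraction of total image area. Defaults:
#'   MA r 2-5 regular, HE r 5-20 irregular, hard exudate r 4-15 sharp,
#'   soft exudate r 10-25 fuzzy; IDRiD-average area fractions.
#' @param n_vessels Range of vessel-like distractor strokes (default 3-6).
#' @param noise_sd Gaussian pixel noise inside the field of view (default 3).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = c(256, 256),
                             fov_radius_fraction = 0.48,
                             lesions = NULL,
                             n_vessels = c(3, 6),
                             noise_sd = 3,
                             seed = 1) {
  defaults <- list(
    MA           = list(radius = c(2, 5),  irregularity = 0.08,
                        max_count = 20L, area_fraction = 0.0010),
    HE           = list(radius = c(5, 20), irregularity = 0.35,
                        max_count = 15L, area_fraction = 0.0103),
    hard_exudate = list(radius = c(4, 15), irregularity = 0.25,
                        max_count = 20L, area_fraction = 0.0090),
    soft_exudate = list(radius = c(10, 25), irregularity = 0.30,
                        max_count = 8L, area_fraction = 0.0038)
  )
  if (!is.null(lesions))
    for (cl in names(lesions)) {
      if (!cl %in% lesion_classes()) stop("unknown lesion class: ", cl)
      defaults[[cl]] <- utils::modifyList(defaults[[cl]], lesions[[cl]])
    }
  image_size <- as.integer(image_size)
  if (any(image_size < 32)) stop("image_size must be at least 32 pixels")
  for (cl in lesion_classes()) {
    les <- defaults[[cl]]
    min_area <- pi * les$radius[1]^2
    if (les$max_count * pi * les$radius[2]^2 * 1.5 <
        les$area_fraction * prod(image_size) && min_area > 0)
      stop(sprintf("area_fraction for %s is infeasible at max_count %d",
                   cl, les$max_count))
  }
  structure(list(image_size = image_size,
                 fov_radius_fraction = fov_radius_fraction,
                 lesions = defaults, n_vessels = as.integer(n_vessels),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

## Linear pixel indices of an irregular blob: a circle of radius r0 whose
## boundary radius is modulated by a few random Fourier harmonics.
blob_indices <- function(h, w, center, r0, irregularity) {
  rmax <- r0 * (1 + irregularity) + 1
  rs <- max(1, floor(center[1] - rmax)):min(h, ceiling(center[1] + rmax))
  cs <- max(1, floor(center[2] - rmax)):min(w, ceiling(center[2] + rmax))
  dr <- outer(rs - center[1], rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - center[2])
  dist <- sqrt(dr^2 + dc^2)
  if (irregularity > 0) {
    K <- 4
    amp <- stats::runif(K, 0, irregularity / K)
    phase <- stats::runif(K, 0, 2 * pi)
    theta <- atan2(dc, dr)
    mod <- 1 + Reduce(`+`, lapply(1:K, function(k)
      amp[k] * cos(k * theta + phase[k])))
  } else mod <- 1
  inside <- dist <= r0 * mod
  idx <- which(inside)
  (cs[((idx - 1) %/% length(rs)) + 1] - 1) * h + rs[((idx - 1) %% length(rs)) + 1]
}

## Random vessel-like stroke: a smooth random walk from near the disc center
## outward, thickness 1-2 px. Returns linear indices.
vessel_indices <- function(h, w, fov_center, fov_radius) {
  pos <- fov_center + stats::runif(2, -0.2, 0.2) * fov_radius
  ang <- stats::runif(1, 0, 2 * pi)
  idx <- integer(0)
  thick <- sample(1:2, 1)
  n_steps <- round(1.2 * fov_radius)
  for (s in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, 0.15)
    pos <- pos + c(cos(ang), sin(ang))
    if (sqrt(sum((pos - fov_center)^2)) > 0.95 * fov_radius) break
    r <- round(pos[1]); c_ <- round(pos[2])
    rr <- max(1, r - thick + 1):min(h, r + thick - 1)
    cc <- max(1, c_ - thick + 1):min(w, c_ + thick - 1)
    idx <- c(idx, as.vector(outer(rr, (cc - 1) * h, `+`)))
  }
  unique(idx)
}

lesion_tints <- list(
  MA           = c(105, 28, 22),
  HE           = c(125, 38, 28),
  hard_exudate = c(244, 222, 96),
  soft_exudate = c(232, 218, 182)
)

#' Generate one synthetic fundus image with ground-truth masks
#'
#' Renders the circular field of view, background shading, vessel
#' distractors, then places lesions class by class with rejection sampling
#' (no inter-lesion overlap, 2 px margin, fully inside the field of view)
#' until the class target area fraction is reached or the count cap hits.
#' Soft exudates are feathered with a Gaussian blur in the *image* only;
#' all masks record the exact pre-blur lesion support.
#'
#' @param config A [synthetic_config()].
#' @return List with `image` ([fundus_image()]), `masks`
#'   ([lesion_mask_set()]), and `counts`, the true per-class lesion counts.
#' @export
generate_image <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_image_impl(config))
}

generate_image_impl <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  fov_r <- config$fov_radius_fraction * min(h, w)
  ctr <- c((h + 1) / 2, (w + 1) / 2) + stats::runif(2, -2, 2)
  rr <- matrix(1:h, h, w)
  cc <- matrix(1:w, h, w, byrow = TRUE)
  dist <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  fov <- dist <= fov_r

  ## background: reddish-orange disc with smooth radial + random shading
  shade <- 1 - 0.25 * (dist / fov_r)^2
  bump <- matrix(stats::rnorm(64), 8, 8)
  bump <- resize_raster(bump, h, w, "bilinear")
  shade <- shade * (1 + 0.06 * bump)
  base <- c(185, 92, 40)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch][fov] <- base[ch] * shade[fov]

  ## vessels
  vessel_col <- c(110, 32, 24)
  nv <- sample(config$n_vessels[1]:config$n_vessels[2], 1)
  for (v in seq_len(nv)) {
    vi <- vessel_indices(h, w, ctr, fov_r)
    vi <- vi[fov[vi]]
    for (ch in 1:3) { pl <- img[, , ch]; pl[vi] <- vessel_col[ch]; img[, , ch] <- pl }
  }

  ## lesions
  occupied <- matrix(FALSE, h, w)
  masks <- list()
  counts <- integer(0)
  soft_alpha <- matrix(0, h, w)
  for (cl in lesion_classes()) {
    les <- config$lesions[[cl]]
    target <- les$area_fraction * h * w
    mask <- matrix(0L, h, w)
    count <- 0L
    placed_area <- 0
    tries <- 0L
    while (placed_area < target && count < les$max_count && tries < 200L) {
      tries <- tries + 1L
      rem <- target - placed_area
      rmax <- min(les$radius[2], sqrt(1.3 * rem / pi))
      if (rmax < les$radius[1]) {
        if (count > 0L) break
        rmax <- les$radius[1]
      }
      r0 <- stats::runif(1, les$radius[1], max(les$radius[1], rmax))
      margin <- r0 * (1 + les$irregularity) + 2
      if (margin >= fov_r) break
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (fov_r - margin)
      center <- ctr + rad * c(cos(ang), sin(ang))
      idx <- blob_indices(h, w, center, r0, les$irregularity)
      if (!length(idx) || any(occupied[idx])) next
      grown <- unique(c(idx, idx + 1L, idx - 1L, idx + h, idx - h))
      grown <- grown[grown >= 1 & grown <= h * w]
      occupied[grown] <- TRUE
      mask[idx] <- 1L
      placed_area <- placed_area + length(idx)
      count <- count + 1L
      tint <- lesion_tints[[cl]] * stats::runif(1, 0.92, 1.08)
      if (cl == "soft_exudate") {
        soft_alpha[idx] <- 1
      } else {
        for (ch in 1:3) { pl <- img[, , ch]; pl[idx] <- tint[ch]; img[, , ch] <- pl }
      }
    }
    masks[[cl]] <- mask
    counts[cl] <- count
  }

  ## feather soft exudates in the image only (masks keep the crisp support)
  if (any(soft_alpha > 0)) {
    alpha <- as.matrix(EBImage::gblur(soft_alpha, sigma = 2))
    alpha <- pmin(pmax(alpha, 0), 1)
    tint <- lesion_tints$soft_exudate
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) + tint[ch] * alpha
  }

  noise <- matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[fov] <- pl[fov] + noise[fov]
    img[, , ch] <- pmin(pmax(pl, 0), 255)
  }
  ## keep the frame outside the field of view strictly black
  for (ch in 1:3) { pl <- img[, , ch]; pl[!fov] <- 0; img[, , ch] <- pl }

  sid <- sprintf("synth%06d", config$seed)
  list(image = fundus_image(img, source_id = sid),
       masks = lesion_mask_set(masks, source_id = sid),
       counts = counts)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` images (PNG) with their per-class mask files in the
#' layout of [read_mask_set()], plus a JSON manifest recording per-image
#' lesion counts and area fractions. Image i uses seed `config$seed + i`,
#' so the tree is reproducible bit for bit.
#'
#' @param config A [synthetic_config()].
#' @param n_images Number of images.
#' @param out_dir Output directory (created if needed); images go to
#'   `images/`, masks to `masks/`.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(config, n_images, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  img_dir <- file.path(out_dir, "images")
  mask_dir <- file.path(out_dir, "masks")
  for (d in c(img_dir, mask_dir))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  manifest <- list(image_size = config$image_size, images = list())
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    gen <- generate_image(cfg_i)
    write_image(gen$image, file.path(img_dir, paste0(gen$image$source_id, ".png")))
    write_mask_set(gen$masks, mask_dir)
    areas <- vapply(gen$masks$masks, function(m)
      sum(m) / prod(config$image_size), numeric(1))
    manifest$images[[gen$image$source_id]] <-
      list(counts = as.list(gen$counts), area_fractions = as.list(areas))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
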