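# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: components by BFS flood fill, matching by a
# literal transcription of the set rules, curves by direct enumeration.

# BFS flood-fill connected components; returns list of linear index vectors
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  comps <- list()
  for (start in which(mask > 0)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      r <- ((cur - 1) %% h) + 1
      cc <- ((cur - 1) %/% h) + 1
      for (o in offs) {
        rr <- r + o[1]; c2 <- cc + o[2]
        if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
        li <- (c2 - 1) * h + rr
        if (mask[li] > 0 && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Literal per-pixel application of the component-matching set rules
oracle_classify <- function(detected, truth, sigma, connectivity = 8) {
  h <- nrow(detected); w <- ncol(detected)
  Dc <- flood_fill_components(detected, connectivity)
  Gc <- flood_fill_components(truth, connectivity)
  Dset <- which(detected > 0); Gset <- which(truth > 0)
  tp <- fp <- fn <- logical(h * w)
  tp[intersect(Dset, Gset)] <- TRUE
  for (Di in Dc)
    if (length(intersect(Di, Gset)) / length(Di) > sigma) tp[Di] <- TRUE
  for (Gj in Gc)
    if (length(intersect(Gj, Dset)) / length(Gj) > sigma) tp[Gj] <- TRUE
  for (Di in Dc) {
    ov <- intersect(Di, Gset)
    if (!length(ov)) fp[Di] <- TRUE
    else if (length(ov) / length(Di) <= sigma) fp[setdiff(Di, Gset)] <- TRUE
  }
  for (Gj in Gc) {
    ov <- intersect(Gj, Dset)
    if (!length(ov)) fn[Gj] <- TRUE
    else if (length(ov) / length(Gj) <= sigma) fn[setdiff(Gj, Dset)] <- TRUE
  }
  fp <- fp & !tp
  fn <- fn & !tp
  c(TP = sum(tp), FP = sum(fp), FN = sum(fn),
    TN = h * w - sum(tp) - sum(fp) - sum(fn))
}

# random blobby binary mask: a few rectangles/discs on an empty grid
random_mask <- function(h, w, n_blobs = 3) {
  m <- matrix(0L, h, w)
  for (i in seq_len(n_blobs)) {
    if (stats::runif(1) < 0.5) {
      r <- sample(h, 1); cc <- sample(w, 1)
      rad <- sample(1:4, 1)
      rows <- max(1, r - rad):min(h, r + rad)
      cols <- max(1, cc - rad):min(w, cc + rad)
      m[rows, cols] <- 1L
    } else {
      r <- sample(h, 1); cc <- sample(w, 1)
      rad <- sample(2:5, 1)
      for (rr in max(1, r - rad):min(h, r + rad))
        for (c2 in max(1, cc - rad):min(w, cc + rad))
          if ((rr - r)^2 + (c2 - cc)^2 <= rad^2) m[rr, c2] <- 1L
    }
  }
  m
}

# small structured test image: dark frame, bright rectangle of content
frame_image <- function(h, w, r0, r1, c0, c1, value = 200) {
  px <- array(0, c(h, w, 3))
  px[r0:r1, c0:c1, ] <- value
  fundus_image(px, source_id = "frame")
}

tiny_model_config <- function(input_size = 16, base_channels = 4,
                              num_classes = 2) {
  model_config(input_size = input_size, num_classes = num_classes,
               base_channels = base_channels, encoder_stages = 2,
               attention_stages = 2, dropout_rate = 0)
}
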