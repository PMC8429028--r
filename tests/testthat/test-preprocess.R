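test_that("content box matches an exhaustive scan and degenerates gracefully", {
  ## content only in columns 50-149 of a 100x200 frame (1-based 51:150)
  img <- frame_image(100, 200, 1, 100, 51, 150)
  expect_equal(find_content_box(img), c(0L, 100L, 50L, 150L))

  ## exhaustive per-pixel oracle on a random sprinkle
  set.seed(21)
  px <- array(0, c(40, 30, 3))
  on <- cbind(sample(5:35, 6), sample(4:27, 6))
  for (i in seq_len(nrow(on))) px[on[i, 1], on[i, 2], ] <- 150
  box <- find_content_box(fundus_image(px))
  bright <- which(apply(px, c(1, 2), max) > 10, arr.ind = TRUE)
  expect_equal(box, c(min(bright[, 1]) - 1L, max(bright[, 1]),
                      min(bright[, 2]) - 1L, max(bright[, 2])))

  ## all-black and borderless images give the full frame
  black <- fundus_image(array(0, c(8, 12, 3)))
  expect_equal(find_content_box(black), c(0L, 8L, 0L, 12L))
  full <- fundus_image(array(200, c(8, 12, 3)))
  expect_equal(find_content_box(full), c(0L, 8L, 0L, 12L))
})

test_that("normalization emits the target square and preserves aspect", {
  img <- frame_image(100, 200, 1, 100, 51, 150)  # square content, wide frame
  he <- matrix(0L, 100, 200); he[40:60, 90:110] <- 1L
  masks <- lesion_mask_set(list(HE = he), source_id = "frame")
  nm <- normalize_image(img, masks, target_size = 256)
  expect_identical(dim(nm$image$pixels), c(256L, 256L, 3L))
  expect_identical(dim(nm$masks$masks$HE), c(256L, 256L))
  ## content was a 100x100 square: no padding required
  expect_equal(unname(nm$record$pad), c(0L, 0L, 0L, 0L))
  expect_equal(nm$record$crop_box, c(0L, 100L, 50L, 150L))

  ## rectangular content: padding makes it square, content aspect kept
  img2 <- frame_image(120, 80, 21, 80, 11, 50)   # content 60 rows x 40 cols
  nm2 <- normalize_image(img2, target_size = 240)
  expect_identical(dim(nm2$image$pixels), c(240L, 240L, 3L))
  box <- find_content_box(nm2$image)
  ## 60x40 content scaled by 240/60 = 4; aspect distortion at most 1 px
  ## when measured back at the pre-resize scale
  sf <- nm2$record$scale_factor
  expect_lte(abs((box[2] - box[1]) / sf - 60), 1)
  expect_lte(abs((box[4] - box[3]) / sf - 40), 1)
})

test_that("normalization is idempotent and keeps image/mask alignment", {
  set.seed(4)
  gen <- generate_image(synthetic_config(image_size = c(96, 128), seed = 17))
  nm <- normalize_image(gen$image, gen$masks, target_size = 128)
  nm2 <- normalize_image(nm$image, nm$masks, target_size = 128)
  expect_lt(mean(abs(nm2$image$pixels - nm$image$pixels)), 2)
  for (cl in lesion_classes()) {
    a <- nm$masks$masks[[cl]]; b <- nm2$masks$masks[[cl]]
    if (sum(a) + sum(b) > 0)
      expect_gt(sum(a & b) / max(sum(a | b), 1), 0.9)
  }

  ## a marked pixel lands at the same place in image and mask
  px <- array(0, c(50, 70, 3))
  px[10:40, 20:60, ] <- 120
  px[25, 33, ] <- 255                       # marker in the image
  mk <- matrix(0L, 50, 70); mk[25, 33] <- 1L
  nmk <- normalize_image(fundus_image(px), lesion_mask_set(list(MA = mk)),
                         target_size = 128)
  bright <- which(nmk$image$pixels[, , 1] == max(nmk$image$pixels[, , 1]),
                  arr.ind = TRUE)
  marked <- which(nmk$masks$masks$MA == 1L, arr.ind = TRUE)
  expect_true(nrow(marked) >= 1)
  d <- min(sqrt((bright[, 1] - mean(marked[, 1]))^2 +
                (bright[, 2] - mean(marked[, 2]))^2))
  expect_lte(d, 1.5)
})

test_that("training resolution resize preserves blob centroids", {
  m <- matrix(0L, 256, 256); m[97:160, 113:176] <- 1L
  img <- fundus_image(array(100, c(256, 256, 3)), record = list(target_size = 256L))
  tr <- to_train_resolution(img, lesion_mask_set(list(HE = m)), train_size = 128)
  expect_identical(dim(tr$image$pixels), c(128L, 128L, 3L))
  cen0 <- colMeans(which(m == 1L, arr.ind = TRUE)) / 2
  cen1 <- colMeans(which(tr$masks$masks$HE == 1L, arr.ind = TRUE))
  expect_lt(max(abs(cen0 - cen1)), 1)
  ## identity when already at size
  same <- to_train_resolution(tr$image, tr$masks, train_size = 128)
  expect_equal(same$image$pixels, tr$image$pixels)
})

test_that("invert_record restores original geometry", {
  gen <- generate_image(synthetic_config(image_size = c(80, 120), seed = 9))
  nm <- normalize_image(gen$image, gen$masks, target_size = 128)

  ## all-zero mask comes back all-zero at the original size
  z <- invert_record(nm$record, matrix(0L, 128, 128))
  expect_identical(dim(z), c(80L, 120L))
  expect_equal(sum(z), 0)

  ## round trip of real masks: high IoU for lesions of a few px radius
  for (cl in c("HE", "hard_exudate", "soft_exudate")) {
    orig <- gen$masks$masks[[cl]]
    if (sum(orig) < 50) next
    back <- invert_record(nm$record, nm$masks$masks[[cl]])
    iou <- sum(back & orig) / sum(back | orig)
    expect_gte(iou, 0.8)
  }
  expect_error(invert_record(nm$record, matrix(0L, 37, 37)), "37x37")
})
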