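test_that("connected components match flood-fill and connectivity semantics", {
  ## empty mask
  expect_equal(extract_components(matrix(0L, 5, 5))$n, 0L)

  ## diagonal pair: one component under 8-connectivity, two under 4
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(extract_components(d, 8)$n, 1L)
  expect_equal(extract_components(d, 4)$n, 2L)

  ## random masks against the BFS oracle, both connectivities
  set.seed(11)
  for (rep in 1:20) {
    m <- random_mask(32, 32, sample(1:5, 1))
    for (conn in c(4, 8)) {
      cs <- extract_components(m, conn)
      oracle <- flood_fill_components(m, conn)
      expect_equal(cs$n, length(oracle))
      expect_setequal(lapply(cs$components, sort), oracle)
    }
  }
})

test_that("lesion counting follows component structure", {
  empty <- lesion_mask_set(dim = c(20, 20))
  expect_equal(unname(count_lesions(empty)), c(0L, 0L, 0L, 0L))

  m5 <- matrix(0L, 40, 40)
  centers <- cbind(c(5, 5, 20, 33, 33), c(5, 30, 18, 8, 30))
  for (i in 1:5) m5[centers[i, 1] + 0:2, centers[i, 2] + 0:2] <- 1L
  ms <- lesion_mask_set(list(MA = m5))
  expect_equal(count_lesions(ms)[["MA"]], 5L)

  ## merging two blobs by a bridge pixel reduces the count by one
  m5[7, 5:30] <- 1L   # connect blob 1 and blob 2
  expect_equal(count_lesions(lesion_mask_set(list(MA = m5)))[["MA"]], 4L)
})

test_that("matching follows the literal set rules on the worked example", {
  det <- matrix(0L, 12, 12); det[1:2, 1:2] <- 1L   # 2x2 detection
  tru <- matrix(0L, 12, 12); tru[2:4, 2:4] <- 1L   # 3x3 truth, 1 px overlap
  res <- classify_pixels(det, tru, match_config(sigma = 0.2))
  ## ratio_D = 1/4 > 0.2 credits the detection; ratio_G = 1/9 <= 0.2 leaves
  ## the remaining truth pixels as misses
  expect_equal(unname(res$counts), c(4L, 0L, 8L, 132L))
  expect_equal(res$counts, oracle_classify(det, tru, 0.2))
  m <- compute_metrics(res$counts)
  expect_equal(m$sensitivity, 1 / 3)
  expect_equal(m$precision, 1)
  expect_equal(m$f1, 0.5)

  ## perfect match
  p <- matrix(0L, 8, 8); p[3:5, 3:5] <- 1L
  rp <- classify_pixels(p, p, match_config(0.2))
  expect_equal(unname(rp$counts), c(9L, 0L, 0L, 55L))
  mp <- compute_metrics(rp$counts)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$precision,
                 mp$accuracy, mp$f1), rep(1, 5))
})

test_that("sigma = 0 reduces to touch-matching", {
  ## large detection touching a small truth by one pixel: full credit
  det <- matrix(0L, 20, 20); det[5:14, 5:14] <- 1L
  tru <- matrix(0L, 20, 20); tru[14:16, 14:16] <- 1L
  res <- classify_pixels(det, tru, match_config(sigma = 0))
  expect_equal(res$counts[["FP"]], 0L)
  expect_equal(res$counts[["FN"]], 0L)
  expect_equal(res$counts[["TP"]], sum(det | tru))
  ## a detached detection stays FP even at sigma 0
  det2 <- det; det2[1:2, 18:19] <- 1L
  res2 <- classify_pixels(det2, tru, match_config(sigma = 0))
  expect_equal(res2$counts[["FP"]], 4L)
})

test_that("matching equals the brute-force oracle on random pairs", {
  set.seed(99)
  for (rep in 1:40) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    det <- random_mask(h, w, sample(0:4, 1))
    tru <- random_mask(h, w, sample(0:4, 1))
    sg <- sample(c(0, 0.2, 0.5, 1), 1)
    res <- classify_pixels(det, tru, match_config(sigma = sg))
    expect_equal(res$counts, oracle_classify(det, tru, sg))
    ## conservation
    expect_equal(sum(res$counts), h * w)
  }
})

test_that("TP is monotonically non-increasing in sigma", {
  set.seed(7)
  for (rep in 1:10) {
    det <- random_mask(24, 24, 3); tru <- random_mask(24, 24, 3)
    tps <- vapply(c(0, 0.1, 0.2, 0.5, 0.8, 1), function(sg)
      classify_pixels(det, tru, match_config(sg))$counts[["TP"]], numeric(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("metrics handle degenerate confusion counts", {
  m <- compute_metrics(c(TP = 4, FP = 0, FN = 8, TN = 132))
  expect_equal(m$sensitivity, 1 / 3)
  expect_equal(m$f1, 0.5)
  z <- compute_metrics(c(TP = 0, FP = 0, FN = 5, TN = 95))
  expect_equal(z$sensitivity, 0)
  allneg <- compute_metrics(c(TP = 0, FP = 0, FN = 0, TN = 100))
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$accuracy, 1)
  expect_true("sensitivity" %in% allneg$undefined)
})

test_that("label raster export uses the red/blue/purple palette", {
  det <- matrix(0L, 12, 12); det[1:2, 1:2] <- 1L
  tru <- matrix(0L, 12, 12); tru[2:4, 2:4] <- 1L
  res <- classify_pixels(det, tru, match_config(sigma = 0.2))
  f <- withr::local_tempfile(fileext = ".png")
  write_label_raster(res, f)
  img <- png::readPNG(f) * 255
  expect_equal(img[1, 1, ], c(160, 32, 240))   # TP purple
  expect_equal(img[4, 4, ], c(255, 0, 0))      # FN red
  expect_equal(img[12, 12, ], c(0, 0, 0))      # TN black
})

test_that("ROC behaves at the extremes and matches pROC", {
  set.seed(13)
  truth <- rbinom(4000, 1, 0.2)
  ## perfect separation
  expect_equal(roc_curve(truth + 0, truth)$auc, 1)
  ## score reversal flips the area
  sc <- runif(4000) + truth * 0.4
  r1 <- roc_curve(sc, truth)
  r2 <- roc_curve(-sc, truth)
  expect_equal(r1$auc + r2$auc, 1, tolerance = 1e-10)
  ## agreement with an established implementation
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, sc, quiet = TRUE)))
  expect_equal(r1$auc, as.numeric(ref), tolerance = 1e-8)
  expect_error(roc_curve(sc, rep(1, 4000)), "constant")
})

test_that("PR curve is exact for perfect scores and near prevalence for noise", {
  set.seed(14)
  truth <- rbinom(20000, 1, 0.15)
  expect_equal(pr_curve(truth + 0, truth)$aupr, 1)
  noise <- runif(20000)
  expect_equal(pr_curve(noise, truth)$aupr, 0.15, tolerance = 0.02)
  ## constant scores collapse to a single point; area still defined
  cst <- pr_curve(rep(0, 20000), truth)
  expect_true(is.finite(cst$aupr))
  expect_error(pr_curve(noise, rep(0, 20000)), "positives")
})
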