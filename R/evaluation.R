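## Component-matching evaluation: pixels are credited as TP/FP/FN/TN from the
## overlap between whole connected components of the detection and of the
## ground truth, governed by a minimal overlap fraction sigma.

#' Matching configuration for the overlap metric
#'
#' @param sigma Minimal overlap fraction in \[0, 1\] a whole component needs
#'   (strictly) to be credited as true positive; default 0.2. At
#'   `sigma = 0` any detected component touching the truth is fully
#'   credited.
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @return A `match_config` list.
#' @export
match_config <- function(sigma = 0.2, connectivity = 8) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0 || sigma > 1)
    stop("sigma must be a single number in [0, 1]")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(sigma = sigma, connectivity = as.integer(connectivity)),
            class = "match_config")
}

#' Label the connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity. Adjacency is
#' resolved with `igraph::components` over the pixel-adjacency graph.
#'
#' @param mask Binary matrix (any nonzero value is foreground).
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `component_set`: `labels` (integer matrix, 0 =
#'   background, components numbered from 1), `components` (list of linear
#'   pixel index vectors), `n` (component count) and `shape`.
#' @export
extract_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  labels <- matrix(0L, h, w)
  if (!length(fg)) {
    return(structure(list(labels = labels, components = list(), n = 0L,
                          shape = c(h, w)), class = "component_set"))
  }
  ## map linear index -> vertex id (1..nfg)
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c_ <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    rr <- r + o[1]; cc <- c_ + o[2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    if (!any(ok)) next
    nb <- (cc[ok] - 1L) * h + rr[ok]
    hit <- vid[nb] > 0L
    if (!any(hit)) next
    edges <- c(edges, rbind(vid[fg[ok][hit]], vid[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  comps <- split(fg, memb)
  names(comps) <- NULL
  structure(list(labels = labels, components = comps,
                 n = length(comps), shape = c(h, w)),
            class = "component_set")
}

#' @exportS3Method base::print
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set %dx%d, %d components>\n",
              x$shape[1], x$shape[2], x$n))
  invisible(x)
}

as_component_set <- function(x, connectivity) {
  if (inherits(x, "component_set")) x else extract_components(x, connectivity)
}

#' Classify pixels by component-overlap matching
#'
#' Given detected components `D_1..D_N` (union `D`) and ground-truth
#' components `G_1..G_M` (union `G`), a pixel is TP iff it lies in `D ∩ G`,
#' in some `D_i` with `|D_i ∩ G| / |D_i| > sigma`, or in some `G_j` with
#' `|G_j ∩ D| / |G_j| > sigma`. A pixel is FP iff it lies in a `D_i` that
#' misses `G` entirely, or in `D_i \ G` when that component's overlap ratio
#' is `<= sigma`; FN symmetrically on the truth side; all remaining pixels
#' are TN. TP takes priority when a pixel satisfies rules of several
#' categories. The inequalities are strict, so at `sigma = 0` a detected
#' component touching the truth anywhere is credited in full.
#'
#' @param detected Binary matrix or [extract_components()] result.
#' @param truth Binary matrix or [extract_components()] result.
#' @param config A [match_config()].
#' @return List with `counts` (named integer vector TP/FP/FN/TN), `labels`
#'   (integer matrix: 0 TN, 1 TP, 2 FP, 3 FN), `sigma` and `connectivity`.
#' @export
classify_pixels <- function(detected, truth, config = match_config()) {
  D <- as_component_set(detected, config$connectivity)
  G <- as_component_set(truth, config$connectivity)
  if (!identical(D$shape, G$shape))
    stop(sprintf("shape mismatch: detected %dx%d vs truth %dx%d",
                 D$shape[1], D$shape[2], G$shape[1], G$shape[2]))
  sigma <- config$sigma
  h <- D$shape[1]; w <- D$shape[2]
  labD <- D$labels; labG <- G$labels
  inD <- labD > 0L; inG <- labG > 0L

  ovD <- tabulate(labD[inD & inG], nbins = D$n)      # |D_i ∩ G|
  szD <- tabulate(labD[inD], nbins = D$n)            # |D_i|
  ovG <- tabulate(labG[inD & inG], nbins = G$n)      # |G_j ∩ D|
  szG <- tabulate(labG[inG], nbins = G$n)            # |G_j|

  tpD <- which(ovD / pmax(szD, 1L) > sigma)          # fully-credited D_i
  tpG <- which(ovG / pmax(szG, 1L) > sigma)          # fully-credited G_j

  tp <- (inD & inG) |
    (inD & matrix(labD %in% tpD, h, w)) |
    (inG & matrix(labG %in% tpG, h, w))
  fp <- inD & !tp
  fn <- inG & !tp
  labels <- matrix(0L, h, w)
  labels[tp] <- 1L; labels[fp] <- 2L; labels[fn] <- 3L
  counts <- c(TP = sum(tp), FP = sum(fp), FN = sum(fn),
              TN = h * w - sum(tp) - sum(fp) - sum(fn))
  list(counts = counts, labels = labels,
       sigma = sigma, connectivity = config$connectivity)
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total` and `F1 = 2*SE*PR/(SE+PR)`. A
#' zero denominator yields 0 and the affected metric is listed in the
#' `undefined` field.
#'
#' @param counts Named vector with elements TP, FP, FN, TN (e.g. from
#'   [classify_pixels()]), or the list returned by [classify_pixels()].
#' @return A `metrics_report` list with the five metrics and `undefined`.
#' @export
compute_metrics <- function(counts) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  se <- ratio(tp, tp + fn, "sensitivity")
  sp <- ratio(tn, tn + fp, "specificity")
  pr <- ratio(tp, tp + fp, "precision")
  acc <- ratio(tp + tn, tp + fp + fn + tn, "accuracy")
  f1 <- if (se + pr > 0) 2 * se * pr / (se + pr) else {
    undefined <- c(undefined, "f1"); 0
  }
  structure(list(sensitivity = se, specificity = sp, precision = pr,
                 accuracy = acc, f1 = f1, undefined = undefined),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("SE %.4f  SP %.4f  PR %.4f  ACC %.4f  F1 %.4f\n",
              x$sensitivity, x$specificity, x$precision, x$accuracy, x$f1))
  if (length(x$undefined))
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Export a TP/FP/FN/TN label raster as a colored PNG
#'
#' Renders the per-pixel classification of [classify_pixels()] in the
#' conventional palette: missed truth (FN) red, spurious detection (FP)
#' blue, agreement (TP) purple, background (TN) black.
#'
#' @param labels Integer matrix from [classify_pixels()] (0 TN, 1 TP,
#'   2 FP, 3 FN), or the full result list.
#' @param path PNG output path.
#' @return The path, invisibly.
#' @export
write_label_raster <- function(labels, path) {
  if (is.list(labels)) labels <- labels$labels
  pal <- rbind(c(0, 0, 0), c(160, 32, 240), c(0, 0, 255), c(255, 0, 0))
  out <- array(0, c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[labels + 1L, ch],
                                        nrow(labels), ncol(labels))
  png::writePNG(out / 255, path)
  invisible(path)
}

sweep_curve <- function(scores, truth) {
  truth <- as.integer(truth > 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  ctp <- cumsum(t); cfp <- cumsum(1 - t)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each threshold
  list(tp = ctp[keep], fp = cfp[keep], P = sum(truth), N = sum(1 - truth))
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Pixel-level ROC curve and AUC
#'
#' Sweeps a descending threshold over the pixel probabilities; the area
#' under the curve is computed by the trapezoid rule.
#'
#' @param probs Numeric array/vector of per-pixel scores.
#' @param truth Binary array/vector of the same length.
#' @return List with `fpr`, `tpr` (including the (0,0) and (1,1) anchors)
#'   and `auc`.
#' @export
roc_curve <- function(probs, truth) {
  probs <- as.numeric(probs); truth <- as.integer(as.numeric(truth) > 0)
  if (length(probs) != length(truth)) stop("probs and truth differ in length")
  if (all(truth == 1L) || all(truth == 0L))
    stop("ROC curve is undefined for constant truth")
  cv <- sweep_curve(probs, truth)
  tpr <- c(0, cv$tp / cv$P, 1)
  fpr <- c(0, cv$fp / cv$N, 1)
  list(fpr = fpr, tpr = tpr, auc = trapz(fpr, tpr))
}

#' Pixel-level precision-recall curve and AUPR
#'
#' Analogous to [roc_curve()] with precision/recall axes; the curve is
#' anchored at recall 0 with the precision of the smallest detected set
#' (precision is taken as 1 there when no pixel is scored highest), and the
#' area is computed by the trapezoid rule.
#'
#' @inheritParams roc_curve
#' @return List with `recall`, `precision` and `aupr`.
#' @export
pr_curve <- function(probs, truth) {
  probs <- as.numeric(probs); truth <- as.integer(as.numeric(truth) > 0)
  if (length(probs) != length(truth)) stop("probs and truth differ in length")
  if (all(truth == 0L)) stop("PR curve is undefined without positives")
  cv <- sweep_curve(probs, truth)
  rec <- cv$tp / cv$P
  prec <- cv$tp / (cv$tp + cv$fp)
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  list(recall = rec, precision = prec, aupr = trapz(rec, prec))
}

#' Count lesions per class by connected components
#'
#' @param masks A [lesion_mask_set()] (typically predicted masks).
#' @param connectivity 4 or 8 (default 8).
#' @return Named integer vector of component counts, one per lesion class.
#' @export
count_lesions <- function(masks, connectivity = 8) {
  stopifnot(inherits(masks, "lesion_mask_set"))
  vapply(masks$masks,
         function(m) extract_components(m, connectivity)$n,
         integer(1))
}
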