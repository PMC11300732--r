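# Fixtures built in code and independent oracles used across test files.

# A solid square nucleus with a constant-color crop.
square_instance <- function(id, x, y, side, label = "a", category_id = 1L,
                            color = c(0.3, 0.2, 0.5)) {
  m <- matrix(TRUE, side, side)
  crop <- array(rep(color, each = side * side), dim = c(side, side, 3))
  nuclei_instance(id, label, category_id, bbox = c(x, y, side, side),
                  mask = m, crop = crop)
}

tiny_class_map <- function() class_map(c("a", "b", "c"), c(3L, 5L, 9L))

small_spec <- function(seed = 1L, probs = c(0.7, 0.2, 0.1),
                       n_nuclei = c(12L, 18L), size = 96L) {
  scene_spec(height = size, width = size,
             class_probabilities = probs, n_nuclei = n_nuclei,
             radius = c(3.5, 6), seed = seed)
}

# ---- independent oracles -------------------------------------------------

# AP by numeric integration of the interpolated precision envelope on a grid.
oracle_ap <- function(tp, n_gt, grid_n = 20000L) {
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  p_at <- function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }
  rs <- seq(1 / grid_n, 1, length.out = grid_n)
  mean(vapply(rs, p_at, numeric(1)))
}

# Maximum number of IoU-threshold matches by exhaustive assignment search.
oracle_max_matches <- function(det_boxes, gt_boxes, thr) {
  nd <- length(det_boxes); ng <- length(gt_boxes)
  if (nd == 0L || ng == 0L) return(0L)
  iou_ok <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    iou_ok[i, j] <- iou(det_boxes[[i]], gt_boxes[[j]]) >= thr
  best <- 0L
  recurse <- function(i, used) {
    if (i > nd) { best <<- max(best, sum(used)); return(invisible()) }
    recurse(i + 1L, used)                      # detection i unmatched
    for (j in which(iou_ok[i, ] & !used)) {
      used[j] <- TRUE; recurse(i + 1L, used); used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ng))
  best
}

# Straight-line per-pixel channel statistics in the log-opponent space.
oracle_opponent_stats <- function(image) {
  rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                      0.1967, 0.7244, 0.0782,
                      0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  h <- dim(image)[1]; w <- dim(image)[2]
  vals <- matrix(NA_real_, h * w, 3)
  k <- 1L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    lms <- log10(rgb2lms %*% image[i, j, ] * 255 + 1)
    vals[k, ] <- c((lms[1] + lms[2] + lms[3]) / sqrt(3),
                   (lms[1] + lms[2] - 2 * lms[3]) / sqrt(6),
                   (lms[1] - lms[2]) / sqrt(2))
    k <- k + 1L
  }
  list(mean = colMeans(vals), std = apply(vals, 2, sd))
}

# One-vs-rest balanced accuracy straight from the matrix cells.
oracle_balanced_accuracy <- function(cm) {
  total <- sum(cm)
  vapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    (sens + spec) / 2
  }, numeric(1))
}

# Pixel-set union of instance masks, assembled instance by instance.
oracle_mask_union <- function(instances, height, width) {
  u <- matrix(FALSE, height, width)
  for (inst in instances) u <- u | instance_full_mask(inst, height, width)
  u
}

expect_same_instances <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$instance_id, b[[i]]$instance_id)
    expect_identical(a[[i]]$class_label, b[[i]]$class_label)
    expect_identical(a[[i]]$bbox, b[[i]]$bbox)
    expect_identical(a[[i]]$mask, b[[i]]$mask)
  }
}
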