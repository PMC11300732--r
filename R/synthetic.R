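# Synthetic nuclei scenes with known ground truth.
#
# Emulates the statistical structure the augmentation method assumes: dense
# fields of non-overlapping, similarly sized elliptical nuclei on a pale
# eosin-like background, with a configurable (typically severe) class
# imbalance, encoded in the same 3-channel mask dialect as the real data.
# Shapes are ellipses with mild boundary waviness rather than realistic
# textures: the algorithms under test depend only on masks, classes, sizes
# and colors.

#' Specification of a synthetic nuclei scene
#'
#' @param height,width scene size in pixels.
#' @param class_labels character vector of class labels.
#' @param class_probabilities simplex vector (sums to 1), the per-nucleus
#'   class distribution — the imbalance control.
#' @param n_nuclei `c(min, max)` range of nuclei per scene.
#' @param radius `c(min, max)` semi-axis range in pixels; the default keeps
#'   the max/min ratio at 2 (the similar-size regime the nine-point occupancy
#'   test is designed for).
#' @param colors optional K x 3 matrix of per-class RGB fill colors in
#'   `[0, 1]`; defaults to a hematoxylin-like palette.
#' @param background length-3 RGB background color (eosin-like pale pink).
#' @param bg_noise_sd Gaussian pixel noise sd, gives the color-normalization
#'   statistics something non-degenerate to match.
#' @param seed integer base seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       class_labels = c("tumor", "lymphocyte", "stromal"),
                       class_probabilities = c(0.7, 0.2, 0.1),
                       n_nuclei = c(20L, 35L), radius = c(4, 8),
                       colors = NULL,
                       background = c(0.91, 0.80, 0.88),
                       bg_noise_sd = 0.02, seed = 1L) {
  k <- length(class_labels)
  if (length(class_probabilities) != k || any(class_probabilities < 0) ||
      abs(sum(class_probabilities) - 1) > 1e-8)
    mcp_stop("class_probabilities must be a simplex vector over the labels",
             "spec_error")
  if (radius[1] <= 0 || radius[2] < radius[1])
    mcp_stop("radius range must be positive and ordered", "spec_error")
  if (radius[2] / radius[1] > 2)
    mcp_warn("radius ratio > 2 leaves the similar-size regime the nine-point test assumes",
             "size_regime_warning")
  if (is.null(colors)) {
    hues <- seq(0.58, 0.78, length.out = k)  # blue-purple hematoxylin range
    colors <- t(vapply(hues, function(h) grDevices::hsv(h, 0.55, 0.45),
                       character(1)))
    colors <- t(grDevices::col2rgb(as.vector(colors)) / 255)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_labels = class_labels,
                 class_probabilities = class_probabilities,
                 n_nuclei = as.integer(n_nuclei), radius = radius,
                 colors = colors, background = background,
                 bg_noise_sd = bg_noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Class map implied by a scene spec
#' @param spec a [scene_spec()].
#' @return a [class_map()] with intensities 1..K.
#' @export
scene_class_map <- function(spec) class_map(spec$class_labels,
                                            seq_along(spec$class_labels))

# wavy ellipse footprint as a full-scene logical matrix
ellipse_mask <- function(cx, cy, a, b, theta, wave_amp, wave_phase,
                         height, width) {
  r <- ceiling(max(a, b) * (1 + wave_amp)) + 1L
  ys <- max(0L, floor(cy - r)):min(height - 1L, ceiling(cy + r))
  xs <- max(0L, floor(cx - r)):min(width - 1L, ceiling(cx + r))
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  u <- (gx * cos(theta) + gy * sin(theta)) / a
  v <- (-gx * sin(theta) + gy * cos(theta)) / b
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  inside <- rho <= 1 + wave_amp * sin(3 * phi + wave_phase)
  m <- matrix(FALSE, height, width)
  m[ys + 1L, xs + 1L] <- inside
  m
}

#' Generate one synthetic nuclei scene
#'
#' Nuclei are placed by rejection sampling (up to 1000 rejections total);
#' when space runs out, fewer nuclei are returned with a warning. The
#' returned mask triplet and instance list are mutually consistent (the
#' 3-channel parser round-trips them exactly) and generation is deterministic
#' under `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `image` (RGB array), `mask` ([mask_triplet()]),
#'   `instances` (list of [nuclei_instance()] with crops attached).
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- spec$height; w <- spec$width
  image <- array(rep(spec$background, each = h * w), dim = c(h, w, 3))
  image <- image + array(stats::rnorm(h * w * 3, 0, spec$bg_noise_sd),
                         dim = c(h, w, 3))
  image <- pmin(pmax(image, 0), 1)
  occupied <- matrix(FALSE, h, w)
  target <- if (spec$n_nuclei[1] == spec$n_nuclei[2]) spec$n_nuclei[1] else
    resample(spec$n_nuclei[1]:spec$n_nuclei[2], 1L)
  margin <- ceiling(spec$radius[2] * 1.15) + 1
  instances <- list()
  rejections <- 0L
  while (length(instances) < target && rejections < 1000L) {
    a <- stats::runif(1, spec$radius[1], spec$radius[2])
    b <- stats::runif(1, spec$radius[1], spec$radius[2])
    theta <- stats::runif(1, 0, pi)
    wave_phase <- stats::runif(1, 0, 2 * pi)
    cx <- stats::runif(1, margin, w - 1 - margin)
    cy <- stats::runif(1, margin, h - 1 - margin)
    m <- ellipse_mask(cx, cy, a, b, theta, 0.06, wave_phase, h, w)
    if (!any(m) || any(m & occupied)) { rejections <- rejections + 1L; next }
    cls_idx <- sample.int(length(spec$class_labels), 1L,
                          prob = spec$class_probabilities)
    col <- spec$colors[cls_idx, ] +
      stats::rnorm(3, 0, 0.015)  # slight per-nucleus stain variation
    col <- pmin(pmax(col, 0), 1)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[m] <- col[ch] + stats::rnorm(sum(m), 0, 0.01)
      image[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    occupied <- occupied | m
    instances[[length(instances) + 1L]] <- instance_from_full_mask(
      m, length(instances) + 1L, spec$class_labels[cls_idx], cls_idx,
      image = NULL)
  }
  if (length(instances) < target)
    mcp_warn(sprintf("placed %d of %d requested nuclei before giving up",
                     length(instances), target), "placement_budget_warning")
  instances <- attach_crops(instances, image)
  mask <- render_three_channel_mask(instances, scene_class_map(spec), h, w)
  list(image = image, mask = mask, instances = instances)
}

#' Generate a synthetic dataset with COCO annotations
#'
#' Per-image seeds are derived from `(seed, image index)`, so any image can be
#' regenerated independently.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes (>= 1).
#' @param seed base seed (defaults to `spec$seed`).
#' @return list with `images`, `masks`, `instances` (named lists, names
#'   `"img_1"`, ...), `coco` (a [coco_document()]), `class_map`.
#' @export
generate_dataset <- function(spec, n_images, seed = spec$seed) {
  if (n_images < 1L) mcp_stop("n_images must be >= 1", "spec_error")
  ids <- paste0("img_", seq_len(n_images))
  scenes <- lapply(seq_len(n_images), function(i)
    generate_scene(spec, seed = derive_seed(seed, ids[i])))
  images <- stats::setNames(lapply(scenes, `[[`, "image"), ids)
  masks <- stats::setNames(lapply(scenes, `[[`, "mask"), ids)
  instances <- stats::setNames(lapply(scenes, `[[`, "instances"), ids)
  records <- data.frame(id = ids, file_name = paste0(ids, ".png"),
                        height = spec$height, width = spec$width,
                        stringsAsFactors = FALSE)
  coco <- annotations_to_coco(instances, scene_class_map(spec), records)
  list(images = images, masks = masks, instances = instances, coco = coco,
       class_map = scene_class_map(spec))
}

#' Perturb ground truth into synthetic detector output
#'
#' Creates detections with known error structure for exercising the metrics:
#' each ground-truth box is missed with probability `miss_rate`; surviving
#' detections have their class swapped (uniformly to another class) with
#' probability `class_confusion_rate`, their box jittered by rounded Gaussian
#' offsets, and a score drawn uniformly from `score_range` (correct-class
#' detections use the upper half of the range so ranking is informative).
#'
#' @param gt data frame: `image_id`, `category_id`, `x`, `y`, `w`, `h`.
#' @param categories data frame with `id`, `name`.
#' @param miss_rate,class_confusion_rate probabilities in `[0, 1]`.
#' @param bbox_jitter sd (pixels) of the box-corner jitter.
#' @param score_range `c(lo, hi)` detection score range.
#' @param seed integer seed.
#' @return list with `detections` (data frame with `score`) and `truth`
#'   (list: `n_gt`, `n_missed`, `n_detected`, `n_confused`, `detected_idx`,
#'   `confused_idx`).
#' @export
perturb_to_detections <- function(gt, categories, miss_rate = 0.1,
                                  class_confusion_rate = 0,
                                  bbox_jitter = 0,
                                  score_range = c(0.5, 0.99), seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1 || class_confusion_rate < 0 ||
      class_confusion_rate > 1)
    mcp_stop("rates must lie in [0, 1]", "spec_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(gt)
  missed <- stats::runif(n) < miss_rate
  confused <- !missed & stats::runif(n) < class_confusion_rate &
    nrow(categories) > 1L
  rows <- list()
  for (i in seq_len(n)) {
    if (missed[i]) next
    cid <- gt$category_id[i]
    if (confused[i]) cid <- resample(setdiff(categories$id, cid), 1L)
    jit <- if (bbox_jitter > 0) round(stats::rnorm(2, 0, bbox_jitter)) else c(0, 0)
    score <- if (confused[i])
      stats::runif(1, score_range[1], mean(score_range)) else
      stats::runif(1, mean(score_range), score_range[2])
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = gt$image_id[i], category_id = cid,
      x = gt$x[i] + jit[1], y = gt$y[i] + jit[2],
      w = max(1, gt$w[i]), h = max(1, gt$h[i]),
      score = score, stringsAsFactors = FALSE)
  }
  detections <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), category_id = integer(),
               x = numeric(), y = numeric(), w = numeric(), h = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  list(detections = detections,
       truth = list(n_gt = n, n_missed = sum(missed),
                    n_detected = n - sum(missed), n_confused = sum(confused),
                    detected_idx = which(!missed),
                    confused_idx = which(confused)))
}

#' Ground-truth boxes of a dataset as a data frame
#'
#' @param instances named list (by image id) of lists of [nuclei_instance()].
#' @return data frame `image_id`, `category_id`, `x`, `y`, `w`, `h`.
#' @export
gt_boxes <- function(instances) {
  rows <- list()
  for (img in names(instances)) for (inst in instances[[img]]) {
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = img, category_id = inst$category_id,
      x = inst$bbox[1], y = inst$bbox[2], w = inst$bbox[3], h = inst$bbox[4],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), category_id = integer(),
               x = numeric(), y = numeric(), w = numeric(), h = numeric(),
               stringsAsFactors = FALSE)
}
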