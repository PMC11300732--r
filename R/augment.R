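# Overlap-avoiding copy-paste augmentation for dense nuclei scenes.
#
# For each training image: build a binary occupancy map (location threshold,
# LT) from the existing ground truth, find which classes the image is missing,
# sample instances of those classes from the whole training pool, and paste
# each one only where a nine-point occupancy probe finds free space. LT is
# updated after every paste, so pasted instances never collide with earlier
# ones. The nine-point test assumes instances of broadly similar sizes; a
# strict full-footprint mode guarantees zero overlap regardless.

#' Augmentation configuration
#'
#' @param n_missing_classes max number of missing classes to sample per image
#'   (`n`); 0 disables pasting.
#' @param k_samples_per_class instances sampled per chosen class (`k`).
#' @param seed integer RNG seed; per-image streams are derived from it.
#' @param placement_attempts candidate locations tried per instance before
#'   giving up (1 = a single draw, rejected instances are simply not pasted).
#' @param strict_occupancy if `TRUE`, a paste additionally requires the whole
#'   instance footprint to be free in LT, guaranteeing zero mask overlap even
#'   for dissimilar instance sizes.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(n_missing_classes, k_samples_per_class, seed = 1L,
                           placement_attempts = 1L, strict_occupancy = FALSE) {
  if (n_missing_classes < 0L || k_samples_per_class < 1L ||
      placement_attempts < 1L)
    mcp_stop("need n >= 0, k >= 1, placement_attempts >= 1", "config_error")
  structure(list(n_missing_classes = as.integer(n_missing_classes),
                 k_samples_per_class = as.integer(k_samples_per_class),
                 seed = as.integer(seed),
                 placement_attempts = as.integer(placement_attempts),
                 strict_occupancy = isTRUE(strict_occupancy)),
            class = "augment_config")
}

#' Build the location threshold (occupancy map) of an image
#'
#' Binary grid the size of the image: 1 (occupied) wherever any instance mask
#' covers a pixel, 0 (free) elsewhere.
#'
#' @param instances list of [nuclei_instance()] of one image.
#' @param height,width image dimensions in pixels.
#' @return logical height x width matrix of class `location_threshold`.
#' @export
build_location_threshold <- function(instances, height, width) {
  lt <- matrix(FALSE, height, width)
  for (inst in instances) {
    rows <- (inst$bbox[2] + 1L):(inst$bbox[2] + inst$bbox[4])
    cols <- (inst$bbox[1] + 1L):(inst$bbox[1] + inst$bbox[3])
    if (max(rows) > height || max(cols) > width)
      mcp_stop(sprintf("instance %d outside image bounds", inst$instance_id),
               "instance_error")
    lt[rows, cols] <- lt[rows, cols] | inst$mask
  }
  class(lt) <- c("location_threshold", class(lt))
  lt
}

#' Classes absent from an image
#'
#' @param instances list of [nuclei_instance()] of one image.
#' @param all_classes character vector, the dataset's class universe.
#' @return character vector of labels not present in the image.
#' @export
missing_classes <- function(instances, all_classes) {
  present <- unique(vapply(instances, function(i) i$class_label, character(1)))
  extra <- setdiff(present, all_classes)
  if (length(extra))
    mcp_stop(paste0("instance class(es) outside the class universe: ",
                    paste(extra, collapse = ", ")), "unknown_class_error")
  setdiff(all_classes, present)
}

#' Sample instances of missing classes from the training pool
#'
#' Chooses `min(n, |missing|)` classes uniformly without replacement, then for
#' each chosen class `min(k, pool size)` instances uniformly without
#' replacement. A chosen class with an empty pool is skipped with a warning.
#'
#' @param missing character vector of missing class labels.
#' @param pool named list (by class label) of lists of [nuclei_instance()],
#'   the whole training dataset's instances.
#' @param cfg an [augment_config()].
#' @return object of class `chosen_instances`: list with `items` (instances in
#'   sampled order) and `classes` (their labels).
#' @export
choose_instances <- function(missing, pool, cfg) {
  items <- list(); classes <- character(0)
  if (length(missing)) {
    n <- min(cfg$n_missing_classes, length(missing))
    picked <- if (n > 0L) resample(missing, n) else character(0)
    for (cls in picked) {
      avail <- pool[[cls]]
      if (is.null(avail) || length(avail) == 0L) {
        mcp_warn(paste0("no pool instances for missing class '", cls,
                        "'; skipped"), "empty_pool_warning")
        next
      }
      k <- min(cfg$k_samples_per_class, length(avail))
      idx <- resample(seq_along(avail), k)
      items <- c(items, avail[idx])
      classes <- c(classes, rep(cls, k))
    }
  }
  structure(list(items = items, classes = classes),
            class = "chosen_instances")
}

half_size <- function(v) as.integer(floor(v / 2))

#' Propose a random placement point with its eight probes
#'
#' The center is drawn uniformly from the open interval
#' `(w_ins/2, w_LT - w_ins/2)` on x and `(h_ins/2, h_LT - h_ins/2)` on y
#' (margins rounded outward so all probes stay in bounds). The probes are the
#' eight offsets `(kx, ky)` with `kx` in `{-w/2, 0, w/2}` and `ky` in
#' `{-h/2, 0, h/2}`, excluding `(0, 0)` (half-sizes rounded down).
#'
#' @param lt a [build_location_threshold()] grid (only its shape is used).
#' @param w_ins,h_ins instance width/height in pixels; must be smaller than
#'   the grid.
#' @return object of class `placement_point`: list with `p0 = c(x, y)` and
#'   `probe_points` (8 x 2 matrix), all 0-based.
#' @export
propose_point <- function(lt, w_ins, h_ins) {
  h_lt <- nrow(lt); w_lt <- ncol(lt)
  hw <- half_size(w_ins); hh <- half_size(h_ins)
  x_lo <- hw + 1L; x_hi <- w_lt - hw - 1L  # 0-based, strict open margins
  y_lo <- hh + 1L; y_hi <- h_lt - hh - 1L
  if (x_lo > x_hi || y_lo > y_hi)
    mcp_stop(sprintf("no valid location: instance %dx%d in grid %dx%d",
                     w_ins, h_ins, w_lt, h_lt), "no_valid_location_error")
  x <- resample(x_lo:x_hi, 1L)
  y <- resample(y_lo:y_hi, 1L)
  offs <- expand.grid(kx = c(-hw, 0L, hw), ky = c(-hh, 0L, hh))
  offs <- offs[!(offs$kx == 0L & offs$ky == 0L), ]
  probes <- cbind(x + offs$kx, y + offs$ky)
  structure(list(p0 = c(x = x, y = y), probe_points = probes),
            class = "placement_point")
}

#' Nine-point occupancy test
#'
#' A candidate location is free when the occupancy grid is 0 at the center and
#' at all eight surrounding probe points; any occupied probe rejects it.
#'
#' @param lt occupancy grid (logical matrix).
#' @param pt a [propose_point()] result.
#' @return `TRUE` if all nine points are free.
#' @export
is_location_free <- function(lt, pt) {
  xs <- c(pt$p0[["x"]], pt$probe_points[, 1])
  ys <- c(pt$p0[["y"]], pt$probe_points[, 2])
  if (any(xs < 0L) || any(ys < 0L) || any(xs >= ncol(lt)) || any(ys >= nrow(lt)))
    mcp_stop("probe point out of bounds", "placement_error")
  !any(lt[cbind(ys + 1L, xs + 1L)])
}

# Full-footprint variant used by strict_occupancy mode.
footprint_free <- function(lt, inst, pt) {
  x0 <- pt$p0[["x"]] - half_size(inst$bbox[3])
  y0 <- pt$p0[["y"]] - half_size(inst$bbox[4])
  rows <- (y0 + 1L):(y0 + inst$bbox[4])
  cols <- (x0 + 1L):(x0 + inst$bbox[3])
  !any(lt[rows, cols] & inst$mask)
}

#' Paste one instance at an accepted location
#'
#' Composites the instance crop onto the image through its binary mask
#' (background pixels of the crop leave the image untouched), appends a new
#' ground-truth instance with a fresh id and translated bbox/mask, and marks
#' the pasted footprint occupied in LT.
#'
#' @param image RGB array.
#' @param gt_instances list of [nuclei_instance()], the image's ground truth.
#' @param lt occupancy grid.
#' @param instance the [nuclei_instance()] to paste; must carry a `crop`.
#' @param pt accepted [propose_point()] location ([is_location_free()] must
#'   hold — violating it is a caller bug).
#' @param new_id id for the pasted instance (default: max existing + 1).
#' @return list with updated `image`, `gt_instances`, `lt` and the pasted
#'   `instance`.
#' @export
paste_instance <- function(image, gt_instances, lt, instance, pt,
                           new_id = NULL) {
  if (!is_location_free(lt, pt))
    mcp_stop("paste_instance called on an occupied location (caller bug)",
             "contract_error")
  if (is.null(instance$crop))
    mcp_stop("instance has no RGB crop to paste", "instance_error")
  w <- instance$bbox[3]; h <- instance$bbox[4]
  x0 <- pt$p0[["x"]] - half_size(w)
  y0 <- pt$p0[["y"]] - half_size(h)
  rows <- (y0 + 1L):(y0 + h); cols <- (x0 + 1L):(x0 + w)
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > nrow(lt) || max(cols) > ncol(lt))
    mcp_stop("pasted footprint out of bounds", "placement_error")
  m <- instance$mask
  for (ch in 1:3) {
    sub <- image[rows, cols, ch]
    sub[m] <- instance$crop[, , ch][m]
    image[rows, cols, ch] <- sub
  }
  if (is.null(new_id)) {
    existing <- vapply(gt_instances, function(i) i$instance_id, integer(1))
    new_id <- if (length(existing)) max(existing) + 1L else 1L
  }
  pasted <- nuclei_instance(new_id, instance$class_label,
                            instance$category_id,
                            bbox = c(x0, y0, w, h), mask = m,
                            crop = instance$crop,
                            source_image_id = instance$source_image_id)
  lt[rows, cols] <- lt[rows, cols] | m
  list(image = image, gt_instances = c(gt_instances, list(pasted)), lt = lt,
       instance = pasted)
}

#' Augment one image by pasting instances of its missing classes
#'
#' Runs the full per-image cycle: occupancy map, missing classes, instance
#' sampling, and for each sampled instance up to `placement_attempts` random
#' location proposals — pasted at the first free one, otherwise left out
#' (never forced). The occupancy map is updated after every accepted paste.
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param image RGB array (normalized; crops are pasted as-is).
#' @param gt_instances image ground truth, list of [nuclei_instance()].
#' @param pool training-wide instance pool, named list by class label; pool
#'   instances must carry crops.
#' @param cfg an [augment_config()].
#' @param all_classes class universe (labels).
#' @return list with `image`, `gt_instances`, `lt` and `paste_log` (data frame
#'   with one row per sampled instance: class, source id, outcome, x, y).
#' @export
augment_image <- function(image, gt_instances, pool, cfg, all_classes) {
  assert_rgb_image(image)
  lt <- build_location_threshold(gt_instances, nrow(image), ncol(image))
  miss <- missing_classes(gt_instances, all_classes)
  chins <- choose_instances(miss, pool, cfg)
  log_rows <- list()
  for (i in seq_along(chins$items)) {
    inst <- chins$items[[i]]
    outcome <- "rejected-occupied"; px <- NA_integer_; py <- NA_integer_
    for (attempt in seq_len(cfg$placement_attempts)) {
      pt <- tryCatch(propose_point(lt, inst$bbox[3], inst$bbox[4]),
                     mcpaste_error = function(e) NULL)
      if (is.null(pt)) { outcome <- "rejected-no-location"; break }
      free <- is_location_free(lt, pt) &&
        (!cfg$strict_occupancy || footprint_free(lt, inst, pt))
      if (free) {
        res <- paste_instance(image, gt_instances, lt, inst, pt)
        image <- res$image; gt_instances <- res$gt_instances; lt <- res$lt
        outcome <- "pasted"
        px <- pt$p0[["x"]]; py <- pt$p0[["y"]]
        break
      }
    }
    log_rows[[i]] <- data.frame(
      class = inst$class_label, source_id = inst$instance_id,
      outcome = outcome, x = px, y = py, stringsAsFactors = FALSE)
  }
  paste_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(class = character(), source_id = integer(),
               outcome = character(), x = integer(), y = integer(),
               stringsAsFactors = FALSE)
  list(image = image, gt_instances = gt_instances, lt = lt,
       paste_log = paste_log)
}

#' Augment a whole dataset
#'
#' Processes every image independently with an RNG stream derived from
#' `(cfg$seed, image id)`, so results do not depend on iteration order. The
#' pasting pool is built from all images' instances (crops attached from the
#' supplied — typically color-normalized — images).
#'
#' @param dataset list with `images` (named list of RGB arrays) and
#'   `instances` (named list, same names, of lists of [nuclei_instance()]).
#' @param cfg an [augment_config()].
#' @param all_classes class universe; defaults to the labels present.
#' @return list with `images`, `instances`, `paste_logs`, and `summary` (data
#'   frame of per-class before/after counts) carrying attribute
#'   `imbalance_ratio` = c(before, after).
#' @export
augment_dataset <- function(dataset, cfg, all_classes = NULL) {
  if (length(dataset$images) == 0L)
    mcp_stop("dataset is empty", "empty_input_error")
  ids <- names(dataset$images)
  stopifnot(identical(sort(ids), sort(names(dataset$instances))))
  with_crops <- lapply(ids, function(id)
    attach_crops(dataset$instances[[id]], dataset$images[[id]]))
  names(with_crops) <- ids
  flat <- unlist(with_crops, recursive = FALSE, use.names = FALSE)
  labs <- vapply(flat, function(i) i$class_label, character(1))
  if (is.null(all_classes)) all_classes <- sort(unique(labs))
  pool <- split(flat, factor(labs, levels = all_classes))
  before <- count_instances(flat, all_classes)

  out_images <- list(); out_instances <- list(); logs <- list()
  for (id in ids) {
    old <- .Random.seed_save()
    set.seed(derive_seed(cfg$seed, id))
    res <- augment_image(dataset$images[[id]], with_crops[[id]], pool, cfg,
                         all_classes)
    .Random.seed_restore(old)
    out_images[[id]] <- res$image
    out_instances[[id]] <- res$gt_instances
    logs[[id]] <- res$paste_log
  }
  after <- count_instances(unlist(out_instances, recursive = FALSE,
                                  use.names = FALSE), all_classes)
  summary <- data.frame(class = all_classes, before = as.integer(before),
                        after = as.integer(after), stringsAsFactors = FALSE)
  attr(summary, "imbalance_ratio") <- c(before = imbalance_ratio(before),
                                        after = imbalance_ratio(after))
  list(images = out_images, instances = out_instances, paste_logs = logs,
       summary = summary)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Random horizontal/vertical flip of an image and its ground truth
#'
#' Applies a horizontal flip with probability `ratio` and, independently, a
#' vertical flip with probability `ratio`; masks, crops and bboxes are
#' transformed consistently.
#'
#' @param image RGB array.
#' @param gt_instances list of [nuclei_instance()].
#' @param ratio flip probability in `[0, 1]` per axis.
#' @param force optional `c(horizontal, vertical)` logical to bypass the coin
#'   flips (used for deterministic tests).
#' @return list with `image`, `gt_instances`, `flipped = c(h, v)`.
#' @export
random_flip <- function(image, gt_instances, ratio = 0.5, force = NULL) {
  if (ratio < 0 || ratio > 1) mcp_stop("ratio must be in [0, 1]", "config_error")
  flips <- if (!is.null(force)) as.logical(force) else stats::runif(2) < ratio
  h <- nrow(image); w <- ncol(image)
  if (flips[1]) {  # horizontal: mirror columns
    image <- image[, w:1, , drop = FALSE]
    gt_instances <- lapply(gt_instances, function(inst) {
      inst$mask <- inst$mask[, rev(seq_len(ncol(inst$mask))), drop = FALSE]
      if (!is.null(inst$crop))
        inst$crop <- inst$crop[, rev(seq_len(dim(inst$crop)[2])), , drop = FALSE]
      inst$bbox[1] <- w - inst$bbox[1] - inst$bbox[3]
      inst
    })
  }
  if (flips[2]) {  # vertical: mirror rows
    image <- image[h:1, , , drop = FALSE]
    gt_instances <- lapply(gt_instances, function(inst) {
      inst$mask <- inst$mask[rev(seq_len(nrow(inst$mask))), , drop = FALSE]
      if (!is.null(inst$crop))
        inst$crop <- inst$crop[rev(seq_len(dim(inst$crop)[1])), , , drop = FALSE]
      inst$bbox[2] <- h - inst$bbox[2] - inst$bbox[4]
      inst
    })
  }
  list(image = image, gt_instances = gt_instances, flipped = flips)
}
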