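#' A single annotated nucleus
#'
#' The atomic unit handled by the augmentation pipeline: one nucleus with its
#' class, instance identity, binary footprint, bounding box and (optionally)
#' the RGB pixels it covers.
#'
#' Coordinates are 0-based pixel indices with x running over columns and y
#' over rows; `bbox = c(x, y, w, h)` is the tight axis-aligned bounds of the
#' mask, half-open in pixel terms. The mask (and crop, when present) are
#' stored bbox-local: a logical `h x w` matrix whose `[1,1]` entry is image
#' pixel `(x, y)`.
#'
#' @param instance_id positive integer, the blue-channel value identifying the
#'   nucleus within its image.
#' @param class_label character class label.
#' @param category_id integer COCO category id.
#' @param bbox integer `c(x, y, w, h)`, 0-based.
#' @param mask logical `h x w` matrix, bbox-local; must be nonempty and tight
#'   (touch all four bbox edges).
#' @param crop optional numeric `h x w x 3` RGB array cut to the bbox; pixels
#'   outside the mask are carried but never composited.
#' @param source_image_id identifier of the image the nucleus came from.
#' @return object of class `nuclei_instance`.
#' @export
nuclei_instance <- function(instance_id, class_label, category_id, bbox, mask,
                            crop = NULL, source_image_id = NA_character_) {
  bbox <- as.integer(bbox)
  if (length(bbox) != 4L || bbox[3] < 1L || bbox[4] < 1L || any(bbox[1:2] < 0L))
    mcp_stop("bbox must be c(x, y, w, h) with w, h >= 1 and x, y >= 0",
             "instance_error")
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), c(bbox[4], bbox[3])))
    mcp_stop("mask must be a logical h x w matrix matching the bbox",
             "instance_error")
  if (!any(mask))
    mcp_stop("instance mask must be nonempty", "empty_mask_error")
  if (!any(mask[1, ]) || !any(mask[nrow(mask), ]) ||
      !any(mask[, 1]) || !any(mask[, ncol(mask)]))
    mcp_stop("bbox must be the tight bounds of the mask", "instance_error")
  if (!is.null(crop) &&
      (!is_rgb_image(crop) || !identical(dim(crop)[1:2], dim(mask))))
    mcp_stop("crop must be an RGB array with the mask's dimensions",
             "instance_error")
  structure(
    list(instance_id = as.integer(instance_id),
         class_label = as.character(class_label),
         category_id = as.integer(category_id),
         bbox = bbox, mask = mask, crop = crop,
         source_image_id = source_image_id),
    class = "nuclei_instance"
  )
}

#' @export
print.nuclei_instance <- function(x, ...) {
  cat(sprintf("<nuclei_instance #%d '%s' (cat %d) bbox=[%d,%d,%d,%d] area=%d>\n",
              x$instance_id, x$class_label, x$category_id,
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], sum(x$mask)))
  invisible(x)
}

#' Build an instance from a full-image binary mask
#'
#' Computes the tight bbox and stores the bbox-local mask (and crop, when an
#' image is supplied).
#'
#' @param full_mask logical height x width matrix over the whole image.
#' @param instance_id,class_label,category_id,source_image_id see
#'   [nuclei_instance()].
#' @param image optional RGB image to cut the crop from.
#' @return a `nuclei_instance`.
#' @export
instance_from_full_mask <- function(full_mask, instance_id, class_label,
                                    category_id, image = NULL,
                                    source_image_id = NA_character_) {
  if (!any(full_mask)) mcp_stop("instance mask must be nonempty", "empty_mask_error")
  rows <- range(which(rowSums(full_mask) > 0))
  cols <- range(which(colSums(full_mask) > 0))
  local <- full_mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  crop <- NULL
  if (!is.null(image)) {
    crop <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  }
  nuclei_instance(instance_id, class_label, category_id,
                  bbox = c(cols[1] - 1L, rows[1] - 1L,
                           cols[2] - cols[1] + 1L, rows[2] - rows[1] + 1L),
                  mask = local, crop = crop,
                  source_image_id = source_image_id)
}

#' Expand an instance mask back to image coordinates
#'
#' @param inst a [nuclei_instance()].
#' @param height,width image dimensions in pixels.
#' @return logical height x width matrix.
#' @export
instance_full_mask <- function(inst, height, width) {
  m <- matrix(FALSE, height, width)
  rows <- (inst$bbox[2] + 1L):(inst$bbox[2] + inst$bbox[4])
  cols <- (inst$bbox[1] + 1L):(inst$bbox[1] + inst$bbox[3])
  if (max(rows) > height || max(cols) > width)
    mcp_stop("instance bbox exceeds image bounds", "instance_error")
  m[rows, cols] <- inst$mask
  m
}

#' Attach RGB crops to instances from their image
#'
#' Used after color normalization so pasted pixels come from the normalized
#' image.
#'
#' @param instances list of [nuclei_instance()].
#' @param image RGB array the instances were annotated on.
#' @return list of instances with `crop` filled in.
#' @export
attach_crops <- function(instances, image) {
  assert_rgb_image(image)
  lapply(instances, function(inst) {
    rows <- (inst$bbox[2] + 1L):(inst$bbox[2] + inst$bbox[4])
    cols <- (inst$bbox[1] + 1L):(inst$bbox[1] + inst$bbox[3])
    inst$crop <- image[rows, cols, , drop = FALSE]
    inst
  })
}

#' Per-class instance counts
#'
#' @param instances list of [nuclei_instance()] (possibly nested by image; a
#'   flat list is expected — use `unlist(..., recursive = FALSE)` first).
#' @param labels optional label universe; classes with no instances get 0.
#' @return named integer vector.
#' @export
count_instances <- function(instances, labels = NULL) {
  labs <- vapply(instances, function(i) i$class_label, character(1))
  if (is.null(labels)) labels <- unique(labs)
  tab <- table(factor(labs, levels = labels))
  stats::setNames(as.integer(tab), labels)
}

#' Imbalance ratio of a count vector
#'
#' Ratio of the most to the least frequent class. Classes with zero instances
#' are excluded (the ratio would be infinite and says nothing about the
#' sampled classes).
#'
#' @param counts named numeric vector of per-class counts.
#' @return scalar >= 1, or NA if fewer than two classes have instances.
#' @export
imbalance_ratio <- function(counts) {
  pos <- counts[counts > 0]
  if (length(pos) < 2L) return(NA_real_)
  max(pos) / min(pos)
}
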