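#' 3-channel ground-truth mask
#'
#' NuCLS-style ground truth packs two intensity maps into one RGB image: the
#' red channel encodes class (each class one distinct intensity) and the blue
#' channel encodes instance identity (each nucleus one distinct positive
#' value, 0 = background). The green channel carries no defined semantics and
#' is preserved verbatim.
#'
#' @param red,green,blue integer matrices of identical dimensions.
#' @return object of class `mask_triplet` with fields `red`, `green`, `blue`,
#'   `height`, `width`.
#' @export
mask_triplet <- function(red, green, blue) {
  if (!is.matrix(red) || !is.matrix(green) || !is.matrix(blue) ||
      !identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    mcp_stop("red, green, blue must be matrices of identical dimensions",
             "mask_triplet_error")
  storage.mode(red) <- "integer"
  storage.mode(green) <- "integer"
  storage.mode(blue) <- "integer"
  if (any(blue < 0L) || any(red < 0L))
    mcp_stop("channel values must be non-negative", "mask_triplet_error")
  structure(list(red = red, green = green, blue = blue,
                 height = nrow(red), width = ncol(red)),
            class = "mask_triplet")
}

#' @export
print.mask_triplet <- function(x, ...) {
  cat(sprintf("<mask_triplet %dx%d, %d instance(s)>\n", x$height, x$width,
              length(setdiff(unique(as.vector(x$blue)), 0L))))
  invisible(x)
}

#' Parse a 3-channel mask into nuclei instances
#'
#' One instance is produced per distinct nonzero blue value; its class is the
#' red intensity covering its pixels, looked up in `class_map`. The channels
#' are treated as exact maps: an instance whose pixels span two red
#' intensities, or a red intensity absent from the class map, is an error —
#' no majority vote is taken.
#'
#' @param mask a [mask_triplet()].
#' @param class_map a [class_map()] covering every red intensity present.
#' @param image optional RGB image to cut per-instance crops from.
#' @return list of [nuclei_instance()], ordered by instance id.
#' @export
parse_three_channel_mask <- function(mask, class_map, image = NULL) {
  stopifnot(inherits(mask, "mask_triplet"), inherits(class_map, "class_map"))
  if (!is.null(image)) {
    assert_rgb_image(image)
    if (!identical(dim(image)[1:2], c(mask$height, mask$width)))
      mcp_stop("image dimensions do not match the mask", "mask_triplet_error")
  }
  ids <- sort(setdiff(unique(as.vector(mask$blue)), 0L))
  present_reds <- setdiff(unique(mask$red[mask$blue != 0L]), 0L)
  unknown <- setdiff(present_reds, class_map$intensity)
  if (length(unknown))
    mcp_stop(paste0("red intensity value(s) not in class map: ",
                    paste(sort(unknown), collapse = ", ")),
             "unknown_class_error")
  lapply(ids, function(id) {
    sel <- mask$blue == id
    reds <- unique(mask$red[sel])
    if (length(reds) != 1L)
      mcp_stop(sprintf(
        "instance %d spans multiple red intensities (%s); mask is inconsistent",
        id, paste(sort(reds), collapse = ", ")),
        "inconsistent_mask_error")
    row <- class_map[class_map$intensity == reds, ]
    instance_from_full_mask(sel, id, row$label, row$category_id, image = image)
  })
}

#' Render nuclei instances to a 3-channel mask
#'
#' Inverse of [parse_three_channel_mask()]: writes each instance's id into the
#' blue channel and its class intensity into the red channel. Instances must
#' not overlap and ids must be unique.
#'
#' @param instances list of [nuclei_instance()].
#' @param class_map a [class_map()] covering every instance class.
#' @param height,width output dimensions in pixels.
#' @param green optional green channel to preserve (defaults to zeros).
#' @return a [mask_triplet()] such that parsing it reproduces `instances`.
#' @export
render_three_channel_mask <- function(instances, class_map, height, width,
                                      green = NULL) {
  stopifnot(inherits(class_map, "class_map"))
  red <- matrix(0L, height, width)
  blue <- matrix(0L, height, width)
  if (is.null(green)) green <- matrix(0L, height, width)
  ids <- vapply(instances, function(i) i$instance_id, integer(1))
  if (anyDuplicated(ids))
    mcp_stop("instance ids must be unique within an image", "mask_triplet_error")
  colliding <- integer(0)
  for (inst in instances) {
    intensity <- class_map$intensity[match(inst$class_label, class_map$label)]
    if (is.na(intensity))
      mcp_stop(paste0("class not in class map: ", inst$class_label),
               "unknown_class_error")
    rows <- (inst$bbox[2] + 1L):(inst$bbox[2] + inst$bbox[4])
    cols <- (inst$bbox[1] + 1L):(inst$bbox[1] + inst$bbox[3])
    if (max(rows) > height || max(cols) > width)
      mcp_stop(sprintf("instance %d exceeds image bounds", inst$instance_id),
               "mask_triplet_error")
    sub <- blue[rows, cols, drop = FALSE]
    if (any(sub[inst$mask] != 0L))
      colliding <- c(colliding, unique(sub[inst$mask & sub != 0L]),
                     inst$instance_id)
    sub[inst$mask] <- inst$instance_id
    blue[rows, cols] <- sub
    subr <- red[rows, cols, drop = FALSE]
    subr[inst$mask] <- intensity
    red[rows, cols] <- subr
  }
  if (length(colliding))
    mcp_stop(paste0("overlapping instance masks: ids ",
                    paste(sort(unique(colliding)), collapse = ", ")),
             "overlap_error")
  mask_triplet(red, green, blue)
}

#' Read / write a 3-channel mask as PNG
#'
#' Lossless 8-bit PNG; channel values must fit in 0..255 (instance ids above
#' 255 in a single image are not representable in this file dialect).
#'
#' @param path PNG file path.
#' @return `read_mask_png`: a [mask_triplet()].
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    mcp_stop("mask PNG must have at least 3 channels", "mask_triplet_error")
  to_int <- function(ch) {
    m <- round(ch * 255)
    storage.mode(m) <- "integer"
    m
  }
  mask_triplet(to_int(arr[, , 1]), to_int(arr[, , 2]), to_int(arr[, , 3]))
}

#' @rdname read_mask_png
#' @param mask a [mask_triplet()] with all values in 0..255.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mask_triplet"))
  if (max(mask$red, mask$green, mask$blue) > 255L)
    mcp_stop("channel values above 255 cannot be written as 8-bit PNG",
             "mask_triplet_error")
  arr <- array(0, dim = c(mask$height, mask$width, 3))
  arr[, , 1] <- mask$red / 255
  arr[, , 2] <- mask$green / 255
  arr[, , 3] <- mask$blue / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read / write an RGB tissue image as PNG
#'
#' Images are held in memory as height x width x 3 double arrays in `[0, 1]`.
#'
#' @param path PNG file path.
#' @return `read_image_png`: RGB array.
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  arr[, , 1:3, drop = FALSE]
}

#' @rdname read_image_png
#' @param image RGB array in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
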