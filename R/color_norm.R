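# Reinhard color transfer for H&E tissue images.
#
# Pixels are mapped into a decorrelated log-opponent space (the l-alpha-beta
# space of the original color-transfer method: RGB -> LMS cone response ->
# log10 -> opponent axes), per-channel first and second moments are matched to
# a target, and the result is mapped back to RGB. CIELAB is offered as an
# alternative working space because many histology reimplementations use it.

RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                    0.1967, 0.7244, 0.0782,
                    0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
LMS2RGB <- solve(RGB2LMS)
LMS2LAB <- matrix(c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3),
                    1 / sqrt(6), 1 / sqrt(6), -2 / sqrt(6),
                    1 / sqrt(2), -1 / sqrt(2), 0), 3, 3, byrow = TRUE)
LAB2LMS <- solve(LMS2LAB)

# image array -> n x 3 channel matrix in the working space
to_opponent <- function(image, space) {
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  if (space == "lalphabeta") {
    lms <- px %*% t(RGB2LMS)
    # +1 on the 0..255 scale guards log10(0) on pure-black pixels
    loglms <- log10(lms * 255 + 1)
    loglms %*% t(LMS2LAB)
  } else {
    grDevices::convertColor(px, from = "sRGB", to = "Lab")
  }
}

from_opponent <- function(ch, dims, space) {
  if (space == "lalphabeta") {
    loglms <- ch %*% t(LAB2LMS)
    lms <- (10^loglms - 1) / 255
    px <- lms %*% t(LMS2RGB)
  } else {
    px <- grDevices::convertColor(ch, from = "Lab", to = "sRGB", clip = NA)
    px[is.na(px)] <- 0
  }
  px <- pmin(pmax(px, 0), 1)
  array(px, dim = c(dims, 3))
}

#' Per-channel statistics in the normalization working space
#'
#' @param image RGB array, values in `[0, 1]`.
#' @param space working color space: `"lalphabeta"` (log-opponent, default) or
#'   `"lab"` (CIELAB).
#' @return object of class `channel_stats` with fields `mean`, `std` (3-vectors)
#'   and `space`.
#' @export
compute_stats <- function(image, space = c("lalphabeta", "lab")) {
  space <- match.arg(space)
  assert_rgb_image(image)
  ch <- to_opponent(image, space)
  structure(list(mean = colMeans(ch), std = apply(ch, 2, stats::sd),
                 space = space),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("<channel_stats [%s] mean=(%.4f, %.4f, %.4f) std=(%.4f, %.4f, %.4f)>\n",
              x$space, x$mean[1], x$mean[2], x$mean[3],
              x$std[1], x$std[2], x$std[3]))
  invisible(x)
}

#' Reinhard color normalization of one image
#'
#' Each working-space channel is recentred and rescaled,
#' `(v - mean_src) * std_tgt / std_src + mean_tgt`, then mapped back to RGB
#' and clipped to `[0, 1]`. A constant source channel (std 0) cannot be
#' rescaled; its pixels are set to the target mean and a warning is raised
#' when the target std is nonzero.
#'
#' @param source RGB array in `[0, 1]`.
#' @param target a `channel_stats` object (see [compute_stats()]).
#' @return RGB array with the dimensions of `source`.
#' @export
reinhard_normalize <- function(source, target) {
  assert_rgb_image(source)
  stopifnot(inherits(target, "channel_stats"))
  if (!all(is.finite(target$mean)) || !all(is.finite(target$std)))
    mcp_stop("target statistics must be finite", "channel_stats_error")
  ch <- to_opponent(source, target$space)
  m_src <- colMeans(ch)
  s_src <- apply(ch, 2, stats::sd)
  for (c in 1:3) {
    if (s_src[c] == 0) {
      if (target$std[c] != 0)
        mcp_warn(sprintf(
          "source channel %d is constant; pinned to target mean", c),
          "degenerate_source_warning")
      ch[, c] <- target$mean[c]
    } else {
      ch[, c] <- (ch[, c] - m_src[c]) * (target$std[c] / s_src[c]) +
        target$mean[c]
    }
  }
  from_opponent(ch, dim(source)[1:2], target$space)
}

#' Normalize a dataset of images to shared target statistics
#'
#' The reference may be an explicit image, precomputed `channel_stats`, or
#' omitted — in which case the target is the pooled statistics of the dataset
#' (mean over images of the per-image channel means and stds), which removes
#' the arbitrary choice of a reference image and is deterministic.
#'
#' @param images list of RGB arrays (possibly named).
#' @param reference RGB array, `channel_stats`, or `NULL` for pooled stats.
#' @param space working space, see [compute_stats()]; ignored when `reference`
#'   is a `channel_stats`.
#' @return list of normalized images (same names/order); attribute `target`
#'   holds the stats used.
#' @export
normalize_dataset <- function(images, reference = NULL,
                              space = c("lalphabeta", "lab")) {
  space <- match.arg(space)
  if (length(images) == 0L) return(images)
  target <-
    if (inherits(reference, "channel_stats")) reference
    else if (!is.null(reference)) compute_stats(reference, space)
    else {
      per <- lapply(images, compute_stats, space = space)
      structure(list(
        mean = rowMeans(vapply(per, `[[`, numeric(3), "mean")),
        std = rowMeans(vapply(per, `[[`, numeric(3), "std")),
        space = space), class = "channel_stats")
    }
  out <- vector("list", length(images))
  names(out) <- names(images)
  for (i in seq_along(images)) {
    out[[i]] <- tryCatch(reinhard_normalize(images[[i]], target),
      error = function(e) mcp_stop(
        sprintf("image %s: %s", names(images)[i] %||% i, conditionMessage(e)),
        "normalize_error"))
  }
  attr(out, "target") <- target
  out
}
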