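# Count-based class weights and the reference loss functions they feed.
# Pure numeric functions: they exist to compute and export weight tables for a
# detector's classification head and to verify loss behaviour, not to train.

#' Class weights from per-class instance counts
#'
#' `w_c = N / (M * count_c)` with `N` the total instance count and `M` the
#' number of classes, so balanced counts give unit weights and minority
#' classes are up-weighted in inverse proportion to their frequency. A class
#' with zero instances has no finite weight; by default it gets weight 0 (it
#' can never appear in the ground truth) with a warning.
#'
#' @param counts numeric vector of per-class instance counts (optionally
#'   named); entries >= 0, not all zero.
#' @param zero_count `"zero"` (default) or `"error"`.
#' @return object of class `class_weights`: list with `weights`, `counts`,
#'   `total`.
#' @examples
#' compute_class_weights(c(tumor = 3, stroma = 1))  # c(0.667, 2)
#' @export
compute_class_weights <- function(counts, zero_count = c("zero", "error")) {
  zero_count <- match.arg(zero_count)
  if (length(counts) < 1L || any(counts < 0))
    mcp_stop("counts must be a nonempty vector of non-negative numbers",
             "config_error")
  total <- sum(counts)
  if (total == 0)
    mcp_stop("all class counts are zero; no weights are defined",
             "empty_dataset_error")
  m <- length(counts)
  w <- rep(0, m)
  pos <- counts > 0
  w[pos] <- total / (m * counts[pos])
  if (any(!pos)) {
    if (zero_count == "error")
      mcp_stop(paste0("zero-count class(es): ",
                      paste(names(counts)[!pos] %||% which(!pos),
                            collapse = ", ")), "zero_count_error")
    mcp_warn("zero-count class(es) assigned weight 0 (never in ground truth)",
             "zero_count_warning")
  }
  names(w) <- names(counts)
  structure(list(weights = w, counts = counts, total = total),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights over %d classes, N = %g>\n",
              length(x$weights), x$total))
  print(round(x$weights, 4))
  invisible(x)
}

# probs / onehot as vectors (one observation) or matrices (rows = observations)
as_obs_matrix <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Weighted cross-entropy loss
#'
#' `L = -sum_c w_c * log(p_c) * y_c` per observation (the sum collapses to the
#' correct class's term since `y` is one-hot); the batch value is the mean
#' over observations. Probabilities are clamped at 1e-12 before the log.
#'
#' @param probs predicted class probabilities: length-M vector or N x M matrix.
#' @param onehot one-hot ground-truth indicator, same shape.
#' @param weights a [compute_class_weights()] object or numeric length-M
#'   vector; defaults to unit weights.
#' @return scalar loss (>= 0).
#' @export
weighted_cross_entropy <- function(probs, onehot, weights = NULL) {
  p <- as_obs_matrix(probs); y <- as_obs_matrix(onehot)
  if (!identical(dim(p), dim(y)))
    mcp_stop("probs and onehot must have identical shape", "shape_error")
  w <- if (inherits(weights, "class_weights")) weights$weights
       else weights %||% rep(1, ncol(p))
  if (length(w) != ncol(p))
    mcp_stop("weights length must equal the number of classes", "shape_error")
  if (any(rowSums(y == 1) != 1L) || any(y != 0 & y != 1))
    mcp_stop("onehot must have exactly one 1 per observation", "shape_error")
  p <- pmax(p, 1e-12)
  mean(-rowSums(sweep(log(p) * y, 2, w, `*`)))
}

#' Focal loss
#'
#' `-alpha * (1 - p_t)^gamma * log(p_t)` with `p_t` the probability assigned
#' to the correct class; batch mean over observations. With `gamma = 0`,
#' `alpha = 1` it reduces to unweighted cross-entropy. Defaults follow the
#' standard dense-detection setting (`gamma = 2`, `alpha = 0.25`).
#'
#' @inheritParams weighted_cross_entropy
#' @param gamma focusing exponent, >= 0.
#' @param alpha scalar weight in (0, 1].
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(probs, onehot, gamma = 2, alpha = 0.25) {
  if (gamma < 0 || alpha <= 0 || alpha > 1)
    mcp_stop("need gamma >= 0 and 0 < alpha <= 1", "config_error")
  p <- as_obs_matrix(probs); y <- as_obs_matrix(onehot)
  if (!identical(dim(p), dim(y)))
    mcp_stop("probs and onehot must have identical shape", "shape_error")
  if (any(rowSums(y == 1) != 1L) || any(y != 0 & y != 1))
    mcp_stop("onehot must have exactly one 1 per observation", "shape_error")
  pt <- pmax(rowSums(p * y), 1e-12)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}
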