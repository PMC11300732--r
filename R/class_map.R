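#' Class map: label / mask intensity / COCO category id
#'
#' A class map ties together the three identities a nucleus class has in this
#' pipeline: its text label, the intensity value that encodes it in the red
#' channel of a 3-channel mask, and its integer category id in COCO documents.
#'
#' @param labels character vector of unique class labels.
#' @param intensities integer vector of unique, positive red-channel
#'   intensities, one per label.
#' @param category_ids integer vector of category ids; must be `1:length(labels)`
#'   (contiguous from 1). Defaults to label order.
#' @return A `class_map` data frame with columns `label`, `intensity`,
#'   `category_id`.
#' @examples
#' class_map(c("tumor", "fibroblast"), c(3L, 7L))
#' @export
class_map <- function(labels, intensities, category_ids = seq_along(labels)) {
  labels <- as.character(labels)
  intensities <- as.integer(intensities)
  category_ids <- as.integer(category_ids)
  if (length(labels) < 1L)
    mcp_stop("class map needs at least one class", "class_map_error")
  if (anyDuplicated(labels))
    mcp_stop("class labels must be unique", "class_map_error")
  if (length(intensities) != length(labels) || anyDuplicated(intensities) ||
      any(intensities <= 0L))
    mcp_stop("intensities must be unique positive integers, one per label",
             "class_map_error")
  if (!identical(sort(category_ids), seq_along(labels)))
    mcp_stop("category ids must be unique and contiguous from 1", "class_map_error")
  structure(
    data.frame(label = labels, intensity = intensities,
               category_id = category_ids, stringsAsFactors = FALSE),
    class = c("class_map", "data.frame")
  )
}

#' Default class map for the NuCLS 13-class label set
#'
#' Labels follow the published instance-count table ordering; red-channel
#' intensities default to 1..13 in that order (the public release does not fix
#' them in print, so they are configurable).
#'
#' @param intensities optional integer vector of 13 red-channel intensities.
#' @return a [class_map()].
#' @export
nucls_class_map <- function(intensities = 1:13) {
  class_map(nucls_labels(), intensities)
}

#' NuCLS class labels in instance-count order
#' @return character vector of the 13 labels.
#' @export
nucls_labels <- function() {
  c("tumor", "lymphocyte", "fibroblast", "unlabeled", "plasma_cell",
    "macrophage", "vascular_endothelium", "ductal_epithelium",
    "apoptotic_body", "mitotic_figure", "myoepithelium", "neutrophil",
    "eosinophil")
}

#' Published NuCLS per-class instance counts
#'
#' Per-class instance totals of the corrected single-rater dataset (CSRD,
#' training/validation) and the inferred pathologist-truth evaluation
#' multi-rater dataset (IPEMRD, test), as tabulated for the public NuCLS
#' release. Shipped so grouping and class-weight computations can be exercised
#' without downloading the datasets.
#'
#' @return data frame with columns `label`, `csrd`, `ipemrd`.
#' @export
nucls_table_counts <- function() {
  path <- system.file("extdata", "nucls_instance_counts.csv",
                      package = "mcpaste", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Built-in class grouping presets
#'
#' Two dataset configurations are supported out of the box:
#' * `config1`: every label collapses into a single "Nuclei" class, for
#'   evaluating detection without classification.
#' * `config2`: minority classes are pooled — mitotic figure, myoepithelium,
#'   neutrophil, normal (ductal) epithelium and eosinophil become
#'   "Other nuclei"; apoptotic body and unlabeled become "Ambiguous"; the six
#'   remaining labels keep their identity.
#'
#' @param name `"config1"` or `"config2"`.
#' @param labels labels to map (defaults to the NuCLS label set).
#' @return named character vector: `original label -> grouped label`.
#' @export
grouping_preset <- function(name = c("config1", "config2"),
                            labels = nucls_labels()) {
  name <- match.arg(name)
  if (name == "config1") {
    return(stats::setNames(rep("Nuclei", length(labels)), labels))
  }
  other <- c("mitotic_figure", "myoepithelium", "neutrophil",
             "ductal_epithelium", "eosinophil")
  ambiguous <- c("apoptotic_body", "unlabeled")
  g <- stats::setNames(labels, labels)
  g[names(g) %in% other] <- "Other nuclei"
  g[names(g) %in% ambiguous] <- "Ambiguous"
  g
}

#' Regroup per-class counts or instances
#'
#' Applies a grouping (original label -> grouped label) either to a named
#' count vector or to a list of [nuclei_instance()] objects. Counts are summed
#' within groups; instance labels are rewritten (category ids are reassigned
#' contiguously in first-appearance order of the grouped labels). The total
#' instance count is conserved.
#'
#' @param x named numeric vector of per-class counts, or list of
#'   `nuclei_instance` objects.
#' @param grouping named character vector mapping every original label to its
#'   grouped label.
#' @return regrouped counts (named numeric) or instances (list).
#' @examples
#' counts <- c(tumor = 510, eosinophil = 0, neutrophil = 6)
#' group_classes(counts, c(tumor = "tumor", eosinophil = "Other nuclei",
#'                         neutrophil = "Other nuclei"))
#' @export
group_classes <- function(x, grouping) {
  if (is.null(names(grouping)) || anyDuplicated(names(grouping)))
    mcp_stop("grouping must be a named character vector with unique names",
             "grouping_error")
  if (is.numeric(x)) {
    present <- names(x)
    if (is.null(present)) mcp_stop("count vector must be named", "grouping_error")
    missing <- setdiff(present, names(grouping))
    if (length(missing))
      mcp_stop(paste0("grouping does not map label(s): ",
                      paste(missing, collapse = ", ")),
               "mapping_incomplete_error")
    grouped <- grouping[present]
    out <- tapply(as.numeric(x), factor(grouped, levels = unique(grouped)), sum)
    return(stats::setNames(as.numeric(out), names(out)))
  }
  if (is.list(x)) {
    labs <- vapply(x, function(i) i$class_label, character(1))
    missing <- setdiff(unique(labs), names(grouping))
    if (length(missing))
      mcp_stop(paste0("grouping does not map label(s): ",
                      paste(missing, collapse = ", ")),
               "mapping_incomplete_error")
    new_labs <- unname(grouping[labs])
    lvl <- unique(unname(grouping))
    out <- lapply(seq_along(x), function(i) {
      inst <- x[[i]]
      inst$class_label <- new_labs[i]
      inst$category_id <- match(new_labs[i], lvl)
      inst
    })
    return(out)
  }
  mcp_stop("x must be a named count vector or a list of nuclei_instance",
           "grouping_error")
}

#' Class map induced by a grouping
#'
#' @param grouping named character vector (original -> grouped label).
#' @return a [class_map()] over the grouped labels, intensities 1..K in
#'   first-appearance order.
#' @export
grouped_class_map <- function(grouping) {
  lvl <- unique(unname(grouping))
  class_map(lvl, seq_along(lvl))
}
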