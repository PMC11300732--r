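#' COCO annotation document
#'
#' In-memory representation of a COCO object-detection annotation file:
#' `images` and `categories` as data frames, `annotations` as a list (each
#' annotation holds a variable-length polygon segmentation).
#'
#' @param images data frame with columns `id`, `file_name`, `height`, `width`.
#' @param annotations list; each element a list with `id`, `image_id`,
#'   `category_id`, `segmentation` (list of flat polygons), `bbox`
#'   (`c(x, y, w, h)`), `area`, `iscrowd`.
#' @param categories data frame with columns `id`, `name`.
#' @return object of class `coco_document`.
#' @export
coco_document <- function(images, annotations, categories) {
  doc <- structure(list(images = images, annotations = annotations,
                        categories = categories),
                   class = "coco_document")
  validate_coco(doc)
  doc
}

#' Validate a COCO document's referential integrity
#'
#' Checks that annotation ids are unique, every `image_id` / `category_id`
#' resolves, and every area is positive.
#'
#' @param doc a [coco_document()].
#' @return the document, invisibly; errors otherwise.
#' @export
validate_coco <- function(doc) {
  req <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      mcp_stop(paste0(what, " must have columns ", paste(cols, collapse = ", ")),
               "coco_error")
  req(doc$images, c("id", "file_name", "height", "width"), "images")
  req(doc$categories, c("id", "name"), "categories")
  if (anyDuplicated(doc$images$id) || anyDuplicated(doc$categories$id))
    mcp_stop("image and category ids must be unique", "coco_error")
  ann_ids <- vapply(doc$annotations, function(a) as.numeric(a$id), numeric(1))
  if (anyDuplicated(ann_ids))
    mcp_stop("annotation ids must be unique", "coco_error")
  for (a in doc$annotations) {
    if (!(a$image_id %in% doc$images$id))
      mcp_stop(sprintf("annotation %s references unknown image_id %s",
                       a$id, a$image_id), "referential_integrity_error")
    if (!(a$category_id %in% doc$categories$id))
      mcp_stop(sprintf("annotation %s references unknown category_id %s",
                       a$id, a$category_id), "referential_integrity_error")
    if (is.null(a$area) || a$area <= 0)
      mcp_stop(sprintf("annotation %s has non-positive area", a$id),
               "invalid_annotation_error")
  }
  invisible(doc)
}

#' @export
print.coco_document <- function(x, ...) {
  cat(sprintf("<coco_document: %d image(s), %d annotation(s), %d categor%s>\n",
              nrow(x$images), length(x$annotations), nrow(x$categories),
              if (nrow(x$categories) == 1) "y" else "ies"))
  invisible(x)
}

#' Convert nuclei instances to a COCO document
#'
#' One annotation per instance; segmentation polygons are traced from the
#' binary mask at pixel-boundary resolution, `area` is the mask pixel count,
#' `bbox` the tight `c(x, y, w, h)` and `iscrowd` 0.
#'
#' @param instances_by_image named list (names = image ids as character) of
#'   lists of [nuclei_instance()].
#' @param class_map a [class_map()]; categories come from its
#'   label/category_id columns.
#' @param image_records data frame with `id`, `file_name`, `height`, `width`;
#'   every name of `instances_by_image` must appear in `id`.
#' @return a [coco_document()].
#' @export
annotations_to_coco <- function(instances_by_image, class_map, image_records) {
  stopifnot(inherits(class_map, "class_map"))
  categories <- data.frame(id = class_map$category_id, name = class_map$label,
                           stringsAsFactors = FALSE)
  categories <- categories[order(categories$id), ]
  annotations <- list()
  next_id <- 1L
  for (img_id in names(instances_by_image)) {
    rec <- image_records[as.character(image_records$id) == img_id, ]
    if (nrow(rec) != 1L)
      mcp_stop(paste0("no image record for image ", img_id),
               "referential_integrity_error")
    for (inst in instances_by_image[[img_id]]) {
      if (inst$bbox[1] + inst$bbox[3] > rec$width ||
          inst$bbox[2] + inst$bbox[4] > rec$height)
        mcp_stop(sprintf("instance %d outside image %s bounds",
                         inst$instance_id, img_id), "invalid_annotation_error")
      polys <- mask_to_polygons(inst$mask, inst$bbox[1], inst$bbox[2])
      annotations[[next_id]] <- list(
        id = next_id, image_id = rec$id, category_id = inst$category_id,
        segmentation = polys, bbox = as.numeric(inst$bbox),
        area = sum(inst$mask), iscrowd = 0L)
      next_id <- next_id + 1L
    }
  }
  coco_document(image_records, annotations, categories)
}

#' Convert a COCO document back to nuclei instances
#'
#' Polygons are rasterized back to binary masks (holes cannot round-trip;
#' everything else does exactly for pixel-boundary polygons). Instance ids are
#' assigned per image in annotation order.
#'
#' @param doc a [coco_document()].
#' @return named list (by image id) of lists of [nuclei_instance()].
#' @export
coco_to_annotations <- function(doc) {
  validate_coco(doc)
  cat_names <- stats::setNames(doc$categories$name,
                               as.character(doc$categories$id))
  out <- stats::setNames(
    vector("list", nrow(doc$images)), as.character(doc$images$id))
  out[] <- list(list())
  counters <- stats::setNames(integer(nrow(doc$images)),
                              as.character(doc$images$id))
  for (a in doc$annotations) {
    key <- as.character(a$image_id)
    rec <- doc$images[as.character(doc$images$id) == key, ]
    full <- polygons_to_mask(a$segmentation, rec$height, rec$width)
    if (!any(full))
      mcp_stop(sprintf("annotation %s rasterizes to an empty mask", a$id),
               "invalid_annotation_error")
    counters[key] <- counters[key] + 1L
    inst <- instance_from_full_mask(
      full, counters[key], cat_names[[as.character(a$category_id)]],
      as.integer(a$category_id), source_image_id = key)
    out[[key]] <- c(out[[key]], list(inst))
  }
  out
}

#' Read / write COCO JSON
#'
#' Standard top-level keys `images` / `annotations` / `categories`, UTF-8,
#' stable key ordering for diff-ability.
#'
#' @param path JSON file path.
#' @return `read_coco`: a [coco_document()].
#' @export
read_coco <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!all(c("images", "annotations", "categories") %in% names(raw)))
    mcp_stop("JSON lacks images/annotations/categories keys", "coco_error")
  images <- do.call(rbind, lapply(raw$images, function(im)
    data.frame(id = im$id, file_name = im$file_name,
               height = im$height, width = im$width, stringsAsFactors = FALSE)))
  categories <- do.call(rbind, lapply(raw$categories, function(ct)
    data.frame(id = ct$id, name = ct$name, stringsAsFactors = FALSE)))
  annotations <- lapply(raw$annotations, function(a) list(
    id = a$id, image_id = a$image_id, category_id = a$category_id,
    segmentation = lapply(a$segmentation, function(p) as.numeric(unlist(p))),
    bbox = as.numeric(unlist(a$bbox)), area = as.numeric(a$area),
    iscrowd = as.integer(a$iscrowd %||% 0L)))
  if (is.null(images)) images <- data.frame(id = integer(), file_name = character(),
                                            height = integer(), width = integer())
  if (is.null(categories)) categories <- data.frame(id = integer(), name = character())
  coco_document(images, annotations, categories)
}

#' @rdname read_coco
#' @param doc a [coco_document()].
#' @export
write_coco <- function(doc, path) {
  validate_coco(doc)
  payload <- list(
    images = lapply(seq_len(nrow(doc$images)), function(i) list(
      id = doc$images$id[i], file_name = doc$images$file_name[i],
      height = doc$images$height[i], width = doc$images$width[i])),
    annotations = lapply(doc$annotations, function(a) list(
      id = a$id, image_id = a$image_id, category_id = a$category_id,
      segmentation = lapply(a$segmentation, as.numeric),
      bbox = as.numeric(a$bbox), area = a$area, iscrowd = a$iscrowd)),
    categories = lapply(seq_len(nrow(doc$categories)), function(i) list(
      id = doc$categories$id[i], name = doc$categories$name[i]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
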