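test_that("3-channel parser extracts instances with class, tight bbox and order", {
  red <- matrix(0L, 20, 20); blue <- matrix(0L, 20, 20)
  red[6:10, 4:8] <- 3L; blue[6:10, 4:8] <- 1L
  trip <- mask_triplet(red, matrix(0L, 20, 20), blue)
  inst <- parse_three_channel_mask(trip, tiny_class_map())
  expect_length(inst, 1)
  expect_equal(inst[[1]]$class_label, "a")      # intensity 3
  expect_equal(inst[[1]]$category_id, 1L)
  expect_equal(inst[[1]]$bbox, c(3L, 5L, 5L, 5L))
  expect_true(all(inst[[1]]$mask))

  # all-zero mask -> empty list
  empty <- mask_triplet(matrix(0L, 8, 8), matrix(0L, 8, 8), matrix(0L, 8, 8))
  expect_length(parse_three_channel_mask(empty, tiny_class_map()), 0)

  # two disjoint blue regions sharing one red intensity -> same class twice
  red2 <- matrix(0L, 20, 20); blue2 <- matrix(0L, 20, 20)
  red2[2:4, 2:4] <- 3L; blue2[2:4, 2:4] <- 1L
  red2[10:12, 10:12] <- 3L; blue2[10:12, 10:12] <- 2L
  out <- parse_three_channel_mask(
    mask_triplet(red2, matrix(0L, 20, 20), blue2), tiny_class_map())
  expect_length(out, 2)
  expect_equal(vapply(out, `[[`, character(1), "class_label"), c("a", "a"))
})

test_that("parser rejects unknown intensities and inconsistent instances", {
  red <- matrix(0L, 10, 10); blue <- matrix(0L, 10, 10)
  red[2:4, 2:4] <- 7L; blue[2:4, 2:4] <- 1L   # 7 not in class map
  expect_error(
    parse_three_channel_mask(mask_triplet(red, matrix(0L, 10, 10), blue),
                             tiny_class_map()),
    class = "unknown_class_error", regexp = "7")

  red[2:4, 2:4] <- 3L; red[3, 3] <- 5L        # one instance, two intensities
  expect_error(
    parse_three_channel_mask(mask_triplet(red, matrix(0L, 10, 10), blue),
                             tiny_class_map()),
    class = "inconsistent_mask_error", regexp = "1")
})

test_that("render is the exact inverse of parse on non-overlapping instances", {
  cm <- tiny_class_map()
  # empty list -> all-zero triplet
  trip0 <- render_three_channel_mask(list(), cm, 12, 12)
  expect_true(all(trip0$red == 0L) && all(trip0$blue == 0L))

  # single instance roundtrip
  inst <- square_instance(4L, 2, 3, 4, label = "b", category_id = 2L)
  trip1 <- render_three_channel_mask(list(inst), cm, 15, 15)
  back1 <- parse_three_channel_mask(trip1, cm)
  expect_same_instances(list(inst), back1)
  expect_equal(trip1$red[5, 4], 5L)  # class "b" intensity

  # 50 random non-overlapping instances roundtrip exactly (seeded)
  set.seed(71)
  occupied <- matrix(FALSE, 120, 120)
  insts <- list()
  while (length(insts) < 50) {
    side <- sample(3:7, 1)
    x <- sample(0:(120 - side), 1); y <- sample(0:(120 - side), 1)
    if (any(occupied[(y + 1):(y + side), (x + 1):(x + side)])) next
    occupied[(y + 1):(y + side), (x + 1):(x + side)] <- TRUE
    lab <- sample(cm$label, 1)
    insts[[length(insts) + 1]] <- square_instance(
      length(insts) + 1L, x, y, side, label = lab,
      category_id = cm$category_id[cm$label == lab])
  }
  trip <- render_three_channel_mask(insts, cm, 120, 120)
  expect_same_instances(insts, parse_three_channel_mask(trip, cm))

  # green channel is carried verbatim, never interpreted
  g <- matrix(17L, 15, 15)
  trip_g <- render_three_channel_mask(list(inst), cm, 15, 15, green = g)
  expect_identical(trip_g$green, g)
  expect_same_instances(list(inst), parse_three_channel_mask(trip_g, cm))
})

test_that("render refuses overlapping instances, naming the colliding ids", {
  cm <- tiny_class_map()
  a <- square_instance(1L, 2, 2, 5)
  b <- square_instance(2L, 4, 4, 5)
  expect_error(render_three_channel_mask(list(a, b), cm, 20, 20),
               class = "overlap_error", regexp = "1.*2")
})

test_that("mask PNG files round-trip losslessly", {
  red <- matrix(0L, 9, 11); blue <- matrix(0L, 9, 11)
  red[2:5, 3:6] <- 3L; blue[2:5, 3:6] <- 42L
  trip <- mask_triplet(red, matrix(7L, 9, 11), blue)
  tf <- tempfile(fileext = ".png")
  write_mask_png(trip, tf)
  back <- read_mask_png(tf)
  expect_identical(back$red, trip$red)
  expect_identical(back$green, trip$green)
  expect_identical(back$blue, trip$blue)
})

test_that("annotations_to_coco produces valid polygon annotations", {
  cm <- tiny_class_map()
  inst <- square_instance(1L, 2, 3, 5)
  recs <- data.frame(id = "im1", file_name = "im1.png", height = 20,
                     width = 20, stringsAsFactors = FALSE)
  doc <- annotations_to_coco(list(im1 = list(inst)), cm, recs)
  a <- doc$annotations[[1]]
  expect_equal(a$area, 25)
  expect_equal(a$bbox, c(2, 3, 5, 5))
  expect_equal(a$iscrowd, 0L)
  expect_equal(nrow(doc$categories), 3)

  # zero images -> categories only
  doc0 <- annotations_to_coco(
    stats::setNames(list(), character(0)), cm,
    data.frame(id = character(), file_name = character(),
               height = integer(), width = integer()))
  expect_length(doc0$annotations, 0)
  expect_equal(nrow(doc0$categories), 3)
})

test_that("COCO conversion round-trips a synthetic multi-image dataset", {
  ds <- generate_dataset(small_spec(seed = 5), 3, seed = 9)
  back <- coco_to_annotations(ds$coco)
  expect_setequal(names(back), names(ds$instances))
  for (id in names(back)) {
    orig <- ds$instances[[id]]; rec <- back[[id]]
    expect_equal(length(rec), length(orig))
    for (i in seq_along(orig)) {
      a <- instance_full_mask(orig[[i]], 96, 96)
      b <- instance_full_mask(rec[[i]], 96, 96)
      expect_gte(sum(a & b) / sum(a | b), 0.98)
      expect_equal(rec[[i]]$class_label, orig[[i]]$class_label)
    }
  }
  # file write/read preserves the document
  tf <- tempfile(fileext = ".json")
  write_coco(ds$coco, tf)
  doc2 <- read_coco(tf)
  expect_equal(length(doc2$annotations), length(ds$coco$annotations))
  expect_equal(doc2$images$id, ds$coco$images$id)
  back2 <- coco_to_annotations(doc2)
  for (id in names(back)) expect_same_instances(back[[id]], back2[[id]])
})

test_that("coco_to_annotations validates referential integrity", {
  cm <- tiny_class_map()
  inst <- square_instance(1L, 2, 3, 5)
  recs <- data.frame(id = "im1", file_name = "im1.png", height = 20,
                     width = 20, stringsAsFactors = FALSE)
  doc <- annotations_to_coco(list(im1 = list(inst)), cm, recs)
  doc$annotations[[1]]$image_id <- "ghost"
  expect_error(coco_to_annotations(doc),
               class = "referential_integrity_error")
  # empty document -> empty grouping
  doc0 <- annotations_to_coco(
    stats::setNames(list(), character(0)), cm,
    data.frame(id = character(), file_name = character(),
               height = integer(), width = integer()))
  expect_length(coco_to_annotations(doc0), 0)
})

test_that("polygon tracing/rasterization is exact for hole-free shapes", {
  set.seed(31)
  for (rep in 1:20) {
    side <- sample(5:14, 1)
    m <- matrix(FALSE, side, side)
    # random blob: union of rectangles, always hole-free enough in practice
    for (k in 1:3) {
      r <- sort(sample(seq_len(side), 2)); c <- sort(sample(seq_len(side), 2))
      m[r[1]:r[2], c[1]:c[2]] <- TRUE
    }
    polys <- mask_to_polygons(m)
    back <- polygons_to_mask(polys, side, side)
    expect_true(all(back[m]))  # no filled pixel is lost (holes may be filled)
  }
  # simply connected case is exact
  disc <- outer(1:11, 1:11, function(i, j) (i - 6)^2 + (j - 6)^2 <= 20)
  expect_identical(polygons_to_mask(mask_to_polygons(disc), 11, 11), disc)
})

test_that("group_classes sums counts, rewrites labels and conserves totals", {
  counts <- c(tumor = 10, stroma = 4, other = 1)
  ident <- stats::setNames(names(counts), names(counts))
  expect_equal(group_classes(counts, ident), counts)

  g <- c(tumor = "tumor", stroma = "rest", other = "rest")
  expect_equal(group_classes(counts, g), c(tumor = 10, rest = 5))

  expect_error(group_classes(counts, g[1:2]),
               class = "mapping_incomplete_error", regexp = "other")

  # conservation on random vectors
  set.seed(4)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    v <- stats::setNames(rpois(k, 20), paste0("c", seq_len(k)))
    gr <- stats::setNames(paste0("g", sample(1:3, k, replace = TRUE)),
                          names(v))
    expect_equal(sum(group_classes(v, gr)), sum(v))
  }

  # instance regrouping rewrites labels and conserves count
  insts <- list(square_instance(1L, 0, 0, 3, label = "stroma"),
                square_instance(2L, 5, 5, 3, label = "other"))
  out <- group_classes(insts, g)
  expect_equal(vapply(out, `[[`, character(1), "class_label"),
               c("rest", "rest"))
  expect_length(out, 2)
})

test_that("built-in groupings reproduce the published dataset configurations", {
  tab <- nucls_table_counts()
  counts <- stats::setNames(tab$ipemrd, tab$label)
  g1 <- group_classes(counts, grouping_preset("config1"))
  expect_equal(unname(g1), sum(counts))
  expect_equal(names(g1), "Nuclei")

  g2 <- group_classes(counts, grouping_preset("config2"))
  expect_equal(sum(g2), sum(counts))
  expect_equal(unname(g2[["Other nuclei"]]), 5 + 0 + 6 + 0 + 0)
  expect_equal(unname(g2[["Ambiguous"]]), 13 + 150)
})
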