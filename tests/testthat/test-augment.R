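test_that("location threshold equals the union of instance masks", {
  lt0 <- build_location_threshold(list(), 30, 30)
  expect_false(any(lt0))

  one <- square_instance(1L, 4, 6, 5)
  lt1 <- build_location_threshold(list(one), 30, 30)
  expect_equal(sum(lt1), 25)

  scene <- generate_scene(small_spec(seed = 12))
  lt <- build_location_threshold(scene$instances, 96, 96)
  expect_identical(unclass(lt)[, ], oracle_mask_union(scene$instances, 96, 96)[, ])
})

test_that("missing_classes is the set difference against the class universe", {
  all_cls <- c("a", "b", "c", "d")
  insts <- list(square_instance(1L, 0, 0, 3, label = "a"),
                square_instance(2L, 5, 5, 3, label = "c"))
  expect_setequal(missing_classes(insts, all_cls), c("b", "d"))
  expect_length(missing_classes(insts, c("a", "c")), 0)
  expect_setequal(missing_classes(list(), all_cls), all_cls)
  expect_error(missing_classes(insts, c("a")), class = "unknown_class_error")
})

test_that("choose_instances samples k per chosen missing class, reproducibly", {
  pool <- list(a = lapply(1:5, function(i) square_instance(i, 0, 0, 3, label = "a")),
               b = list())
  cfg <- augment_config(1, 2, seed = 7)

  empty <- choose_instances(character(0), pool, cfg)
  expect_length(empty$items, 0)

  set.seed(7)
  got <- choose_instances("a", pool, cfg)
  expect_length(got$items, 2)
  expect_equal(got$classes, c("a", "a"))

  set.seed(7)
  again <- choose_instances("a", pool, cfg)
  expect_identical(vapply(got$items, `[[`, integer(1), "instance_id"),
                   vapply(again$items, `[[`, integer(1), "instance_id"))

  expect_warning(choose_instances("b", pool, cfg),
                 class = "empty_pool_warning")
})

test_that("proposed points respect the open-interval margins of the occupancy grid", {
  lt <- build_location_threshold(list(), 100, 100)
  set.seed(5)
  for (i in 1:10000) {
    pt <- propose_point(lt, 10, 10)
    expect_true(pt$p0[["x"]] > 5 && pt$p0[["x"]] < 95)
    expect_true(pt$p0[["y"]] > 5 && pt$p0[["y"]] < 95)
  }
  expect_error(propose_point(build_location_threshold(list(), 8, 8), 10, 10),
               class = "no_valid_location_error")
})

test_that("the eight probes sit at the half-size offsets around the center", {
  lt <- build_location_threshold(list(), 50, 50)
  set.seed(9)
  pt <- propose_point(lt, 4, 4)
  x <- pt$p0[["x"]]; y <- pt$p0[["y"]]
  expected <- rbind(c(x - 2, y - 2), c(x, y - 2), c(x + 2, y - 2),
                    c(x - 2, y),                  c(x + 2, y),
                    c(x - 2, y + 2), c(x, y + 2), c(x + 2, y + 2))
  expect_equal(nrow(pt$probe_points), 8)  # nine points counting the center
  got <- pt$probe_points[order(pt$probe_points[, 2], pt$probe_points[, 1]), ]
  exp <- expected[order(expected[, 2], expected[, 1]), ]
  expect_equal(unname(got), unname(exp))

  # odd sizes use floored half-sizes and stay in bounds
  pt3 <- propose_point(lt, 5, 7)
  expect_true(all(pt3$probe_points >= 0) && all(pt3$probe_points <= 49))
})

test_that("nine-point occupancy test matches a direct pixel oracle", {
  set.seed(13)
  free_lt <- build_location_threshold(list(), 40, 40)
  full_lt <- free_lt | TRUE
  pt <- propose_point(free_lt, 6, 6)
  expect_true(is_location_free(free_lt, pt))
  expect_false(is_location_free(full_lt, pt))

  for (i in 1:500) {
    lt <- matrix(runif(40 * 40) < 0.3, 40, 40)
    pt <- propose_point(lt, 6, 8)
    xs <- c(pt$p0[["x"]], pt$probe_points[, 1])
    ys <- c(pt$p0[["y"]], pt$probe_points[, 2])
    oracle <- all(!lt[cbind(ys + 1, xs + 1)])
    expect_identical(is_location_free(lt, pt), oracle)
  }
})

test_that("paste_instance composites through the mask and updates GT and LT", {
  h <- 40; w <- 40
  image <- array(0.9, dim = c(h, w, 3))
  lt <- build_location_threshold(list(), h, w)
  inst <- square_instance(99L, 0, 0, 6, color = c(0.1, 0.2, 0.3))
  set.seed(3)
  pt <- propose_point(lt, 6, 6)
  res <- paste_instance(image, list(), lt, inst, pt)

  expect_length(res$gt_instances, 1)
  expect_equal(sum(res$lt), 36)
  pasted <- res$gt_instances[[1]]
  expect_equal(pasted$bbox[3:4], c(6L, 6L))
  # pixels outside the pasted mask are bitwise unchanged
  outside <- !instance_full_mask(pasted, h, w)
  for (ch in 1:3)
    expect_identical(res$image[, , ch][outside], image[, , ch][outside])
  # pixels inside carry the crop
  expect_equal(unique(res$image[, , 1][!outside]), 0.1)

  # re-rendered triplet parses back to the pasted instance
  cm <- class_map("a", 1L)
  trip <- render_three_channel_mask(res$gt_instances, cm, h, w)
  expect_same_instances(res$gt_instances, parse_three_channel_mask(trip, cm))

  # pasting on an occupied location is a caller bug
  expect_error(paste_instance(res$image, res$gt_instances, res$lt, inst, pt),
               class = "contract_error")
})

test_that("augment_image follows the five-step cycle and logs outcomes", {
  scene <- generate_scene(small_spec(seed = 2, probs = c(1, 0, 0)))
  pool <- list(
    lymphocyte = list(square_instance(7L, 0, 0, 5, label = "lymphocyte",
                                      category_id = 2L)),
    stromal = list(square_instance(8L, 0, 0, 5, label = "stromal",
                                   category_id = 3L)))
  all_cls <- c("tumor", "lymphocyte", "stromal")

  # n = 0: no-op
  set.seed(1)
  res0 <- augment_image(scene$image, scene$instances, pool,
                        augment_config(0, 1), all_cls)
  expect_identical(res0$image, scene$image)
  expect_equal(nrow(res0$paste_log), 0)

  # image already containing every class: nothing attempted
  full_scene <- generate_scene(small_spec(seed = 4, probs = c(1, 1, 1) / 3,
                                          n_nuclei = c(30L, 30L)))
  present <- unique(vapply(full_scene$instances, `[[`, character(1),
                           "class_label"))
  if (length(present) == 3) {
    res1 <- augment_image(full_scene$image, full_scene$instances, pool,
                          augment_config(3, 2), all_cls)
    expect_equal(nrow(res1$paste_log), 0)
  }

  # fully occupied grid: every item rejected, ground truth unchanged
  blocked <- square_instance(1L, 0, 0, 96, label = "tumor")
  set.seed(6)
  res2 <- augment_image(array(0.5, dim = c(96, 96, 3)), list(blocked), pool,
                        augment_config(2, 2), all_cls)
  expect_length(res2$gt_instances, 1)
  expect_true(all(res2$paste_log$outcome != "pasted"))

  # LT stays equal to the union of GT masks after every paste
  set.seed(11)
  res3 <- augment_image(scene$image, scene$instances, pool,
                        augment_config(2, 3), all_cls)
  expect_identical(unclass(res3$lt)[, ],
                   oracle_mask_union(res3$gt_instances, 96, 96)[, ])

  # determinism under a fixed seed
  set.seed(42)
  a <- augment_image(scene$image, scene$instances, pool,
                     augment_config(2, 3), all_cls)
  set.seed(42)
  b <- augment_image(scene$image, scene$instances, pool,
                     augment_config(2, 3), all_cls)
  expect_identical(a$image, b$image)
  expect_identical(a$paste_log, b$paste_log)
})

test_that("augment_dataset rebalances, conserves and never drops classes", {
  spec <- small_spec(seed = 20, probs = c(0.9, 0.08, 0.02))
  ds <- generate_dataset(spec, 6, seed = 20)
  cfg <- augment_config(3, 4, seed = 99)
  res <- augment_dataset(list(images = ds$images, instances = ds$instances),
                         cfg, all_classes = spec$class_labels)

  # before counts come straight from the per-image ground truth
  flat <- unlist(ds$instances, recursive = FALSE, use.names = FALSE)
  expect_equal(res$summary$before,
               unname(count_instances(flat, spec$class_labels)))
  # per-image class sets never shrink
  for (id in names(ds$instances)) {
    before_cls <- unique(vapply(ds$instances[[id]], `[[`, character(1),
                                "class_label"))
    after_cls <- unique(vapply(res$instances[[id]], `[[`, character(1),
                               "class_label"))
    expect_true(all(before_cls %in% after_cls))
  }
  # counts only grow
  expect_true(all(res$summary$after >= res$summary$before))

  # dataset where every image has all classes is untouched
  rich <- generate_dataset(small_spec(seed = 21, probs = c(1, 1, 1) / 3,
                                      n_nuclei = c(40L, 40L)), 3, seed = 21)
  has_all <- all(vapply(rich$instances, function(l)
    length(unique(vapply(l, `[[`, character(1), "class_label"))) == 3,
    logical(1)))
  if (has_all) {
    res_rich <- augment_dataset(list(images = rich$images,
                                     instances = rich$instances),
                                cfg, all_classes = spec$class_labels)
    expect_equal(res_rich$summary$after, res_rich$summary$before)
  }
})

test_that("random flips transform image, masks and boxes consistently", {
  scene <- generate_scene(small_spec(seed = 30))
  # ratio 0 is the identity
  res <- random_flip(scene$image, scene$instances, ratio = 0)
  expect_identical(res$image, scene$image)

  # forced double flip is the identity
  f1 <- random_flip(scene$image, scene$instances, force = c(TRUE, TRUE))
  f2 <- random_flip(f1$image, f1$gt_instances, force = c(TRUE, TRUE))
  expect_identical(f2$image, scene$image)
  expect_same_instances(f2$gt_instances, scene$instances)

  # flipped bbox equals tight bounds of the flipped full mask
  for (inst in f1$gt_instances[1:5]) {
    full <- instance_full_mask(inst, 96, 96)
    rows <- range(which(rowSums(full) > 0)); cols <- range(which(colSums(full) > 0))
    expect_equal(inst$bbox,
                 c(cols[1] - 1L, rows[1] - 1L,
                   cols[2] - cols[1] + 1L, rows[2] - rows[1] + 1L))
  }
})
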