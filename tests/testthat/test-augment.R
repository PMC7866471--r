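test_that("coordinate channels match the normalized-grid definition", {
  mg <- meshgrid_channels(2, 2)
  expect_equal(mg[, , 1], matrix(c(0, 1, 0, 1), 2, 2))   # Y: rows
  expect_equal(mg[, , 2], matrix(c(0, 0, 1, 1), 2, 2))   # X: columns

  # degenerate single-pixel axis: 0/0 defined as 0
  mg1 <- meshgrid_channels(1, 1)
  expect_equal(dim(mg1), c(1, 1, 2))
  expect_true(all(mg1 == 0))

  # transposition symmetry between the two channels
  for (hw in list(c(3, 5), c(4, 4), c(1, 7))) {
    a <- meshgrid_channels(hw[1], hw[2])
    b <- meshgrid_channels(hw[2], hw[1])
    expect_equal(t(matrix(a[, , 1], hw[1], hw[2])),
                 matrix(b[, , 2], hw[2], hw[1]))
  }
  expect_error(meshgrid_channels(0, 4), "positive")
})

test_that("appending coordinate channels twice is rejected", {
  s <- append_meshgrid(tiny_sample())
  expect_equal(dim(s$image)[3], 3)
  expect_error(append_meshgrid(s), "already")
})

test_that("flips are involutions and move the lumen centroid as mirrors", {
  s <- tiny_sample(6)
  for (dir in c("up-down", "left-right")) {
    twice <- apply_flip(apply_flip(s, dir), dir)
    expect_equal(twice$image, s$image)
    expect_equal(twice$mask, s$mask)
  }
  ctr <- function(m) colMeans(which(m == 1L, arr.ind = TRUE))
  c0 <- ctr(s$mask)
  clr <- ctr(apply_flip(s, "left-right")$mask)
  expect_equal(unname(clr[1]), unname(c0[1]))
  expect_equal(unname(clr[2]), ncol(s$mask) + 1 - unname(c0[2]))
  cud <- ctr(apply_flip(s, "up-down")$mask)
  expect_equal(unname(cud[1]), nrow(s$mask) + 1 - unname(c0[1]))
  expect_error(apply_flip(s, "diagonal"), "unknown flip")
})

test_that("right-angle rotations form the cyclic group of order 4", {
  s <- tiny_sample(4)
  r <- s
  for (i in 1:4) r <- apply_rotation(r, 90)
  expect_equal(r$image, s$image)
  expect_equal(r$mask, s$mask)
  # 180 = 90 twice; 270 = 90 three times
  expect_equal(apply_rotation(s, 180)$mask,
               apply_rotation(apply_rotation(s, 90), 90)$mask)
  expect_equal(apply_rotation(s, 270)$image,
               apply_rotation(apply_rotation(apply_rotation(s, 90), 90), 90)$image)
  # pixel-count histogram is invariant under rotation
  for (ang in c(90, 180, 270)) {
    expect_equal(table(apply_rotation(s, ang)$mask), table(s$mask))
  }
  expect_error(apply_rotation(s, 45), "90, 180, 270")
  ns <- tiny_sample(4)
  ns$image <- array(0, c(4, 6, 1)); ns$mask <- matrix(0L, 4, 6)
  expect_error(apply_rotation(ns, 90), "square")
})

test_that("image and mask stay pixel-aligned under every transform", {
  # transform an indicator image equal to the mask and compare
  set.seed(31)
  for (rep in 1:10) {
    mask <- random_mask(8)
    s <- as_sample(new_frame(matrix(mask / 2, 8, 8)), new_label_mask(mask))
    cfg <- strategy_config("meshgrid_flip_rotate")
    out <- random_augment(s, cfg)
    expect_equal(out$image[, , 1], out$mask / 2)
  }
})

test_that("the identity strategy returns the sample unchanged", {
  s <- tiny_sample()
  out <- random_augment(s, strategy_config("none"))
  expect_identical(out$image, s$image)
  expect_identical(out$mask, s$mask)
})

test_that("augmentation draws are reproducible under a fixed seed", {
  s <- tiny_sample(8)
  cfg <- strategy_config("meshgrid_flip_rotate")
  a <- random_augment(s, cfg, seed = 99)
  b <- random_augment(s, cfg, seed = 99)
  expect_identical(a$image, b$image)
  expect_identical(a$meta$ops, b$meta$ops)
})

test_that("rotation options are drawn uniformly (10,000 draws, 0.25 +/- 0.02)", {
  cfg <- strategy_config("flip_rotate")
  set.seed(1234)
  rot <- replicate(10000, ivusseg:::draw_augment_ops(cfg)$rotation)
  freq <- table(factor(rot, levels = c(0, 90, 180, 270))) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.02))
  flip <- replicate(3000, ivusseg:::draw_augment_ops(cfg)$flip)
  expect_setequal(unique(flip), c("none", "up-down", "left-right"))
})

test_that("coordinate channels travel with the image under transforms by default", {
  s <- append_meshgrid(tiny_sample(4))
  rot <- apply_rotation(s, 90)
  mg <- meshgrid_channels(4, 4)
  rot90 <- function(m) t(m)[4:1, ]
  expect_equal(rot$image[, , 2], rot90(mg[, , 1]))
  expect_equal(rot$image[, , 3], rot90(mg[, , 2]))
  # invariant mode regenerates coordinates after the transform instead
  cfg <- augment_config(enable_rotate = TRUE, enable_meshgrid = TRUE,
                        meshgrid_invariant = TRUE)
  set.seed(5)
  out <- random_augment(tiny_sample(4), cfg)
  expect_equal(out$image[, , 2], mg[, , 1])
  expect_equal(out$image[, , 3], mg[, , 2])
})

test_that("additive MeshGrid mode perturbs intensities without extra channels", {
  cfg <- augment_config(enable_meshgrid = TRUE, meshgrid_mode = "add")
  s <- tiny_sample(4)
  out <- random_augment(s, cfg)
  expect_equal(dim(out$image)[3], 1)
  mg <- meshgrid_channels(4, 4)
  expect_equal(out$image[, , 1], s$image[, , 1] + 0.5 * (mg[, , 1] + mg[, , 2]))
})

test_that("strategy names map to the documented flag triples", {
  expect_equal(strategy_channels(strategy_config("none")), 1L)
  expect_equal(strategy_channels(strategy_config("flip_rotate")), 1L)
  expect_equal(strategy_channels(strategy_config("meshgrid")), 3L)
  expect_equal(strategy_channels(strategy_config("meshgrid_flip_rotate")), 3L)
  cfg <- strategy_config("flip_rotate")
  expect_true(cfg$enable_flip && cfg$enable_rotate && !cfg$enable_meshgrid)
  expect_equal(cfg$rotation_angles, c(90, 180, 270))
  expect_error(strategy_config("zoom"), "unknown augmentation strategy")
})
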