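test_that("noiseless concentric config yields circular lumen of the expected area", {
  cfg <- phantom_config(image_size = 128L, lumen_radius_range = c(0.15, 0.15),
                        wall_thickness_range = c(0.06, 0.06),
                        eccentricity_max = 0, axis_ratio_range = c(1, 1),
                        speckle_scale = 0, gradient_strength = 0)
  ph <- make_phantom(cfg, seed = 5)
  r <- 0.15 * 128
  lumen_px <- sum(ph$mask$labels == 1L)
  # rasterization can deviate from the analytic area by at most ~one
  # one-pixel-wide band along the circumference
  expect_lt(abs(lumen_px - pi * r^2), 2 * pi * r)
  # concentric: lumen centroid at the image centre within a pixel
  ctr <- which(ph$mask$labels == 1L, arr.ind = TRUE)
  expect_lt(abs(mean(ctr[, 1]) - (128 / 2 + 0.5)), 1)
  expect_lt(abs(mean(ctr[, 2]) - (128 / 2 + 0.5)), 1)
})

test_that("same config and seed reproduce the phantom bit for bit", {
  cfg <- tiny_phantom_config()
  a <- make_phantom(cfg, seed = 11)
  b <- make_phantom(cfg, seed = 11)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  c <- make_phantom(cfg, seed = 12)
  expect_false(identical(a$frame$pixels, c$frame$pixels))
})

test_that("every phantom satisfies nesting, intensity range and class balance", {
  cfg <- tiny_phantom_config()
  for (seed in 1:20) {
    ph <- make_phantom(cfg, seed = seed)
    lab <- ph$mask$labels
    expect_setequal(unique(as.vector(lab)), 0:2)
    # lumen strictly inside the EEM-enclosed region
    expect_true(all(lab[lab == 1L] >= 0))
    eem_region <- lab >= 1L
    expect_true(all(eem_region[lab == 1L]))
    # intensities in [0, 1], speckle never touches labels
    expect_gte(min(ph$frame$pixels), 0)
    expect_lte(max(ph$frame$pixels), 1)
    # background majority; structures above 0.5% of pixels each
    n <- length(lab)
    expect_gt(sum(lab == 0L) / n, 0.5)
    expect_gt(sum(lab == 1L) / n, 0.005)
    expect_gt(sum(lab == 2L) / n, 0.005)
  }
})

test_that("lumen region is simply connected (single 4-connected component)", {
  cfg <- tiny_phantom_config()
  n_components <- function(mask, cls) {
    lab <- mask == cls
    seen <- matrix(FALSE, nrow(lab), ncol(lab))
    comps <- 0
    for (start in which(lab & !seen)) {
      if (seen[start]) next
      comps <- comps + 1
      queue <- start
      seen[start] <- TRUE
      nr <- nrow(lab)
      while (length(queue)) {
        q <- queue[length(queue)]; queue <- queue[-length(queue)]
        r <- (q - 1) %% nr + 1; cc <- (q - 1) %/% nr + 1
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + d[1]; ccc <- cc + d[2]
          if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= ncol(lab)) {
            qq <- rr + nr * (ccc - 1)
            if (lab[qq] && !seen[qq]) { seen[qq] <- TRUE; queue <- c(queue, qq) }
          }
        }
      }
    }
    comps
  }
  for (seed in c(2, 9)) {
    ph <- make_phantom(cfg, seed = seed)
    expect_equal(n_components(ph$mask$labels, 1L), 1)
    expect_equal(n_components(ph$mask$labels >= 1L, TRUE), 1)
  }
})

test_that("corpus carries per-patient geometry and a disjoint patient split", {
  cfg <- tiny_phantom_config()
  ds <- make_corpus(cfg, n_patients = 5L, frames_per_patient = 4L, seed = 3L,
                    n_train_patients = 4L)
  expect_length(ds$frames, 20)
  expect_equal(length(unique(ds$patient_id)), 5)
  expect_equal(sum(ds$split == "train"), 4)
  expect_equal(sum(ds$split == "test"), 1)
  train_p <- names(ds$split)[ds$split == "train"]
  test_p <- names(ds$split)[ds$split == "test"]
  expect_length(intersect(train_p, test_p), 0)
  # frames of one patient are correlated: within-patient lumen-area spread
  # well below the between-patient spread
  areas <- vapply(seq_along(ds$frames),
                  function(i) sum(ds$masks[[i]]$labels == 1L), numeric(1))
  by_pat <- split(areas, ds$patient_id)
  within <- mean(vapply(by_pat, sd, numeric(1)))
  between <- sd(vapply(by_pat, mean, numeric(1)))
  expect_lt(within, between)
  # different corpus seeds draw different geometry
  ds2 <- make_corpus(cfg, n_patients = 5L, frames_per_patient = 4L, seed = 4L,
                     n_train_patients = 4L)
  expect_false(identical(ds$frames[[1]]$pixels, ds2$frames[[1]]$pixels))
})

test_that("corpus generation rejects impossible splits and bad configs", {
  cfg <- tiny_phantom_config()
  expect_error(make_corpus(cfg, n_patients = 1L, frames_per_patient = 3L),
               "patient-wise split")
  expect_error(phantom_config(catheter_radius = 0.2), "catheter_radius")
  expect_error(phantom_config(lumen_radius_range = c(0.4, 0.3)),
               "lumen_radius_range")
  expect_error(phantom_config(gradient_strength = 1.5), "gradient_strength")
  expect_error(phantom_config(lumen_radius_range = c(0.2, 0.3),
                              wall_thickness_range = c(0.2, 0.25)),
               "wall_thickness_range")
})

test_that("written corpus round-trips through its manifest", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config()
  ds <- make_corpus(cfg, n_patients = 3L, frames_per_patient = 2L, seed = 8L,
                    n_train_patients = 2L)
  manifest <- write_corpus(ds, dir)
  expect_true(file.exists(manifest))
  ds2 <- load_dataset(manifest)
  expect_length(ds2$frames, 6)
  expect_identical(ds2$masks[[1]]$labels, ds$masks[[1]]$labels)
  expect_equal(sort(names(ds2$split)), sort(names(ds$split)))
  # images survive up to 8-bit quantization
  expect_lt(max(abs(ds2$frames[[1]]$pixels - ds$frames[[1]]$pixels)), 1 / 255)
})
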