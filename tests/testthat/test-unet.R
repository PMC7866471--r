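test_that("layer trace halves and doubles spatial sizes exactly", {
  cfg <- model_config(input_size = 128L, depth = 4L, base_channels = 4L,
                      max_channels = 64L)
  tr <- layer_trace(cfg)
  enc <- tr$spatial[grepl("^enc", tr$block)]
  dec <- tr$spatial[grepl("^dec", tr$block)]
  expect_equal(enc, c(128, 64, 32, 16, 8))
  expect_equal(dec, c(16, 32, 64, 128))
  # channel schedule doubles up to the cap
  expect_equal(tr$channels[grepl("^enc", tr$block)], c(4, 8, 16, 32, 64))
})

test_that("configuration invariants are enforced with informative errors", {
  expect_error(model_config(input_size = 100L, depth = 8L), "divisible by 2\\^depth")
  expect_error(model_config(input_size = 256L, depth = 8L), "bottleneck")
  expect_error(model_config(num_classes = 1L), "num_classes")
  expect_error(model_config(input_channels = 2L), "input_channels")
})

test_that("the full-scale architecture has 9 encoder blocks, 8 decoder blocks and a 2x2 bottleneck", {
  cfg <- model_config(input_size = 512L, depth = 8L, base_channels = 8L,
                      max_channels = 128L)
  tr <- layer_trace(cfg)
  expect_equal(sum(grepl("^enc", tr$block)), 9)
  expect_equal(sum(grepl("^dec", tr$block)), 8)
  expect_equal(min(tr$spatial), 2)
  m <- build_unet(cfg, seed = 1)
  # encoder blocks materialized in the parameter list
  expect_true(all(sprintf("enc%d.c1.w", 1:9) %in% names(m$params)))
  expect_false("enc10.c1.w" %in% names(m$params))
  expect_true(all(sprintf("dec%d.c1.w", 1:8) %in% names(m$params)))
})

test_that("forward output is a per-pixel probability simplex of the right shape", {
  cfg <- model_config(input_size = 32L, depth = 3L, base_channels = 4L,
                      max_channels = 32L)
  m <- build_unet(cfg, seed = 2)
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  p <- unet_forward(m, x)
  expect_equal(dim(p), c(32, 32, 3, 2))
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p, c(1, 2, 4), sum) - 1)), 1e-5)
})

test_that("inference is deterministic and input shapes are validated", {
  cfg <- model_config(input_size = 32L, depth = 2L, base_channels = 4L,
                      max_channels = 16L)
  m <- build_unet(cfg, seed = 3)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(unet_forward(m, x), unet_forward(m, x))
  bad <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_error(unet_forward(m, bad), "dimension error.*32x32.*16x16")
  bad3 <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_error(unet_forward(m, bad3), "expected 1 channels, got 3")
})

test_that("encoder channels are non-decreasing and capped", {
  cfg <- model_config(input_size = 256L, depth = 7L, base_channels = 4L,
                      max_channels = 32L)
  ch <- ivusseg:::unet_channels(cfg)
  expect_true(all(diff(ch) >= 0))
  expect_equal(max(ch), 32)
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- model_config(input_size = 64L, depth = 3L, base_channels = 4L,
                      max_channels = 32L)
  m1 <- build_unet(cfg, seed = 1)
  m2 <- build_unet(cfg, seed = 999)
  expect_equal(count_parameters(m1), count_parameters(m2))
  # independent count from the architecture definition
  ch <- c(4, 8, 16, 32)
  conv_n <- function(k, ci, co) k * k * ci * co + co
  bn_n <- function(c) 2 * c
  expected <- 0
  for (b in 1:4) {
    cin <- if (b == 1) 1 else ch[b]
    expected <- expected + conv_n(3, cin, ch[b]) + bn_n(ch[b]) +
      conv_n(3, ch[b], ch[b]) + bn_n(ch[b])
    if (b <= 3) expected <- expected + conv_n(3, ch[b], ch[b + 1]) + bn_n(ch[b + 1])
  }
  for (d in 1:3) {
    expected <- expected + (5 * 5 * ch[d] * ch[d + 1] + ch[d]) + bn_n(ch[d]) +
      conv_n(3, 2 * ch[d], ch[d]) + bn_n(ch[d]) +
      conv_n(3, ch[d], ch[d]) + bn_n(ch[d])
  }
  expected <- expected + conv_n(1, ch[1], 3)
  expect_equal(count_parameters(m1), expected)
})

test_that("probability decoding breaks ties toward the lowest class", {
  u <- array(1 / 3, c(4, 4, 3))
  expect_true(all(decode_probs(u)$labels == 0L))
  onehot <- array(0, c(2, 2, 3))
  layout <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  for (r in 1:2) for (c in 1:2) onehot[r, c, layout[r, c] + 1] <- 1
  expect_equal(decode_probs(onehot)$labels, layout)
})

test_that("an untrained model still yields a valid mask and checkpoints round-trip", {
  cfg <- model_config(input_size = 32L, depth = 2L, base_channels = 4L,
                      max_channels = 16L, input_channels = 3L)
  m <- build_unet(cfg, seed = 4)
  frame <- new_frame(matrix(runif(32 * 32), 32, 32))
  mask <- predict_mask(m, frame)
  expect_true(all(mask$labels %in% 0:2))
  # strategy/channel mismatch is rejected
  expect_error(predict_mask(m, frame, strategy_config("none")),
               "channel mismatch")
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_identical(predict_mask(m2, frame)$labels, mask$labels)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$depth, 2)
  expect_equal(sidecar$input_channels, 3)
})

test_that("fused batch-norm/LeakyReLU kernel matches the plain R reference", {
  set.seed(77)
  x <- array(rnorm(6 * 6 * 3 * 4), c(6, 6, 3, 4))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  run <- list(mean = rep(0, 3), var = rep(1, 3))
  ref <- ivusseg:::bn_fwd(x, gamma, beta, TRUE, run)
  refy <- ivusseg:::lrelu_fwd(ref$y, 0.01)
  got <- ivusseg:::cpp_bn_act_fwd(x, gamma, beta, run$mean, run$var,
                                  TRUE, 0.1, 1e-5, 0.01, TRUE)
  expect_equal(got$y, refy, tolerance = 1e-12)
  expect_equal(got$rmean, ref$run$mean, tolerance = 1e-12)
  expect_equal(got$rvar, ref$run$var, tolerance = 1e-12)
})
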