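test_that("confusion matrix matches counting identities and the double-loop oracle", {
  # perfect agreement: diagonal with row sums equal to class pixel counts
  t1 <- random_mask(12)
  cm <- confusion_matrix(t1, t1, k = 2)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(unname(diag(cm)), unname(tabulate(factor(t1, levels = 0:2))))

  # total disagreement concentrates in one off-diagonal cell
  cm2 <- confusion_matrix(matrix(2L, 10, 10), matrix(1L, 10, 10), k = 2)
  expect_equal(unname(cm2[2, 3]), 100)
  expect_equal(sum(cm2), 100)

  # random pairs equal the brute-force tally
  set.seed(14)
  for (rep in 1:5) {
    p <- random_mask(16); t_ <- random_mask(16)
    expect_equal(unname(unclass(confusion_matrix(p, t_, 2))),
                 oracle_confusion(p, t_, 2))
  }
  expect_error(confusion_matrix(random_mask(4), random_mask(5), 2),
               "shape mismatch")
  expect_error(confusion_matrix(matrix(3L, 2, 2), matrix(0L, 2, 2), 2),
               "outside")
})

test_that("per-class IoU follows its defining ratio including the undefined rule", {
  t1 <- matrix(0L, 20, 20); t1[1:10, 1:10] <- 1L      # class 1: 100 px
  p1 <- matrix(0L, 20, 20); p1[6:10, 1:10] <- 1L      # 50 hit
  p1[11:15, 1:10] <- 1L                               # 50 false positives
  cm <- confusion_matrix(p1, t1, k = 2)
  iou <- iou_per_class(cm)
  expect_equal(unname(iou[2]), 50 / 150)
  # class 2 absent from truth and prediction: undefined, excluded from mean
  expect_true(is.na(iou[3]))
  expect_equal(miou(cm), mean(iou[1:2]))

  perfect <- confusion_matrix(t1, t1, k = 2)
  expect_true(all(iou_per_class(perfect)[1:2] == 1))
  expect_equal(miou(perfect), 1)
})

test_that("mean IoU equals the brute-force per-pixel evaluation on random masks", {
  set.seed(3)
  for (rep in 1:50) {
    p <- random_mask(16); t_ <- random_mask(16)
    expect_equal(miou(confusion_matrix(p, t_, 2)), oracle_miou(p, t_, 2),
                 tolerance = 1e-12)
  }
})

test_that("confusion matrices accumulate across frames (micro-averaging identity)", {
  set.seed(8)
  ps <- lapply(1:4, function(i) random_mask(10))
  ts <- lapply(1:4, function(i) random_mask(10))
  summed <- Reduce(`+`, Map(function(p, t_) confusion_matrix(p, t_, 2), ps, ts))
  pooled <- confusion_matrix(do.call(rbind, ps), do.call(rbind, ts), 2)
  expect_equal(unclass(summed), unclass(pooled), ignore_attr = TRUE)
  expect_equal(miou(summed), miou(pooled))
})

test_that("swapping prediction and truth transposes the matrix and preserves IoU", {
  set.seed(4)
  p <- random_mask(12); t_ <- random_mask(12)
  a <- confusion_matrix(p, t_, 2)
  b <- confusion_matrix(t_, p, 2)
  expect_equal(unclass(a), t(unclass(b)), ignore_attr = TRUE)
  expect_equal(iou_per_class(a), iou_per_class(b))
})

test_that("mask-list evaluation handles oracle and degenerate predictors", {
  cfg <- tiny_phantom_config()
  truths <- lapply(1:4, function(s) make_phantom(cfg, seed = s)$mask)
  # oracle predictor: every IoU 1
  r <- evaluate_masks(truths, truths)
  expect_equal(r$lumen_iou, 1)
  expect_equal(r$eem_csa_iou, 1)
  expect_equal(r$miou_eq3, 1)
  # constant-background predictor: lumen IoU 0
  blanks <- lapply(truths, function(m) matrix(0L, 64, 64))
  r0 <- evaluate_masks(blanks, truths)
  expect_equal(r0$lumen_iou, 0)
})

test_that("filled EEM-CSA IoU dominates ring IoU on nested phantom masks", {
  cfg <- tiny_phantom_config()
  truths <- lapply(1:6, function(s) make_phantom(cfg, seed = s)$mask)
  # plausible imperfect predictor: truth eroded by one ring of pixels
  shrink <- function(m) {
    lab <- m$labels
    out <- lab
    n <- nrow(lab)
    inner <- lab[c(2:n, n), ] >= 1 & lab[c(1, 1:(n - 1)), ] >= 1 &
      lab[, c(2:n, n)] >= 1 & lab[, c(1, 1:(n - 1))] >= 1
    out[!inner & lab == 2L] <- 0L
    new_label_mask(out)
  }
  preds <- lapply(truths, shrink)
  ring <- evaluate_masks(preds, truths, eem_csa_mode = "ring")
  filled <- evaluate_masks(preds, truths, eem_csa_mode = "filled")
  expect_gte(filled$eem_csa_iou, ring$eem_csa_iou)
})

test_that("macro averaging averages per-frame IoUs rather than pooling pixels", {
  t1 <- matrix(0L, 4, 4); t1[1:2, 1:2] <- 1L
  p_good <- t1
  t2 <- matrix(0L, 4, 4); t2[1, 1] <- 1L
  p_bad <- matrix(0L, 4, 4)
  micro <- evaluate_masks(list(p_good, p_bad), list(t1, t2), average = "micro")
  macro <- evaluate_masks(list(p_good, p_bad), list(t1, t2), average = "macro")
  expect_equal(micro$lumen_iou, 4 / 5)
  expect_equal(macro$lumen_iou, mean(c(1, 0)))
})

test_that("evaluating a model reports metadata and rejects an empty test split", {
  ds <- make_micro_dataset()
  mc <- model_config(input_size = 16L, depth = 2L, base_channels = 4L,
                     max_channels = 8L)
  m <- build_unet(mc, seed = 2)
  r <- evaluate_model(m, ds, strategy = "none", seed = 1L)
  expect_s3_class(r, "ivus_eval_report")
  expect_equal(r$n_frames, 2)
  expect_true(all(!is.na(r$per_class_iou) | TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$strategy, "none")

  ds_all_train <- ds
  ds_all_train$split[] <- "train"
  expect_error(evaluate_model(m, ds_all_train), "test split is empty")
})

test_that("the ablation harness is bookkeeping-correct at tiny scale", {
  ds <- make_micro_dataset()
  mc <- model_config(input_size = 16L, depth = 2L, base_channels = 4L,
                     max_channels = 8L)
  tc <- train_config(batch_size = 2L, total_iterations = 2L)
  ab1 <- run_ablation(ds, mc, tc, strategies = "none", seeds = 1L)
  expect_equal(nrow(ab1$runs), 1)
  expect_equal(nrow(ab1$summary), 1)
  ab <- run_ablation(ds, mc, tc,
                     strategies = c("none", "meshgrid_flip_rotate"),
                     seeds = c(1L, 2L))
  expect_equal(nrow(ab$runs), 4)
  expect_equal(nrow(ab$summary), 2)
  expect_equal(ab$summary$n_runs, c(2, 2))
  expect_true(all(ab$runs$lumen_iou >= 0 & ab$runs$lumen_iou <= 1))
})
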