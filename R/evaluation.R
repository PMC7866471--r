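# Evaluation: per-class IoU and mean IoU from pooled pixel confusion
# matrices, model evaluation over a test split, and the four-arm
# augmentation ablation harness.

#' Pixel confusion matrix between predicted and true masks
#'
#' Entry \code{(i, j)} counts pixels of true class \code{i} predicted as
#' class \code{j} (classes 0..k, background included as class 0, \code{k}
#' structures beyond it). Matrices accumulate across frames by elementwise
#' addition (micro-averaging).
#'
#' @param predicted,truth [new_label_mask()] objects (or integer matrices)
#'   of equal shape with labels in \code{[0, k]}.
#' @param k number of classes excluding background (default 2: lumen, ring).
#' @return A \code{(k+1) x (k+1)} integer matrix of class
#'   \code{ivus_confusion}.
#' @export
confusion_matrix <- function(predicted, truth, k = 2L) {
  p <- if (inherits(predicted, "ivus_mask")) predicted$labels else predicted
  t_ <- if (inherits(truth, "ivus_mask")) truth$labels else truth
  if (!identical(dim(p), dim(t_)))
    stop(sprintf("shape mismatch: predicted %s vs truth %s",
                 paste(dim(p), collapse = "x"), paste(dim(t_), collapse = "x")),
         call. = FALSE)
  pv <- as.integer(p); tv <- as.integer(t_)
  if (any(pv < 0L | pv > k) || any(tv < 0L | tv > k))
    stop(sprintf("labels outside [0, %d]", k), call. = FALSE)
  counts <- tabulate(tv * (k + 1L) + pv + 1L, nbins = (k + 1L)^2)
  cm <- matrix(counts, k + 1L, k + 1L, byrow = TRUE,
               dimnames = list(true = 0:k, predicted = 0:k))
  structure(cm, class = c("ivus_confusion", "matrix", "array"))
}

#' Per-class intersection-over-union from a confusion matrix
#'
#' \code{IoU_i = p_ii / (row_i + col_i - p_ii)}. A class absent from both
#' truth and prediction (zero denominator) is undefined and returned as
#' \code{NA}, to be excluded from means.
#'
#' @param cm a [confusion_matrix()] (accumulated sums are fine).
#' @return Numeric vector of length k+1, possibly with \code{NA}s.
#' @export
iou_per_class <- function(cm) {
  cm <- unclass(cm)
  di <- diag(cm)
  denom <- rowSums(cm) + colSums(cm) - di
  ifelse(denom > 0, di / denom, NA_real_)
}

#' Mean intersection-over-union
#'
#' Arithmetic mean of the defined per-class IoUs over all classes 0..k,
#' background included.
#'
#' @param cm a [confusion_matrix()].
#' @return Scalar in \code{[0, 1]}.
#' @export
miou <- function(cm) {
  ious <- iou_per_class(cm)
  if (all(is.na(ious)))
    stop("MIoU undefined: every class is absent from truth and prediction",
         call. = FALSE)
  mean(ious, na.rm = TRUE)
}

#' Evaluate paired lists of predicted and ground-truth masks
#'
#' The metric core behind [evaluate_model()], usable with predictions from
#' any source. Pools the pixel confusion matrix over frames (micro) or
#' averages per-frame IoUs (macro).
#'
#' @param pred_masks,truth_masks parallel lists of [new_label_mask()]
#'   objects or integer matrices.
#' @param eem_csa_mode \code{"ring"} scores the exclusive EEM-ring class;
#'   \code{"filled"} merges lumen and ring into the EEM-bounded region.
#' @param average \code{"micro"} or \code{"macro"}.
#' @return A list with per-class IoUs, lumen IoU, EEM-CSA IoU and the
#'   multi-class mean IoU.
#' @export
evaluate_masks <- function(pred_masks, truth_masks,
                           eem_csa_mode = c("ring", "filled"),
                           average = c("micro", "macro")) {
  eem_csa_mode <- match.arg(eem_csa_mode)
  average <- match.arg(average)
  stopifnot(length(pred_masks) == length(truth_masks), length(pred_masks) > 0)
  get_lab <- function(m) if (inherits(m, "ivus_mask")) m$labels else m

  cm3 <- matrix(0, 3, 3)
  cm_csa <- matrix(0, 2, 2)
  per_frame <- vector("list", length(pred_masks))
  for (i in seq_along(pred_masks)) {
    p <- get_lab(pred_masks[[i]]); t_ <- get_lab(truth_masks[[i]])
    ci <- confusion_matrix(p, t_, k = 2L)
    cm3 <- cm3 + ci
    pf <- list(iou = iou_per_class(ci))
    if (eem_csa_mode == "filled") {
      cf <- confusion_matrix((p >= 1L) * 1L, (t_ >= 1L) * 1L, k = 1L)
      cm_csa <- cm_csa + cf
      pf$csa <- iou_per_class(cf)[2]
    }
    per_frame[[i]] <- pf
  }
  if (average == "micro") {
    iou <- iou_per_class(cm3)
    csa <- if (eem_csa_mode == "filled") iou_per_class(cm_csa)[2] else iou[3]
    m3 <- miou(cm3)
  } else {
    mat <- do.call(rbind, lapply(per_frame, `[[`, "iou"))
    iou <- colMeans(mat, na.rm = TRUE)
    csa <- if (eem_csa_mode == "filled")
      mean(vapply(per_frame, `[[`, numeric(1), "csa"), na.rm = TRUE) else iou[3]
    m3 <- mean(iou, na.rm = TRUE)
  }
  list(per_class_iou = stats::setNames(iou, c("background", "lumen", "eem_ring")),
       lumen_iou = unname(iou[2]),
       eem_csa_iou = unname(csa),
       miou_eq3 = m3,
       eem_csa_mode = eem_csa_mode,
       average = average,
       n_frames = length(pred_masks))
}

#' Evaluate a trained model on the test split
#'
#' Predicts every test frame, pools the pixel confusion matrix over frames
#' (micro-averaging; per-frame macro averaging available) and reports
#' per-class IoU, the strict multi-class mean IoU over all classes, and the
#' EEM-CSA IoU in one of two readings: \code{"ring"} scores the exclusive
#' EEM-ring class; \code{"filled"} merges lumen and ring into the
#' EEM-bounded cross-section and scores it as a binary region.
#'
#' @param model a trained [build_unet()] model.
#' @param dataset an [new_dataset()] with a non-empty test split.
#' @param eem_csa_mode \code{"ring"} or \code{"filled"}.
#' @param average \code{"micro"} (pixel-pooled, default) or \code{"macro"}.
#' @param strategy optional strategy label recorded in the report.
#' @param seed optional run seed recorded in the report.
#' @return A list of class \code{ivus_eval_report}.
#' @export
evaluate_model <- function(model, dataset, eem_csa_mode = c("ring", "filled"),
                           average = c("micro", "macro"),
                           strategy = NA_character_, seed = NA_integer_) {
  idx <- split_indices(dataset, "test")
  if (length(idx) == 0) stop("test split is empty", call. = FALSE)
  preds <- lapply(idx, function(i) predict_mask(model, dataset$frames[[i]]))
  truths <- dataset$masks[idx]
  report <- evaluate_masks(preds, truths, eem_csa_mode, average)
  report$strategy <- strategy
  report$seed <- seed
  structure(report, class = "ivus_eval_report")
}

#' @export
print.ivus_eval_report <- function(x, ...) {
  cat(sprintf("<eval report: %d frames, %s averaging, EEM-CSA mode '%s'>\n",
              x$n_frames, x$average, x$eem_csa_mode))
  cat(sprintf("  lumen IoU   %.4f\n", x$lumen_iou))
  cat(sprintf("  EEM-CSA IoU %.4f\n", x$eem_csa_iou))
  cat(sprintf("  MIoU (all classes) %.4f\n", x$miou_eq3))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an [evaluate_model()] report.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the augmentation ablation
#'
#' Trains one model per (strategy, seed) pair on the train split, evaluates
#' each on the shared test split, and tabulates per-strategy mean and sd of
#' lumen IoU and EEM-CSA IoU — the structural twin of a four-arm
#' augmentation comparison. Arms differ only in strategy: the weight
#' initialization and data order derive from the same per-seed streams.
#'
#' @param dataset an [new_dataset()].
#' @param model_config a [model_config()] template; \code{input_channels} is
#'   adjusted per strategy automatically.
#' @param train_config a [train_config()] template; \code{strategy} and
#'   \code{seed} are overridden per arm.
#' @param strategies character vector of strategy names.
#' @param seeds integer vector of seeds.
#' @param eem_csa_mode \code{"ring"} or \code{"filled"}.
#' @param verbose print progress.
#' @return A list of class \code{ivus_ablation} with \code{runs} (one row per
#'   run) and \code{summary} (one row per strategy) data.frames.
#' @export
run_ablation <- function(dataset, model_config, train_config,
                         strategies = c("none", "flip_rotate", "meshgrid",
                                        "meshgrid_flip_rotate"),
                         seeds = 1L,
                         eem_csa_mode = c("ring", "filled"), verbose = FALSE) {
  stopifnot(length(strategies) >= 1, length(seeds) >= 1)
  eem_csa_mode <- match.arg(eem_csa_mode)
  rows <- list()
  for (strat in strategies) {
    aug <- strategy_config(strat)
    mc <- model_config
    mc$input_channels <- strategy_channels(aug)
    for (sd_ in seeds) {
      tc <- train_config
      tc$strategy <- strat
      tc$seed <- derive_seed(sd_, "batching")
      model <- build_unet(mc, seed = derive_seed(sd_, "weights"))
      if (verbose) message(sprintf("ablation arm %s / seed %d", strat, sd_))
      tr <- train_unet(model, dataset, tc, verbose = verbose)
      ev <- evaluate_model(tr$model, dataset, eem_csa_mode = eem_csa_mode,
                           strategy = strat, seed = sd_)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strat, seed = sd_,
        lumen_iou = ev$lumen_iou, eem_csa_iou = ev$eem_csa_iou,
        miou_eq3 = ev$miou_eq3, n_frames = ev$n_frames,
        final_loss = utils::tail(tr$history$loss, 1),
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  summ <- do.call(rbind, lapply(split(runs, runs$strategy)[unique(runs$strategy)],
    function(g) data.frame(
      strategy = g$strategy[1], n_runs = nrow(g),
      lumen_iou_mean = mean(g$lumen_iou),
      lumen_iou_sd = if (nrow(g) > 1) sd(g$lumen_iou) else 0,
      eem_csa_iou_mean = mean(g$eem_csa_iou),
      eem_csa_iou_sd = if (nrow(g) > 1) sd(g$eem_csa_iou) else 0,
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, eem_csa_mode = eem_csa_mode),
            class = "ivus_ablation")
}

#' @export
print.ivus_ablation <- function(x, ...) {
  cat(sprintf("<ablation over %d runs, EEM-CSA mode '%s'>\n",
              nrow(x$runs), x$eem_csa_mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
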