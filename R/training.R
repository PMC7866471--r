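# Training: Adam on sparse softmax cross-entropy over online-augmented
# batches drawn with replacement, with a step learning-rate schedule.

#' Training configuration
#'
#' Defaults reproduce the full clinical training regime: Adam, initial
#' learning rate 0.001 decayed by 0.1 every 2000 iterations, batch size 16,
#' 8000 iterations. Scaled-down values are used throughout the test suite.
#'
#' @param learning_rate initial step size.
#' @param decay_factor multiplicative decay, in \code{(0, 1]}.
#' @param decay_every iterations between decays.
#' @param batch_size samples per optimizer step.
#' @param total_iterations optimizer steps.
#' @param seed global RNG seed of the run (batch draws and augmentation).
#' @param strategy augmentation strategy name; see [strategy_config()].
#' @param log_every record (step, lr, loss) every this many iterations.
#' @param class_weights optional per-class loss weights; off by default.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters (framework
#'   defaults).
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.001, decay_factor = 0.1,
                         decay_every = 2000L, batch_size = 16L,
                         total_iterations = 8000L, seed = 1L,
                         strategy = "none", log_every = 1L,
                         class_weights = NULL,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  cfg <- list(learning_rate = learning_rate, decay_factor = decay_factor,
              decay_every = as.integer(decay_every),
              batch_size = as.integer(batch_size),
              total_iterations = as.integer(total_iterations),
              seed = as.integer(seed), strategy = strategy,
              log_every = as.integer(log_every),
              class_weights = class_weights,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_eps = adam_eps)
  if (cfg$learning_rate <= 0) stop_config("learning_rate", "must be > 0")
  if (cfg$decay_factor <= 0 || cfg$decay_factor > 1)
    stop_config("decay_factor", "must lie in (0, 1]")
  if (cfg$decay_every < 1) stop_config("decay_every", "must be >= 1")
  if (cfg$batch_size < 1) stop_config("batch_size", "must be >= 1")
  if (cfg$total_iterations < 1) stop_config("total_iterations", "must be >= 1")
  strategy_config(cfg$strategy)  # validates the name
  structure(cfg, class = "train_config")
}

#' Step learning-rate schedule
#'
#' \code{rate = learning_rate * decay_factor ^ floor(step / decay_every)}:
#' piecewise constant and non-increasing; with the defaults, 0.001 at step
#' 0, 0.0001 at step 2000, 1e-5 at step 4000.
#'
#' @param step 0-based iteration index (vectorized).
#' @param config a [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(step, config) {
  stopifnot(all(step >= 0))
  config$learning_rate * config$decay_factor^floor(step / config$decay_every)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, config) {
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the network on the training split of a dataset
#'
#' Runs \code{total_iterations} Adam steps over batches drawn with
#' replacement from the train split, with the configured augmentation
#' strategy applied online (a fresh random draw per sample per step). The
#' model's input channel count must match the strategy (3 channels iff
#' coordinate channels are concatenated). Fully reproducible from
#' \code{config$seed}.
#'
#' @param model a [build_unet()] model.
#' @param dataset an [new_dataset()]; its train split must be non-empty and
#'   its frames must match the model input size.
#' @param config a [train_config()].
#' @param verbose print a progress line every \code{log_every * 10} steps.
#' @return A list of class \code{ivus_training} with the trained
#'   \code{model} and a \code{history} data.frame (step, lr, loss).
#' @export
train_unet <- function(model, dataset, config, verbose = FALSE) {
  stopifnot(inherits(model, "ivus_unet"), inherits(dataset, "ivus_dataset"),
            inherits(config, "train_config"))
  idx <- split_indices(dataset, "train")
  if (length(idx) == 0) stop("train split is empty", call. = FALSE)
  aug <- strategy_config(config$strategy)
  if (strategy_channels(aug) != model$config$input_channels)
    stop(sprintf(
      "channel/strategy mismatch: strategy '%s' provides %d channels, model expects %d",
      config$strategy, strategy_channels(aug), model$config$input_channels),
      call. = FALSE)
  S <- model$config$input_size
  base <- lapply(idx, function(i) as_sample(dataset$frames[[i]],
                                            dataset$masks[[i]]))
  if (any(vapply(base, function(s) dim(s$image)[1], numeric(1)) != S))
    stop(sprintf("dataset frames do not match model input size %d", S),
         call. = FALSE)
  opt <- adam_init(model$params)
  hist_steps <- integer(0); hist_lr <- numeric(0); hist_loss <- numeric(0)
  set.seed(config$seed)
  for (it in seq_len(config$total_iterations)) {
    lr <- lr_schedule(it - 1L, config)
    draws <- sample.int(length(base), config$batch_size, replace = TRUE)
    x <- array(0, c(S, S, model$config$input_channels, config$batch_size))
    y <- array(0L, c(S, S, config$batch_size))
    for (b in seq_len(config$batch_size)) {
      s <- random_augment(base[[draws[b]]], aug)
      x[, , , b] <- s$image
      y[, , b] <- s$mask
    }
    fw <- unet_fwd(model, x, training = TRUE)
    model$state <- fw$st
    lg <- softmax_ce(fw$logits, y, want_grad = TRUE,
                     class_weights = config$class_weights)
    grads <- unet_bwd(model, lg$grad, fw)
    upd <- adam_step(model$params, grads, opt, lr, config)
    model$params <- upd$params
    opt <- upd$opt
    if (it %% config$log_every == 0 || it == config$total_iterations) {
      hist_steps <- c(hist_steps, it)
      hist_lr <- c(hist_lr, lr)
      hist_loss <- c(hist_loss, lg$loss)
      if (verbose && (it %% (config$log_every * 10) == 0))
        message(sprintf("[%s] step %d/%d lr=%g loss=%.4f",
                        config$strategy, it, config$total_iterations, lr, lg$loss))
    }
  }
  structure(list(model = model,
                 history = data.frame(step = hist_steps, lr = hist_lr,
                                      loss = hist_loss)),
            class = "ivus_training")
}
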