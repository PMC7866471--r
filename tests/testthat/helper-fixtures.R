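# Shared fixtures and independent oracles used across the suite.

# Small, fast phantom configuration for unit tests.
tiny_phantom_config <- function(...) {
  phantom_config(image_size = 64L, catheter_radius = 0.03,
                 speckle_scale = 0.2, ...)
}

# A deterministic tiny sample with an asymmetric image, handy for
# augmentation geometry checks.
tiny_sample <- function(n = 4L) {
  img <- matrix(seq_len(n * n) / (n * n), n, n)
  mask <- matrix(0L, n, n)
  mask[1:2, 1:2] <- 1L
  mask[n, n] <- 2L
  as_sample(new_frame(img), new_label_mask(mask))
}

# Independent O(H*W) double-loop confusion-matrix tally (metric oracle).
oracle_confusion <- function(pred, truth, k) {
  cm <- matrix(0, k + 1, k + 1)
  for (r in seq_len(nrow(truth))) {
    for (c in seq_len(ncol(truth))) {
      i <- truth[r, c]; j <- pred[r, c]
      cm[i + 1, j + 1] <- cm[i + 1, j + 1] + 1
    }
  }
  cm
}

# Independent per-pixel evaluation of the segmentation mean-IoU definition:
# IoU_i = p_ii / (sum_j p_ij + sum_j p_ji - p_ii), averaged over defined
# classes 0..k.
oracle_miou <- function(pred, truth, k) {
  cm <- oracle_confusion(pred, truth, k)
  ious <- numeric(0)
  for (i in seq_len(k + 1)) {
    denom <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
    if (denom > 0) ious <- c(ious, cm[i, i] / denom)
  }
  mean(ious)
}

# Brute-force per-pixel evaluation of the softmax cross-entropy: explicit
# softmax then -log p at the true label, averaged.
oracle_ce <- function(scores, labels) {
  d <- dim(scores)
  if (length(d) == 3) {
    scores <- array(scores, c(d, 1L))
    labels <- array(labels, c(dim(labels), 1L))
    d <- dim(scores)
  }
  total <- 0; npix <- 0
  for (n in seq_len(d[4])) {
    for (r in seq_len(d[1])) {
      for (c in seq_len(d[2])) {
        z <- scores[r, c, , n]
        p <- exp(z - max(z)); p <- p / sum(p)
        pt <- min(max(p[labels[r, c, n] + 1], 1e-12), 1 - 1e-12)
        total <- total - log(pt)
        npix <- npix + 1
      }
    }
  }
  total / npix
}

# Random valid label mask.
random_mask <- function(n, k = 2L) {
  matrix(sample(0:k, n * n, replace = TRUE), n, n)
}

# Miniature corpus for fast train/evaluate plumbing tests.
make_micro_dataset <- function(size = 16L, n_pat = 3L, fpp = 2L, seed = 5L) {
  cfg <- phantom_config(image_size = size, catheter_radius = 0.03,
                        speckle_scale = 0.2)
  make_corpus(cfg, n_patients = n_pat, frames_per_patient = fpp, seed = seed,
              n_train_patients = n_pat - 1L)
}

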