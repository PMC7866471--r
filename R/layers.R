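# R-level layer math: batch normalization, LeakyReLU and the softmax
# cross-entropy head. Convolutions live in src/ops.cpp; everything here is
# vectorized over (H, W, C, N) arrays.

# Reshape (H, W, C, N) so channels become columns of a matrix.
to_channel_mat <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  xp
}

from_channel_mat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

bn_fwd <- function(x, gamma, beta, training, run, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xp <- to_channel_mat(x)
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp * xp) - mu * mu
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xp, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = from_channel_mat(y, d), run = run,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d))
}

bn_bwd <- function(dy, cache) {
  dyp <- to_channel_mat(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  dxhat <- sweep(dyp, 2, cache$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dxp <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"),
               2, cache$invstd, "*")
  list(dx = from_channel_mat(dxp, cache$d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  y
}

lrelu_bwd <- function(dy, x, slope) {
  dx <- dy
  neg <- x < 0
  dx[neg] <- slope * dy[neg]
  dx
}

# Numerically stable softmax over the class axis of (H, W, K[, N]) scores.
softmax_probs <- function(scores) {
  d <- dim(scores)
  if (length(d) == 3) d <- c(d, 1L)
  K <- d[3]
  zm <- aperm(array(scores, d), c(1, 2, 4, 3))
  dim(zm) <- c(d[1] * d[2] * d[4], K)
  m <- zm[, 1]
  for (k in seq_len(K)[-1]) m <- pmax(m, zm[, k])
  e <- exp(zm - m)
  p <- e / rowSums(e)
  dim(p) <- c(d[1], d[2], d[4], K)
  p <- aperm(p, c(1, 2, 4, 3))
  if (length(dim(scores)) == 3) dim(p) <- dim(scores)
  p
}

# Shared engine for the loss and its gradient wrt the scores.
softmax_ce <- function(scores, labels, want_grad = FALSE, class_weights = NULL) {
  d <- dim(scores)
  if (is.null(d) || !length(d) %in% c(3, 4))
    stop("scores must be an (H, W, K) or (H, W, K, N) array", call. = FALSE)
  if (length(d) == 3) d <- c(d, 1L)
  K <- d[3]
  lab <- as.integer(as.vector(labels))
  if (length(lab) != d[1] * d[2] * d[4])
    stop(sprintf("labels (%d px) do not align with scores (%d px)",
                 length(lab), d[1] * d[2] * d[4]), call. = FALSE)
  if (any(lab < 0L | lab >= K))
    stop(sprintf("domain error: labels must lie in [0, %d)", K), call. = FALSE)

  zm <- aperm(array(scores, d), c(1, 2, 4, 3))
  dim(zm) <- c(length(lab), K)
  m <- zm[, 1]
  for (k in seq_len(K)[-1]) m <- pmax(m, zm[, k])
  e <- exp(zm - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_along(lab), lab + 1L)
  eps <- 1e-12
  pt <- pmin(pmax(p[idx], eps), 1 - eps)

  if (is.null(class_weights)) {
    loss <- -mean(log(pt))
    wrow <- NULL
  } else {
    stopifnot(length(class_weights) == K)
    wrow <- class_weights[lab + 1L]
    loss <- -sum(wrow * log(pt)) / sum(wrow)
  }
  if (!want_grad) return(list(loss = loss))

  g <- p
  g[idx] <- g[idx] - 1
  if (is.null(wrow)) g <- g / length(lab)
  else g <- g * (wrow / sum(wrow))
  dim(g) <- c(d[1], d[2], d[4], K)
  g <- aperm(g, c(1, 2, 4, 3))
  list(loss = loss, grad = g)
}

#' Sparse softmax cross-entropy loss
#'
#' Mean over pixels (and batch) of the negative log softmax probability of
#' the true class: the per-pixel multi-class cross-entropy applied directly
#' to integer labels. Probabilities are clamped to \code{[1e-12, 1 - 1e-12]}
#' before the logarithm.
#'
#' @param scores pre-softmax class scores, an \code{(H, W, K)} or
#'   \code{(H, W, K, N)} array.
#' @param labels integer labels in \code{[0, K)}, shaped \code{(H, W)} or
#'   \code{(H, W, N)}.
#' @param class_weights optional length-K per-class weights (weighted mean
#'   over pixels); off by default.
#' @return Non-negative scalar loss.
#' @export
sparse_softmax_cross_entropy <- function(scores, labels, class_weights = NULL) {
  softmax_ce(scores, labels, want_grad = FALSE, class_weights = class_weights)$loss
}
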