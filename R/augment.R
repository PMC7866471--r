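# Online augmentation: flips, right-angle rotations and coordinate
# ("MeshGrid") channels, applied identically to image channels and mask.

#' Augmentation configuration and the four ablation strategies
#'
#' The four arms of the augmentation ablation map onto three flags:
#' \tabular{ll}{
#'   \code{none} \tab no flip, no rotation, no coordinate channels \cr
#'   \code{flip_rotate} \tab random flip + random right-angle rotation \cr
#'   \code{meshgrid} \tab coordinate channels only \cr
#'   \code{meshgrid_flip_rotate} \tab all of the above \cr
#' }
#' Rotations are restricted to \code{{90, 180, 270}} degrees and flips to
#' up-down or left-right; each random draw includes the identity option.
#'
#' @param enable_flip,enable_rotate,enable_meshgrid strategy flags.
#' @param meshgrid_mode \code{"concat"} appends two coordinate channels
#'   (the default reading of pixel-level positional information);
#'   \code{"add"} arithmetically adds the mean coordinate grid to the
#'   intensity channel instead, kept for comparison.
#' @param meshgrid_invariant if \code{TRUE}, coordinate channels are
#'   regenerated after the geometric transforms (augmentation-invariant
#'   coordinates); default \code{FALSE} transforms them with the image.
#' @param seed optional RNG seed recorded in the config.
#' @return An object of class \code{augment_config}.
#' @export
augment_config <- function(enable_flip = FALSE, enable_rotate = FALSE,
                           enable_meshgrid = FALSE,
                           meshgrid_mode = c("concat", "add"),
                           meshgrid_invariant = FALSE, seed = NULL) {
  structure(list(enable_flip = isTRUE(enable_flip),
                 enable_rotate = isTRUE(enable_rotate),
                 enable_meshgrid = isTRUE(enable_meshgrid),
                 meshgrid_mode = match.arg(meshgrid_mode),
                 meshgrid_invariant = isTRUE(meshgrid_invariant),
                 rotation_angles = c(90, 180, 270),
                 seed = seed),
            class = "augment_config")
}

#' @param strategy one of \code{"none"}, \code{"flip_rotate"},
#'   \code{"meshgrid"}, \code{"meshgrid_flip_rotate"}.
#' @rdname augment_config
#' @export
strategy_config <- function(strategy, ...) {
  flags <- switch(strategy,
    none = c(FALSE, FALSE, FALSE),
    flip_rotate = c(TRUE, TRUE, FALSE),
    meshgrid = c(FALSE, FALSE, TRUE),
    meshgrid_flip_rotate = c(TRUE, TRUE, TRUE),
    stop(sprintf("unknown augmentation strategy '%s'", strategy), call. = FALSE))
  cfg <- augment_config(flags[1], flags[2], flags[3], ...)
  cfg$strategy <- strategy
  cfg
}

#' Number of image channels a strategy feeds the network
#' @param config an [augment_config()].
#' @return 1, or 3 when coordinate channels are concatenated.
#' @export
strategy_channels <- function(config) {
  if (config$enable_meshgrid && config$meshgrid_mode == "concat") 3L else 1L
}

#' Build a training sample from a frame and its mask
#'
#' @param frame a [new_frame()].
#' @param mask a [new_label_mask()] aligned to the frame.
#' @return A list of class \code{ivus_sample} with a single-channel
#'   \code{image} array (H x W x 1), the integer \code{mask} matrix and a
#'   provenance \code{meta} list.
#' @export
as_sample <- function(frame, mask) {
  stopifnot(inherits(frame, "ivus_frame"), inherits(mask, "ivus_mask"))
  if (!identical(dim(frame$pixels), dim(mask$labels)))
    stop("frame and mask shapes differ", call. = FALSE)
  img <- array(frame$pixels, c(dim(frame$pixels), 1L))
  structure(list(image = img, mask = mask$labels,
                 meta = list(patient_id = frame$patient_id,
                             frame_index = frame$frame_index,
                             has_meshgrid = FALSE, ops = character(0))),
            class = "ivus_sample")
}

#' Normalized coordinate channels
#'
#' Channel 1 (Y) holds the row coordinate divided by \code{height - 1},
#' channel 2 (X) the column coordinate divided by \code{width - 1}; both lie
#' in \code{[0, 1]}. A single-pixel axis uses the convention 0/0 = 0.
#'
#' @param height,width positive integers.
#' @return An array of dimension \code{c(height, width, 2)}.
#' @export
meshgrid_channels <- function(height, width) {
  if (height < 1 || width < 1)
    stop("meshgrid dimensions must be positive", call. = FALSE)
  ydiv <- max(height - 1, 1)
  xdiv <- max(width - 1, 1)
  y <- matrix(rep((seq_len(height) - 1) / ydiv, width), height, width)
  x <- matrix(rep((seq_len(width) - 1) / xdiv, each = height), height, width)
  out <- array(0, c(height, width, 2))
  out[, , 1] <- y; out[, , 2] <- x
  out
}

#' Append coordinate channels to a sample
#'
#' Coordinate channels become channels 2 and 3; appending twice is rejected.
#'
#' @param sample an [as_sample()] object.
#' @return The sample with a 3-channel image.
#' @export
append_meshgrid <- function(sample) {
  if (isTRUE(sample$meta$has_meshgrid))
    stop("coordinate channels already appended", call. = FALSE)
  d <- dim(sample$image)
  mg <- meshgrid_channels(d[1], d[2])
  img <- array(0, c(d[1], d[2], d[3] + 2L))
  img[, , seq_len(d[3])] <- sample$image
  img[, , d[3] + 1L] <- mg[, , 1]
  img[, , d[3] + 2L] <- mg[, , 2]
  sample$image <- img
  sample$meta$has_meshgrid <- TRUE
  sample
}

flip_matrix <- function(m, direction) {
  switch(direction,
    "up-down" = m[rev(seq_len(nrow(m))), , drop = FALSE],
    "left-right" = m[, rev(seq_len(ncol(m))), drop = FALSE],
    stop(sprintf("unknown flip direction '%s'", direction), call. = FALSE))
}

# Counter-clockwise quarter-turn of a matrix.
rot90_matrix <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_to_channels <- function(img, f) {
  d <- dim(img)
  out <- NULL
  for (c in seq_len(d[3])) {
    r <- f(img[, , c])
    if (is.null(out)) out <- array(0, c(dim(r), d[3]))
    out[, , c] <- r
  }
  out
}

#' Flip a sample up-down or left-right
#'
#' All image channels and the mask are flipped identically; coordinate
#' channels, when present, are flipped as data rather than regenerated.
#'
#' @param sample an [as_sample()] object.
#' @param direction \code{"up-down"} or \code{"left-right"}.
#' @return The flipped sample.
#' @export
apply_flip <- function(sample, direction) {
  if (!direction %in% c("up-down", "left-right"))
    stop(sprintf("unknown flip direction '%s'", direction), call. = FALSE)
  sample$image <- apply_to_channels(sample$image,
                                    function(m) flip_matrix(m, direction))
  sample$mask <- flip_matrix(sample$mask, direction)
  sample$meta$ops <- c(sample$meta$ops, paste0("flip:", direction))
  sample
}

#' Rotate a sample by a right angle
#'
#' @param sample an [as_sample()] object with square spatial shape.
#' @param angle one of 90, 180, 270 (degrees, counter-clockwise).
#' @return The rotated sample.
#' @export
apply_rotation <- function(sample, angle) {
  if (!angle %in% c(90, 180, 270))
    stop("rotation angle must be one of 90, 180, 270", call. = FALSE)
  d <- dim(sample$image)
  if (d[1] != d[2])
    stop("right-angle rotation requires a square sample", call. = FALSE)
  k <- angle / 90
  rot <- function(m) { for (i in seq_len(k)) m <- rot90_matrix(m); m }
  sample$image <- apply_to_channels(sample$image, rot)
  sample$mask <- rot(sample$mask)
  sample$meta$ops <- c(sample$meta$ops, paste0("rot:", angle))
  sample
}

# Random draw of the geometric ops for one sample. Rotation and flip are
# independent and uniform, each including the identity option.
draw_augment_ops <- function(config) {
  rotation <- if (config$enable_rotate) sample(c(0, 90, 180, 270), 1) else 0
  flip <- if (config$enable_flip)
    sample(c("none", "up-down", "left-right"), 1) else "none"
  list(rotation = rotation, flip = flip)
}

#' Randomly augment a sample under a strategy
#'
#' With flips/rotations enabled, each call independently draws
#' rotate-or-not (uniform over none/90/180/270) and flip-or-not (uniform
#' over none/up-down/left-right). With coordinate channels enabled in
#' \code{"concat"} mode they are appended before the geometric transforms
#' and transformed with the image (unless
#' \code{config$meshgrid_invariant}); in \code{"add"} mode the mean
#' coordinate grid is added to the intensity channel. All flags off returns
#' the input unchanged (the \code{none} strategy is the identity).
#'
#' @param sample an [as_sample()] object.
#' @param config an [augment_config()].
#' @param seed optional seed fixing this draw.
#' @return The augmented sample; the ops applied are recorded in
#'   \code{meta$ops}.
#' @export
random_augment <- function(sample, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$enable_meshgrid && !isTRUE(sample$meta$has_meshgrid)) {
    if (config$meshgrid_mode == "concat") {
      if (!config$meshgrid_invariant) sample <- append_meshgrid(sample)
    } else {
      d <- dim(sample$image)
      mg <- meshgrid_channels(d[1], d[2])
      sample$image[, , 1] <- sample$image[, , 1] + 0.5 * (mg[, , 1] + mg[, , 2])
      sample$meta$ops <- c(sample$meta$ops, "meshgrid:add")
    }
  }
  ops <- draw_augment_ops(config)
  if (ops$rotation != 0) sample <- apply_rotation(sample, ops$rotation)
  if (ops$flip != "none") sample <- apply_flip(sample, ops$flip)
  if (config$enable_meshgrid && config$meshgrid_mode == "concat" &&
      config$meshgrid_invariant && !isTRUE(sample$meta$has_meshgrid)) {
    sample <- append_meshgrid(sample)
  }
  sample
}
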