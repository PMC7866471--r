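#' IVUS frame and label-mask containers
#'
#' A frame is one grayscale short-axis IVUS image with provenance; a label
#' mask is a per-pixel integer class map aligned to a frame. Class encoding
#' is mutually exclusive: 0 = background, 1 = lumen, 2 = EEM ring (the
#' EEM-bounded cross-section minus the lumen). The geometric "EEM-CSA"
#' region of clinical use is reconstructed as labels \code{{1, 2}} at
#' evaluation time.
#'
#' @param pixels numeric matrix of intensities in \code{[0, 1]}; square.
#' @param patient_id opaque patient identifier.
#' @param frame_index integer frame position within the pullback, 0-based.
#' @param source_path optional originating file path.
#' @return An object of class \code{ivus_frame}.
#' @export
new_frame <- function(pixels, patient_id = NA_character_, frame_index = 0L,
                      source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) != ncol(pixels))
    stop(sprintf("frames must be square; got %d x %d", nrow(pixels), ncol(pixels)),
         call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stop("frame intensities must lie in [0, 1]; normalize first", call. = FALSE)
  structure(
    list(pixels = pixels, patient_id = as.character(patient_id),
         frame_index = as.integer(frame_index), source_path = source_path),
    class = "ivus_frame")
}

#' @param labels integer matrix with values in \code{{0, 1, 2}}.
#' @rdname new_frame
#' @export
new_label_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), 0:2)
  if (length(bad))
    stop(sprintf("label values outside {0,1,2}: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  structure(list(labels = labels), class = "ivus_mask")
}

#' @export
print.ivus_frame <- function(x, ...) {
  cat(sprintf("<ivus_frame %dx%d patient=%s frame=%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$frame_index))
  invisible(x)
}

#' @export
print.ivus_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<ivus_mask %dx%d bg=%d lumen=%d ring=%d>\n",
              nrow(x$labels), ncol(x$labels), tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}

#' Assemble a dataset of paired frames and masks with a patient-wise split
#'
#' @param frames list of [new_frame()] objects.
#' @param masks list of [new_label_mask()] objects, parallel to \code{frames}.
#' @param split named character vector mapping patient id to \code{"train"}
#'   or \code{"test"}; every patient occurring in \code{frames} must appear,
#'   and no patient may be assigned to both splits.
#' @return An object of class \code{ivus_dataset}.
#' @export
new_dataset <- function(frames, masks, split) {
  if (length(frames) != length(masks))
    stop("frames and masks must have equal length", call. = FALSE)
  if (length(frames) == 0) stop("dataset is empty", call. = FALSE)
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), dim(masks[[i]]$labels)))
      stop(sprintf("sample %d: mask shape does not match frame", i), call. = FALSE)
  }
  pids <- vapply(frames, function(f) f$patient_id, character(1))
  if (!all(unique(pids) %in% names(split)))
    stop("every patient id must appear in the split mapping", call. = FALSE)
  if (anyDuplicated(names(split)))
    stop("split-integrity error: a patient id is assigned more than once",
         call. = FALSE)
  if (!all(split %in% c("train", "test")))
    stop("split values must be 'train' or 'test'", call. = FALSE)
  structure(list(frames = frames, masks = masks,
                 patient_id = pids, split = split),
            class = "ivus_dataset")
}

#' @export
print.ivus_dataset <- function(x, ...) {
  cat(sprintf("<ivus_dataset %d frames, %d patients (%d train / %d test)>\n",
              length(x$frames), length(x$split),
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' Indices of the frames belonging to one split
#'
#' @param dataset an [new_dataset()] object.
#' @param split \code{"train"} or \code{"test"}.
#' @return Integer vector of sample indices.
#' @export
split_indices <- function(dataset, split = c("train", "test")) {
  split <- match.arg(split)
  pats <- names(dataset$split)[dataset$split == split]
  which(dataset$patient_id %in% pats)
}
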