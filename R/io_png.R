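# PNG and manifest I/O with fixed label and coordinate conventions.
# Coordinates are row-major, origin top-left. Masks round-trip bit-exactly.

#' Read and write label-mask PNGs
#'
#' Masks are stored as 8-bit grayscale PNG holding the raw class values
#' 0/1/2; writing then reading reproduces the label array exactly. Any pixel
#' outside the class domain \code{{0, 1, 2}} is a label-domain error.
#'
#' @param path PNG file path.
#' @return [new_label_mask()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    # Palette/RGB-expanded masks: accept only if all channels agree.
    ch <- dim(arr)[3]
    for (c in seq_len(min(ch, 3))[-1]) {
      if (!isTRUE(all.equal(arr[, , 1], arr[, , c])))
        stop("mask PNG has unequal colour channels; not a label image",
             call. = FALSE)
    }
    arr <- arr[, , 1]
  }
  vals <- as.integer(round(arr * 255))
  bad <- setdiff(unique(vals), 0:2)
  if (length(bad))
    stop(sprintf("label-domain error: mask contains values outside {0,1,2}: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  new_label_mask(matrix(vals, nrow(arr), ncol(arr)))
}

#' @param mask a [new_label_mask()].
#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  if (!inherits(mask, "ivus_mask")) stop("mask must be an ivus_mask", call. = FALSE)
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' Read and write grayscale image PNGs as frames
#'
#' Images are written as 8-bit grayscale; reading normalizes nothing (PNG is
#' already in \code{[0, 1]}), so a write/read round trip is exact up to 8-bit
#' quantization.
#'
#' @param path PNG file path.
#' @param patient_id,frame_index provenance attached to the frame on read.
#' @return [new_frame()] for the reader; the path, invisibly, for the writer.
#' @export
read_image_png <- function(path, patient_id = NA_character_, frame_index = 0L) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  new_frame(arr, patient_id = patient_id, frame_index = frame_index,
            source_path = path)
}

#' @param frame a [new_frame()].
#' @rdname read_image_png
#' @export
write_image_png <- function(frame, path) {
  if (!inherits(frame, "ivus_frame")) stop("frame must be an ivus_frame", call. = FALSE)
  png::writePNG(frame$pixels, path)
  invisible(path)
}

#' Load a dataset from a manifest CSV
#'
#' The manifest has columns \code{path_image, path_mask, patient_id,
#' frame_index, split}. Relative paths are resolved against the manifest's
#' directory. The patient-wise split is validated at load time: a patient
#' assigned to both splits, duplicated image paths, missing files or an
#' empty manifest are errors.
#'
#' @param manifest_path CSV path.
#' @return An [new_dataset()].
#' @export
load_dataset <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop("empty-dataset error: manifest has no rows", call. = FALSE)
  need <- c("path_image", "path_mask", "patient_id", "frame_index", "split")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop(sprintf("manifest lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(man$path_image))
    stop("manifest contains duplicate image paths", call. = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  man$path_image <- resolve(man$path_image)
  man$path_mask <- resolve(man$path_mask)
  gone <- c(man$path_image[!file.exists(man$path_image)],
            man$path_mask[!file.exists(man$path_mask)])
  if (length(gone))
    stop(sprintf("manifest references missing files: %s",
                 paste(utils::head(gone, 3), collapse = ", ")), call. = FALSE)
  split_tab <- unique(man[, c("patient_id", "split")])
  if (anyDuplicated(split_tab$patient_id))
    stop("split-integrity error: a patient id appears in both splits",
         call. = FALSE)
  frames <- vector("list", nrow(man))
  masks <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    frames[[i]] <- read_image_png(man$path_image[i],
                                  patient_id = man$patient_id[i],
                                  frame_index = man$frame_index[i])
    masks[[i]] <- read_mask_png(man$path_mask[i])
  }
  split <- stats::setNames(split_tab$split, split_tab$patient_id)
  new_dataset(frames, masks, split)
}
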