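# Minimal DICOM I/O for uncompressed grayscale single/multi-frame images.
#
# No installed R package reads DICOM, so the subset this pipeline touches is
# implemented here: little-endian transfer syntaxes (explicit or implicit
# VR), MONOCHROME 8- or 16-bit pixel data, Rows/Columns/NumberOfFrames and
# PatientID tags. The writer emits explicit-VR little endian and exists
# mainly to build fixtures and export phantoms.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(bytes) {
  if (length(bytes) %% 2 == 1) c(bytes, as.raw(0)) else bytes
}

# One explicit-VR little-endian data element.
dcm_element <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    US = dcm_u16(value),
    UL = dcm_u32(value),
    IS = dcm_pad(charToRaw(as.character(value))),
    UI = ,
    CS = ,
    LO = dcm_pad(charToRaw(as.character(value))),
    OB = value,
    stop("unsupported VR: ", vr))
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(bytes)), bytes)
  } else {
    c(head, dcm_u16(length(bytes)), bytes)
  }
}

#' Write frames as a minimal multi-frame DICOM file
#'
#' Emits an uncompressed explicit-VR little-endian grayscale DICOM with 8-bit
#' pixel data (intensities quantized from \code{[0, 1]}), suitable as input
#' for [read_dicom_frames()]. Intended for phantom export and test fixtures,
#' not for clinical interchange.
#'
#' @param frames a list of [new_frame()] objects of identical size.
#' @param path output file.
#' @param patient_id value for the PatientID tag.
#' @return The path, invisibly.
#' @export
write_dicom_frames <- function(frames, path, patient_id = "ANON") {
  if (inherits(frames, "ivus_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  dims <- dim(frames[[1]]$pixels)
  pix <- lapply(frames, function(f) {
    if (!identical(dim(f$pixels), dims))
      stop("all frames must share one size", call. = FALSE)
    # DICOM stores rows consecutively (row-major).
    as.raw(round(t(f$pixels) * 255))
  })
  pixdata <- dcm_pad(do.call(c, pix))

  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.3.1"),
    dcm_element(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.3.1"),
    dcm_element(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_element(0x0008, 0x0060, "CS", "US"),
    dcm_element(0x0010, 0x0020, "LO", patient_id),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", length(frames)),
    dcm_element(0x0028, 0x0010, "US", dims[1]),
    dcm_element(0x0028, 0x0011, "US", dims[2]),
    dcm_element(0x0028, 0x0100, "US", 8L),
    dcm_element(0x0028, 0x0101, "US", 8L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OB", pixdata))

  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", length(meta)),
           meta, body)
  writeBin(out, path)
  invisible(path)
}

read_u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
read_u32 <- function(bytes, at) {
  readBin(bytes[at:(at + 3)], "integer", size = 4, endian = "little")
}

#' Read frames from a grayscale DICOM file
#'
#' Supports uncompressed little-endian DICOM (explicit or implicit VR),
#' single- or multi-frame, 8- or 16-bit MONOCHROME pixel data. Each stored
#' frame becomes one [new_frame()] with intensities min-max normalized to
#' \code{[0, 1]} per frame (a constant frame maps to all zeros);
#' \code{frame_index} preserves storage order. Non-square frames and
#' non-image or compressed files are errors.
#'
#' @param path DICOM file path.
#' @return A list of [new_frame()] objects.
#' @export
read_dicom_frames <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  else if (length(bytes) < 16)
    stop("format error: not a readable DICOM file", call. = FALSE)

  tags <- list()
  n <- length(bytes)
  while (pos + 7 <= n) {
    group <- read_u16(bytes, pos); elem <- read_u16(bytes, pos + 2L)
    vrb <- as.integer(bytes[(pos + 4L):(pos + 5L)])
    explicit <- all(vrb >= 65L & vrb <= 90L)  # two uppercase letters => explicit VR
    vr <- if (explicit) rawToChar(bytes[(pos + 4L):(pos + 5L)]) else NA_character_
    if (explicit) {
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- read_u32(bytes, pos + 8L); hdr <- 12L
      } else {
        len <- read_u16(bytes, pos + 6L); hdr <- 8L
      }
    } else {
      len <- read_u32(bytes, pos + 4L); hdr <- 8L
    }
    if (len < 0 || pos + hdr + len - 1L > n)
      stop("format error: truncated or compressed DICOM element", call. = FALSE)
    val <- bytes[(pos + hdr):(pos + hdr + len - 1L)]
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- val
    pos <- pos + hdr + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }

  need <- function(key, what) {
    if (is.null(tags[[key]]))
      stop(sprintf("format error: DICOM lacks %s (%s)", what, key), call. = FALSE)
    tags[[key]]
  }
  rows <- read_u16(need("0028,0010", "Rows"), 1L)
  cols <- read_u16(need("0028,0011", "Columns"), 1L)
  if (rows != cols)
    stop(sprintf("dimension error: frames must be square, got %d x %d",
                 rows, cols), call. = FALSE)
  bits <- if (!is.null(tags[["0028,0100"]])) read_u16(tags[["0028,0100"]], 1L) else 8L
  if (!bits %in% c(8L, 16L))
    stop(sprintf("format error: unsupported BitsAllocated %d", bits), call. = FALSE)
  nframes <- if (!is.null(tags[["0028,0008"]]))
    as.integer(trimws(rawToChar(tags[["0028,0008"]]))) else 1L
  pixraw <- need("7fe0,0010", "PixelData")
  pid <- if (!is.null(tags[["0010,0020"]]))
    trimws(rawToChar(tags[["0010,0020"]])) else basename(path)

  per_frame <- as.integer(rows) * as.integer(cols)
  if (bits == 8L) {
    vals <- as.integer(pixraw)
  } else {
    vals <- readBin(pixraw, "integer", n = length(pixraw) / 2L, size = 2,
                    signed = FALSE, endian = "little")
  }
  if (length(vals) < per_frame * nframes)
    stop("format error: pixel data shorter than Rows*Columns*NumberOfFrames",
         call. = FALSE)

  lapply(seq_len(nframes), function(k) {
    v <- vals[((k - 1L) * per_frame + 1L):(k * per_frame)]
    m <- t(matrix(v, nrow = cols, ncol = rows))  # undo row-major storage
    lo <- min(m); hi <- max(m)
    m <- if (hi > lo) (m - lo) / (hi - lo) else matrix(0, rows, cols)
    new_frame(m, patient_id = pid, frame_index = k - 1L, source_path = path)
  })
}
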