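#' Video sequences
#'
#' A `video_sequence` is an ordered set of equally sized 8-bit frames plus a
#' frame rate. Frames are stored as numeric matrices (grayscale, `H x W`) or
#' `H x W x 3` arrays (color) with values on the 0--255 scale. Pixel
#' coordinates throughout the package are 0-based with `x` the column and `y`
#' the row, origin at the top-left pixel center.
#'
#' @param frames list of `H x W` matrices or `H x W x 3` arrays, values 0-255.
#' @param fps frames per second (Hz), must be positive.
#' @return An object of class `video_sequence` with fields `frames`, `fps`,
#'   `width`, `height`, `n_frames`, `color`.
#' @export
video_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0)
    stop("'frames' must be a non-empty list", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number", call. = FALSE)
  dims <- lapply(frames, dim)
  d1 <- dims[[1]]
  if (is.null(d1) || !(length(d1) %in% c(2L, 3L)))
    stop("frames must be H x W matrices or H x W x 3 arrays", call. = FALSE)
  same <- vapply(dims, function(d) identical(d[1:2], d1[1:2]), logical(1))
  if (!all(same))
    stop("all frames must share identical dimensions", call. = FALSE)
  structure(
    list(frames = frames, fps = fps,
         width = as.integer(d1[2]), height = as.integer(d1[1]),
         n_frames = length(frames),
         color = length(d1) == 3L),
    class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat(sprintf("video_sequence: %d frame(s), %dx%d px, %.4g Hz, %s\n",
              x$n_frames, x$width, x$height, x$fps,
              if (x$color) "color" else "grayscale"))
  invisible(x)
}

#' Read a video from an image-sequence directory
#'
#' Reads a directory of lexically ordered PNG (or TIFF) files into a
#' [video_sequence]. Image-sequence directories carry no frame-rate metadata,
#' so `fps` must be supplied (the documented acquisition default for the
#' supported recordings is 12.5 Hz, but nothing is hard-coded).
#'
#' @param path directory containing the frame images.
#' @param fps frame rate to attach (Hz).
#' @return A [video_sequence].
#' @export
read_video <- function(path, fps) {
  if (missing(fps))
    stop("'fps' is required: image-sequence directories carry no rate metadata",
         call. = FALSE)
  if (!dir.exists(path))
    stop("not a readable directory: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- sort(files, method = "radix")
  if (length(files) == 0)
    stop("no PNG/TIFF frames found in ", path, call. = FALSE)
  frames <- lapply(files, read_frame_file)
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, function(d) identical(d[1:2], dims[[1]][1:2]), logical(1))))
    stop("frames of mixed size in ", path, call. = FALSE)
  video_sequence(frames, fps = fps)
}

read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF frames", call. = FALSE)
    tiff::readTIFF(f)
  } else {
    png::readPNG(f)
  }
  # drop alpha channel if present; scale to 0-255
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  round(img * 255)
}

#' Write a video as a PNG image sequence
#'
#' Writes one zero-padded PNG per frame (`frame_000000.png`, ...) into `path`,
#' a lossless representation that [read_video] reads back bit-exactly.
#'
#' @param seq a [video_sequence].
#' @param path output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_video <- function(seq, path) {
  stopifnot(inherits(seq, "video_sequence"))
  if (seq$n_frames == 0) stop("empty sequence", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  files <- file.path(path, sprintf("frame_%06d.png", seq_len(seq$n_frames) - 1L))
  for (i in seq_len(seq$n_frames)) {
    png::writePNG(clamp01(seq$frames[[i]] / 255), files[i])
  }
  invisible(files)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Convert a color frame to grayscale
#'
#' Applies the ITU-R BT.601 luma weights (0.299, 0.587, 0.114) to an 8-bit RGB
#' frame. Already-grayscale input is returned unchanged, so the operation is
#' idempotent. The result is kept in double precision (no re-quantization).
#'
#' @param frame `H x W x 3` array or `H x W` matrix, values 0-255.
#' @return `H x W` numeric matrix.
#' @export
to_grayscale <- function(frame) {
  d <- dim(frame)
  if (length(d) == 2) return(frame)
  if (length(d) == 3 && d[3] == 3)
    return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  stop("frame must be H x W or H x W x 3", call. = FALSE)
}

# Grayscale view of every frame of a sequence (list of H x W matrices).
gray_frames <- function(seq) lapply(seq$frames, to_grayscale)
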