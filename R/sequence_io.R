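#' Frame sequences
#'
#' A `frame_sequence` is an ordered list of 2-D grayscale intensity matrices
#' (values in \[0, 1\], rows = y increasing downward, columns = x increasing
#' rightward) plus the acquisition rate in frames per second. All spectral
#' math downstream uses `fps` as the sampling rate, so it must be the true
#' acquisition rate; it is always supplied by the caller, never read from
#' file metadata.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param fps frames per second (Hz), > 0.
#' @param source_id free-text identifier carried through the pipeline.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, source_id = "") {
  if (!is.list(frames) || length(frames) < 2L)
    stop("insufficient frames: a frame_sequence needs at least 2 frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch: all frames must share the same height x width", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number (Hz)", call. = FALSE)
  structure(list(frames = frames, fps = fps, source_id = as.character(source_id)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence '%s': %d frames of %d x %d px at %g fps (%.1f s)\n",
              x$source_id, length(x$frames), d[1], d[2], x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

# collapse a h x w x channels array to grayscale by unweighted channel mean,
# matching a monochrome-camera workflow where any fixed convention suffices
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 2L || nc == 4L) nc <- nc - 1L  # drop alpha
    out <- img[, , 1L]
    if (nc > 1L) for (k in 2:nc) out <- out + img[, , k]
    return(out / nc)
  }
  stop("unsupported image array with ", length(dim(img)), " dimensions", call. = FALSE)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop("unsupported image format '", ext, "'", call. = FALSE)),
    error = function(e) stop("failed to read frame '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  as_gray(img)
}

#' Read an image sequence
#'
#' Reads a multi-page TIFF or a directory of lexicographically ordered
#' PNG/TIFF frames into a [frame_sequence]. Frames are converted to grayscale
#' (unweighted channel mean for color inputs) with intensities in \[0, 1\]
#' as returned by the PNG/TIFF readers. Video containers (AVI/MP4) are not
#' decodable here and raise an informative error; export such files to a
#' TIFF stack or frame directory first.
#'
#' @param path a multi-page TIFF file or a directory of image frames.
#' @param fps acquisition frame rate in Hz (caller-supplied, see
#'   [frame_sequence]).
#' @param source_id identifier; defaults to the file or directory name.
#' @return A [frame_sequence].
#' @export
read_sequence <- function(path, fps, source_id = basename(path)) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) < 2L)
      stop("insufficient frames: found ", length(files), " image file(s) in '",
           path, "'", call. = FALSE)
    frames <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("avi", "mp4", "mov", "mkv"))
      stop("video container '", ext, "' is not supported; convert '", path,
           "' to a multi-page TIFF or a directory of frames", call. = FALSE)
    if (!ext %in% c("tif", "tiff"))
      stop("unsupported sequence format '", ext, "' for '", path, "'", call. = FALSE)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("failed to read '", path, "': ",
                                               conditionMessage(e), call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, as_gray)
  } else {
    stop("no such file or directory: '", path, "'", call. = FALSE)
  }
  frame_sequence(frames, fps = fps, source_id = source_id)
}

#' Per-frame motion parameter records
#'
#' A `motion_record` holds the four frame-to-frame motion parameters
#' extracted from an image sequence: mean clockwise rotation angle
#' (`pos_angle`, rad, >= 0), mean anti-clockwise rotation magnitude
#' (`neg_angle`, rad, >= 0), and the centre-of-mass displacement in polar
#' form (`com_rho` in pixels >= 0, `com_theta` in radians in (-pi, pi\]).
#' Untrackable transitions are stored as zeros, never as gaps, so the series
#' are always complete for spectral analysis.
#'
#' @param pos_angle,neg_angle,com_rho,com_theta equal-length numeric series.
#' @param fps sampling rate in Hz.
#' @param source_id identifier.
#' @param com_dx,com_dy optional cartesian centre-of-mass steps, kept for
#'   inspection alongside the polar form.
#' @return An object of class `motion_record`.
#' @export
motion_record <- function(pos_angle, neg_angle, com_rho, com_theta, fps,
                          source_id = "", com_dx = NULL, com_dy = NULL) {
  n <- length(pos_angle)
  if (n < 2L)
    stop("insufficient frames: a motion_record needs at least 2 transitions", call. = FALSE)
  if (length(neg_angle) != n || length(com_rho) != n || length(com_theta) != n)
    stop("all four motion series must have equal length", call. = FALSE)
  series <- list(pos_angle = pos_angle, neg_angle = neg_angle,
                 com_rho = com_rho, com_theta = com_theta)
  if (anyNA(series, recursive = TRUE) ||
      !all(vapply(series, function(s) all(is.finite(s)), logical(1))))
    stop("motion series must be finite with no missing values", call. = FALSE)
  if (any(pos_angle < 0) || any(neg_angle < 0) || any(com_rho < 0))
    stop("pos_angle, neg_angle and com_rho must be non-negative", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number (Hz)", call. = FALSE)
  if (is.null(com_dx)) com_dx <- com_rho * cos(com_theta)
  if (is.null(com_dy)) com_dy <- com_rho * sin(com_theta)
  structure(c(series, list(com_dx = com_dx, com_dy = com_dy,
                           fps = fps, source_id = as.character(source_id))),
            class = "motion_record")
}

#' @export
print.motion_record <- function(x, ...) {
  cat(sprintf("motion_record '%s': %d frame transitions at %g fps\n",
              x$source_id, length(x$pos_angle), x$fps))
  cat(sprintf("  mean pos_angle %.4g rad, mean neg_angle %.4g rad, mean com_rho %.4g px\n",
              mean(x$pos_angle), mean(x$neg_angle), mean(x$com_rho)))
  invisible(x)
}

#' @export
length.motion_record <- function(x) length(x$pos_angle)

#' Write a motion record to CSV
#'
#' The CSV is the pipeline's persistent intermediate: comma-separated, '.'
#' decimal, Unix newlines, one header row
#' `frame,pos_angle,neg_angle,com_rho,com_theta,com_dx,com_dy`. Angles are in
#' radians, displacements in pixels. Values are serialized with 15
#' significant digits so a read/write round trip reproduces the record.
#'
#' @param record a [motion_record].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(record, path) {
  stopifnot(inherits(record, "motion_record"))
  n <- length(record$pos_angle)
  fmt <- function(v) sprintf("%.15g", v)
  lines <- c("frame,pos_angle,neg_angle,com_rho,com_theta,com_dx,com_dy",
             paste(seq_len(n), fmt(record$pos_angle), fmt(record$neg_angle),
                   fmt(record$com_rho), fmt(record$com_theta),
                   fmt(record$com_dx), fmt(record$com_dy), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a motion record from CSV
#'
#' Expects at least the columns `frame,pos_angle,neg_angle,com_rho,com_theta`
#' written by [write_motion_csv] (extra columns are ignored apart from the
#' optional cartesian `com_dx`/`com_dy`).
#'
#' @param path CSV file path.
#' @param fps sampling rate in Hz (caller-supplied).
#' @param source_id identifier; defaults to the file name.
#' @return A [motion_record].
#' @export
read_motion_csv <- function(path, fps, source_id = basename(path)) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("failed to parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("frame", "pos_angle", "neg_angle", "com_rho", "com_theta")
  if (!all(need %in% names(df)))
    stop("malformed header in '", path, "': expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  if (nrow(df) < 2L)
    stop("insufficient frames: '", path, "' has ", nrow(df), " data row(s)", call. = FALSE)
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric value in column '", col, "' at data row ", bad,
           " of '", path, "'", call. = FALSE)
    }
    if (anyNA(v))
      stop("missing value in column '", col, "' at data row ",
           which(is.na(v))[1], " of '", path, "'", call. = FALSE)
  }
  motion_record(df$pos_angle, df$neg_angle, df$com_rho, df$com_theta,
                fps = fps, source_id = source_id,
                com_dx = if ("com_dx" %in% names(df)) df$com_dx else NULL,
                com_dy = if ("com_dy" %in% names(df)) df$com_dy else NULL)
}

#' Write a frame sequence as a multi-page TIFF
#'
#' @param seq a [frame_sequence].
#' @param path output .tif path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(seq, path, bits = 16L) {
  stopifnot(inherits(seq, "frame_sequence"))
  frames <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}
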