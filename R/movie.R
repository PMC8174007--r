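# Movie container: a height x width x frames array of 16-bit intensities
# with pixel size (um/px) and frame interval (s) carried as attributes.

#' Construct a movie object
#'
#' @param frames Numeric array `[height, width, n_frames]` (a single matrix
#'   is promoted to one frame).
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s.
#' @return An object of class `spt_movie`.
#' @export
spt_movie <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3,
    pixel_size > 0, frame_interval > 0)
  structure(frames,
    pixel_size = pixel_size, frame_interval = frame_interval,
    class = "spt_movie"
  )
}

#' @export
print.spt_movie <- function(x, ...) {
  d <- dim(x)
  cat(
    "<spt_movie> ", d[1], "x", d[2], " px, ", d[3], " frames, ",
    attr(x, "pixel_size"), " um/px, ", attr(x, "frame_interval"), " s/frame\n",
    sep = ""
  )
  invisible(x)
}

#' @export
`[.spt_movie` <- function(x, ...) {
  out <- NextMethod()
  # subsetting that keeps 3 dims keeps the class
  if (is.array(out) && length(dim(out)) == 3) {
    spt_movie(out, attr(x, "pixel_size"), attr(x, "frame_interval"))
  } else {
    out
  }
}

#' Read a multi-page TIFF movie
#'
#' Frames are read in acquisition (page) order as unsigned integer data.
#' Pixel size and frame interval come from the caller, not file tags, so
#' the same movie read anywhere carries the same calibration.
#'
#' @param path Path to a single-channel multi-page TIFF.
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s.
#' @return An [spt_movie()].
#' @export
read_movie <- function(path, pixel_size = 0.1, frame_interval = 0.03) {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      stop("failed to read TIFF '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (length(pages) == 0) stop("empty TIFF stack: ", path, call. = FALSE)
  if (length(dim(pages[[1]])) != 2) {
    stop("multi-channel TIFF not supported: ", path, call. = FALSE)
  }
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1)))) {
    stop("inconsistent frame dimensions in ", path, call. = FALSE)
  }
  spt_movie(
    array(unlist(pages), dim = c(d, length(pages))),
    pixel_size = pixel_size, frame_interval = frame_interval
  )
}

#' Write a movie as 16-bit multi-page TIFF
#'
#' @param movie An [spt_movie()]; values are clipped to `[0, 65535]` and
#'   rounded.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "spt_movie"))
  n <- dim(movie)[3]
  pages <- lapply(seq_len(n), function(t) {
    pmin(pmax(round(unclass(movie)[, , t]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum across a frame range; the standard way to visualise
#' the structure explored by all photoconverted molecules over a recording.
#'
#' @param movie An [spt_movie()].
#' @param frame_range Integer vector of frame indices (default: all).
#' @return A matrix of the movie's height x width.
#' @export
max_projection <- function(movie, frame_range = NULL) {
  stopifnot(inherits(movie, "spt_movie"))
  frame_range <- frame_range %||% seq_len(dim(movie)[3])
  if (length(frame_range) == 0) {
    stop("empty frame range", call. = FALSE)
  }
  stopifnot(all(frame_range >= 1), all(frame_range <= dim(movie)[3]))
  apply(unclass(movie)[, , frame_range, drop = FALSE], c(1, 2), max)
}
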