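#' Image stack container
#'
#' An ordered set of equally sized single-channel frames with a fixed frame
#' interval. All pixel coordinates in this package are 0-based, rectangles
#' half-open `[x0, x1) x [y0, y1)` (x = column, y = row); this convention is
#' stated here once and used everywhere.
#'
#' @param frames Numeric array of dim `height x width x n_frames` (n >= 2).
#' @param frame_interval Seconds per frame (> 0).
#' @param metadata Named list.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, frame_interval, metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("frames must be a height x width x n_frames array")
  }
  if (dim(frames)[3] < 2L) stopf("an image stack needs at least 2 frames")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stopf("frame_interval must be a positive number of seconds")
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %dx%d px @ %.4g s/frame\n",
              d[3], d[2], d[1], x$frame_interval))
  invisible(x)
}

#' Rectangular or mask region of interest
#'
#' @param x0,y0,x1,y1 Rectangle corners, 0-based half-open (`x` = column,
#'   `y` = row): pixels with `x0 <= x < x1`, `y0 <= y < y1`.
#' @param label Region label.
#' @return An `roi` object.
#' @export
roi_rect <- function(x0, y0, x1, y1, label = "roi") {
  structure(list(label = label, type = "rect",
                 coords = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)),
            class = "roi")
}

#' @param mask Logical matrix (height x width), TRUE = pixel in the region.
#' @rdname roi_rect
#' @export
roi_mask <- function(mask, label = "roi") {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stopf("mask must be a logical matrix")
  }
  structure(list(label = label, type = "mask", coords = mask), class = "roi")
}

#' @noRd
check_rect <- function(r, width, height, what = "roi") {
  if (length(r) != 4L || anyNA(r)) stopf("%s rectangle must be c(x0,y0,x1,y1)", what)
  if (r[3] <= r[1] || r[4] <= r[2]) {
    stopf("geometry error: %s region is empty (half-open [x0,x1)x[y0,y1))", what)
  }
  if (r[1] < 0 || r[2] < 0 || r[3] > width || r[4] > height) {
    stopf("geometry error: %s region exceeds the %dx%d frame", what, width, height)
  }
  invisible(r)
}

#' @noRd
rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

# Linear pixel indices of an roi within a height x width frame.
#' @noRd
roi_pixels <- function(roi, height, width) {
  stopifnot(inherits(roi, "roi"))
  if (roi$type == "rect") {
    r <- roi$coords
    check_rect(r, width, height, roi$label)
    rows <- (r[["y0"]] + 1L):r[["y1"]]
    cols <- (r[["x0"]] + 1L):r[["x1"]]
    as.vector(outer(rows, (cols - 1L) * height, `+`))
  } else {
    m <- roi$coords
    if (nrow(m) != height || ncol(m) != width) {
      stopf("geometry error: mask roi '%s' does not match the frame size", roi$label)
    }
    idx <- which(m)
    if (!length(idx)) stopf("geometry error: mask roi '%s' is empty", roi$label)
    idx
  }
}

#' Write an image stack as multi-page TIFF
#'
#' Frames are stored as unsigned 16-bit grayscale. The frame interval (and
#' any metadata) is written to a JSON sidecar file `<path>.json`, the
#' package's stack metadata convention; [read_stack()] reads it back.
#'
#' @param stack An [image_stack()]; pixel values must lie in 0..65535.
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (min(stack$frames) < 0 || max(stack$frames) > 65535) {
    stopf("pixel values must lie in 0..65535 for 16-bit output")
  }
  pages <- lapply(seq_len(d[3]), function(k) stack$frames[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- c(list(frame_interval_s = stack$frame_interval), stack$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' The frame interval is taken from the JSON sidecar `<path>.json` written by
#' [write_stack_tiff()] if present, else from `frame_interval_override`;
#' lacking both is an error.
#'
#' @param path TIFF path.
#' @param frame_interval_override Seconds per frame, used when the file
#'   carries no frame-interval metadata.
#' @return An [image_stack()] with integer pixel counts (0..65535).
#' @export
read_stack <- function(path, frame_interval_override = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("unreadable TIFF '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stopf("image stack '%s' has fewer than 2 frames", path)
  shp <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), shp), logical(1)))) {
    stopf("inconsistent frame shapes in '%s'", path)
  }

  side_path <- paste0(path, ".json")
  metadata <- list()
  fi <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fi <- side$frame_interval_s
    metadata <- side[setdiff(names(side), "frame_interval_s")]
  }
  if (is.null(fi)) fi <- frame_interval_override
  if (is.null(fi)) {
    stopf("no frame interval in metadata for '%s' and no override given", path)
  }
  frames <- array(0, dim = c(shp[1], shp[2], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- round(pages[[k]] * 65535)
  image_stack(frames, fi, metadata)
}

#' Extract a background-subtracted ROI trace from a stack
#'
#' Per frame `i`, the trace value is `mean(cell pixels) - mean(background
#' pixels)`; the background is re-estimated on every frame (rather than once
#' globally) so that slow illumination drift cancels. Optionally the top
#' `bg_trim` fraction of background pixels is dropped per frame before
#' averaging, to discard bright debris reflections; off by default.
#'
#' @param stack An [image_stack()].
#' @param cell,background Disjoint [roi_rect()] / [roi_mask()] regions.
#' @param bg_trim Fraction (0..0.5) of the brightest background pixels to
#'   drop per frame; 0 disables trimming.
#' @return A [fluor_trace()] with `time[i] = (i - 1) * frame_interval`.
#' @export
extract_trace <- function(stack, cell, background, bg_trim = 0) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  ci <- roi_pixels(cell, d[1], d[2])
  bi <- roi_pixels(background, d[1], d[2])
  if (length(intersect(ci, bi))) {
    stopf("geometry error: cell and background ROIs overlap")
  }
  if (bg_trim < 0 || bg_trim >= 0.5) stopf("bg_trim must be in [0, 0.5)")

  n <- d[3]
  npix <- d[1] * d[2]
  fmat <- matrix(stack$frames, nrow = npix, ncol = n)
  cell_means <- colMeans(fmat[ci, , drop = FALSE])
  bg_px <- fmat[bi, , drop = FALSE]
  bg_means <- if (bg_trim > 0) {
    apply(bg_px, 2, function(v) {
      keep <- v <= quantile(v, 1 - bg_trim, type = 7)
      mean(v[keep])
    })
  } else {
    colMeans(bg_px)
  }
  md <- c(stack$metadata,
          list(cell_roi = cell$label, background_roi = background$label,
               n_cell_pixels = length(ci), background_subtracted = TRUE))
  fluor_trace((seq_len(n) - 1L) * stack$frame_interval,
              cell_means - bg_means, md)
}

#' Read / write a trace as CSV
#'
#' Two-column CSV with header `time_s,intensity`. Values are written with 17
#' significant digits so that the write-read round trip is exact for
#' doubles.
#'
#' @param path CSV path.
#' @param trace A [fluor_trace()].
#' @return `read_trace_csv`: a [fluor_trace()]. `write_trace_csv`:
#'   invisibly, `path`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, header = TRUE, colClasses = "character",
                 check.names = FALSE)
  if (!all(c("time_s", "intensity") %in% names(df))) {
    stopf("'%s' must have header columns time_s,intensity", path)
  }
  tm <- suppressWarnings(as.numeric(df$time_s))
  iv <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(tm) | is.na(iv))
  if (length(bad)) {
    stopf("non-numeric value in '%s' at data row %d", path, bad[1])
  }
  if (any(diff(tm) <= 0)) {
    stopf("time column of '%s' is not strictly increasing", path)
  }
  fluor_trace(tm, iv, list(source = path))
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,intensity", con)
  writeLines(sprintf("%.17g,%.17g", trace$time, trace$value), con)
  invisible(path)
}

#' Read an ROI definition from JSON
#'
#' Schema: `{"label": ..., "type": "rect"|"mask", "coords": [x0,y0,x1,y1]
#' or row-major 0/1 matrix}`.
#'
#' @param path JSON path.
#' @return An `roi` object.
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$type) || !j$type %in% c("rect", "mask")) {
    stopf("roi file '%s' must have type \"rect\" or \"mask\"", path)
  }
  label <- if (is.null(j$label)) "roi" else j$label
  if (j$type == "rect") {
    roi_rect(j$coords[1], j$coords[2], j$coords[3], j$coords[4], label)
  } else {
    roi_mask(matrix(as.logical(j$coords), nrow = nrow(j$coords)), label)
  }
}
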