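# Motion energy analysis (MEA): frame differencing within a region of interest.

#' Construct a frame stack
#'
#' A frame stack is an ordered sequence of equally shaped 2-D grayscale
#' intensity grids, the raw material for motion energy analysis.
#'
#' @param frames a list of numeric matrices (all the same dimension) or a 3-D
#'   array with dimensions `c(nrow, ncol, n_frames)`.
#' @param fps frames per second (default 25, the usual PAL video rate).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 25) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a frame stack needs at least 2 frames", call. = FALSE)
  }
  d <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !identical(dim(f), d)) {
      stop(sprintf("frame %d does not match the shape of frame 1 (%d x %d)",
                   k, d[1], d[2]), call. = FALSE)
    }
    if (anyNA(f) || any(!is.finite(f)) || any(f < 0)) {
      stop(sprintf("frame %d contains non-finite or negative intensities", k),
           call. = FALSE)
    }
  }
  assert_scalar_number(fps, "fps", min = 1e-9)
  structure(list(frames = frames, fps = fps, dim = d),
            class = "frame_stack")
}

#' Define a rectangular region of interest
#'
#' Row and column ranges use 0-based half-open indexing `[from, to)`, so
#' `roi(c(0, 10), c(0, 20))` covers the top-left 10 x 20 pixel block.
#'
#' @param rows integer vector `c(from, to)`, 0-based half-open.
#' @param cols integer vector `c(from, to)`, 0-based half-open.
#' @return an object of class `roi` with an `area` field (pixel count).
#' @export
roi <- function(rows, cols) {
  for (r in list(rows = rows, cols = cols)) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] < 0 || r[2] <= r[1]) {
      stop("roi ranges must be c(from, to) with 0 <= from < to", call. = FALSE)
    }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 area = as.integer((rows[2] - rows[1]) * (cols[2] - cols[1]))),
            class = "roi")
}

check_roi_in_frame <- function(r, d) {
  if (r$rows[2] > d[1]) {
    stop(sprintf("roi row range [%d,%d) exceeds frame height %d",
                 r$rows[1], r$rows[2], d[1]), call. = FALSE)
  }
  if (r$cols[2] > d[2]) {
    stop(sprintf("roi column range [%d,%d) exceeds frame width %d",
                 r$cols[1], r$cols[2], d[2]), call. = FALSE)
  }
  invisible(r)
}

#' Construct a motion energy time series (METS)
#'
#' @param values per-frame non-negative movement magnitudes; the value at frame
#'   t is derived from frames t-1 and t, and frame 0 carries 0 by convention.
#' @param fps frames per second.
#' @param roi_area pixel count of the region of interest the series came from
#'   (needed for size standardization), or `NA` if unknown.
#' @param person_role `"patient"` or `"therapist"`.
#' @return an object of class `mets`.
#' @export
mets <- function(values, fps = 25, roi_area = NA_integer_,
                 person_role = c("patient", "therapist")) {
  person_role <- match.arg(person_role)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("motion energy values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("motion energy values must be non-negative", call. = FALSE)
  }
  assert_scalar_number(fps, "fps", min = 1e-9)
  structure(list(values = values, fps = fps, roi_area = roi_area,
                 person_role = person_role),
            class = "mets")
}

#' @export
print.mets <- function(x, ...) {
  cat(sprintf("<mets> %s, %d frames @ %g fps, roi_area = %s\n",
              x$person_role, length(x$values), x$fps,
              ifelse(is.na(x$roi_area), "NA", x$roi_area)))
  invisible(x)
}

#' @export
length.mets <- function(x) length(x$values)

#' Compute a motion energy time series by frame differencing
#'
#' Counts, for every consecutive frame pair, the ROI pixels whose absolute
#' intensity change exceeds `diff_threshold`. Frame 0 has no predecessor and
#' carries motion energy 0, so the series is frame-aligned with the stack.
#'
#' @param stack a [frame_stack()].
#' @param region a [roi()] lying inside the frame shape.
#' @param diff_threshold minimum absolute intensity change for a pixel to count
#'   as moving, in the same units as the frame intensities (default 10 on a
#'   0-255 scale).
#' @param fps,person_role metadata forwarded to [mets()].
#' @return a [mets()] of the same length as the stack, with `roi_area` set.
#' @export
compute_motion_energy <- function(stack, region, diff_threshold = 10,
                                  person_role = "patient") {
  stopifnot(inherits(stack, "frame_stack"), inherits(region, "roi"))
  assert_scalar_number(diff_threshold, "diff_threshold", min = 0)
  check_roi_in_frame(region, stack$dim)
  ri <- (region$rows[1] + 1L):region$rows[2]
  ci <- (region$cols[1] + 1L):region$cols[2]
  n <- length(stack$frames)
  values <- numeric(n)
  prev <- stack$frames[[1L]][ri, ci, drop = FALSE]
  for (t in 2:n) {
    cur <- stack$frames[[t]][ri, ci, drop = FALSE]
    values[t] <- sum(abs(cur - prev) > diff_threshold)
    prev <- cur
  }
  mets(values, fps = stack$fps, roi_area = region$area,
       person_role = person_role)
}

#' Ratio of the larger to the smaller region of interest
#'
#' Used by size standardization: the series recorded with the smaller ROI is
#' scaled up by this ratio so that the two persons' value ranges are
#' comparable.
#'
#' @param roi_a,roi_b [roi()] objects or plain positive areas.
#' @return a list with `ratio` (>= 1) and `smaller` (`"a"`, `"b"` or `"tie"`).
#' @export
roi_ratio <- function(roi_a, roi_b) {
  area <- function(x) if (inherits(x, "roi")) x$area else x
  a <- area(roi_a); b <- area(roi_b)
  if (!is.finite(a) || !is.finite(b) || a < 1 || b < 1) {
    stop("both roi areas must be >= 1", call. = FALSE)
  }
  list(ratio = max(a, b) / min(a, b),
       smaller = if (a < b) "a" else if (b < a) "b" else "tie")
}

#' Read a frame stack from a multi-page TIFF or a directory of images
#'
#' Requires the `tiff` package. A directory is read as one frame per file in
#' lexicographic order; RGB images are converted to grayscale by channel
#' averaging.
#'
#' @param path a multi-page TIFF file or a directory of single-frame TIFFs.
#' @param fps frames per second recorded in the result.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, fps = 25) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading frame stacks requires the 'tiff' package", call. = FALSE)
  }
  to_gray <- function(img) {
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    img
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) < 2L) stop("need at least 2 frame files", call. = FALSE)
    frames <- lapply(files, function(f) to_gray(tiff::readTIFF(f)))
  } else {
    frames <- lapply(tiff::readTIFF(path, all = TRUE), to_gray)
  }
  frame_stack(frames, fps = fps)
}

#' Write / read a METS as delimited text with a JSON metadata sidecar
#'
#' The series is written as tab-separated `frame,value` pairs (0-based frames)
#' and the metadata (`fps`, `roi_area`, `person_role`) to `<path>.json`.
#'
#' @param x a [mets()].
#' @param path output file path.
#' @return `write_mets` returns `path` invisibly; `read_mets` a [mets()].
#' @export
write_mets <- function(x, path) {
  stopifnot(inherits(x, "mets"))
  utils::write.table(
    data.frame(frame = seq_along(x$values) - 1L, value = x$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fps = x$fps, roi_area = x$roi_area, person_role = x$person_role),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mets
#' @export
read_mets <- function(path) {
  tab <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  mets(tab$value, fps = meta$fps,
       roi_area = if (is.null(meta$roi_area)) NA_integer_ else meta$roi_area,
       person_role = meta$person_role)
}
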