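read_frame_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(
    ext,
    png = {
      x <- png::readPNG(path, info = TRUE)
      info <- attr(x, "info")
      depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
      x * (2^depth - 1)  # back to raw sample values
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
      if (is.list(x)) {
        if (length(x) > 1L) {
          abort("Multi-page TIFF stacks are not supported; supply one frame per file.")
        }
        x <- x[[1]]
      }
      x
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("Reading JPEG requires the 'jpeg' package.")
      }
      jpeg::readJPEG(path) * 255
    },
    abort(sprintf("Unsupported image format '.%s' (supported: png, tiff, jpg).", ext))
  )
  if (length(dim(img)) == 3L) {
    # color: Rec. 601 luminance; equal channels reduce to the common value
    nch <- dim(img)[3]
    w <- c(0.299, 0.587, 0.114)[seq_len(min(nch, 3L))]
    w <- w / sum(w)
    img <- Reduce(`+`, lapply(seq_along(w), function(k) w[k] * img[, , k]))
  }
  storage.mode(img) <- "double"
  img
}

#' Load a movie from an ordered list of image files
#'
#' Reads numbered single-frame image files (PNG, single-page TIFF, JPEG) in
#' the order given and stacks them into an [image_stack()]. Color frames are
#' reduced to one channel with Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); intensities are kept on the raw sample
#' scale of the file (0..255 for 8-bit, 0..65535 for 16-bit).
#'
#' @param paths Character vector of file paths, in temporal order.
#' @param fps Frame rate of the footage, frames per second.
#' @param um_per_px Pixel size, micrometers.
#' @return An [image_stack()].
#' @export
load_stack <- function(paths, fps = 1, um_per_px = 1) {
  if (length(paths) == 0L) abort("No input files given.")
  frames <- lapply(paths, read_frame_file)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) {
    abort("Input frames have mixed dimensions; all frames must match.")
  }
  image_stack(frames, fps = fps, um_per_px = um_per_px)
}

#' Load a movie from a video file
#'
#' Decodes a video container by shelling out to an `ffmpeg` binary on the
#' PATH (extracting frames as 16-bit grayscale PNG), then loads the frames
#' with [load_stack()]. The frame rate is read from the container unless
#' `fps_override` is given.
#'
#' @param path Video file.
#' @param fps_override Optional frame rate to record instead of the
#'   container's.
#' @param um_per_px Pixel size, micrometers.
#' @return An [image_stack()].
#' @export
load_video <- function(path, fps_override = NULL, um_per_px = 1) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg)) {
    abort("Video loading requires an `ffmpeg` binary on the PATH.")
  }
  out <- tempfile("frames")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  status <- system2(ffmpeg,
                    c("-i", shQuote(path), "-pix_fmt", "gray16be", "-vsync", "0",
                      shQuote(file.path(out, "frame_%06d.png"))),
                    stdout = FALSE, stderr = FALSE)
  files <- sort(list.files(out, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (status != 0 || length(files) == 0L) {
    abort(sprintf("ffmpeg could not decode '%s'.", path))
  }
  fps <- fps_override
  if (is.null(fps)) {
    probe <- suppressWarnings(
      system2(ffmpeg, c("-i", shQuote(path)), stdout = TRUE, stderr = TRUE)
    )
    m <- regmatches(probe, regexpr("[0-9.]+ fps", probe))
    fps <- if (length(m)) as.numeric(sub(" fps", "", m[[1]])) else 1
  }
  load_stack(files, fps = fps, um_per_px = um_per_px)
}

#' Write / read a 16-bit label mask
#'
#' Serializes a [roi_set()] as a 16-bit grayscale TIFF (or PNG) whose pixel
#' values are the ROI ids (0 = background), so membership is exactly
#' recoverable. At most 65535 ROIs fit into 16 bits.
#'
#' @param rois A [roi_set()].
#' @param path Output file; extension selects TIFF (`.tif`/`.tiff`) or PNG.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(rois, path) {
  if (nrow(rois) > 65535L) abort("More than 65535 ROIs cannot be stored in 16 bits.")
  lab <- as_label_matrix(rois)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(lab / 65535, path)
  } else {
    abort("Label masks are written as .tiff or .png.")
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @param min_size_px Minimum cluster size kept when reading back.
#' @export
read_label_mask <- function(path, min_size_px = 1L) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lab <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else {
    round(png::readPNG(path) * 65535)
  }
  roi_set_from_labels(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)),
                      min_size_px = min_size_px)
}

pivot_roi_wide <- function(df, value_col) {
  wide <- tidyr::pivot_wider(df,
                             id_cols = "frame",
                             names_from = "roi_id",
                             names_prefix = "roi_",
                             values_from = dplyr::all_of(value_col))
  dplyr::arrange(wide, .data$frame)
}

pivot_roi_long <- function(wide, value_col) {
  long <- tidyr::pivot_longer(wide, -"frame",
                              names_to = "roi_id", names_prefix = "roi_",
                              values_to = value_col)
  long$roi_id <- as.integer(long$roi_id)
  dplyr::arrange(long, .data$roi_id, .data$frame)[, c("roi_id", "frame", value_col)]
}

#' Write tabular results to CSV
#'
#' All writers use comma separators, `.` decimals, a header row and UTF-8.
#' Traces, rates and spikes are written wide: an integer `frame` column plus
#' one `roi_<id>` column per ROI, one row per frame. Edges are written one
#' row per directed edge. Values round-trip through the matching readers at
#' full double precision.
#'
#' @param traces Long tibble `(roi_id, frame, brightness)` from
#'   [extract_traces()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(nrow(traces) > 0)
  readr::write_csv(pivot_roi_wide(traces, "brightness"), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  out <- pivot_roi_long(wide, "brightness")
  class(out) <- c("trace_set", class(out))
  out
}

#' @rdname write_traces_csv
#' @param rates Long tibble `(roi_id, frame, rate)` from [rate_of_change()].
#' @export
write_rates_csv <- function(rates, path) {
  stopifnot(nrow(rates) > 0)
  readr::write_csv(pivot_roi_wide(rates, "rate"), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_rates_csv <- function(path) {
  pivot_roi_long(readr::read_csv(path, show_col_types = FALSE), "rate")
}

#' @rdname write_traces_csv
#' @param spikes Long tibble containing `(roi_id, frame, spike)` from
#'   [detect_spikes()].
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(nrow(spikes) > 0)
  readr::write_csv(pivot_roi_wide(spikes, "spike"), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_spikes_csv <- function(path) {
  out <- pivot_roi_long(readr::read_csv(path, show_col_types = FALSE), "spike")
  out$spike <- as.integer(out$spike)
  out
}

#' @rdname write_traces_csv
#' @param edges Edge tibble from [reconstruct_network()] / [tidy()].
#' @export
write_edges_csv <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_edges_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_traces_csv
#' @param rois A [roi_set()]; written as `id, centroid_row, centroid_col,
#'   area_px` (pixel coordinates, 1-based).
#' @export
write_rois_csv <- function(rois, path) {
  readr::write_csv(
    tibble::as_tibble(rois)[, c("id", "centroid_row", "centroid_col", "area_px")],
    path)
  invisible(path)
}
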