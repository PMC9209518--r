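#' Read a FRAP trace from CSV
#'
#' Expected columns: `frame`, `time_s`, `i_bleached`, `i_control`,
#' `i_background`. The bleach frame comes from a `bleach_frame` argument, a
#' `bleach_frame` column (constant), or a JSON sidecar `<file>.json` with a
#' `bleach_frame` field.
#'
#' @param path CSV path.
#' @param bleach_frame Optional explicit index of the first post-bleach
#'   frame (1-based).
#' @return A `frap_trace` tibble.
#' @export
read_frap_trace <- function(path, bleach_frame = NULL) {
  df <- as_tibble(utils::read.csv(path))
  need <- c("frame", "time_s", "i_bleached", "i_control", "i_background")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("Missing columns: %s", paste(miss, collapse = ", ")))
  if (is.null(bleach_frame)) {
    if ("bleach_frame" %in% names(df)) {
      bleach_frame <- df$bleach_frame[1]
    } else {
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        bleach_frame <- jsonlite::read_json(sidecar)$bleach_frame
      }
    }
  }
  if (is.null(bleach_frame)) abort("`bleach_frame` not found (argument, column or sidecar).")
  structure(df[need], class = c("frap_trace", class(df)),
            bleach_frame = as.integer(bleach_frame))
}

#' Write a FRAP trace to CSV (with JSON sidecar for the bleach frame)
#'
#' @param trace A `frap_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(list(bleach_frame = attr(trace, "bleach_frame")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write an image stack as a multi-page TIFF (requires the tiff package)
#'
#' Frames are written in acquisition order (axes T, then YX per page), with
#' intensities rescaled to \[0, 1\] as 32-bit floats; the scale factor is
#' saved in a JSON sidecar together with frame times, pixel size and any
#' ground truth.
#'
#' @param stack A `chromo_timelapse` or numeric array `(ny, nx, n_frames)`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required to write TIFF stacks.")
  }
  meta <- list()
  if (inherits(stack, "chromo_timelapse")) {
    meta <- list(time_s = stack$time_s, pixel_size_um = stack$pixel_size_um,
                 cell_id = stack$cell_id,
                 events = stack$truth$events[, c("kind", "frame", "y_um", "x_um")])
    stack <- stack$frames
  }
  lo <- min(stack); hi <- max(stack)
  pages <- purrr::map(seq_len(dim(stack)[3]), ~ (stack[, , .x] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta$intensity_scale <- hi - lo
  meta$intensity_offset <- lo
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_timelapse()]
#'
#' @param path TIFF path (JSON sidecar `<path>.json` is read when present).
#' @return A list with `frames` (array), plus any sidecar metadata.
#' @export
read_timelapse <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required to read TIFF stacks.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- simplify2array(pages)
  out <- list(frames = frames)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) {
      frames <- frames * meta$intensity_scale + (meta$intensity_offset %||% 0)
    }
    out <- c(list(frames = frames),
             meta[setdiff(names(meta), c("intensity_scale", "intensity_offset"))])
  }
  out
}
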