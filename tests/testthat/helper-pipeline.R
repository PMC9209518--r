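# shared helpers for the test suite

# run the full detect -> link pipeline on one synthetic time-lapse
track_cell <- function(preset, seed, cell_id = 1L, threshold = 90,
                       max_disp_um = 1.2, ...) {
  tl <- make_timelapse(preset, seed = seed, cell_id = cell_id, ...)
  det <- detect_foci(tl, threshold = threshold)
  lt <- link_tracks(det, max_disp_um = max_disp_um, max_gap_frames = 1)
  list(tl = tl, det = det, lt = lt)
}

# detect + link on an existing time-lapse object
track_cell_from <- function(tl, threshold = 90) {
  det <- detect_foci(tl, threshold = threshold)
  list(det = det, lt = link_tracks(det, max_disp_um = 1.2, max_gap_frames = 1))
}

# noiseless corrected FRAP curve for a preset
noiseless_curve <- function(preset, seed = 1) {
  correct_trace(make_frap_trace(preset, seed = seed, noise_sd = 0))
}

# single Gaussian blob (tests build their own fixtures)
render_blobs_for_test <- function(img, cy, cx, amp, sigma) {
  yy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  xx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img + amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
}

# render one hard disk in a blank image
disk_image <- function(ny, nx, cy, cx, r, fg = 100, bg = 0) {
  img <- matrix(bg, ny, nx)
  img[disk_mask_for_test(ny, nx, cy, cx, r)] <- fg
  img
}

disk_mask_for_test <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
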