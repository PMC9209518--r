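#' Detect chromocenter foci in a time-lapse stack
#'
#' Per-frame thresholding and connected-component labelling; detections are
#' reported as intensity-weighted centroids in micrometres.
#'
#' @param stack A `chromo_timelapse` (see [make_timelapse()]) or a numeric
#'   array `(ny, nx, n_frames)`.
#' @param time_s Frame times (taken from the object if available).
#' @param pixel_size_um Pixel size (idem).
#' @param threshold Absolute intensity threshold; `NULL` uses Otsu's method
#'   on the first frame (one constant threshold for the whole stack).
#' @param min_area Minimum component area in pixels.
#' @param cell_id Identifier carried through to the detections.
#'
#' @return A tibble with `cell_id`, `frame`, `time_s`, `y_um`, `x_um`,
#'   `area_px`, `intensity` (summed).
#' @export
detect_foci <- function(stack, time_s = NULL, pixel_size_um = NULL,
                        threshold = NULL, min_area = 3, cell_id = NULL) {
  if (inherits(stack, "chromo_timelapse")) {
    time_s <- time_s %||% stack$time_s
    pixel_size_um <- pixel_size_um %||% stack$pixel_size_um
    cell_id <- cell_id %||% stack$cell_id
    stack <- stack$frames
  }
  if (is.null(pixel_size_um)) abort("`pixel_size_um` is required.")
  n_frames <- dim(stack)[3]
  time_s <- time_s %||% seq_len(n_frames)
  cell_id <- cell_id %||% 1L
  if (is.null(threshold)) {
    f1 <- stack[, , 1]
    rng <- range(f1)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image((f1 - rng[1]) / diff(rng))) * diff(rng)
  }
  purrr::map_dfr(seq_len(n_frames), function(f) {
    img <- stack[, , f]
    lab <- EBImage::bwlabel(img > threshold)
    nl <- max(lab)
    if (nl == 0) return(tibble())
    rows <- purrr::map_dfr(seq_len(nl), function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      if (nrow(px) < min_area) return(tibble())
      w <- img[px]
      tibble(
        cell_id = cell_id, frame = f, time_s = time_s[f],
        y_um = sum(px[, 1] * w) / sum(w) * pixel_size_um,
        x_um = sum(px[, 2] * w) / sum(w) * pixel_size_um,
        area_px = nrow(px), intensity = sum(w)
      )
    })
    rows
  })
}

#' Link detections into tracks with coalescence/cleavage calling
#'
#' Frame-to-frame assignment by the Hungarian algorithm on gated Euclidean
#' distances, with gap closing. With `allow_merge_split = TRUE`, a track that
#' loses its detection but ends within `max_disp_um` of a detection claimed
#' by another track is merged into it (a *coalescence*); an unmatched
#' detection appearing within `max_disp_um` of a track that was matched in
#' the same frame seeds a child track (a *cleavage*).
#'
#' @param detections Tibble from [detect_foci()] (columns `frame`, `time_s`,
#'   `y_um`, `x_um`, optional `cell_id`, `intensity`).
#' @param max_disp_um Gating radius per frame step; `NULL` uses 3x the median
#'   frame-to-frame nearest-neighbour displacement estimated from the data.
#' @param max_gap_frames Frames a track may go undetected before closing.
#' @param allow_merge_split Call coalescence/cleavage events.
#'
#' @return A list of class `chromo_tracks`:
#' * `points`: detections with a `track_id` column;
#' * `tracks`: per-track metadata (`track_id`, `cell_id`, `start_frame`,
#'   `end_frame`, `duration_s`, `n_points`, `parent`, `merged_into`);
#' * `events`: tibble (`kind`, `frame`, `time_s`, `y_um`, `x_um`,
#'   `participants` list-column of track ids);
#' * `max_disp_um` actually used.
#' @export
link_tracks <- function(detections, max_disp_um = NULL, max_gap_frames = 1L,
                        allow_merge_split = TRUE) {
  if (nrow(detections) == 0) {
    return(structure(list(
      points = detections, tracks = tibble(), events = empty_events(),
      max_disp_um = max_disp_um
    ), class = "chromo_tracks"))
  }
  det <- dplyr::arrange(detections, .data$frame)
  if (!"cell_id" %in% names(det)) det$cell_id <- 1L
  cells <- unique(det$cell_id)
  if (length(cells) > 1) {
    # link each cell independently, with globally unique track ids
    parts <- purrr::map(cells, function(cid) {
      link_tracks(det[det$cell_id == cid, ], max_disp_um = max_disp_um,
                  max_gap_frames = max_gap_frames,
                  allow_merge_split = allow_merge_split)
    })
    offset <- 0L
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      p$points$track_id <- p$points$track_id + offset
      p$tracks$track_id <- p$tracks$track_id + offset
      p$tracks$parent <- p$tracks$parent + offset
      p$tracks$merged_into <- p$tracks$merged_into + offset
      p$events$participants <- purrr::map(p$events$participants, ~ .x + offset)
      p$events$cell_id <- rep(cells[i], nrow(p$events))
      offset <- if (nrow(p$tracks)) max(p$tracks$track_id) else offset
      parts[[i]] <- p
    }
    return(structure(list(
      points = purrr::map_dfr(parts, "points"),
      tracks = purrr::map_dfr(parts, "tracks"),
      events = purrr::map_dfr(parts, "events"),
      max_disp_um = max_disp_um
    ), class = "chromo_tracks"))
  }
  if (is.null(max_disp_um)) max_disp_um <- 3 * median_nn_step(det)
  if (max_disp_um <= 0) abort("`max_disp_um` must be > 0.")

  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  # track state
  st <- list(id = integer(0), cell = integer(0), last_frame = integer(0),
             y = numeric(0), x = numeric(0), open = logical(0),
             start_frame = integer(0), start_time = numeric(0),
             last_time = numeric(0), n = integer(0),
             parent = integer(0), merged_into = integer(0))
  next_id <- 1L
  events <- list()

  new_track <- function(st, cell, f, tm, y, x, parent = NA_integer_) {
    st$id <- c(st$id, next_id); st$cell <- c(st$cell, cell)
    st$last_frame <- c(st$last_frame, f); st$y <- c(st$y, y); st$x <- c(st$x, x)
    st$open <- c(st$open, TRUE)
    st$start_frame <- c(st$start_frame, f); st$start_time <- c(st$start_time, tm)
    st$last_time <- c(st$last_time, tm); st$n <- c(st$n, 1L)
    st$parent <- c(st$parent, parent); st$merged_into <- c(st$merged_into, NA_integer_)
    st
  }

  for (f in frames) {
    di <- which(det$frame == f)
    D <- det[di, ]
    tm <- D$time_s[1]
    cand <- which(st$open & (f - st$last_frame) <= (max_gap_frames + 1L) &
                    st$cell == D$cell_id[1])
    assigned_det <- rep(NA_integer_, nrow(D))  # track index per detection
    matched_tr <- integer(0)
    prev_y <- st$y; prev_x <- st$x

    if (length(cand)) {
      gate <- max_disp_um * (f - st$last_frame[cand])
      cost <- outer(st$y[cand], D$y_um, "-")^2 + outer(st$x[cand], D$x_um, "-")^2
      cost <- sqrt(cost)
      big <- 1e9
      cost[cost > gate] <- big
      nr <- length(cand); nc <- nrow(D)
      m <- max(nr, nc)
      pad <- matrix(big, m, m)
      pad[seq_len(nr), seq_len(nc)] <- cost
      sol <- clue::solve_LSAP(pad)
      for (r in seq_len(nr)) {
        c_ <- sol[r]
        if (c_ <= nc && pad[r, c_] < big) {
          ti <- cand[r]
          assigned_det[c_] <- ti
          matched_tr <- c(matched_tr, ti)
          st$last_frame[ti] <- f; st$last_time[ti] <- tm
          st$y[ti] <- D$y_um[c_]; st$x[ti] <- D$x_um[c_]
          st$n[ti] <- st$n[ti] + 1L
          det$track_id[di[c_]] <- st$id[ti]
        }
      }
    }

    # unmatched detections: cleavage children or new tracks
    for (c_ in which(is.na(assigned_det))) {
      parent <- NA_integer_
      if (allow_merge_split && length(matched_tr)) {
        dists <- sqrt((prev_y[matched_tr] - D$y_um[c_])^2 +
                        (prev_x[matched_tr] - D$x_um[c_])^2)
        ok <- which(dists <= max_disp_um)
        if (length(ok)) {
          ti <- matched_tr[ok[which.min(dists[ok])]]
          parent <- st$id[ti]
          events[[length(events) + 1]] <- tibble(
            kind = "cleavage", frame = f, time_s = tm,
            y_um = D$y_um[c_], x_um = D$x_um[c_],
            participants = list(c(parent, next_id))
          )
        }
      }
      st <- new_track(st, D$cell_id[c_], f, tm, D$y_um[c_], D$x_um[c_], parent)
      det$track_id[di[c_]] <- next_id
      next_id <- next_id + 1L
    }

    # open tracks that lost their detection: coalescence or gap/closure
    lost <- which(st$open & st$last_frame < f & st$cell == D$cell_id[1])
    for (ti in lost) {
      merged <- FALSE
      gap_f <- f - st$last_frame[ti]
      if (allow_merge_split && gap_f <= max_gap_frames + 1L && length(matched_tr)) {
        dists <- sqrt((st$y[matched_tr] - st$y[ti])^2 + (st$x[matched_tr] - st$x[ti])^2)
        ok <- which(dists <= max_disp_um * gap_f & matched_tr != ti)
        if (length(ok)) {
          tj <- matched_tr[ok[which.min(dists[ok])]]
          st$open[ti] <- FALSE
          st$merged_into[ti] <- st$id[tj]
          events[[length(events) + 1]] <- tibble(
            kind = "coalescence", frame = f, time_s = tm,
            y_um = st$y[tj], x_um = st$x[tj],
            participants = list(c(st$id[ti], st$id[tj]))
          )
          merged <- TRUE
        }
      }
      if (!merged && (f - st$last_frame[ti]) > max_gap_frames) {
        st$open[ti] <- FALSE
      }
    }
  }

  tracks <- tibble(
    track_id = st$id, cell_id = st$cell,
    start_frame = st$start_frame, end_frame = st$last_frame,
    duration_s = st$last_time - st$start_time,
    n_points = st$n, parent = st$parent, merged_into = st$merged_into
  )
  ev <- if (length(events)) dplyr::bind_rows(events) else empty_events()
  structure(list(points = det, tracks = tracks, events = ev,
                 max_disp_um = max_disp_um),
            class = "chromo_tracks")
}

empty_events <- function() {
  tibble(kind = character(0), frame = integer(0), time_s = numeric(0),
         y_um = numeric(0), x_um = numeric(0), participants = list())
}

median_nn_step <- function(det) {
  frames <- sort(unique(det$frame))
  if (length(frames) < 2) return(1)
  steps <- purrr::map_dbl(seq_len(length(frames) - 1), function(i) {
    a <- det[det$frame == frames[i], ]
    b <- det[det$frame == frames[i + 1], ]
    if (!nrow(a) || !nrow(b)) return(NA_real_)
    d <- sqrt(outer(a$y_um, b$y_um, "-")^2 + outer(a$x_um, b$x_um, "-")^2)
    median(apply(d, 1, min))
  })
  median(steps, na.rm = TRUE)
}

#' Per-cell fraction of long tracks engaging in an event
#'
#' A track qualifies when its duration is at least `min_duration_s`
#' (default 10 min); it is *engaged* when its id appears among the
#' participants of at least one coalescence or cleavage event. Cells with no
#' qualifying track are excluded with a warning.
#'
#' @param tracks Either a `chromo_tracks` object or its `tracks` tibble.
#' @param events Events tibble (ignored when `tracks` is a `chromo_tracks`).
#' @param min_duration_s Minimum track duration.
#'
#' @return A tibble per cell: `cell_id`, `n_qualifying`, `n_engaged`,
#'   `engagement` (fraction in \[0, 1\]). Summarize across cells as a median
#'   with interquartile range via [summarize_engagement()].
#' @export
event_engagement <- function(tracks, events = NULL, min_duration_s = 600) {
  if (inherits(tracks, "chromo_tracks")) {
    events <- tracks$events
    tracks <- tracks$tracks
  }
  if (is.null(events)) abort("`events` is required.")
  engaged_ids <- unique(unlist(events$participants))
  qual <- dplyr::filter(tracks, .data$duration_s >= min_duration_s)
  dropped <- setdiff(unique(tracks$cell_id), unique(qual$cell_id))
  if (length(dropped)) {
    warn(sprintf("%d cell(s) without qualifying tracks excluded.", length(dropped)))
  }
  qual |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_qualifying = dplyr::n(),
      n_engaged = sum(.data$track_id %in% engaged_ids),
      engagement = .data$n_engaged / .data$n_qualifying,
      .groups = "drop"
    )
}

#' Median engagement with interquartile range across cells
#'
#' @param engagement Output of [event_engagement()], possibly row-bound over
#'   many cells, with an optional `condition` column.
#' @return One row per condition: `median`, `q25`, `q75`, `n_cells`.
#' @export
summarize_engagement <- function(engagement) {
  g <- if ("condition" %in% names(engagement)) "condition" else character(0)
  engagement |>
    dplyr::group_by(dplyr::across(dplyr::all_of(g))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median = median(.data$engagement),
      q25 = unname(quantile(.data$engagement, 0.25)),
      q75 = unname(quantile(.data$engagement, 0.75)),
      .groups = "drop"
    )
}

#' Match called events against ground truth
#'
#' Greedy one-to-one matching of called to truth events of the same kind
#' within a frame tolerance and a spatial tolerance.
#'
#' @param called,truth Event tibbles (`kind`, `frame`, `y_um`, `x_um`).
#' @param tol_frames Frame tolerance (default 1).
#' @param tol_um Spatial tolerance in micrometres.
#' @return A one-row tibble: `n_called`, `n_truth`, `n_matched`, `precision`,
#'   `recall`.
#' @export
evaluate_events <- function(called, truth, tol_frames = 1L, tol_um = 1.5) {
  used <- rep(FALSE, nrow(truth))
  n_matched <- 0L
  if (nrow(called)) {
    for (i in seq_len(nrow(called))) {
      cand <- which(!used & truth$kind == called$kind[i] &
                      abs(truth$frame - called$frame[i]) <= tol_frames)
      if (!length(cand)) next
      d <- sqrt((truth$y_um[cand] - called$y_um[i])^2 +
                  (truth$x_um[cand] - called$x_um[i])^2)
      j <- cand[which.min(d)]
      if (min(d) <= tol_um) {
        used[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  tibble(
    n_called = nrow(called), n_truth = nrow(truth), n_matched = n_matched,
    precision = if (nrow(called)) n_matched / nrow(called) else NA_real_,
    recall = if (nrow(truth)) n_matched / nrow(truth) else NA_real_
  )
}
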