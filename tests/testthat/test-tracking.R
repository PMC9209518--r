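test_that("well-separated stationary foci give one track each and no events", {
  det <- tidyr::expand_grid(frame = 1:10, focus = 1:2) |>
    dplyr::mutate(time_s = frame * 30,
                  y_um = ifelse(focus == 1, 5, 15),
                  x_um = 10, cell_id = 1L) |>
    dplyr::select(-focus)
  lt <- link_tracks(det, max_disp_um = 1.2)
  expect_equal(nrow(lt$tracks), 2)
  expect_equal(nrow(lt$events), 0)
  expect_equal(sort(unique(lt$points$track_id)), 1:2)
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(1)
  base <- tidyr::expand_grid(frame = 1:8, focus = 1:4) |>
    dplyr::mutate(time_s = frame, cell_id = 1L,
                  y_um = focus * 4 + rnorm(dplyr::n(), sd = 0.1),
                  x_um = focus * 3 + rnorm(dplyr::n(), sd = 0.1))
  shuffled <- base[sample(nrow(base)), ]
  a <- link_tracks(dplyr::select(base, -focus), max_disp_um = 1)
  b <- link_tracks(dplyr::select(shuffled, -focus), max_disp_um = 1)
  key <- function(lt) {
    dplyr::arrange(lt$points, .data$frame, .data$y_um) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(sig = paste(round(.data$y_um, 6), collapse = "|")) |>
      dplyr::pull(.data$sig) |> sort()
  }
  expect_identical(key(a), key(b))
})

test_that("a scripted merge yields exactly one coalescence at the scripted frame", {
  forced <- tibble::tibble(kind = "coalescence", frame = 20L, focus = NA_integer_)
  tl <- make_timelapse("ctrl_dynamics", seed = 21, forced_events = forced)
  expect_equal(nrow(tl$truth$events), 1)
  expect_equal(tl$truth$events$kind, "coalescence")
  expect_equal(tl$truth$events$frame, 20L)

  res <- track_cell_from(tl)
  co <- res$lt$events[res$lt$events$kind == "coalescence", ]
  expect_equal(nrow(co), 1)
  expect_lte(abs(co$frame - 20L), 1L)
})

test_that("a scripted split yields exactly one cleavage at the scripted frame", {
  forced <- tibble::tibble(kind = "cleavage", frame = 15L, focus = NA_integer_)
  tl <- make_timelapse("ctrl_dynamics", seed = 22, forced_events = forced)
  expect_equal(tl$truth$events$kind, "cleavage")
  expect_equal(tl$truth$events$frame, 15L)

  res <- track_cell_from(tl)
  cl <- res$lt$events[res$lt$events$kind == "cleavage", ]
  expect_equal(nrow(cl), 1)
  expect_lte(abs(cl$frame - 15L), 1L)
})

test_that("event-free noiseless movies are tracked exactly", {
  p <- chromodyn_preset("dynamics", "ctrl_dynamics")
  p$fusion_rate <- 0; p$fission_rate <- 0
  tl <- make_timelapse(p, seed = 8)
  det <- detect_foci(tl, threshold = 90)
  lt <- link_tracks(det, max_disp_um = 1.2)
  truth_n <- length(unique(tl$truth$positions$focus_id))
  expect_equal(nrow(lt$tracks), truth_n)
  expect_equal(nrow(lt$events), 0)
  expect_true(all(lt$tracks$n_points == max(det$frame)))
  # every truth focus matches one track start-to-end within half a pixel
  first <- dplyr::filter(lt$points, .data$frame == 1)
  t1 <- dplyr::filter(tl$truth$positions, .data$frame == 1)
  d <- sqrt(outer(first$y_um, t1$y_um, "-")^2 + outer(first$x_um, t1$x_um, "-")^2)
  expect_true(all(apply(d, 1, min) < 0.15))
})

test_that("engagement counts qualifying tracks with at least one event", {
  tracks <- tibble::tibble(track_id = 1:4, cell_id = 1L,
                           duration_s = c(1200, 900, 300, 700))
  ev <- tibble::tibble(kind = "coalescence", frame = 10L, time_s = 300,
                       y_um = 0, x_um = 0, participants = list(c(1L, 3L)))
  eng <- event_engagement(tracks, ev, min_duration_s = 600)
  # track 3 is too short to qualify; track 1 engaged among the 3 qualifying
  expect_equal(eng$n_qualifying, 3)
  expect_equal(eng$n_engaged, 1)
  expect_equal(eng$engagement, 1 / 3)

  none <- event_engagement(tracks, ev[0, ], min_duration_s = 600)
  expect_equal(none$engagement, 0)

  short <- tibble::tibble(track_id = 1L, cell_id = 2L, duration_s = 100)
  expect_warning(event_engagement(short, ev, min_duration_s = 600), "excluded")
})

test_that("called events match ground truth with high precision and recall", {
  evals <- purrr::map_dfr(1:12, function(s) {
    res <- track_cell("ctrl_dynamics", seed = 400 + s, cell_id = s)
    evaluate_events(res$lt$events, res$tl$truth$events)
  })
  expect_gte(sum(evals$n_matched) / sum(evals$n_called), 0.85)
  expect_gte(sum(evals$n_matched) / sum(evals$n_truth), 0.85)
})
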