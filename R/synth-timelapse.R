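#' Simulate a chromocenter time-lapse with stochastic fusion and fission
#'
#' Renders one nucleus (maximum-intensity-projected view) whose chromocenter
#' foci follow fractional-Brownian-motion paths and undergo stochastic
#' coalescence (fusion) and cleavage (fission) events. The simulation runs
#' frame by frame: a scheduled fusion steers the nearest partner focus into
#' contact along a bounded-speed separation schedule and then merges the
#' blobs with summed intensity; a fission displaces the two daughters by one
#' blob radius in opposite directions, choosing the split axis that keeps
#' them clear of neighbouring foci. A soft volume-exclusion constraint keeps
#' non-fusing foci from drifting into unresolvable contact, so every visual
#' merge corresponds to a scheduled event and stays resolvable by the
#' tracker. Event times follow a Poisson process with per-focus rates
#' `fusion_rate` and `fission_rate` (events per focus per minute). Ground
#' truth records every executed event with frame index and participant ids.
#'
#' @param preset Dynamics preset list or name (see
#'   [chromodyn_preset()]`("dynamics")`).
#' @param nucleus Nucleus preset list or name (default
#'   `"timelapse_nucleus"`).
#' @param seed Integer seed.
#' @param cell_id Identifier stored with all outputs.
#' @param forced_events Optional tibble (`kind`, `frame`, `focus`) of
#'   scripted events overriding the stochastic schedule (for testing);
#'   `frame` is the scheduled start, a fusion completes a few frames later.
#'
#' @return A list of class `chromo_timelapse`:
#' * `frames`: numeric array `(ny, nx, n_frames)`;
#' * `time_s`: frame acquisition times;
#' * `pixel_size_um`;
#' * `truth`: list with `positions` (tibble: `focus_id`, `frame`, `time_s`,
#'   `y_um`, `x_um`, `intensity`, `radius_um`) and `events` (tibble: `kind`,
#'   `frame`, `time_s`, `y_um`, `x_um`, `participants` list-column);
#' * `cell_id`.
#' @export
make_timelapse <- function(preset, nucleus = "timelapse_nucleus", seed = 1L,
                           cell_id = 1L, forced_events = NULL) {
  if (is.character(preset)) preset <- chromodyn_preset("dynamics", preset)
  if (is.character(nucleus)) nucleus <- chromodyn_preset("nucleus", nucleus)
  validate_dynamics_preset(preset)

  ps <- nucleus$voxel_size_um
  shape <- unlist(nucleus$image_shape)
  ny <- shape[1]; nx <- shape[2]
  r_nuc <- nucleus$nucleus_radius_um %||% (min(ny, nx) * ps * 0.42)
  cc_r <- if (is.list(nucleus$cc_radius_um)) nucleus$cc_radius_um$mean else nucleus$cc_radius_um
  if (cc_r >= r_nuc) abort("Infeasible preset: focus radius exceeds nucleus radius.")
  center <- c(ny, nx) * ps / 2

  dt <- preset$frame_interval_s
  n_frames <- floor(preset$duration_s / dt) + 1L
  time_s <- (seq_len(n_frames) - 1) * dt
  n0 <- preset$n_foci

  step_max <- 0.9   # um/frame upper bound on steered approach speed
  sep_close <- 0.5  # um separation one frame before a merge completes
  d_min <- 1.25     # um soft volume-exclusion distance between foci

  with_seed(derive_seed(seed, 1), {
    init <- sample_in_disk(n0, center, r_nuc - 1.5 * cc_r, min_sep = 2.5 * cc_r + 1.2)
    n0 <- nrow(init)

    fbm_increments <- function(n) {
      if (n < 1) return(matrix(numeric(0), 0, 2))
      cbind(diff(c(0, fbm_coord(n, dt, preset$d_app, preset$alpha))),
            diff(c(0, fbm_coord(n, dt, preset$d_app, preset$alpha))))
    }

    # per-focus state; matrices gain columns as fission creates new foci
    pos <- array(NA_real_, dim = c(n_frames, 2, n0))
    pos[1, , ] <- t(init)
    inc <- purrr::map(seq_len(n0), ~ fbm_increments(n_frames - 1))
    inc_row <- rep(0L, n0)              # rows consumed per focus
    int_mat <- matrix(1, n_frames, n0)
    rad_mat <- matrix(cc_r, n_frames, n0)
    birth <- rep(1L, n0)
    death <- rep(n_frames, n0)
    busy_until <- rep(0L, n0)

    if (is.null(forced_events)) {
      rate_tot <- (preset$fusion_rate + preset$fission_rate) * n0 * preset$duration_s / 60
      n_ev <- rpois(1, rate_tot)
      sched <- tibble(
        frame = if (n_ev > 0) sort(sample(2:(n_frames - 10L), n_ev, replace = TRUE)) else integer(0),
        kind = if (n_ev > 0) {
          ifelse(runif(n_ev) < preset$fusion_rate /
                   max(preset$fusion_rate + preset$fission_rate, 1e-12),
                 "coalescence", "cleavage")
        } else character(0),
        focus = NA_integer_
      )
    } else {
      # forced events: `frame` is the completion frame; fusions start their
      # approach 5 frames earlier so the merge lands exactly on `frame`
      sched <- forced_events
      if (!"focus" %in% names(sched)) sched$focus <- NA_integer_
      sched$n_app <- ifelse(sched$kind == "coalescence", 5L, NA_integer_)
      sched$frame <- ifelse(sched$kind == "coalescence",
                            pmax(sched$frame - 5L, 2L), sched$frame)
    }
    if (!"n_app" %in% names(sched)) sched$n_app <- NA_integer_

    events <- list()
    fusions <- list()  # active approaches: list(i, j, m_left)

    add_focus <- function(p0, f, intens, rad) {
      k <- dim(pos)[3] + 1L
      newpos <- array(NA_real_, dim = c(n_frames, 2, 1))
      newpos[f, , 1] <- p0
      pos <<- array(c(pos, newpos), dim = c(n_frames, 2, k))
      inc[[k]] <<- fbm_increments(n_frames - f)
      inc_row[k] <<- 0L
      int_mat <<- cbind(int_mat, 0); rad_mat <<- cbind(rad_mat, 0)
      int_mat[f:n_frames, k] <<- intens
      rad_mat[f:n_frames, k] <<- rad
      birth[k] <<- f
      death[k] <<- n_frames
      busy_until[k] <<- 0L
      k
    }

    for (f in 2:n_frames) {
      alive <- which(birth < f & death >= f)
      # diffusion step
      for (i in alive) {
        inc_row[i] <- inc_row[i] + 1L
        pos[f, , i] <- pos[f - 1, , i] + inc[[i]][inc_row[i], ]
        # stay inside the nucleus
        d <- sqrt(sum((pos[f, , i] - center)^2))
        lim <- r_nuc - 1.2 * cc_r
        if (d > lim) pos[f, , i] <- center + (pos[f, , i] - center) * lim / d
      }

      # steered fusion approaches (override the partner's diffusion)
      if (length(fusions)) {
        done <- logical(length(fusions))
        for (a in seq_along(fusions)) {
          fu <- fusions[[a]]
          i <- fu$i; j <- fu$j
          fu$m_left <- fu$m_left - 1L
          if (fu$m_left >= 1L) {
            target <- sep_close + step_max * (fu$m_left - 1L)
            dir <- pos[f, , j] - pos[f, , i]
            nd <- sqrt(sum(dir^2))
            dir <- if (nd > 1e-9) dir / nd else c(1, 0)
            pos[f, , j] <- pos[f, , i] + dir * min(target, nd)
          } else {
            # merge completes this frame
            pos[f, , j] <- pos[f, , i]
            death[j] <- f - 1L
            int_mat[f:n_frames, i] <- int_mat[f, i] + int_mat[f - 1, j]
            rad_mat[f:n_frames, i] <- (rad_mat[f, i]^3 + rad_mat[f - 1, j]^3)^(1 / 3)
            events[[length(events) + 1]] <- tibble(
              kind = "coalescence", frame = f, time_s = time_s[f],
              y_um = pos[f, 1, i], x_um = pos[f, 2, i],
              participants = list(c(j, i))
            )
            done[a] <- TRUE
          }
          fusions[[a]] <- fu
        }
        fusions <- fusions[!done]
      }

      # soft volume exclusion between non-fusing alive foci
      alive <- which(birth <= f & death >= f)
      excl <- alive
      for (fu in fusions) excl <- setdiff(excl, c(fu$i, fu$j))
      if (length(excl) > 1) {
        for (rep_ in 1:2) {
          pts <- t(pos[f, , excl, drop = FALSE][1, , ])
          dm <- as.matrix(stats::dist(pts))
          dm[upper.tri(dm, diag = TRUE)] <- Inf
          close_pairs <- which(dm < d_min, arr.ind = TRUE)
          if (!nrow(close_pairs)) break
          for (r in seq_len(nrow(close_pairs))) {
            a <- excl[close_pairs[r, 1]]; b <- excl[close_pairs[r, 2]]
            dvec <- pos[f, , a] - pos[f, , b]
            dd <- sqrt(sum(dvec^2))
            u2 <- if (dd > 1e-9) dvec / dd else c(sin(runif(1, 0, 2 * pi)), cos(runif(1, 0, 2 * pi)))
            push <- (d_min - dd) / 2
            pos[f, , a] <- pos[f, , a] + push * u2
            pos[f, , b] <- pos[f, , b] - push * u2
          }
        }
      }

      # events scheduled to start at this frame
      for (e in which(sched$frame == f)) {
        cand <- which(birth <= f - 2 & death >= f & busy_until < f)
        if (sched$kind[e] == "coalescence") {
          if (length(cand) < 2) next
          i <- if (!is.na(sched$focus[e]) && sched$focus[e] %in% cand) sched$focus[e] else sample(cand, 1)
          others <- setdiff(cand, i)
          dists <- vapply(others, function(j) sqrt(sum((pos[f, , j] - pos[f, , i])^2)), numeric(1))
          j <- others[which.min(dists)]
          d0 <- min(dists)
          n_app <- if (!is.na(sched$n_app[e])) sched$n_app[e] else
            max(2L, ceiling((d0 - sep_close) / step_max) + 1L)
          if (f + n_app > n_frames - 1L) next
          busy_until[i] <- f + n_app + 2L
          busy_until[j] <- n_frames
          fusions[[length(fusions) + 1]] <- list(i = i, j = j, m_left = n_app)
        } else {
          if (!length(cand)) next
          i <- if (!is.na(sched$focus[e]) && sched$focus[e] %in% cand) sched$focus[e] else sample(cand, 1)
          # split axis maximizing clearance from the other foci
          others <- setdiff(which(birth <= f & death >= f), i)
          r_i <- rad_mat[f, i]
          angles <- seq(0, pi, length.out = 9)[-9]
          clearance <- vapply(angles, function(a) {
            u <- c(sin(a), cos(a))
            if (!length(others)) return(Inf)
            min(vapply(others, function(o) {
              min(sqrt(sum((pos[f, , i] + r_i * u - pos[f, , o])^2)),
                  sqrt(sum((pos[f, , i] - r_i * u - pos[f, , o])^2)))
            }, numeric(1)))
          }, numeric(1))
          if (max(clearance) < d_min) next
          u <- {
            a <- angles[which.max(clearance)]
            c(sin(a), cos(a))
          }
          pos0 <- pos[f, , i]
          off <- r_i * u
          k <- add_focus(pos0 + off, f, int_mat[f, i] / 2, r_i / 2^(1 / 3))
          int_mat[f:n_frames, i] <- int_mat[f, i] / 2
          rad_mat[f:n_frames, i] <- r_i / 2^(1 / 3)
          pos[f, , i] <- pos0 - off
          busy_until[i] <- f + 2L
          busy_until[k] <- f + 2L
          events[[length(events) + 1]] <- tibble(
            kind = "cleavage", frame = f, time_s = time_s[f],
            y_um = pos0[1], x_um = pos0[2],
            participants = list(c(i, k))
          )
        }
      }
    }

    n_all <- dim(pos)[3]
    positions <- purrr::map_dfr(seq_len(n_all), function(i) {
      fr <- birth[i]:death[i]
      tibble(focus_id = i, frame = fr, time_s = time_s[fr],
             y_um = pos[fr, 1, i], x_um = pos[fr, 2, i],
             intensity = int_mat[fr, i], radius_um = rad_mat[fr, i])
    })

    # render; blob width tracks the focus radius and, for a constant-density
    # body projected to 2D, peak intensity scales with the radius -- fused
    # blobs brighten, fission daughters dim only mildly and stay detectable
    psf <- nucleus$psf_sigma_um %||% 0.12
    sigma_of <- function(r) sqrt((0.28 * r)^2 + psf^2)
    nuc_mask <- disk_mask(ny, nx, center[1] / ps, center[2] / ps, r_nuc / ps)
    base <- matrix(nucleus$background, ny, nx)
    base[nuc_mask] <- base[nuc_mask] + nucleus$eu_intensity

    frames <- array(0, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      idx <- which(birth <= f & death >= f)
      img <- base
      if (length(idx)) {
        ctr <- cbind(pos[f, 1, idx] / ps, pos[f, 2, idx] / ps)
        sig <- sigma_of(rad_mat[f, idx])
        amp <- nucleus$cc_intensity * rad_mat[f, idx] / cc_r
        img <- render_blobs(img, ctr, amp, sig / ps)
      }
      frames[, , f] <- img + rnorm(ny * nx, sd = nucleus$noise_sd %||% 0)
    }

    ev <- if (length(events)) dplyr::bind_rows(events) else
      tibble(kind = character(0), frame = integer(0), time_s = numeric(0),
             y_um = numeric(0), x_um = numeric(0), participants = list())

    structure(
      list(frames = frames, time_s = time_s, pixel_size_um = ps,
           truth = list(positions = positions, events = ev,
                        birth = birth, death = death),
           cell_id = cell_id),
      class = "chromo_timelapse"
    )
  })
}
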