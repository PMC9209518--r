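#' Background-correct and normalize a FRAP trace
#'
#' Subtracts the background ROI, optionally divides by the (background
#' subtracted) unbleached control-chromocenter ROI to cancel acquisition
#' bleaching, and normalizes to the mean of the pre-bleach frames so the
#' pre-bleach level is 1 by construction.
#'
#' @param trace A `frap_trace` tibble (see [make_frap_trace()] /
#'   [read_frap_trace()]) with columns `frame`, `time_s`, `i_bleached`,
#'   `i_control`, `i_background`.
#' @param use_control Divide by the control ROI to remove the shared
#'   acquisition-bleaching trend (default `TRUE`).
#' @param bleach_frame Index (1-based) of the first post-bleach frame;
#'   defaults to the trace's `bleach_frame` attribute.
#'
#' @return A tibble of class `frap_curve` with columns `frame`, `time_s`,
#'   `intensity` (normalized) and `phase` (`"pre"`/`"post"`), carrying the
#'   `bleach_frame` attribute.
#' @examples
#' curve <- correct_trace(make_frap_trace("hp1a_ctrl", seed = 1))
#' @export
correct_trace <- function(trace, use_control = TRUE, bleach_frame = NULL) {
  bleach_frame <- bleach_frame %||% attr(trace, "bleach_frame")
  if (is.null(bleach_frame)) abort("`bleach_frame` is required (attribute or argument).")
  n <- nrow(trace)
  if (bleach_frame < 2 || bleach_frame > n) abort("`bleach_frame` must satisfy 1 < bleach_frame <= n_frames.")

  num <- trace$i_bleached - trace$i_background
  if (use_control) {
    den <- trace$i_control - trace$i_background
    bad <- which(den <= 0)
    if (length(bad)) {
      abort(sprintf("Control minus background is <= 0 at frame %d; cannot correct.", bad[1]))
    }
    ratio <- num / den
  } else {
    ratio <- num
  }
  pre <- seq_len(bleach_frame - 1L)
  pre_mean <- mean(ratio[pre])
  if (!is.finite(pre_mean) || pre_mean == 0) abort("Pre-bleach mean is zero; cannot normalize.")

  out <- tibble(
    frame = trace$frame,
    time_s = trace$time_s,
    intensity = ratio / pre_mean,
    phase = ifelse(trace$frame < bleach_frame, "pre", "post")
  )
  structure(out, class = c("frap_curve", class(out)), bleach_frame = as.integer(bleach_frame))
}

#' Fit a one-phase association to a FRAP recovery curve
#'
#' Nonlinear least squares of
#' \deqn{Y = Y_0 + (P - Y_0)(1 - e^{-K x})}
#' on the post-bleach frames only, with \eqn{x} the time since the first
#' post-bleach frame. Constraints: \eqn{K > 0}, \eqn{P \ge Y_0}.
#' Initialization: \eqn{Y_0} from the first post-bleach value, \eqn{P} from
#' the mean of the final 10% of frames, \eqn{K} from the observed half-rise
#' time; on non-convergence the fit is retried from jittered starts and, if
#' still failing, returned with `converged = FALSE` rather than silent
#' values.
#'
#' @param curve A `frap_curve` from [correct_trace()], or a numeric vector of
#'   normalized intensities (then `time_s` and `bleach_frame` are required).
#' @param time_s,bleach_frame Used only when `curve` is a bare numeric vector.
#' @param restarts Number of jittered restarts on failure.
#'
#' @return An object of class `frap_fit`: a list with `y0`, `plateau`,
#'   `k_per_s`, `t_half_s` (= ln2 / K), `mobile_fraction`,
#'   `immobile_fraction`, `first_post` (observed first post-bleach value,
#'   used for the fractions), `pre_bleach` (normalized pre-bleach level),
#'   `rss`, `converged` and `n_post`. Use [generics::tidy()] /
#'   [generics::glance()] to get tibbles.
#' @examples
#' fit <- fit_recovery(correct_trace(make_frap_trace("hp1a_ctrl", seed = 1)))
#' tidy(fit)
#' @export
fit_recovery <- function(curve, time_s = NULL, bleach_frame = NULL, restarts = 5L) {
  if (inherits(curve, "frap_curve") || is.data.frame(curve)) {
    bleach_frame <- bleach_frame %||% attr(curve, "bleach_frame")
    time_s <- curve$time_s
    y_all <- curve$intensity
  } else {
    y_all <- as.numeric(curve)
  }
  if (is.null(time_s) || is.null(bleach_frame)) {
    abort("`time_s` and `bleach_frame` are required with a bare numeric curve.")
  }
  n <- length(y_all)
  post <- bleach_frame:n
  if (length(post) < 8) abort("At least 8 post-bleach frames are required.")
  x <- time_s[post] - time_s[bleach_frame]
  y <- y_all[post]
  pre_level <- mean(y_all[seq_len(bleach_frame - 1L)])

  y0_init <- y[1]
  plateau_init <- mean(tail(y, max(2L, ceiling(0.1 * length(y)))))
  mid <- (y0_init + plateau_init) / 2
  t_mid <- x[which(y >= mid)[1]]
  k_init <- if (is.na(t_mid) || t_mid <= 0) 1 / max(x[2], 1e-6) else log(2) / t_mid
  dp_init <- max(plateau_init - y0_init, 1e-6)

  fit1 <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + dp * (1 - exp(-k * x)),
        start = start,
        lower = c(y0 = -Inf, dp = 0, k = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15),
        data = list(y = y, x = x)
      ),
      error = function(e) NULL
    )
  }

  # degenerate flat curve: no recovery to fit, report plateau = y0 directly
  if (diff(range(y)) < 1e-10) {
    fr <- frap_fractions(pre_bleach = pre_level, first_post = y[1], plateau = y[1])
    res <- list(
      y0 = y[1], plateau = y[1], k_per_s = NA_real_, t_half_s = NA_real_,
      mobile_fraction = fr$mobile, immobile_fraction = fr$immobile,
      first_post = y[1], pre_bleach = pre_level, rss = 0,
      converged = TRUE, n_post = length(y),
      diagnostics = "flat post-bleach curve: no recovery, rate not identifiable"
    )
    return(structure(res, class = "frap_fit"))
  }

  start <- list(y0 = y0_init, dp = dp_init, k = k_init)
  fit <- fit1(start)
  tries <- 0L
  while (is.null(fit) && tries < restarts) {
    tries <- tries + 1L
    start_j <- list(
      y0 = y0_init * runif(1, 0.5, 1.5),
      dp = dp_init * runif(1, 0.5, 2),
      k = k_init * exp(runif(1, -1.5, 1.5))
    )
    fit <- fit1(start_j)
  }

  if (is.null(fit)) {
    res <- list(
      y0 = NA_real_, plateau = NA_real_, k_per_s = NA_real_, t_half_s = NA_real_,
      mobile_fraction = NA_real_, immobile_fraction = NA_real_,
      first_post = y[1], pre_bleach = pre_level, rss = NA_real_,
      converged = FALSE, n_post = length(y),
      diagnostics = "one-phase association fit failed after restarts"
    )
    return(structure(res, class = "frap_fit"))
  }

  cf <- coef(fit)
  y0_hat <- unname(cf["y0"])
  plateau_hat <- y0_hat + unname(cf["dp"])
  k_hat <- unname(cf["k"])
  fr <- frap_fractions(pre_bleach = pre_level, first_post = y[1], plateau = plateau_hat)

  res <- list(
    y0 = y0_hat, plateau = plateau_hat, k_per_s = k_hat,
    t_half_s = half_time(k_hat),
    mobile_fraction = fr$mobile, immobile_fraction = fr$immobile,
    first_post = y[1], pre_bleach = pre_level,
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE, n_post = length(y), diagnostics = NULL
  )
  structure(res, class = "frap_fit")
}

#' Half-time of recovery from a rate constant
#'
#' @param k_per_s One-phase association rate constant (1/s); must be > 0.
#' @return `log(2) / k_per_s`, in seconds.
#' @examples
#' half_time(log(2) / 8) # 8 s
#' @export
half_time <- function(k_per_s) {
  if (any(!is.finite(k_per_s)) || any(k_per_s <= 0)) abort("`k_per_s` must be > 0.")
  log(2) / k_per_s
}

#' Mobile and immobile fractions from a FRAP fit
#'
#' \deqn{F_m = (P - I_{first\,post}) / (I_{pre} - I_{first\,post})}
#' with the observed first post-bleach value (not the fitted \eqn{Y_0}), and
#' immobile fraction \eqn{1 - F_m}. Estimates are clamped to \[0, 1\] with a
#' warning, since noise can push them slightly outside.
#'
#' @param fit Optionally a `frap_fit`; its `plateau`, `pre_bleach` and
#'   `first_post` fields are used unless overridden.
#' @param pre_bleach,first_post,plateau Normalized levels.
#' @return A list with elements `mobile` and `immobile`.
#' @examples
#' frap_fractions(pre_bleach = 1, first_post = 0.3, plateau = 0.825) # 0.75
#' @export
frap_fractions <- function(fit = NULL, pre_bleach = NULL, first_post = NULL,
                           plateau = NULL) {
  if (!is.null(fit)) {
    pre_bleach <- pre_bleach %||% fit$pre_bleach
    first_post <- first_post %||% fit$first_post
    plateau <- plateau %||% fit$plateau
  }
  if (is.null(pre_bleach) || is.null(first_post) || is.null(plateau)) {
    abort("`pre_bleach`, `first_post` and `plateau` are all required.")
  }
  if (pre_bleach <= first_post) {
    abort("`pre_bleach` must exceed `first_post` (bleach failed?).")
  }
  fm <- (plateau - first_post) / (pre_bleach - first_post)
  if (fm < 0 || fm > 1) {
    warn(sprintf("Mobile fraction %.3f clamped to [0, 1].", fm))
    fm <- min(max(fm, 0), 1)
  }
  list(mobile = fm, immobile = 1 - fm)
}

#' Summarize FRAP fits per condition and compare conditions
#'
#' Computes per-condition medians, means and SEMs of the half-time and
#' mobile/immobile fractions, and (for exactly two conditions) a two-sided
#' Mann-Whitney test per quantity: exact for group sizes < 50 without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param fits A list of `frap_fit` objects, or a tibble as produced by
#'   row-binding `tidy(fit)` results.
#' @param labels Condition label per fit (recycled against `fits`).
#' @return A list with `summary` (tibble per condition and quantity) and
#'   `tests` (tibble of Mann-Whitney p-values per quantity; absent with a
#'   single condition).
#' @export
summarize_frap <- function(fits, labels) {
  df <- if (is.data.frame(fits)) as_tibble(fits) else purrr::map_dfr(fits, tidy)
  df$condition <- rep_len(labels, nrow(df))
  df <- dplyr::filter(df, .data$converged)
  long <- tidyr::pivot_longer(
    dplyr::select(df, "condition", "t_half_s", "mobile_fraction", "immobile_fraction"),
    -"condition", names_to = "quantity", values_to = "value"
  )
  summary <- long |>
    dplyr::group_by(.data$condition, .data$quantity) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  conds <- unique(df$condition)
  if (length(conds) < 2) {
    return(list(summary = summary, tests = NULL))
  }
  if (any(table(df$condition) < 2)) abort("Need >= 2 fits per condition for testing.")
  tests <- long |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      p_value = mw_test(.data$value[.data$condition == conds[1]],
                        .data$value[.data$condition == conds[2]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(group1 = conds[1], group2 = conds[2], method = "Mann-Whitney (two-sided)")
  list(summary = summary, tests = tests)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Exact when both groups have fewer than 50 observations and there are no
#' ties; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @return The two-sided p-value.
#' @examples
#' mw_test(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
#' @export
mw_test <- function(x, y) {
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Raw-median FRAP summary (uncorrected)
#'
#' Alongside the fully corrected fit, reports the per-frame median of raw,
#' background-subtracted bleached-ROI intensities across traces, on both the
#' natural and log2 scale, labelled as *not* control-corrected. Useful when
#' acquisitions are summarized as raw median intensity over time.
#'
#' @param traces A list of `frap_trace` tibbles.
#' @return A tibble with `frame`, `time_s`, `median_intensity`,
#'   `log2_median_intensity` and a `corrected = FALSE` marker column.
#' @export
frap_raw_median <- function(traces) {
  stacked <- purrr::map_dfr(traces, function(tr) {
    tibble(frame = tr$frame, time_s = tr$time_s,
           value = tr$i_bleached - tr$i_background)
  })
  stacked |>
    dplyr::group_by(.data$frame, .data$time_s) |>
    dplyr::summarise(median_intensity = median(.data$value), .groups = "drop") |>
    dplyr::mutate(
      log2_median_intensity = log2(pmax(.data$median_intensity, .Machine$double.eps)),
      corrected = FALSE
    )
}
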