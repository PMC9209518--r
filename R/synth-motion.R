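# Fractional Gaussian noise by exact Cholesky factorisation of the fGn
# covariance. Tracks in this package are a few hundred frames, so exact
# simulation is cheap; the factor is cached per (n, H).
fgn_chol_cache <- new.env(parent = emptyenv())

fgn <- function(n, H) {
  if (n > 5000) abort("fgn(): n too large for exact simulation (max 5000).")
  if (abs(H - 0.5) < 1e-12) return(rnorm(n))
  key <- sprintf("%d_%.10f", n, H)
  L <- fgn_chol_cache[[key]]
  if (is.null(L)) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j))
    acvf <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
    L <- t(chol(acvf + diag(1e-12, n)))
    fgn_chol_cache[[key]] <- L
  }
  as.numeric(L %*% rnorm(n))
}

# One fBm coordinate sampled at times k*dt (k = 1..n), scaled so that
# Var X(t) = 2 * d * t^alpha  (two such coordinates give MSD = 4 d tau^alpha).
fbm_coord <- function(n, dt, d, alpha) {
  if (d == 0) return(rep(0, n))
  H <- alpha / 2
  cumsum(sqrt(2 * d) * dt^H * fgn(n, H))
}

#' Simulate a 2D anomalous-diffusion trajectory
#'
#' Positions are sampled from fractional Brownian motion with Hurst exponent
#' \eqn{\alpha/2}, scaled so the ensemble MSD satisfies
#' \eqn{\mathrm{MSD}(\tau) = 4 D_{app} \tau^\alpha}, plus optional constant
#' drift of speed `velocity` along a random direction. `alpha = 1` is
#' ordinary Brownian motion (i.i.d. Gaussian increments).
#'
#' @param preset A dynamics preset list or name (see
#'   [chromodyn_preset()]`("dynamics")`); fields used: `d_app`
#'   (um^2/s^alpha), `alpha` in (0, 2], `velocity` (um/s),
#'   `frame_interval_s`, `duration_s`.
#' @param seed Integer seed.
#' @param origin Starting position `c(y, x)` in um.
#'
#' @return A tibble of class `chromo_track` with columns `frame`, `time_s`,
#'   `y_um`, `x_um`.
#' @examples
#' tr <- make_trajectory(list(d_app = 0.01, alpha = 0.7, velocity = 0,
#'                            frame_interval_s = 1, duration_s = 99,
#'                            n_foci = 1, fusion_rate = 0, fission_rate = 0),
#'                       seed = 1)
#' @export
make_trajectory <- function(preset, seed = 1L, origin = c(0, 0)) {
  if (is.character(preset)) preset <- chromodyn_preset("dynamics", preset)
  validate_dynamics_preset(preset)
  dt <- preset$frame_interval_s
  n_steps <- floor(preset$duration_s / dt)
  tim <- (0:n_steps) * dt
  with_seed(seed, {
    y <- c(0, fbm_coord(n_steps, dt, preset$d_app, preset$alpha))
    x <- c(0, fbm_coord(n_steps, dt, preset$d_app, preset$alpha))
    theta <- runif(1, 0, 2 * pi)
  })
  y <- y + origin[1] + preset$velocity * sin(theta) * tim
  x <- x + origin[2] + preset$velocity * cos(theta) * tim
  out <- tibble(frame = seq_along(tim), time_s = tim, y_um = y, x_um = x)
  structure(out, class = c("chromo_track", class(out)))
}
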