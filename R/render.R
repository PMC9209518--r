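# shared rendering primitives for the synthetic image generators

# Add isotropic Gaussian blobs to a 2D image (in place, returns matrix).
# centers_px: matrix with columns (y, x) in pixel units (1-based, fractional ok)
render_blobs <- function(img, centers_px, amplitude, sigma_px) {
  ny <- nrow(img); nx <- ncol(img)
  amplitude <- rep_len(amplitude, nrow(centers_px))
  sigma_px <- rep_len(sigma_px, nrow(centers_px))
  for (b in seq_len(nrow(centers_px))) {
    cy <- centers_px[b, 1]; cx <- centers_px[b, 2]
    s <- sigma_px[b]
    w <- ceiling(4 * s)
    ys <- max(1, floor(cy - w)):min(ny, ceiling(cy + w))
    xs <- max(1, floor(cx - w)):min(nx, ceiling(cx + w))
    if (!length(ys) || !length(xs)) next
    gy <- exp(-(ys - cy)^2 / (2 * s^2))
    gx <- exp(-(xs - cx)^2 / (2 * s^2))
    img[ys, xs] <- img[ys, xs] + amplitude[b] * outer(gy, gx)
  }
  img
}

# Hard disk mask (TRUE inside), center/radius in pixels
disk_mask <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Sample n points uniformly in a disk with a minimum pairwise separation.
# Gives up (returns fewer points) after max_tries rejections per point.
sample_in_disk <- function(n, center, radius, min_sep, max_tries = 400) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n && tries < max_tries * n) {
    tries <- tries + 1
    r <- radius * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- center + r * c(sin(th), cos(th))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  pts
}
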