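# Six parametric degradation scenarios emulating poor capture conditions in
# capsule endoscopy: lens fogging, sensor noise, defocus, motion blur, uneven
# illumination, and chromatic aberration. Every operator maps a valid 8-bit
# image to a valid 8-bit image of the same size; none moves pixels, so
# ground-truth masks remain valid for the degraded frames.

SCENARIOS <- c("fog", "gaussian_noise", "defocus", "motion_blur", "brightness", "color_jitter")

# --- convolution backbone ---------------------------------------------------

# Reflect an out-of-range index back into 1..n (handles pads wider than n).
reflect_index <- function(i, n) {
  if (n == 1) {
    return(rep(1L, length(i)))
  }
  period <- 2L * n - 2L
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j + 1L)
}

# 2-D convolution with reflective border handling. The image is padded by
# reflection, convolved via EBImage's FFT filter (circular wrap only touches
# the pad), then cropped back.
conv2_reflect <- function(m, kernel) {
  a <- (nrow(kernel) - 1) / 2
  b <- (ncol(kernel) - 1) / 2
  if (a == 0 && b == 0) {
    return(m * kernel[1, 1])
  }
  h <- nrow(m)
  w <- ncol(m)
  ri <- reflect_index(seq(1 - a, h + a), h)
  ci <- reflect_index(seq(1 - b, w + b), w)
  padded <- m[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[seq_len(h) + a, seq_len(w) + b, drop = FALSE]
}

convolve_image <- function(image, kernel) {
  image <- as_rgb_image(image)
  d <- dim(image)
  out <- array(0, d)
  for (c in 1:3) {
    out[, , c] <- conv2_reflect(matrix(as.double(image[, , c]), d[1], d[2]), kernel)
  }
  finish_image(out)
}

# --- scenarios --------------------------------------------------------------

#' Fogging: lens condensation overlay
#'
#' Alpha-composites randomly placed soft white disks ("fog circles") over the
#' frame. The number of disks grows with `intensity`, so coverage and mean
#' brightness increase monotonically with it; each disk contributes a soft
#' alpha peaking at `transparency`.
#'
#' @param image an [rgb_image].
#' @param intensity fog intensity coefficient in `[0.25, 1]`.
#' @param transparency per-disk opacity (default 0.05; 0 is an exact no-op).
#' @param seed optional integer seed for disk placement.
#' @return a degraded [rgb_image].
#' @export
apply_fog <- function(image, intensity, transparency = 0.05, seed = NULL) {
  if (intensity < 0.25 || intensity > 1) stopf("fog intensity must lie in [0.25, 1]")
  if (transparency < 0 || transparency > 1) stopf("transparency must lie in [0, 1]")
  image <- as_rgb_image(image)
  d <- dim(image)
  h <- d[1]
  w <- d[2]
  out <- array(as.double(image), d)
  with_seed_opt(seed, {
    # disk count scales with area; ~150 disks on a 336x336 frame at full fog
    n_disks <- stats::rpois(1, intensity * 150 * (h * w) / 336^2)
    for (i in seq_len(n_disks)) {
      cy <- stats::runif(1, 1, h)
      cx <- stats::runif(1, 1, w)
      r <- stats::runif(1, 0.06, 0.22) * min(h, w)
      rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
      dd <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
      # flat core, linear falloff over the outer 30% of the radius
      alpha <- transparency * pmin(1, pmax(0, (r - dd) / (0.3 * r)))
      for (c in 1:3) {
        out[rows, cols, c] <- out[rows, cols, c] * (1 - alpha) + 255 * alpha
      }
    }
  })
  finish_image(out)
}

#' Additive Gaussian sensor noise
#'
#' Adds independent zero-mean Gaussian noise to each pixel of each color
#' channel in real arithmetic, then rounds and clips to `[0, 255]`.
#'
#' @param image an [rgb_image].
#' @param variance noise variance in squared intensity counts; the sampled
#'   range is `[5, 300]`.
#' @param seed optional integer seed.
#' @param check_range enforce the `[5, 300]` range (default). Disable to probe
#'   behavior outside it, e.g. `variance = 0` is then an exact no-op.
#' @return a degraded [rgb_image].
#' @export
apply_gaussian_noise <- function(image, variance, seed = NULL, check_range = TRUE) {
  if (variance < 0) stopf("noise variance must be non-negative")
  if (check_range && (variance < 5 || variance > 300)) {
    stopf("noise variance must lie in [5, 300]")
  }
  image <- as_rgb_image(image)
  if (variance == 0) {
    return(image)
  }
  out <- with_seed_opt(seed, {
    as.double(image) + stats::rnorm(length(image), 0, sqrt(variance))
  })
  finish_image(array(out, dim(image)))
}

# Normalized disk point-spread function with an anti-aliased (coverage) edge.
disk_kernel <- function(radius) {
  s <- ceiling(radius)
  g <- seq(-s, s)
  dd <- sqrt(outer(g^2, g^2, "+"))
  # pmin/pmax drop the dim attribute; restore it
  k <- matrix(pmin(1, pmax(0, radius + 0.5 - dd)), nrow(dd), ncol(dd))
  k / sum(k)
}

#' Defocus blur
#'
#' Convolves each channel with a normalized disk point-spread function of the
#' given radius (soft, alias-blurred edge; reflective borders). Radius 0 is
#' the identity; a constant image is unchanged for any radius because the
#' kernel sums to one.
#'
#' @param image an [rgb_image].
#' @param radius disk radius in pixels (>= 0); the sampling range used for
#'   robustness sets is `[1, 8]`.
#' @return a degraded [rgb_image].
#' @export
apply_defocus <- function(image, radius) {
  if (radius < 0) stopf("defocus radius must be non-negative")
  image <- as_rgb_image(image)
  if (radius == 0) {
    return(image)
  }
  convolve_image(image, disk_kernel(radius))
}

# Normalized line kernel: unit-weight samples accumulated along the segment
# with bilinear (anti-aliased) splatting.
motion_kernel <- function(angle_deg, length_px) {
  if (length_px == 1) {
    return(matrix(1, 1, 1))
  }
  half <- (length_px - 1) / 2
  s <- ceiling(half)
  size <- 2 * s + 1
  k <- matrix(0, size, size)
  # a centered line segment is invariant under 180-degree rotation, so
  # canonicalize the angle to [0, 180) for bit-identical opposite directions;
  # cospi/sinpi are exact at the axis angles
  angle_deg <- angle_deg %% 180
  t <- seq(-half, half, by = 0.1)
  xs <- t * cospi(angle_deg / 180) + s + 1
  ys <- -t * sinpi(angle_deg / 180) + s + 1 # image rows grow downward
  x0 <- floor(xs)
  y0 <- floor(ys)
  fx <- xs - x0
  fy <- ys - y0
  for (i in seq_along(t)) {
    for (dy in 0:1) {
      for (dx in 0:1) {
        wgt <- (if (dx == 0) 1 - fx[i] else fx[i]) * (if (dy == 0) 1 - fy[i] else fy[i])
        if (wgt > 0) k[y0[i] + dy, x0[i] + dx] <- k[y0[i] + dy, x0[i] + dx] + wgt
      }
    }
  }
  k / sum(k)
}

#' Linear motion blur
#'
#' Convolves with a normalized anti-aliased line kernel simulating camera
#' motion of `length_px` pixels along `angle_deg`. Angles lie on the 15-degree
#' grid `{0, 15, ..., 345}` and lengths in 1..25; length 1 is the identity and
#' opposite angles (0 vs 180) give identical kernels.
#'
#' @param image an [rgb_image].
#' @param angle_deg motion direction, a multiple of 15 in `[0, 360)`.
#' @param length_px motion extent in pixels, integer in 1..25.
#' @return a degraded [rgb_image].
#' @export
apply_motion_blur <- function(image, angle_deg, length_px) {
  if (angle_deg %% 15 != 0 || angle_deg < 0 || angle_deg >= 360) {
    stopf("angle_deg must be a multiple of 15 in [0, 360)")
  }
  if (length_px != round(length_px) || length_px < 1 || length_px > 25) {
    stopf("length_px must be an integer in 1..25")
  }
  image <- as_rgb_image(image)
  if (length_px == 1) {
    return(image)
  }
  convolve_image(image, motion_kernel(angle_deg, length_px))
}

#' Random-brightness (power-law) transform
#'
#' Applies the power-law intensity mapping `S = r^(1/gamma)` to normalized
#' intensities `r = pixel / 255`: gamma above one brightens the frame, below
#' one darkens it, and the endpoints 0 and 255 are fixed points.
#'
#' @param image an [rgb_image].
#' @param gamma exponent parameter; the sampled range is `[0.75, 1.25]`.
#' @param check_range enforce that range (default `TRUE`).
#' @return a degraded [rgb_image].
#' @export
apply_brightness <- function(image, gamma, check_range = TRUE) {
  if (gamma <= 0) stopf("gamma must be positive")
  if (check_range && (gamma < 0.75 || gamma > 1.25)) {
    stopf("gamma must lie in [0.75, 1.25]")
  }
  image <- as_rgb_image(image)
  if (gamma == 1) {
    return(image)
  }
  s <- (as.double(image) / 255)^(1 / gamma) * 255
  finish_image(array(s, dim(image)))
}

# Vectorized HSV -> RGB on the h in [0,1), s,v in [0,1] scale.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p, ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v, ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t, ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' HSV color jitter
#'
#' Simulates chromatic aberration: the frame is converted to HSV on the 8-bit
#' convention (H in half-degree units 0..179, S and V in 0..255), the three
#' channels are shifted by the given amounts (H wraps modulo 180, S and V
#' clip), and the result is converted back to RGB.
#'
#' @param image an [rgb_image].
#' @param h_shift,s_shift,v_shift channel shifts in 8-bit units, each in
#'   `[-5, 5]`.
#' @return a degraded [rgb_image].
#' @export
apply_color_jitter <- function(image, h_shift, s_shift, v_shift) {
  for (sh in c(h_shift, s_shift, v_shift)) {
    if (abs(sh) > 5) stopf("HSV shifts must lie in [-5, 5]")
  }
  image <- as_rgb_image(image)
  d <- dim(image)
  rgb <- rbind(
    as.double(image[, , 1]),
    as.double(image[, , 2]),
    as.double(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255) # rows h, s, v in [0,1]
  h8 <- (hsv[1, ] * 180 + h_shift) %% 180
  s8 <- clip255(hsv[2, ] * 255 + s_shift)
  v8 <- clip255(hsv[3, ] * 255 + v_shift)
  out <- hsv_to_rgb(h8 / 180, s8 / 255, v8 / 255) * 255
  finish_image(array(c(out[, 1], out[, 2], out[, 3]), d))
}

sample_scenario_params <- function(scenario) {
  switch(scenario,
    fog = list(intensity = stats::runif(1, 0.25, 1), transparency = 0.05),
    gaussian_noise = list(variance = stats::runif(1, 5, 300)),
    defocus = list(radius = stats::runif(1, 1, 8)),
    motion_blur = list(
      angle_deg = sample(seq(0, 345, by = 15), 1),
      length_px = sample(1:25, 1)
    ),
    brightness = list(gamma = stats::runif(1, 0.75, 1.25)),
    color_jitter = list(
      h_shift = stats::runif(1, -5, 5),
      s_shift = stats::runif(1, -5, 5),
      v_shift = stats::runif(1, -5, 5)
    ),
    stopf("unknown scenario '%s'", scenario)
  )
}

apply_scenario <- function(image, scenario, params, seed = NULL) {
  switch(scenario,
    fog = apply_fog(image, params$intensity, params$transparency %||% 0.05, seed = seed),
    gaussian_noise = apply_gaussian_noise(image, params$variance, seed = seed),
    defocus = apply_defocus(image, params$radius),
    motion_blur = apply_motion_blur(image, params$angle_deg, params$length_px),
    brightness = apply_brightness(image, params$gamma),
    color_jitter = apply_color_jitter(image, params$h_shift, params$s_shift, params$v_shift),
    stopf("unknown scenario '%s'", scenario)
  )
}

#' Build a corrupted robustness test set
#'
#' Applies each requested degradation scenario to each source frame, sampling
#' scenario parameters uniformly from their configured ranges with a per-item
#' derived seed, and records full provenance. All six scenarios over an
#' n-frame corpus yield `6 * n` corrupted frames. Since none of the operators
#' displaces pixels, the source ground-truth masks remain valid.
#'
#' @param images list of [rgb_image]s.
#' @param scenarios character vector of scenario names (default: all six).
#' @param seed master integer seed; item seeds are derived from it.
#' @return a list of class `"corrupted_set"` with `images` (list of corrupted
#'   frames, ordered image-major) and `provenance` (data.frame with columns
#'   `source`, `scenario`, `params` (JSON), `seed`).
#' @export
corrupt_dataset <- function(images, scenarios = SCENARIOS, seed = 1L) {
  if (length(images) == 0) stopf("no images supplied")
  bad <- setdiff(scenarios, SCENARIOS)
  if (length(bad)) stopf("unknown scenario(s): %s", paste(bad, collapse = ", "))
  n_out <- length(images) * length(scenarios)
  out <- vector("list", n_out)
  prov <- data.frame(
    source = integer(n_out), scenario = character(n_out),
    params = character(n_out), seed = integer(n_out)
  )
  item <- 0L
  for (i in seq_along(images)) {
    for (sc in scenarios) {
      item <- item + 1L
      s <- derive_seed(seed, item)
      params <- with_seed_opt(s, sample_scenario_params(sc))
      out[[item]] <- apply_scenario(images[[i]], sc, params, seed = derive_seed(s, 1L))
      prov$source[item] <- i
      prov$scenario[item] <- sc
      prov$params[item] <- as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
      prov$seed[item] <- s
    }
  }
  structure(list(images = out, provenance = prov), class = "corrupted_set")
}
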