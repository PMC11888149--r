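# Synthetic capsule-endoscopy-like scenes with known ground truth. Two color
# populations with known tri-variate Gaussian RGB distributions are arranged
# as spatially coherent blobs inside a circular field of view, so every other
# module can be exercised — and its error rates predicted analytically —
# without any external imagery.

#' Default clean / contaminated color palettes
#'
#' Package-default Gaussian color parameters emulating the qualitative
#' appearance of capsule frames: clean mucosa pinkish (red-dominant), and
#' contaminated regions yellow-green (green well above blue). These are
#' package defaults chosen for plausible appearance and a comfortable class
#' separation (Mahalanobis distance between means above 4 under either
#' covariance), not measurements of any real corpus.
#'
#' @return a list with elements `clean` and `contaminated`, each a list with
#'   `mean` (RGB 3-vector, 0-255) and `cov` (3 x 3 SPD matrix).
#' @export
default_palettes <- function() {
  list(
    clean = list(
      mean = c(185, 115, 110),
      cov = matrix(c(
        144, 60, 48,
        60, 100, 40,
        48, 40, 100
      ), 3, 3, byrow = TRUE)
    ),
    contaminated = list(
      mean = c(150, 140, 70),
      cov = matrix(c(
        196, 84, 42,
        84, 144, 48,
        42, 48, 100
      ), 3, 3, byrow = TRUE)
    )
  )
}

#' Mahalanobis separation between two class palettes
#'
#' Distance between the class means in units of the given covariance; the
#' quantity that governs the Bayes error of the two-Gaussian mixture.
#'
#' @param palette_a,palette_b lists with `mean` and `cov` as in
#'   [default_palettes()].
#' @param use which covariance to measure against: that of `a`, of `b`, or
#'   their average (default).
#' @return a non-negative scalar.
#' @export
palette_separation <- function(palette_a, palette_b,
                               use = c("average", "a", "b")) {
  use <- match.arg(use)
  s <- switch(use,
    average = (palette_a$cov + palette_b$cov) / 2,
    a = palette_a$cov,
    b = palette_b$cov
  )
  d <- palette_a$mean - palette_b$mean
  sqrt(as.numeric(stats::mahalanobis(rbind(d), center = rep(0, 3), cov = s)))
}

#' Scene generator configuration
#'
#' @param height,width frame dimensions in pixels (default 336, a common
#'   capsule frame resolution).
#' @param clean,contaminated class palettes (`mean` + `cov`), defaulting to
#'   [default_palettes()].
#' @param contamination_fraction_target desired contaminated fraction of the
#'   field of view, in `[0, 1]`.
#' @param n_blobs number of smooth contamination blobs (Gaussian bumps whose
#'   superlevel set forms the contaminated region).
#' @param blob_scale characteristic blob radius in pixels; default is 15% of
#'   the smaller frame dimension.
#' @param fov_margin margin fraction passed to [circular_fov()].
#' @param seed integer seed making the scene reproducible.
#' @return a list of class `"scene_config"`.
#' @export
scene_config <- function(height = 336, width = 336,
                         clean = default_palettes()$clean,
                         contaminated = default_palettes()$contaminated,
                         contamination_fraction_target = 0.3,
                         n_blobs = 6, blob_scale = NULL,
                         fov_margin = 0, seed = 1L) {
  if (contamination_fraction_target < 0 || contamination_fraction_target > 1) {
    stopf("contamination_fraction_target must lie in [0, 1]")
  }
  for (p in list(clean, contaminated)) {
    if (any(p$mean < 0) || any(p$mean > 255)) stopf("palette means must lie in [0, 255]")
    tryCatch(chol(p$cov), error = function(e) stopf("palette covariance must be SPD"))
  }
  if (n_blobs < 1) stopf("n_blobs must be at least 1")
  structure(
    list(
      height = height, width = width, clean = clean, contaminated = contaminated,
      contamination_fraction_target = contamination_fraction_target,
      n_blobs = n_blobs,
      blob_scale = blob_scale %||% 0.15 * min(height, width),
      fov_margin = fov_margin, seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

# Smooth random field: sum of Gaussian bumps at random in-FOV centers.
blob_field <- function(h, w, n_blobs, blob_scale, fov) {
  field <- matrix(0, h, w)
  ys <- seq_len(h)
  xs <- seq_len(w)
  in_fov <- which(fov, arr.ind = TRUE)
  for (i in seq_len(n_blobs)) {
    ctr <- in_fov[sample.int(nrow(in_fov), 1), ]
    amp <- stats::runif(1, 0.5, 1.5)
    sc <- blob_scale * stats::runif(1, 0.6, 1.4)
    # slight anisotropy so blobs are elliptical rather than round
    sy <- sc * stats::runif(1, 0.7, 1.3)
    sx <- sc * stats::runif(1, 0.7, 1.3)
    field <- field + amp * exp(-outer(
      (ys - ctr[1])^2 / (2 * sy^2),
      (xs - ctr[2])^2 / (2 * sx^2), "+"
    ))
  }
  field
}

#' Generate one labeled synthetic scene
#'
#' Builds a circular field of view, draws `n_blobs` random smooth blobs and
#' thresholds their superposition at the in-FOV quantile matching the target
#' contamination fraction (so the realized fraction matches the target up to
#' pixel quantization), then samples every pixel's color i.i.d. from its
#' class Gaussian, rounds and clips to 8 bits. Pixels outside the FOV are
#' black and labeled contaminated.
#'
#' @param config a [scene_config()].
#' @return an object of class `"labeled_scene"`: list with `image`
#'   ([rgb_image]), `mask` ([binary_mask], `TRUE` = clean), `fov`,
#'   `realized_contamination_fraction` and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) stopf("config must come from scene_config()")
  h <- config$height
  w <- config$width
  fov <- circular_fov(h, w, config$fov_margin)
  target <- config$contamination_fraction_target
  with_seed_opt(config$seed, {
    contaminated <- matrix(FALSE, h, w)
    if (target >= 1) {
      contaminated[fov] <- TRUE
    } else if (target > 0) {
      field <- blob_field(h, w, config$n_blobs, config$blob_scale, fov)
      thr <- stats::quantile(field[fov], probs = 1 - target, names = FALSE, type = 7)
      contaminated <- field >= thr & fov
    }
    mask <- fov & !contaminated
    img <- array(0, c(h, w, 3))
    for (cls in c("clean", "contaminated")) {
      sel <- if (cls == "clean") mask else contaminated
      n <- sum(sel)
      if (n > 0) {
        pal <- config[[cls]]
        cols <- MASS::mvrnorm(n, mu = pal$mean, Sigma = pal$cov)
        if (n == 1) cols <- matrix(cols, 1, 3)
        for (c in 1:3) {
          plane <- img[, , c]
          plane[sel] <- cols[, c]
          img[, , c] <- plane
        }
      }
    }
  })
  structure(
    list(
      image = finish_image(img),
      mask = binary_mask(mask),
      fov = fov,
      realized_contamination_fraction = mean(contaminated[fov]),
      config = config
    ),
    class = "labeled_scene"
  )
}

#' Generate a corpus of labeled synthetic scenes
#'
#' Draws per-scene contamination targets uniformly from
#' `contamination_range`, so the corpus spans clean-dominant to
#' contamination-dominant frames, and generates every scene with a seed
#' derived from `seed` (byte-identical reruns). With `out_dir` set, frames and
#' masks are written as PNG next to a `manifest.csv` (columns `image_path`,
#' `mask_path`, `split`) and a `params.json` snapshot of the generator
#' settings.
#'
#' @param n number of scenes.
#' @param config template [scene_config()]; its per-scene `seed` and
#'   contamination target are overridden.
#' @param contamination_range length-2 range of contamination targets
#'   (default `c(0.05, 0.95)`).
#' @param seed master integer seed.
#' @param out_dir optional output directory (created if missing). When given,
#'   scenes are written to disk and not kept in memory unless `keep = TRUE`.
#' @param keep return the scene objects in memory (default: `TRUE` when
#'   `out_dir` is `NULL`).
#' @return a list of class `"scene_corpus"` with `scenes` (list or `NULL`),
#'   `manifest` (data.frame), `targets`, and `seed`.
#' @export
generate_corpus <- function(n, config = scene_config(),
                            contamination_range = c(0.05, 0.95),
                            seed = 1L, out_dir = NULL,
                            keep = is.null(out_dir)) {
  if (n < 1) stopf("n must be at least 1")
  if (length(contamination_range) != 2 || diff(contamination_range) < 0) {
    stopf("contamination_range must be an increasing length-2 vector")
  }
  targets <- with_seed_opt(
    derive_seed(seed, 0L),
    stats::runif(n, contamination_range[1], contamination_range[2])
  )
  scenes <- if (keep) vector("list", n) else NULL
  manifest <- data.frame(
    image_path = character(n), mask_path = character(n),
    split = rep("eval", n), contamination_target = targets,
    realized_contamination = numeric(n), seed = integer(n)
  )
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n)) {
    cfg <- config
    cfg$contamination_fraction_target <- targets[i]
    cfg$seed <- derive_seed(seed, i)
    scene <- generate_scene(cfg)
    manifest$realized_contamination[i] <- scene$realized_contamination_fraction
    manifest$seed[i] <- cfg$seed
    if (!is.null(out_dir)) {
      ip <- file.path(out_dir, sprintf("scene_%04d.png", i))
      mp <- file.path(out_dir, sprintf("scene_%04d_mask.png", i))
      write_image(scene$image, ip)
      write_mask(scene$mask, mp)
      manifest$image_path[i] <- ip
      manifest$mask_path[i] <- mp
    }
    if (keep) scenes[[i]] <- scene
  }
  if (!is.null(out_dir)) {
    # the CSV lives inside out_dir, so store paths relative to it;
    # read_manifest() resolves them against the manifest's directory
    on_disk <- manifest
    on_disk$image_path <- basename(on_disk$image_path)
    on_disk$mask_path <- basename(on_disk$mask_path)
    utils::write.csv(on_disk, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        n = n, seed = seed, contamination_range = contamination_range,
        height = config$height, width = config$width,
        clean = config$clean, contaminated = config$contaminated,
        n_blobs = config$n_blobs, blob_scale = config$blob_scale,
        fov_margin = config$fov_margin
      ),
      file.path(out_dir, "params.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  structure(
    list(scenes = scenes, manifest = manifest, targets = targets, seed = seed),
    class = "scene_corpus"
  )
}

#' Monte-Carlo Bayes risk of a two-Gaussian pixel mixture
#'
#' Samples labels from the class priors and colors from the corresponding
#' Gaussians, classifies each draw with the true generating parameters, and
#' returns the misclassification rate — the irreducible error floor any pixel
#' classifier faces on scenes generated from these palettes.
#'
#' @param clean,contaminated palettes (`mean` + `cov`).
#' @param prior_clean prior probability of the clean class.
#' @param n number of Monte-Carlo draws (default `1e6`).
#' @param seed integer seed.
#' @param quantize round-and-clip draws to 8-bit integers first, mimicking
#'   the image pipeline (default `TRUE`).
#' @return the estimated Bayes risk in `[0, 1]`.
#' @export
bayes_risk_mc <- function(clean, contaminated, prior_clean = 0.5, n = 1e6,
                          seed = 1L, quantize = TRUE) {
  model <- new_gbc_model(
    clean$mean, clean$cov, contaminated$mean, contaminated$cov,
    prior_clean = prior_clean
  )
  with_seed_opt(seed, {
    is_clean <- stats::runif(n) < prior_clean
    x <- matrix(0, n, 3)
    if (any(is_clean)) {
      x[is_clean, ] <- MASS::mvrnorm(sum(is_clean), clean$mean, clean$cov)
    }
    if (any(!is_clean)) {
      x[!is_clean, ] <- MASS::mvrnorm(sum(!is_clean), contaminated$mean, contaminated$cov)
    }
    if (quantize) x <- round(clip255(x))
    pred_clean <- gbc_posterior(x, model)[, 1] >= 0.5
    mean(pred_clean != is_clean)
  })
}
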