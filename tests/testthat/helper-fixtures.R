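# Shared fixtures: all synthetic, built in code at test time.

const_image <- function(value, h = 8, w = 8) {
  rgb_image(array(as.integer(value), c(h, w, 3)))
}

rand_image <- function(h = 16, w = 16, seed = 1) {
  withr::with_seed(seed, rgb_image(array(sample(0:255, h * w * 3, TRUE), c(h, w, 3))))
}

# Moderately overlapping palettes: Mahalanobis separation ~2.4, so the Bayes
# risk is clearly non-zero and degradations have measurable effect.
palettes_overlapping <- function() {
  p <- default_palettes()
  list(
    clean = list(mean = c(175, 120, 105), cov = p$clean$cov),
    contaminated = list(mean = c(158, 132, 88), cov = p$contaminated$cov)
  )
}

small_corpus <- function(n, h = 32, seed = 1, palettes = default_palettes(),
                         contamination_range = c(0.1, 0.9)) {
  generate_corpus(
    n,
    config = scene_config(
      height = h, width = h,
      clean = palettes$clean, contaminated = palettes$contaminated
    ),
    contamination_range = contamination_range, seed = seed
  )
}

corpus_images <- function(corpus) lapply(corpus$scenes, `[[`, "image")
corpus_masks <- function(corpus) lapply(corpus$scenes, `[[`, "mask")

# Independent sRGB (D65) -> XYZ -> CIELAB reference, straight from the
# textbook constants; deliberately not sharing code with the package.
reference_lab <- function(rgb255) {
  u <- rgb255 / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), 3, 3, byrow = TRUE)
  xyz <- as.vector(m %*% lin) / c(0.95047, 1, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fv <- f(xyz)
  c(L = 116 * fv[2] - 16, a = 500 * (fv[1] - fv[2]), b = 200 * (fv[2] - fv[3]))
}

# Random symmetric positive-definite 3x3 matrix.
random_spd3 <- function() {
  a <- matrix(rnorm(9), 3, 3)
  crossprod(a) + diag(0.5, 3)
}

# Naive multivariate normal log density with explicit inverse and determinant.
naive_mvn_logpdf <- function(x, mu, sigma) {
  d <- x - mu
  -0.5 * (3 * log(2 * pi) + log(det(sigma)) + as.numeric(d %*% solve(sigma) %*% d))
}

# O(n^2) pair-counting AUROC oracle with half-credit for ties.
auroc_pairs <- function(p, labels) {
  pos <- p[labels]
  neg <- p[!labels]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}
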