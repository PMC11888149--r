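test_that("class pixel extraction counts and errors are correct", {
  img <- const_image(100, 8, 8)
  all_clean <- binary_mask(matrix(TRUE, 8, 8))
  x <- extract_class_pixels(list(img), list(all_clean), "clean")
  expect_equal(dim(x), c(64, 3))
  expect_error(
    extract_class_pixels(list(img), list(all_clean), "contaminated"),
    "absent from training annotation"
  )

  # two 8x8 images with half-true masks: 64 pixels of each class
  half <- binary_mask(matrix(rep(c(TRUE, FALSE), each = 32), 8, 8))
  x2 <- extract_class_pixels(list(img, img), list(half, half), "clean")
  expect_equal(nrow(x2), 64)
  x3 <- extract_class_pixels(list(img, img), list(half, half), "contaminated")
  expect_equal(nrow(x3), 64)
})

test_that("fitting recovers priors exactly and regularizes degenerate spread", {
  # 30 clean + 70 contaminated pixels on a 10x10 frame -> prior 0.3
  img <- rand_image(10, 10, seed = 1)
  msk <- binary_mask(matrix(rep(c(TRUE, FALSE), c(30, 70)), 10, 10))
  m <- gbc_fit(list(img), list(msk), epsilon = 1e-3)
  expect_equal(m$clean$prior, 0.3)
  expect_equal(m$contaminated$prior, 0.7)
  expect_equal(m$clean$prior + m$contaminated$prior, 1, tolerance = 1e-12)

  # identical pixels in one class: covariance collapses to epsilon * I
  cimg <- const_image(120, 10, 10)
  m2 <- gbc_fit(list(cimg), list(msk), epsilon = 1e-3)
  expect_equal(m2$clean$cov, diag(1e-3, 3), tolerance = 1e-12)
  expect_equal(unname(m2$clean$mean), c(120, 120, 120))

  # unbiased vs ML covariance differ by the (n-1)/n factor
  mu <- gbc_fit(list(img), list(msk), unbiased = TRUE)
  mb <- gbc_fit(list(img), list(msk), unbiased = FALSE)
  expect_equal(mb$clean$cov - diag(1e-3, 3),
    (mu$clean$cov - diag(1e-3, 3)) * 29 / 30,
    tolerance = 1e-9
  )

  # too few pixels per class is rejected
  tiny <- binary_mask(matrix(rep(c(TRUE, FALSE), c(3, 97)), 10, 10))
  expect_error(gbc_fit(list(img), list(tiny)), "at least 4 pixels")
})

test_that("parameter recovery error shrinks with the training pixel count", {
  p <- default_palettes()
  # moment errors decrease with sample size (checked on raw draws)
  errs <- vapply(c(1e3, 1e5), function(n) {
    set.seed(314)
    x <- MASS::mvrnorm(n, p$clean$mean, p$clean$cov)
    max(abs(colMeans(x) - p$clean$mean))
  }, double(1))
  expect_lt(errs[2], errs[1])

  # full-pipeline recovery on generated scenes: fitted moments near the truth
  corp <- small_corpus(20, h = 48, seed = 21)
  m <- gbc_fit(corpus_images(corp), corpus_masks(corp), fov = corp$scenes[[1]]$fov)
  expect_lt(max(abs(m$clean$mean - p$clean$mean)), 2)
  expect_lt(max(abs(m$contaminated$mean - p$contaminated$mean)), 2)
  rel_frob <- function(a, b) norm(a - b, "F") / norm(b, "F")
  expect_lt(rel_frob(m$clean$cov, p$clean$cov), 0.1)
  expect_lt(rel_frob(m$contaminated$cov, p$contaminated$cov), 0.1)
})

test_that("log likelihood matches closed forms and the naive-formula oracle", {
  mu <- c(10, 20, 30)
  cm_i <- wceseg:::make_class_model(mu, diag(3), 0.5, 10)
  expect_equal(gbc_log_likelihood(mu, cm_i), -1.5 * log(2 * pi), tolerance = 1e-12)

  cm_4 <- wceseg:::make_class_model(mu, diag(4, 3), 0.5, 10)
  expect_equal(gbc_log_likelihood(mu, cm_4), -1.5 * log(2 * pi) - log(8),
    tolerance = 1e-12
  )

  set.seed(99)
  for (i in 1:200) {
    sigma <- random_spd3()
    mu <- runif(3, 0, 255)
    x <- runif(3, 0, 255)
    cm <- wceseg:::make_class_model(mu, sigma, 0.5, 10)
    expect_equal(gbc_log_likelihood(x, cm), naive_mvn_logpdf(x, mu, sigma),
      tolerance = 1e-10
    )
  }

  expect_error(gbc_log_likelihood(c(NA, 1, 2), cm_i), "non-finite")
})

test_that("posteriors normalize, respect priors, and match the ratio oracle", {
  p <- default_palettes()
  # identical class models and equal priors: exactly (0.5, 0.5)
  m_sym <- new_gbc_model(p$clean$mean, p$clean$cov, p$clean$mean, p$clean$cov, 0.5)
  post <- gbc_posterior(c(100, 100, 100), m_sym)
  expect_equal(as.numeric(post), c(0.5, 0.5), tolerance = 1e-12)

  # a degenerate prior dominates regardless of the observation
  m_one <- new_gbc_model(p$clean$mean, p$clean$cov, p$contaminated$mean, p$contaminated$cov, 1)
  expect_equal(as.numeric(gbc_posterior(c(5, 250, 5), m_one)), c(1, 0))

  m <- new_gbc_model(p$clean$mean, p$clean$cov, p$contaminated$mean, p$contaminated$cov, 0.3)
  set.seed(5)
  x <- matrix(runif(300, 0, 255), 100, 3)
  post <- gbc_posterior(x, m)
  expect_true(all(abs(rowSums(post) - 1) <= 1e-12))
  # posterior ratio equals exp(delta log prior + delta log likelihood)
  lr <- log(0.3 / 0.7) + gbc_log_likelihood(x, m$clean) -
    gbc_log_likelihood(x, m$contaminated)
  # restrict to ratios where neither posterior has lost precision to 1 - p
  # (at |lr| = 20 the smaller posterior is ~2e-9, representable to ~5e-8
  # relative once stored as 1 minus the larger one)
  ok <- abs(lr) < 20
  expect_equal(log(post[ok, 1] / post[ok, 2]), lr[ok], tolerance = 1e-6)
})

test_that("segmentation is vectorization-exact and respects ties and FOV", {
  p <- default_palettes()
  m <- new_gbc_model(p$clean$mean, p$clean$cov, p$contaminated$mean, p$contaminated$cov, 0.4)

  for (s in 1:5) {
    img <- rand_image(16, 16, seed = s)
    seg <- gbc_segment(img, m)
    loop_p <- matrix(0, 16, 16)
    for (i in 1:16) {
      for (j in 1:16) {
        loop_p[i, j] <- gbc_posterior(as.double(img[i, j, ]), m)[1, 1]
      }
    }
    expect_lt(max(abs(loop_p - seg$p_clean)), 1e-12)
    expect_identical(unclass(seg$mask), loop_p >= 0.5)
  }

  # pixels at the clean mean with separated classes are all labeled clean
  px <- array(rep(round(p$clean$mean), each = 64), c(8, 8, 3))
  seg <- gbc_segment(rgb_image(px), m)
  expect_true(all(seg$mask))

  # exact posterior ties label the pixel clean
  m_tie <- new_gbc_model(p$clean$mean, p$clean$cov, p$clean$mean, p$clean$cov, 0.5)
  seg_tie <- gbc_segment(rand_image(8, 8, seed = 2), m_tie)
  expect_true(all(seg_tie$mask))
  expect_true(all(seg_tie$p_clean == 0.5))

  # outside-FOV pixels are contaminated with zero posterior
  fov <- circular_fov(16, 16)
  seg_f <- gbc_segment(rand_image(16, 16, seed = 9), m, fov = fov)
  expect_false(any(seg_f$mask[!fov]))
  expect_true(all(seg_f$p_clean[!fov] == 0))
})

test_that("labels are invariant to a common scaling of the priors", {
  p <- palettes_overlapping()
  m <- new_gbc_model(p$clean$mean, p$clean$cov, p$contaminated$mean, p$contaminated$cov, 0.3)
  set.seed(12)
  x <- matrix(runif(600, 0, 255), 200, 3)
  labels <- gbc_posterior(x, m)[, 1] >= 0.5
  for (scale in c(0.01, 7)) {
    s_clean <- log(0.3 * scale) + gbc_log_likelihood(x, m$clean)
    s_cont <- log(0.7 * scale) + gbc_log_likelihood(x, m$contaminated)
    expect_identical(s_clean >= s_cont, labels)
  }
})

test_that("the decision boundary is quadratic along any 1-D slice", {
  p <- palettes_overlapping()
  m <- new_gbc_model(p$clean$mean, p$clean$cov, p$contaminated$mean, p$contaminated$cov, 0.5)
  score <- function(t) {
    x <- cbind(t, 120, 100)
    log(m$clean$prior) - log(m$contaminated$prior) +
      gbc_log_likelihood(x, m$clean) - gbc_log_likelihood(x, m$contaminated)
  }
  # fit an exact quadratic through three points; it must reproduce the score
  t0 <- c(0, 100, 200)
  coef <- solve(cbind(1, t0, t0^2), score(t0))
  t_probe <- seq(10, 250, by = 24)
  expect_equal(score(t_probe),
    as.numeric(cbind(1, t_probe, t_probe^2) %*% coef),
    tolerance = 1e-8
  )
  # and the posterior tie sits at the quadratic's root
  roots <- Re(polyroot(coef))
  root <- roots[roots > 0 & roots < 255][1]
  expect_false(is.na(root))
  expect_equal(as.numeric(score(root)), 0, tolerance = 1e-6)
})

test_that("clean fraction is a simple pixel ratio", {
  expect_equal(clean_fraction(binary_mask(matrix(TRUE, 8, 8))), 1)
  expect_equal(clean_fraction(binary_mask(matrix(FALSE, 8, 8))), 0)
  m <- matrix(FALSE, 3, 4)
  m[1, 1:3] <- TRUE
  expect_equal(clean_fraction(binary_mask(m)), 0.25)
  fov <- matrix(c(TRUE, FALSE), 3, 4)
  expect_equal(clean_fraction(binary_mask(m), fov), sum(m & fov) / sum(fov))
})

test_that("model serialization round-trips and validates", {
  corp <- small_corpus(5, h = 24, seed = 31)
  m <- gbc_fit(corpus_images(corp), corpus_masks(corp))
  path <- withr::local_tempfile(fileext = ".json")
  save_gbc(m, path)
  m2 <- load_gbc(path)

  probe <- rand_image(12, 12, seed = 77)
  s1 <- gbc_segment(probe, m)
  s2 <- gbc_segment(probe, m2)
  expect_identical(unclass(s1$mask), unclass(s2$mask))
  expect_equal(s1$p_clean, s2$p_clean, tolerance = 1e-14)

  # the serialized model stores exactly 26 learned numbers
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stored <- length(raw$clean$mean) + length(raw$clean$cov) + length(raw$clean$prior) +
    length(raw$contaminated$mean) + length(raw$contaminated$cov) +
    length(raw$contaminated$prior)
  expect_equal(stored, 26)
  expect_equal(gbc_parameter_count(m2), 26)

  # tampered priors that no longer sum to one are rejected
  raw$clean$prior <- 0.9
  raw$contaminated$prior <- 0.3
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_gbc(bad), "priors sum")
  expect_error(load_gbc(withr::local_tempfile(fileext = ".json")), "does not exist")
})
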