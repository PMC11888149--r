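#' Concatenate class pixels across annotated frames
#'
#' Collects the RGB intensities of every pixel of the requested class (clean =
#' mask `TRUE`, contaminated = mask `FALSE`) from a set of annotated frames
#' into an `N_k x 3` matrix, in image order with a fixed (column-major)
#' within-image order so the result is reproducible.
#'
#' @param images list of [rgb_image]s.
#' @param masks list of paired [binary_mask]s (same length and shapes).
#' @param label `"clean"` or `"contaminated"`.
#' @param fov optional logical FOV matrix applied to every frame.
#' @return an `N_k x 3` double matrix with columns `r`, `g`, `b`.
#' @export
extract_class_pixels <- function(images, masks, label = c("clean", "contaminated"),
                                 fov = NULL) {
  label <- match.arg(label)
  if (length(images) != length(masks)) stopf("images and masks differ in length")
  if (length(images) == 0) stopf("no training images supplied")
  chunks <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- as_rgb_image(images[[i]])
    msk <- masks[[i]]
    check_pair(img, msk)
    d <- dim(img)
    f <- resolve_fov(fov, d[1], d[2])
    sel <- if (label == "clean") msk & f else (!msk) & f
    sel <- as.vector(sel)
    chunks[[i]] <- cbind(
      as.double(img[, , 1][sel]),
      as.double(img[, , 2][sel]),
      as.double(img[, , 3][sel])
    )
  }
  x <- do.call(rbind, chunks)
  if (nrow(x) == 0) stopf("class '%s' absent from training annotation", label)
  colnames(x) <- c("r", "g", "b")
  x
}

make_class_model <- function(mean, cov, prior, n_pixels, epsilon = 0) {
  mean <- as.double(mean)
  cov <- unname(as.matrix(cov))
  if (length(mean) != 3 || !all(dim(cov) == c(3, 3))) {
    stopf("class model needs a 3-vector mean and 3 x 3 covariance")
  }
  if (max(abs(cov - t(cov))) > 1e-9) stopf("covariance must be symmetric")
  cov <- (cov + t(cov)) / 2 + diag(epsilon, 3)
  ch <- tryCatch(chol(cov), error = function(e) {
    stopf("covariance is not positive definite (eigenvalues must be > 0); increase epsilon")
  })
  list(
    mean = stats::setNames(mean, c("r", "g", "b")), cov = cov,
    prior = prior, n_pixels = as.double(n_pixels), chol = ch
  )
}

#' Fit the two-class Gaussian Bayes classifier
#'
#' Estimates, from pixel-annotated frames, the class priors (pixel-count
#' proportions), per-class mean vectors and full 3 x 3 covariance matrices of
#' the RGB intensities — 26 learned numbers in total. Covariances use the
#' unbiased (1/(N-1)) estimator by default and are regularized by
#' `epsilon * I` to guarantee positive definiteness under degenerate
#' annotations; the Cholesky factor is precomputed for inference.
#'
#' @param images list of [rgb_image]s (the fitting subset, e.g. the 20
#'   cluster representatives).
#' @param masks list of paired [binary_mask]s.
#' @param epsilon ridge added to each covariance diagonal, in squared
#'   intensity counts (default `1e-3`).
#' @param fov optional logical FOV matrix; pixels outside it are ignored.
#' @param unbiased use the 1/(N-1) covariance estimator (default `TRUE`);
#'   `FALSE` switches to the 1/N maximum-likelihood form. With millions of
#'   training pixels the two are indistinguishable.
#' @param source_images optional character identifiers stored as fit metadata.
#' @return an object of class `"gbc_model"`.
#' @export
gbc_fit <- function(images, masks, epsilon = 1e-3, fov = NULL, unbiased = TRUE,
                    source_images = NULL) {
  xc <- extract_class_pixels(images, masks, "clean", fov)
  xk <- extract_class_pixels(images, masks, "contaminated", fov)
  if (!all(is.finite(xc)) || !all(is.finite(xk))) stopf("non-finite pixel values")
  nc <- nrow(xc)
  nk <- nrow(xk)
  if (nc < 4 || nk < 4) {
    stopf("need at least 4 pixels per class to identify a covariance (got %d clean, %d contaminated)", nc, nk)
  }
  est_cov <- function(x) {
    s <- stats::cov(x)
    if (!unbiased) s <- s * (nrow(x) - 1) / nrow(x)
    s
  }
  prior_clean <- nc / (nc + nk)
  structure(
    list(
      clean = make_class_model(colMeans(xc), est_cov(xc), prior_clean, nc, epsilon),
      contaminated = make_class_model(colMeans(xk), est_cov(xk), 1 - prior_clean, nk, epsilon),
      epsilon = epsilon,
      unbiased = unbiased,
      source_images = as.character(source_images %||% character())
    ),
    class = "gbc_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a classifier from explicit Gaussian parameters
#'
#' Constructs a `"gbc_model"` directly from known means, covariances and the
#' clean-class prior — useful for analytic studies on synthetic scenes where
#' the generating distributions are known exactly.
#'
#' @param clean_mean,contaminated_mean 3-vectors of RGB means (0-255 scale).
#' @param clean_cov,contaminated_cov 3 x 3 symmetric positive-definite
#'   covariance matrices (intensity^2 units).
#' @param prior_clean prior probability of the clean class, in `[0, 1]`.
#' @param epsilon optional ridge added to both covariances (default 0).
#' @return an object of class `"gbc_model"`.
#' @export
new_gbc_model <- function(clean_mean, clean_cov, contaminated_mean, contaminated_cov,
                          prior_clean = 0.5, epsilon = 0) {
  if (prior_clean < 0 || prior_clean > 1) stopf("prior_clean must lie in [0, 1]")
  structure(
    list(
      clean = make_class_model(clean_mean, clean_cov, prior_clean, NA_real_, epsilon),
      contaminated = make_class_model(
        contaminated_mean, contaminated_cov,
        1 - prior_clean, NA_real_, epsilon
      ),
      epsilon = epsilon,
      unbiased = NA,
      source_images = character()
    ),
    class = "gbc_model"
  )
}

#' @export
print.gbc_model <- function(x, ...) {
  cat("<gbc_model> two-class tri-variate Gaussian Bayes classifier\n")
  for (k in c("clean", "contaminated")) {
    cm <- x[[k]]
    cat(sprintf(
      "  %-12s prior %.4f  mean (%.1f, %.1f, %.1f)  n = %s\n",
      k, cm$prior, cm$mean[1], cm$mean[2], cm$mean[3],
      format(cm$n_pixels, big.mark = ",")
    ))
  }
  cat(sprintf(
    "  %d learned parameters, covariance ridge epsilon = %g\n",
    gbc_parameter_count(x), x$epsilon
  ))
  invisible(x)
}

#' Count the learned parameters of a fitted model
#'
#' Two priors plus, per class, a 3-vector mean and a 3 x 3 covariance:
#' 2 + 2 * (3 + 9) = 26 numbers.
#'
#' @param model a `"gbc_model"`.
#' @return integer parameter count.
#' @export
gbc_parameter_count <- function(model) {
  sum(vapply(
    model[c("clean", "contaminated")],
    function(cm) length(cm$mean) + length(cm$cov) + length(cm$prior),
    double(1)
  ))
}

# Multivariate normal log density via the stored Cholesky factor; x is N x 3.
mvn_log_density <- function(x, cm) {
  u <- forwardsolve(t(cm$chol), t(x) - cm$mean)
  q <- colSums(u^2)
  logdet <- 2 * sum(log(diag(cm$chol)))
  -0.5 * (3 * log(2 * pi) + logdet + q)
}

#' Gaussian class-conditional log likelihood
#'
#' Evaluates the log of the tri-variate normal density `N(x; mu_k, Sigma_k)`
#' through a Cholesky solve — no explicit inverse or determinant is ever
#' formed, keeping the computation stable for pixels far from the class mean.
#'
#' @param x a 3-vector of RGB intensities, or an `N x 3` matrix of them.
#' @param class_model one class of a `"gbc_model"` (e.g. `model$clean`).
#' @return log density value(s).
#' @export
gbc_log_likelihood <- function(x, class_model) {
  if (is.null(dim(x))) x <- matrix(as.double(x), 1, 3)
  if (ncol(x) != 3) stopf("x must have 3 columns (r, g, b)")
  if (!all(is.finite(x))) stopf("non-finite pixel values")
  mvn_log_density(x, class_model)
}

#' Posterior class probabilities of pixels
#'
#' Combines log prior and log likelihood per class and normalizes by
#' log-sum-exp, so the evidence term is computed (not dropped) and the two
#' columns sum to one exactly. The normalized posterior is what makes the
#' probability map usable for AUROC.
#'
#' @param x a 3-vector of RGB intensities, or an `N x 3` matrix.
#' @param model a `"gbc_model"`.
#' @return an `N x 2` matrix with columns `p_clean`, `p_contaminated`.
#' @export
gbc_posterior <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(as.double(x), 1, 3)
  lc <- log(model$clean$prior) + gbc_log_likelihood(x, model$clean)
  lk <- log(model$contaminated$prior) + gbc_log_likelihood(x, model$contaminated)
  m <- pmax(lc, lk)
  # degenerate priors (0) yield -Inf scores; the other class then gets all mass
  ec <- exp(lc - m)
  ek <- exp(lk - m)
  p <- ec / (ec + ek)
  cbind(p_clean = p, p_contaminated = 1 - p)
}

#' Segment a frame into clean and contaminated regions
#'
#' Assigns every pixel to the class with the larger posterior probability
#' (ties go to clean, the positive class) and returns both the hard mask and
#' the clean-class posterior probability map. Pixels outside the optional FOV
#' are labeled contaminated with `p_clean = 0`.
#'
#' @param image an [rgb_image].
#' @param model a `"gbc_model"`.
#' @param fov optional logical FOV matrix.
#' @return a list with `mask` (a [binary_mask], `TRUE` = clean) and `p_clean`
#'   (an `H x W` matrix of posterior probabilities in `[0, 1]`).
#' @export
gbc_segment <- function(image, model, fov = NULL) {
  image <- as_rgb_image(image)
  d <- dim(image)
  x <- cbind(
    as.double(image[, , 1]),
    as.double(image[, , 2]),
    as.double(image[, , 3])
  )
  p <- gbc_posterior(x, model)[, 1]
  p_clean <- matrix(p, d[1], d[2])
  mask <- p_clean >= 0.5 # ties label clean
  if (!is.null(fov)) {
    f <- resolve_fov(fov, d[1], d[2])
    mask[!f] <- FALSE
    p_clean[!f] <- 0
  }
  list(mask = binary_mask(mask), p_clean = p_clean)
}

#' Clean-pixel fraction of a mask
#'
#' The small-bowel visualization quality score: the ratio of clean pixels to
#' all pixels considered (all pixels, or those inside `fov` when given).
#'
#' @param mask a [binary_mask] or logical matrix (`TRUE` = clean).
#' @param fov optional logical FOV matrix.
#' @return a fraction in `[0, 1]`.
#' @export
clean_fraction <- function(mask, fov = NULL) {
  if (!is.logical(mask) || !is.matrix(mask)) stopf("mask must be a logical matrix")
  f <- resolve_fov(fov, nrow(mask), ncol(mask))
  mean(mask[f])
}

#' Serialize a fitted model to JSON
#'
#' Stores the 26 learned parameters (2 priors, 2 means, 2 covariances) plus
#' the regularization constant and fit metadata at full double precision.
#' `load_gbc(save_gbc(m))` reproduces identical posteriors.
#'
#' @param model a `"gbc_model"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_gbc <- function(model, path) {
  if (!inherits(model, "gbc_model")) stopf("model must be a gbc_model")
  pack <- function(cm) {
    list(
      mean = as.double(cm$mean), cov = unname(cm$cov),
      prior = cm$prior, n_pixels = cm$n_pixels
    )
  }
  obj <- list(
    format = "wceseg-gbc-model", version = 1L,
    epsilon = model$epsilon, unbiased = model$unbiased,
    source_images = model$source_images,
    clean = pack(model$clean), contaminated = pack(model$contaminated)
  )
  # I(17) significant digits makes the double -> decimal -> double round trip
  # bit-exact, so a reloaded model reproduces identical posteriors
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load a model saved by [save_gbc()]
#'
#' @param path JSON file written by [save_gbc()].
#' @return a `"gbc_model"` with the Cholesky factors rebuilt.
#' @export
load_gbc <- function(path) {
  if (!file.exists(path)) stopf("model file '%s' does not exist", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wceseg-gbc-model")) {
    stopf("'%s' is not a wceseg model file", path)
  }
  for (k in c("clean", "contaminated")) {
    cm <- obj[[k]]
    if (is.null(cm) || length(cm$mean) != 3 || !all(dim(as.matrix(cm$cov)) == c(3, 3)) ||
      is.null(cm$prior)) {
      stopf("model file '%s' is malformed: class '%s' incomplete", path, k)
    }
  }
  if (abs(obj$clean$prior + obj$contaminated$prior - 1) > 1e-8) {
    stopf("model file '%s' is invalid: class priors sum to %g, not 1", path,
      obj$clean$prior + obj$contaminated$prior)
  }
  unpack <- function(cm) {
    make_class_model(cm$mean, as.matrix(cm$cov), cm$prior, cm$n_pixels %||% NA_real_)
  }
  structure(
    list(
      clean = unpack(obj$clean), contaminated = unpack(obj$contaminated),
      epsilon = obj$epsilon %||% 0, unbiased = obj$unbiased %||% NA,
      source_images = as.character(obj$source_images %||% character())
    ),
    class = "gbc_model"
  )
}
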