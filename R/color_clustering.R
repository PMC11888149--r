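#' Convert an RGB image to CIELAB
#'
#' Uses sRGB companding and the D65 white point (via
#' [grDevices::convertColor()]), so `L` lies in `[0, 100]` and the `a`, `b`
#' opponent axes within `[-128, 127]` for in-gamut colors. CIELAB is used only
#' for frame clustering; classification itself works on raw RGB intensities.
#'
#' @param image an [rgb_image].
#' @return an `H x W x 3` double array with slices `L`, `a`, `b`.
#' @export
rgb_to_cielab <- function(image) {
  image <- as_rgb_image(image)
  d <- dim(image)
  m <- matrix(as.double(image), d[1] * d[2], 3) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3), dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' 3-D CIELAB color histogram feature
#'
#' Bins each pixel's (L, a, b) triple on a fixed uniform grid —
#' `bins_per_channel` bins per channel over `L` in `[0, 100]` and `a`, `b` in
#' `[-128, 127]` — and flattens the 3-D histogram L-major (L slowest, then a,
#' then b) into a vector of length `bins_per_channel^3`. With the default 8
#' bins per channel the feature has 512 entries. Fixed absolute ranges keep
#' features comparable across images; the last bin includes its upper edge.
#'
#' @param lab `H x W x 3` Lab array from [rgb_to_cielab()].
#' @param bins_per_channel number of bins per channel, at least 2.
#' @param fov optional logical FOV matrix; only `TRUE` pixels are counted.
#' @param normalize if `TRUE` (default) the histogram is L1-normalized so
#'   corpora with mixed resolutions are comparable; if `FALSE`, raw counts.
#' @return a numeric vector of class `"histogram_feature"` with attributes
#'   `bins_per_channel` and `normalized`.
#' @export
histogram_3d <- function(lab, bins_per_channel = 8, fov = NULL, normalize = TRUE) {
  if (bins_per_channel < 2) stopf("bins_per_channel must be at least 2")
  b <- as.integer(bins_per_channel)
  d <- dim(lab)
  fov <- resolve_fov(fov, d[1], d[2])
  sel <- as.vector(fov)
  bin_of <- function(v, lo, hi) {
    # uniform edges on [lo, hi]; upper edge inclusive in the last bin
    i <- floor((v - lo) / (hi - lo) * b) + 1L
    pmin(pmax(i, 1L), b)
  }
  iL <- bin_of(lab[, , 1][sel], 0, 100)
  ia <- bin_of(lab[, , 2][sel], -128, 127)
  ib <- bin_of(lab[, , 3][sel], -128, 127)
  idx <- (iL - 1L) * b * b + (ia - 1L) * b + ib
  counts <- tabulate(idx, nbins = b^3)
  counts <- as.double(counts)
  if (normalize) counts <- counts / sum(counts)
  structure(counts,
    bins_per_channel = b, normalized = normalize,
    class = "histogram_feature"
  )
}

#' Histogram feature of an image in one call
#'
#' Convenience composition of [rgb_to_cielab()] and [histogram_3d()].
#'
#' @inheritParams histogram_3d
#' @param image an [rgb_image].
#' @return a `"histogram_feature"` vector.
#' @export
frame_feature <- function(image, bins_per_channel = 8, fov = NULL, normalize = TRUE) {
  histogram_3d(rgb_to_cielab(image), bins_per_channel, fov, normalize)
}

features_matrix <- function(features) {
  if (is.matrix(features)) {
    return(features)
  }
  lens <- vapply(features, length, 1L)
  if (length(unique(lens)) != 1) stopf("all features must have the same length")
  do.call(rbind, lapply(features, as.double))
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center sampled with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) {
      stopf("degenerate input: fewer than k distinct feature vectors (duplicate centroids)")
    }
    pick <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# One Lloyd run. Assignment ties break toward the lowest cluster index so the
# result is fully determined by the seed.
lloyd <- function(x, centers, max_iter) {
  n <- nrow(x)
  k <- nrow(centers)
  xsq <- rowSums(x^2)
  labels <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d <- matrix(xsq, n, k) - 2 * x %*% t(centers) +
      matrix(rowSums(centers^2), n, k, byrow = TRUE)
    new_labels <- max.col(-d, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        stopf("cluster %d became empty; choose a smaller k", j)
      }
      centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  d <- matrix(xsq, n, k) - 2 * x %*% t(centers) +
    matrix(rowSums(centers^2), n, k, byrow = TRUE)
  wss <- sum(d[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, tot_withinss = max(wss, 0))
}

#' Cluster frames by their color-histogram features
#'
#' Lloyd's K-means with k-means++ initialization, Euclidean distance, and
#' `nstart` independent restarts; the run with the lowest within-cluster sum
#' of squares wins. Results are deterministic given `seed`. An empty final
#' cluster raises an error advising a smaller `k`.
#'
#' @param features a list of `"histogram_feature"` vectors (or a numeric
#'   matrix with one feature per row); at least `k` of them.
#' @param k number of clusters (the study protocol uses 20).
#' @param seed integer seed controlling initialization.
#' @param nstart number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return an object of class `"cluster_assignment"`: list with `labels`
#'   (cluster index in `1..k` per frame), `k`, `centroids` (`k x p` matrix),
#'   `seed` and `tot_withinss`.
#' @export
cluster_frames <- function(features, k = 20, seed = 1L, nstart = 10, max_iter = 300) {
  x <- features_matrix(features)
  n <- nrow(x)
  if (k < 1) stopf("k must be positive")
  if (n < k) stopf("cannot form %d clusters from %d frames", k, n)
  best <- NULL
  with_seed_opt(seed, {
    for (r in seq_len(nstart)) {
      fit <- lloyd(x, kmeanspp_init(x, k), max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  structure(
    list(
      labels = best$labels, k = as.integer(k), centroids = best$centers,
      seed = seed, tot_withinss = best$tot_withinss
    ),
    class = "cluster_assignment"
  )
}

#' Select one representative frame per cluster
#'
#' Draws uniformly at random one member from each cluster; the complement of
#' the returned indices is the evaluation subset. With K = 20 clusters over a
#' 2000-frame corpus this yields the study's 20 fitting / 1980 evaluation
#' split.
#'
#' @param assignment a `"cluster_assignment"` from [cluster_frames()].
#' @param seed integer seed for the within-cluster draws.
#' @return an integer vector of length `assignment$k` of frame indices, one
#'   per cluster (ordered by cluster index).
#' @export
select_representatives <- function(assignment, seed = 1L) {
  if (!inherits(assignment, "cluster_assignment")) {
    stopf("assignment must come from cluster_frames()")
  }
  with_seed_opt(seed, {
    vapply(seq_len(assignment$k), function(j) {
      members <- which(assignment$labels == j)
      if (length(members) == 1) members else sample(members, 1)
    }, integer(1))
  })
}
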