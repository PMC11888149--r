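# Internal helpers shared across modules.

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Round real-valued pixel data and rebuild a valid 8-bit image array.
finish_image <- function(x) {
  x <- round(clip255(x))
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

# Derive a stream seed from a master seed and an item index. Constants are
# arbitrary odd multipliers; the result stays below 2^31 - 1 so it is a
# valid input for set.seed() on 32-bit integer platforms.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(i) * 7919) %%
    2147483647)
}

# Evaluate `expr` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; with seed = NULL the current RNG stream is used.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# fov = NULL means "all pixels"; callers pass image dims for expansion.
resolve_fov <- function(fov, h, w) {
  if (is.null(fov)) {
    return(matrix(TRUE, h, w))
  }
  if (!is.logical(fov) || !is.matrix(fov)) {
    stopf("fov must be a logical matrix or NULL")
  }
  if (nrow(fov) != h || ncol(fov) != w) {
    stopf(
      "fov dimensions (%d x %d) do not match image dimensions (%d x %d)",
      nrow(fov), ncol(fov), h, w
    )
  }
  if (!any(fov)) stopf("fov contains no pixels")
  fov
}
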