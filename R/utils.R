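#' @keywords internal
#' @importFrom stats rnorm runif rexp rlogis plogis var sd pnorm dnorm predict rbinom
#' @importFrom utils write.csv packageVersion
"_PACKAGE"

# Deterministic 31-bit seed derived from (global seed, stage name) so each
# pipeline stage owns an independent stream and can be rerun in isolation.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# 31-bit string hash (used to mix patient ids into subsampling seeds).
hash_id <- function(x) {
  h <- 0
  for (k in utf8ToInt(as.character(x))) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# --- image primitives -------------------------------------------------------
# Images are arrays H x W x 3 with values in [0, 1].

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Bilinear resize of an RGB image array
#'
#' @param img numeric array H x W x 3, values in \[0, 1\].
#' @param out_h,out_w output size in pixels.
#' @return resized H' x W' x 3 array. Returning the input unchanged when the
#'   size is already `out_h` x `out_w` keeps identity transforms exact.
#' @keywords internal
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  # align-corners=FALSE style sampling grid
  ys <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    e <- ch[y1, x0, drop = FALSE]; f <- ch[y1, x1, drop = FALSE]
    top <- a * rep(1 - wx, each = out_h) + b * rep(wx, each = out_h)
    bot <- e * rep(1 - wx, each = out_h) + f * rep(wx, each = out_h)
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  out
}

# Separable Gaussian blur with reflected borders.
gaussian_blur_img <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n), rev(n + 1 - seq_len(min(r, n))))
  out <- img
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    # rows
    chp <- ch[pad_idx(d[1]), , drop = FALSE]
    acc <- matrix(0, d[1], d[2])
    for (i in seq_along(k)) acc <- acc + k[i] * chp[i:(i + d[1] - 1), , drop = FALSE]
    # cols
    accp <- acc[, pad_idx(d[2]), drop = FALSE]
    acc2 <- matrix(0, d[1], d[2])
    for (i in seq_along(k)) acc2 <- acc2 + k[i] * accp[, i:(i + d[2] - 1), drop = FALSE]
    out[, , c] <- acc2
  }
  out
}

rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read a slide image from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return H x W x 3 array in \[0, 1\]. Grayscale images are expanded to three
#'   channels; an alpha channel, if present, is dropped.
#' @export
read_slide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported slide format: ", ext, " (expected png/tif/tiff)")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
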