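#' Time-frequency image rendering configuration
#'
#' @param size output image side length (default 224).
#' @param channels output channels (default 3, grayscale-replicated).
#' @param freq_range frequency crop in Hz (default 0.3-35).
#' @param log_compress apply `log1p` compression before min-max scaling
#'   (default TRUE; EEG TF magnitudes span orders of magnitude).
#' @param colormap "gray" (channel replication, default) or "viridis".
#' @return object of class `render_config`.
#' @export
render_config <- function(size = 224L, channels = 3L,
                          freq_range = c(0.3, 35), log_compress = TRUE,
                          colormap = c("gray", "viridis")) {
  colormap <- match.arg(colormap)
  stopifnot(size >= 2, channels >= 1)
  structure(list(size = as.integer(size), channels = as.integer(channels),
                 freq_range = freq_range, log_compress = log_compress,
                 colormap = colormap),
            class = "render_config")
}

# Separable bilinear resize of a matrix to h x w (pixel-center sampling).
resize_bilinear <- function(M, h, w) {
  lerp_axis <- function(n_src, n_out) {
    pos <- ((seq_len(n_out) - 0.5) * n_src / n_out) + 0.5
    pos <- pmin(pmax(pos, 1), n_src)
    i0 <- pmin(floor(pos), n_src - 1L)
    if (n_src == 1L) i0 <- rep(1L, n_out)
    list(i0 = as.integer(i0), f = pos - i0)
  }
  r <- lerp_axis(nrow(M), h)
  M2 <- M[r$i0, , drop = FALSE] * (1 - r$f) +
    M[pmin(r$i0 + 1L, nrow(M)), , drop = FALSE] * r$f
  c2 <- lerp_axis(ncol(M), w)
  M2[, c2$i0, drop = FALSE] * rep(1 - c2$f, each = h) +
    M2[, pmin(c2$i0 + 1L, ncol(M)), drop = FALSE] * rep(c2$f, each = h)
}

# Magnitude matrix (freq x time) and frequency axis of any TF grid. Bare
# matrices are taken as already cropped and oriented (row 1 = top).
tf_magnitude <- function(grid) {
  if (inherits(grid, "fsst_grid"))
    list(mag = sqrt(grid$energy), freq = grid$freq)
  else if (inherits(grid, "stft_grid"))
    list(mag = Mod(grid$V), freq = grid$freq)
  else if (inherits(grid, "cwt_grid"))
    list(mag = Mod(grid$W), freq = grid$freq)
  else if (is.matrix(grid))
    list(mag = grid, freq = NULL)
  else stop("unsupported grid type", call. = FALSE)
}

#' Render a time-frequency grid to an image
#'
#' Crops the frequency axis to `freq_range`, takes the coefficient
#' magnitude, applies `log1p` compression and per-image min-max scaling to
#' `[0, 1]`, bilinearly resizes to `size x size`, and replicates to
#' `channels` channels (or applies a colormap). Output row 1 is the
#' highest frequency (spectrogram orientation). An all-constant grid maps
#' to an all-zero image with a warning.
#'
#' @param grid an `stft_grid`, `fsst_grid`, `cwt_grid`, or a bare
#'   magnitude matrix (freq x time, rows taken as already cropped).
#' @param cfg a [render_config()].
#' @return `size x size x channels` array of values in `[0, 1]`, class
#'   `tf_image`, with attribute `transform` naming the source grid type.
#' @export
render_tf_image <- function(grid, cfg = render_config()) {
  m <- tf_magnitude(grid)
  if (is.null(m$freq)) {
    mag <- m$mag
  } else {
    keep <- m$freq >= cfg$freq_range[1] & m$freq <= cfg$freq_range[2]
    mag <- m$mag[keep, , drop = FALSE]
    ord <- order(m$freq[keep], decreasing = TRUE)  # high freq at top
    mag <- mag[ord, , drop = FALSE]
  }
  if (!all(is.finite(mag))) stop("grid contains non-finite values",
                                 call. = FALSE)
  if (cfg$log_compress) mag <- log1p(mag)
  rng <- range(mag)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    warning("all-constant grid; rendering an all-zero image")
    pix <- matrix(0, cfg$size, cfg$size)
  } else {
    mag <- (mag - rng[1]) / (rng[2] - rng[1])
    pix <- resize_bilinear(mag, cfg$size, cfg$size)
    pix <- pmin(pmax(pix, 0), 1)
  }
  img <- if (cfg$colormap == "gray") {
    array(pix, dim = c(cfg$size, cfg$size, cfg$channels))
  } else {
    cols <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
    qi <- pmin(pmax(round(pix * 255) + 1L, 1L), 256L)
    array(c(cols[1L, qi], cols[2L, qi], cols[3L, qi]),
          dim = c(cfg$size, cfg$size, 3L))
  }
  structure(img, class = "tf_image",
            transform = class(grid)[1], config = unclass(cfg))
}

#' Convert a labelled epoch dataset to time-frequency images
#'
#' Batch front-end for the classifier: each 30-s epoch is transformed
#' (CWT scalogram or FSST) and rendered. Images are grayscale and stored
#' as rows of a matrix (`size^2` columns); the classifiers replicate
#' channels on the fly.
#'
#' @param ds an `epoch_dataset`.
#' @param method "cwt" (default) or "fsst".
#' @param tf_cfg transform configuration ([cwt_config()] or
#'   [fsst_config()]).
#' @param render_cfg a [render_config()].
#' @param time_decimation exact CWT time decimation used for imaging
#'   (default 30, i.e. 256 columns before resizing; see [cwt_morse()]).
#' @param progress print progress every 500 epochs.
#' @return object of class `tf_image_set`: list with `images`
#'   (n x size^2 matrix), `labels`, `size`, `method`.
#' @export
epochs_to_images <- function(ds, method = c("cwt", "fsst"), tf_cfg = NULL,
                             render_cfg = render_config(),
                             time_decimation = 30L, progress = FALSE) {
  method <- match.arg(method)
  n <- n_epochs(ds)
  if (is.null(tf_cfg))
    tf_cfg <- if (method == "cwt") cwt_config() else fsst_config()
  bank <- if (method == "cwt") cwt_filter_bank(tf_cfg, 7680L) else NULL
  out <- matrix(0, n, render_cfg$size^2)
  for (i in seq_len(n)) {
    grid <- if (method == "cwt")
      cwt_morse(ds$epochs[i, ], tf_cfg, bank = bank,
                decimate = time_decimation)
    else fsst(ds$epochs[i, ], tf_cfg)
    img <- render_tf_image(grid, cfg = within_channels(render_cfg, 1L))
    out[i, ] <- as.vector(img[, , 1L])
    if (progress && i %% 500L == 0L) msg("imaged %d/%d epochs", i, n)
  }
  structure(list(images = out, labels = ds$labels, size = render_cfg$size,
                 method = method),
            class = "tf_image_set")
}

within_channels <- function(cfg, ch) { cfg$channels <- as.integer(ch); cfg }

#' Export a rendered time-frequency image to PNG
#'
#' @param img a `tf_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tf_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  a <- unclass(img)
  attr(a, "transform") <- NULL; attr(a, "config") <- NULL
  png::writePNG(a, path)
  invisible(path)
}
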