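#' Rendering configuration for synthetic fiber images
#'
#' Maps kb coordinates to pixels through the combing constant (kb of DNA per
#' µm of stretched fiber) and the pixel size; defaults give 0.2 kb/px, the
#' community-standard 2 kb/µm stretching at 0.1 µm pixels. Label tracks are
#' drawn as rectangular intensity blocks of height `band_height_px` centred in
#' a strip of `strip_height_px` rows, blurred with a Gaussian PSF and overlaid
#' with additive Gaussian noise of sd `peak_intensity / snr` on top of a
#' constant background.
#'
#' @param combing_constant_kb_per_um stretching factor (kb/µm).
#' @param pixel_size_um pixel size (µm).
#' @param strip_height_px image strip height (rows).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 = no blur).
#' @param snr peak-signal to noise-sd ratio (`Inf` = noiseless).
#' @param background_level mean background intensity (counts).
#' @param peak_intensity label block intensity (counts; 16-bit range).
#' @param band_height_px fiber thickness in rows.
#' @param seed integer seed making rendering deterministic.
#' @return an object of class `render_config`.
#' @export
render_config <- function(combing_constant_kb_per_um = 2,
                          pixel_size_um = 0.1,
                          strip_height_px = 24,
                          psf_sigma_px = 1,
                          snr = 20,
                          background_level = 50,
                          peak_intensity = 1000,
                          band_height_px = 5,
                          seed = NULL) {
  for (f in c("combing_constant_kb_per_um", "pixel_size_um", "strip_height_px",
              "peak_intensity", "band_height_px"))
    if (!is_number(get(f)) || get(f) <= 0)
      stop_config("render_config field '%s' must be a positive number", f)
  if (!is_number(psf_sigma_px) || psf_sigma_px < 0)
    stop_config("psf_sigma_px must be non-negative")
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop_config("snr must be positive (Inf for noiseless)")
  if (!is_number(background_level) || background_level < 0)
    stop_config("background_level must be non-negative")
  if (!is.null(seed) && !is_count(seed))
    stop_config("seed must be NULL or a non-negative integer")
  structure(list(combing_constant_kb_per_um = combing_constant_kb_per_um,
                 pixel_size_um = pixel_size_um,
                 strip_height_px = as.integer(strip_height_px),
                 psf_sigma_px = psf_sigma_px, snr = snr,
                 background_level = background_level,
                 peak_intensity = peak_intensity,
                 band_height_px = as.integer(band_height_px),
                 seed = seed),
            class = "render_config")
}

#' @rdname render_config
#' @export
kb_per_px <- function(config) {
  config$pixel_size_um * config$combing_constant_kb_per_um
}

# Separable Gaussian blur; zero padding at the borders. Implemented as a
# shifted-sum convolution (kernels are short) to avoid per-call overhead.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(m) {
    n <- nrow(m)
    pad <- matrix(0, r, ncol(m))
    p <- rbind(pad, m, pad)
    out <- matrix(0, n, ncol(m))
    for (j in 0:(2L * r)) out <- out + k[j + 1L] * p[(1L + j):(n + j), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

channel_names <- function(protocol = labeling_protocol()) {
  c("DNA", protocol$pulse1_label, protocol$pulse2_label)
}

#' Render one fiber as a 3-channel image strip
#'
#' Produces an integer array `strip_height_px x width x 3` with channels in
#' the order (DNA, pulse 1, pulse 2). The DNA channel always covers the whole
#' fiber extent; each labeled segment becomes a rectangular block, everything
#' is convolved with the PSF and Gaussian noise of sd `peak/snr` is added,
#' then intensities are clamped to the 16-bit range and rounded (camera
#' quantisation), which makes TIFF round trips exact.
#'
#' @param segments [segment_table] rows of a single fiber (label channels;
#'   a DNA row is optional and redundant).
#' @param fiber_length_kb fiber length (kb).
#' @param config a [render_config()].
#' @param fiber_id identifier stored in the image attributes.
#' @param protocol a [labeling_protocol()] defining channel order.
#' @param seed overrides `config$seed`.
#' @return a `fiber_image`: integer array with attributes `fiber_id` and
#'   `kb_per_px`.
#' @export
render_fiber <- function(segments, fiber_length_kb, config = render_config(),
                         fiber_id = NULL, protocol = labeling_protocol(),
                         seed = config$seed) {
  s <- kb_per_px(config)
  fiber_id <- fiber_id %||%
    (if (nrow(segments)) segments$fiber_id[1] else "fiber")
  if (nrow(segments)) {
    if (length(unique(segments$fiber_id)) > 1L)
      stop_data("render_fiber expects a single fiber, got several ids")
    bad <- segments$start_kb < -1e-9 | segments$end_kb > fiber_length_kb + 1e-9
    if (any(bad))
      stop_data("segment outside fiber [0, %g) on fiber '%s'",
                fiber_length_kb, fiber_id)
  }
  chans <- channel_names(protocol)
  W <- max(1L, as.integer(ceiling(fiber_length_kb / s)))
  H <- config$strip_height_px
  mid <- ceiling(H / 2)
  half <- (config$band_height_px - 1L) %/% 2L
  rows <- max(1L, mid - half):min(H, mid + half)
  img <- array(0, dim = c(H, W, 3L), dimnames = list(NULL, NULL, chans))

  paint <- function(ch, a, b) {
    c0 <- max(1L, floor(a / s) + 1L)
    c1 <- min(W, ceiling(b / s))
    if (c1 >= c0) img[rows, c0:c1, ch] <<- config$peak_intensity
  }
  paint("DNA", 0, fiber_length_kb)
  for (i in seq_len(nrow(segments))) {
    ch <- segments$channel[i]
    if (!ch %in% chans)
      stop_data("unknown channel '%s' on fiber '%s'", ch, fiber_id)
    paint(ch, segments$start_kb[i], segments$end_kb[i])
  }

  img <- with_seed(seed, {
    for (ch in chans) {
      m <- gaussian_blur(img[, , ch], config$psf_sigma_px) +
        config$background_level
      if (is.finite(config$snr))
        m <- m + stats::rnorm(length(m), 0, config$peak_intensity / config$snr)
      img[, , ch] <- m
    }
    img
  })
  storage.mode(img) <- "double"
  img <- round(pmin(pmax(img, 0), 65535))
  storage.mode(img) <- "integer"
  dimnames(img) <- list(NULL, NULL, chans)
  structure(img, fiber_id = fiber_id, kb_per_px = s, class = "fiber_image")
}

#' Render every fiber of a segment table
#'
#' @param segments a [segment_table] with DNA rows (fiber extents).
#' @param config a [render_config()]; each fiber gets a seed derived from
#'   `config$seed` so the whole set is reproducible.
#' @param protocol a [labeling_protocol()].
#' @return a list of `fiber_image` strips, one per fiber.
#' @export
render_fibers <- function(segments, config = render_config(),
                          protocol = labeling_protocol()) {
  ext <- fiber_extents(segments)
  seeds <- if (is.null(config$seed)) vector("list", nrow(ext))
           else as.list(derive_seeds(config$seed, nrow(ext)))
  lapply(seq_len(nrow(ext)), function(i) {
    g <- segments[segments$fiber_id == ext$fiber_id[i] &
                    segments$channel != "DNA", , drop = FALSE]
    render_fiber(g, ext$hi_kb[i], config, fiber_id = ext$fiber_id[i],
                 protocol = protocol, seed = seeds[[i]])
  })
}

#' @export
print.fiber_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("fiber_image '%s': %d x %d px, 3 channels, %.3g kb/px\n",
              attr(x, "fiber_id"), d[1], d[2], attr(x, "kb_per_px")))
  invisible(x)
}
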