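# Minimal baseline TIFF support: multi-page, 16-bit, 3 samples/pixel, chunky,
# uncompressed, little-endian, one strip per page, with per-page JSON metadata
# (fiber_id, kb_per_px) in the ImageDescription tag. No TIFF package exists in
# this R environment, so the small subset the pipeline needs is implemented
# here; files are plain baseline TIFF readable by any external reader.

u16_raw <- function(v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2, endian = "little")
}

u32_raw <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

ifd_entry <- function(tag, type, count, value, is_offset = FALSE) {
  val <- if (is_offset) u32_raw(value)
         else if (type == 3L) c(u16_raw(value), u16_raw(0))  # SHORT inline
         else u32_raw(value)                                  # LONG inline
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val)
}

#' Write fiber images as a multi-page TIFF
#'
#' Stores each strip as one 16-bit RGB-like page (channel order DNA, pulse 1,
#' pulse 2) with `fiber_id` and `kb_per_px` serialised as JSON in the page's
#' ImageDescription tag, and writes a sidecar TSV manifest (fiber_id, page,
#' kb_per_px) next to the image file.
#'
#' @param images list of `fiber_image` strips from [render_fiber()].
#' @param path output TIFF path.
#' @param manifest sidecar manifest path (default `<path>.manifest.tsv`).
#' @return `path`, invisibly.
#' @export
write_fiber_images <- function(images, path,
                               manifest = paste0(path, ".manifest.tsv")) {
  if (length(images) == 0L) stop_data("no image strips to write")
  if (!dir.exists(dirname(path)))
    stop_data("directory does not exist for path '%s'", path)
  pages <- lapply(images, function(img) {
    d <- dim(img)
    if (length(d) != 3L || d[3] != 3L)
      stop_data("each image must be an H x W x 3 array")
    desc <- jsonlite::toJSON(list(fiber_id = attr(img, "fiber_id"),
                                  kb_per_px = attr(img, "kb_per_px")),
                             auto_unbox = TRUE, digits = NA)
    desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0))
    pix <- u16_raw(as.vector(aperm(unclass(img), c(3, 2, 1))))
    list(H = d[1], W = d[2], desc = desc_raw, pix = pix)
  })

  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  # first pass: page layout (bits array, description, pixel strip, IFD)
  page_sizes <- vapply(pages, function(p)
    6L + length(p$desc) + length(p$pix) + ifd_size, integer(1))
  page_starts <- 8L + c(0L, cumsum(page_sizes))[seq_along(pages)]
  ifd_offsets <- page_starts + page_sizes - ifd_size
  chunks <- list()
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    bits_off <- page_starts[i]
    desc_off <- bits_off + 6L
    pix_off <- desc_off + length(p$desc)
    ifd_off <- ifd_offsets[i]
    entries <- c(
      ifd_entry(256L, 4L, 1L, p$W),
      ifd_entry(257L, 4L, 1L, p$H),
      ifd_entry(258L, 3L, 3L, bits_off, is_offset = TRUE),
      ifd_entry(259L, 3L, 1L, 1L),
      ifd_entry(262L, 3L, 1L, 2L),
      ifd_entry(270L, 2L, length(p$desc), desc_off, is_offset = TRUE),
      ifd_entry(273L, 4L, 1L, pix_off),
      ifd_entry(277L, 3L, 1L, 3L),
      ifd_entry(278L, 4L, 1L, p$H),
      ifd_entry(279L, 4L, 1L, length(p$pix)),
      ifd_entry(284L, 3L, 1L, 1L))
    next_off <- if (i < length(pages)) ifd_offsets[i + 1L] else 0L
    ifd <- c(u16_raw(n_entries), entries, u32_raw(next_off))
    chunks[[i]] <- c(u16_raw(c(16L, 16L, 16L)), p$desc, p$pix, ifd)
  }
  header <- c(charToRaw("II"), u16_raw(42L), u32_raw(ifd_offsets[1]))
  writeBin(c(header, do.call(c, chunks)), path)

  man <- data.frame(fiber_id = vapply(images, attr, "", "fiber_id"),
                    page = seq_along(images) - 1L,
                    kb_per_px = vapply(images, attr, 0, "kb_per_px"))
  write_tsv(man, manifest)
  invisible(path)
}

read_u16 <- function(raw, off, n = 1L) {
  if (off + 2L * n - 1L > length(raw)) stop_data("truncated TIFF file")
  readBin(raw[(off):(off + 2L * n - 1L)], "integer", n = n, size = 2,
          signed = FALSE, endian = "little")
}

read_u32 <- function(raw, off, n = 1L) {
  if (off + 4L * n - 1L > length(raw)) stop_data("truncated TIFF file")
  readBin(raw[(off):(off + 4L * n - 1L)], "integer", n = n, size = 4,
          endian = "little")
}

#' Read a multi-page fiber TIFF
#'
#' Reads the subset of baseline TIFF written by [write_fiber_images()]
#' (16-bit, 3 samples/pixel, chunky, uncompressed, little-endian). Per-page
#' scale metadata is taken from the ImageDescription JSON, falling back to the
#' sidecar manifest; pages with no recoverable `kb_per_px` are an error.
#'
#' @param path TIFF path.
#' @param manifest sidecar manifest path (default `<path>.manifest.tsv`).
#' @return list of `fiber_image` strips.
#' @export
read_fiber_images <- function(path, manifest = paste0(path, ".manifest.tsv")) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || read_u16(raw, 3L) != 42L)
    stop_data("'%s' is not a little-endian TIFF file", path)
  man <- if (file.exists(manifest)) read_tsv(manifest) else NULL

  ifd_off <- read_u32(raw, 5L)
  images <- list()
  page <- 0L
  while (ifd_off != 0L) {
    n <- read_u16(raw, ifd_off + 1L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- read_u16(raw, e + 1L)
      type <- read_u16(raw, e + 3L)
      count <- read_u32(raw, e + 5L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        voff = e + 9L)
    }
    val <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      sz <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(t$type)]
      off <- if (sz * t$count > 4L) read_u32(raw, t$voff) + 1L else t$voff
      if (t$type == 2L) {
        s <- raw[off:(off + t$count - 1L)]
        return(rawToChar(s[s != as.raw(0)]))
      }
      if (t$type == 3L) read_u16(raw, off, t$count) else read_u32(raw, off, t$count)
    }
    W <- val(256); H <- val(257)
    if (is.null(W) || is.null(H)) stop_data("TIFF page missing dimensions")
    if (!identical(val(259, 1L), 1L))
      stop_data("unsupported TIFF compression")
    bits <- val(258, 16L)
    if (any(bits != 16L)) stop_data("only 16-bit TIFF is supported")
    spp <- val(277, 1L)
    if (spp != 3L) stop_data("expected 3 samples per pixel")
    offs <- val(273); cnts <- val(279)
    pix_raw <- do.call(c, lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1L):(offs[k] + cnts[k])]))
    if (length(pix_raw) != H * W * 3L * 2L) stop_data("truncated TIFF strip data")
    v <- readBin(pix_raw, "integer", n = H * W * 3L, size = 2,
                 signed = FALSE, endian = "little")
    a <- aperm(array(v, dim = c(3L, W, H)), c(3, 2, 1))

    meta <- tryCatch(jsonlite::fromJSON(val(270, "{}")),
                     error = function(e) list())
    fiber_id <- meta$fiber_id
    kbpp <- meta$kb_per_px
    if ((is.null(fiber_id) || is.null(kbpp)) && !is.null(man)) {
      row <- man[man$page == page, , drop = FALSE]
      if (nrow(row) == 1L) {
        fiber_id <- fiber_id %||% row$fiber_id
        kbpp <- kbpp %||% row$kb_per_px
      }
    }
    if (is.null(kbpp))
      stop_data(paste0("page %d of '%s' has no kb_per_px metadata; supply the ",
                       "scale via the manifest or DetectConfig kb_per_px"),
                page, path)
    dimnames(a) <- list(NULL, NULL, c("DNA", "IdU", "CldU"))
    storage.mode(a) <- "integer"
    images[[length(images) + 1L]] <-
      structure(a, fiber_id = fiber_id %||% sprintf("page%d", page),
                kb_per_px = kbpp, class = "fiber_image")
    ifd_off <- read_u32(raw, ifd_off + 2L + n * 12L + 1L)
    page <- page + 1L
  }
  images
}
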