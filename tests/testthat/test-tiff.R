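render_set <- function(n = 5, seed = 3) {
  cfg <- simulation_config(n, dist_fixed(150), 1 / 150, c(-15, -5),
                           origin_edge_margin_kb = 50, seed = seed)
  render_fibers(truth_segments(sample_fibers(cfg)), render_config(seed = 8))
}

test_that("multi-page TIFF round-trips pixels and metadata", {
  imgs <- render_set()
  path <- withr::local_tempfile(fileext = ".tif")
  write_fiber_images(imgs, path)
  back <- read_fiber_images(path)
  expect_length(back, length(imgs))
  for (i in seq_along(imgs)) {
    expect_identical(as.integer(back[[i]]), as.integer(imgs[[i]]))
    expect_identical(dim(back[[i]]), dim(imgs[[i]]))
    expect_equal(attr(back[[i]], "fiber_id"), attr(imgs[[i]], "fiber_id"))
    expect_equal(attr(back[[i]], "kb_per_px"), attr(imgs[[i]], "kb_per_px"))
  }
})

test_that("written TIFF is readable by an independent reader", {
  imgs <- render_set(n = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fiber_images(imgs, path)
  script <- paste(
    "import tifffile, json, sys",
    "tf = tifffile.TiffFile(sys.argv[1])",
    "assert len(tf.pages) == 2",
    "a = tf.pages[0].asarray()",
    "meta = json.loads(tf.pages[0].description)",
    "print(a.shape[0], a.shape[1], a.shape[2], str(a.dtype),",
    "      int(a.sum()), meta['fiber_id'], meta['kb_per_px'])",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  parts <- strsplit(out, " +")[[1]]
  expect_equal(as.integer(parts[1:3]), dim(imgs[[1]]))
  expect_equal(parts[4], "uint16")
  expect_equal(as.numeric(parts[5]), sum(as.numeric(imgs[[1]])))
  expect_equal(parts[6], attr(imgs[[1]], "fiber_id"))
  expect_equal(as.numeric(parts[7]), attr(imgs[[1]], "kb_per_px"))
})

test_that("scale metadata is required on read", {
  imgs <- render_set(n = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fiber_images(imgs, path)
  # corrupt the JSON key in-place and drop the manifest fallback
  raw <- readBin(path, "raw", file.info(path)$size)
  key <- charToRaw("kb_per_px")
  hit <- which(vapply(seq_len(length(raw) - length(key) + 1L), function(i)
    all(raw[i:(i + length(key) - 1L)] == key), logical(1)))[1]
  raw[hit:(hit + length(key) - 1L)] <- charToRaw("xx_xxx_xx")
  writeBin(raw, path)
  unlink(paste0(path, ".manifest.tsv"))
  expect_error(read_fiber_images(path), "kb_per_px",
               class = "combfork_data_error")
})

test_that("degenerate TIFF inputs are rejected", {
  expect_error(write_fiber_images(list(), withr::local_tempfile()),
               class = "combfork_data_error")
  path <- withr::local_tempfile(fileext = ".tif")
  imgs <- render_set(n = 1)
  write_fiber_images(imgs, path)
  raw <- readBin(path, "raw", 2000)  # truncate mid-strip
  writeBin(raw, path)
  expect_error(read_fiber_images(path), "truncated",
               class = "combfork_data_error")
})
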