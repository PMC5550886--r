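noiseless <- render_config(psf_sigma_px = 0, snr = Inf, background_level = 0)

test_that("noiseless detection inverts the renderer within one pixel", {
  truth <- with_dna(seg_tab("F1", "IdU", 60, 90, "F1", "CldU", 30, 60), 400)
  img <- render_fiber(truth[truth$channel != "DNA", ], 400, noiseless,
                      fiber_id = "F1")
  det <- detect_segments(img, detect_config(min_segment_kb = 0, max_gap_kb = 0))
  rep <- match_to_truth(det, truth, tol_kb = 0.2)
  expect_equal(rep$n_matched, 3)  # DNA + IdU + CldU
  expect_equal(rep$n_detected, 3)
  expect_lte(rep$boundary_mae_kb, 0.2)
})

test_that("gap merging and minimum-length filtering follow the rules", {
  # two IdU runs separated by 0.4 kb: merged under max_gap_kb = 0.5
  tab <- seg_tab("F1", "IdU", 10, 12, "F1", "IdU", 12.4, 14)
  img <- render_fiber(tab, 50, noiseless, fiber_id = "F1")
  det <- detect_segments(img, detect_config(max_gap_kb = 0.5,
                                            min_segment_kb = 0))
  idu <- det[det$channel == "IdU", ]
  expect_equal(nrow(idu), 1)
  expect_equal(idu$start_kb, 10, tolerance = 0.21)
  expect_equal(idu$end_kb, 14, tolerance = 0.21)
  # same input without merging keeps two runs
  det2 <- detect_segments(img, detect_config(max_gap_kb = 0,
                                             min_segment_kb = 0))
  expect_equal(nrow(det2[det2$channel == "IdU", ]), 2)
  # a 0.8 kb run is dropped under min_segment_kb = 1
  img3 <- render_fiber(seg_tab("F1", "IdU", 10, 10.8), 50, noiseless,
                       fiber_id = "F1")
  det3 <- detect_segments(img3, detect_config(min_segment_kb = 1))
  expect_equal(nrow(det3[det3$channel == "IdU", ]), 0)
})

test_that("empty and pathological channels are handled", {
  img <- render_fiber(seg_tab("F1", "IdU", 1, 2)[0, ], 100,
                      render_config(psf_sigma_px = 0, snr = 20), "F1")
  det <- detect_segments(img, detect_config())
  expect_equal(sort(unique(det$channel)), "DNA")  # noise alone yields no label
  bad <- img
  bad[1, 1, 1] <- NA_integer_
  expect_error(detect_segments(bad, detect_config()), "non-finite",
               class = "combfork_data_error")
})

test_that("matching is greedy, one-to-one and tolerance-bounded", {
  truth <- seg_tab("F1", "IdU", 10, 20, "F1", "IdU", 30, 40)
  expect_equal(match_to_truth(truth, truth, 0.5)$n_matched, 2)
  expect_equal(match_to_truth(truth, truth, 0.5)$boundary_mae_kb, 0)
  expect_equal(match_to_truth(truth[0, ], truth, 0.5)$n_matched, 0)
  shifted <- truth
  shifted$start_kb[1] <- shifted$start_kb[1] + 1.0  # 2 x tol
  rep <- match_to_truth(shifted, truth, 0.5)
  expect_equal(rep$n_matched, 1)
  other <- truth
  other$fiber_id <- "F2"
  expect_error(match_to_truth(other, truth, 0.5), "F2",
               class = "combfork_data_error")
})

test_that("blurred noisy rendering still recovers nearly all tracks", {
  cfg <- simulation_config(30, dist_fixed(300), 1 / 300, c(-20, -2),
                           origin_edge_margin_kb = 0, seed = 21)
  truth <- truth_segments(sample_fibers(cfg))
  imgs <- render_fibers(truth, render_config(psf_sigma_px = 2, snr = 20,
                                             seed = 22))
  det <- detect_all(imgs, detect_config(min_segment_kb = 1, max_gap_kb = 0.5))
  big <- truth[truth$end_kb - truth$start_kb >= 3, ]
  rep <- match_to_truth(det, big, tol_kb = 0.6)  # 3 px equivalent
  expect_gte(rep$n_matched / rep$n_truth, 0.95)
})
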