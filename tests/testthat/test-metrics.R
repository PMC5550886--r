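test_that("fork speed implements the flanked and run-off rules", {
  expect_equal(fork_speed(15, 15, TRUE, proto), 0.5)
  expect_equal(fork_speed(12, 20, FALSE, proto), 0.4)  # censored second label
  expect_error(fork_speed(0, 10, TRUE, proto), class = "combfork_data_error")
  expect_error(fork_speed(-3), class = "combfork_data_error")
})

test_that("fork calling covers the canonical track patterns", {
  # single leftward fork: CldU then IdU
  tab <- with_dna(seg_tab("F1", "IdU", 60, 90, "F1", "CldU", 30, 60), 400)
  f <- call_forks(tab, proto)
  expect_equal(nrow(f), 1)
  expect_equal(f$direction, "leftward")
  expect_equal(f$idu_len_kb, 30)
  expect_equal(f$cldu_len_kb, 30)
  expect_true(f$cldu_flanked)
  expect_equal(f$speed_kb_min, 1)

  # contiguous-origin pattern: IdU block flanked by CldU on both sides
  tab <- with_dna(seg_tab("F1", "CldU", 30, 60, "F1", "IdU", 60, 120,
                          "F1", "CldU", 120, 150), 400)
  f <- call_forks(tab, proto)
  expect_equal(nrow(f), 2)
  expect_equal(sort(f$direction), c("leftward", "rightward"))
  expect_equal(f$idu_len_kb, c(30, 30))  # midpoint split at 90
  expect_equal(f$cldu_len_kb, c(30, 30))

  # second label alone never spawns a fork
  tab <- with_dna(seg_tab("F1", "CldU", 200, 230), 400)
  expect_equal(nrow(call_forks(tab, proto)), 0)

  # IdU with no adjacent CldU: directionless, excluded from speed
  tab <- with_dna(seg_tab("F1", "IdU", 100, 130), 400)
  f <- call_forks(tab, proto)
  expect_true(is.na(f$direction) && is.na(f$speed_kb_min))

  # run-off: CldU reaching the fiber end is unflanked
  tab <- with_dna(seg_tab("F1", "IdU", 340, 370, "F1", "CldU", 370, 400), 400)
  f <- call_forks(tab, proto)
  expect_false(f$cldu_flanked)
  expect_equal(f$speed_kb_min, 1)  # 30 kb IdU / 30 min
})

test_that("unit grouping applies the pairing and censoring rules", {
  # two diverging forks across an 18 kb unlabeled origin gap
  tab <- with_dna(seg_tab("F1", "CldU", 11, 41, "F1", "IdU", 41, 71,
                          "F1", "IdU", 89, 119, "F1", "CldU", 119, 149), 400)
  m <- measure_segments(tab, proto)
  expect_equal(nrow(m$units), 1)
  expect_equal(m$units$n_forks, 2)
  expect_equal(m$units$sym_class, "symmetric")
  expect_equal(unique(m$forks$unit_id), m$units$unit_id)

  # lone rightward fork with internal proximal boundary: unidirectional
  tab <- with_dna(seg_tab("F1", "IdU", 100, 130, "F1", "CldU", 130, 160), 400)
  m <- measure_segments(tab, proto)
  expect_equal(m$units$sym_class, "unidirectional")
  expect_equal(m$units$percent_difference, 100)
  expect_true(is.na(m$units$v_left) && m$units$v_right == 1)

  # lone fork whose proximal boundary touches the fiber end: censored
  tab <- with_dna(seg_tab("F1", "IdU", 0, 30, "F1", "CldU", 30, 60), 400)
  m <- measure_segments(tab, proto)
  expect_equal(m$units$sym_class, "unclassifiable")

  # directionless partner rescued across the origin gap (stalled in pulse 1)
  tab <- with_dna(seg_tab("F1", "CldU", 11, 41, "F1", "IdU", 41, 71,
                          "F1", "IdU", 89, 104), 400)
  m <- measure_segments(tab, proto)
  expect_equal(m$units$n_forks, 2)
  expect_equal(m$forks$direction, c("leftward", "rightward"))
  expect_equal(m$forks$speed_kb_min[2], 0.5)  # 15 kb IdU / 30 min
  expect_equal(m$units$sym_class, "asymmetric")  # d = |1 - 0.5| / 1 = 50%
})

test_that("symmetry classes honor the 30 / 100 percent boundaries", {
  expect_equal(classify_symmetry(1.0, 0.8)$sym_class, "symmetric")   # d = 20
  expect_equal(classify_symmetry(1.0, 0.5)$sym_class, "asymmetric")  # d = 50
  expect_equal(classify_symmetry(NA, 1.2)$sym_class, "unidirectional")
  expect_equal(classify_symmetry(NA, 1.2)$percent_difference, 100)
  # "less than 30%" is strict: exactly 30 is asymmetric
  expect_equal(classify_symmetry(1.0, 0.70)$sym_class, "asymmetric")
  expect_equal(classify_symmetry(1.0, 0.7001)$sym_class, "symmetric")
  # both forks present stay asymmetric arbitrarily close to 100
  expect_equal(classify_symmetry(1.0, 0.005)$sym_class, "asymmetric")
  expect_error(classify_symmetry(NA_real_, NA_real_),
               class = "combfork_data_error")
})

test_that("pipeline classes agree with the truth-level classifier", {
  cfg <- uncensored_config(300, seed = 31, firing_window = c(-25, -5),
                           p_dead = 0.15, stall_rate = 0.004)
  fibers <- sample_fibers(cfg)
  m <- measure_segments(truth_segments(fibers, proto), proto)
  got <- table(m$units$sym_class)
  want <- table(unlist(lapply(all_units(fibers), truth_class_oracle)))
  expect_equal(as.list(got), as.list(want))
  # speeds of unstalled pre-pulse forks are recovered exactly
  ok <- m$units$n_forks == 2 & m$units$sym_class != "unclassifiable"
  expect_gt(sum(ok), 50)
})

test_that("unidirectional fraction is monotone in the dead-fork probability", {
  fr <- vapply(c(0, 0.25, 0.5), function(q) {
    cfg <- uncensored_config(400, seed = 77, p_dead = q)
    m <- measure_segments(truth_segments(sample_fibers(cfg), proto), proto)
    cls <- m$units$sym_class[m$units$sym_class != "unclassifiable"]
    mean(cls == "unidirectional")
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # classes partition the classifiable units
  cfg <- uncensored_config(100, seed = 78, p_dead = 0.2, stall_rate = 0.004)
  m <- measure_segments(truth_segments(sample_fibers(cfg), proto), proto)
  n_cls <- sum(m$units$sym_class %in%
                 c("symmetric", "asymmetric", "unidirectional"))
  expect_equal(n_cls + sum(m$units$sym_class == "unclassifiable"),
               nrow(m$units))
})

test_that("fork and unit tables round-trip through their TSV readers", {
  cfg <- uncensored_config(30, seed = 41, p_dead = 0.2)
  m <- measure_segments(truth_segments(sample_fibers(cfg), proto), proto)
  fp <- withr::local_tempfile(fileext = ".tsv")
  up <- withr::local_tempfile(fileext = ".tsv")
  write_forks(m$forks, fp)
  write_units(m$units, up)
  forks <- read_forks(fp)
  units <- read_units(up)
  expect_equal(forks$speed_kb_min, m$forks$speed_kb_min)
  expect_equal(units$sym_class, m$units$sym_class)
  expect_equal(forks$unit_id, m$forks$unit_id)
})
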