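test_that("labeling geometry reproduces hand-derived coordinates", {
  # pre-pulse firing, both forks at 1 kb/min: split-origin pattern
  u <- replication_unit(100, -10, 1, 1)
  s <- apply_labeling(u, 400, proto)
  expect_equal(
    as.data.frame(s)[c("channel", "start_kb", "end_kb")],
    data.frame(channel = c("CldU", "CldU", "IdU", "IdU"),
               start_kb = c(30, 140, 60, 110), end_kb = c(60, 170, 90, 140)),
    ignore_attr = TRUE)

  # right fork dead before labeling: left-side tracks only
  u <- replication_unit(100, -10, 1, 1, right_stall = -Inf)
  s <- apply_labeling(u, 400, proto)
  expect_equal(as.data.frame(s)[c("channel", "start_kb", "end_kb")],
               data.frame(channel = c("CldU", "IdU"),
                          start_kb = c(30, 60), end_kb = c(60, 90)),
               ignore_attr = TRUE)

  # firing at t = 0 with the right fork stalling mid-pulse-2
  u <- replication_unit(100, 0, 1, 1, right_stall = 45)
  s <- apply_labeling(u, 400, proto)
  expect_equal(as.data.frame(s)[c("channel", "start_kb", "end_kb")],
               data.frame(channel = c("CldU", "CldU", "IdU", "IdU"),
                          start_kb = c(40, 130, 70, 100),
                          end_kb = c(70, 145, 100, 130)),
               ignore_attr = TRUE)
})

test_that("degenerate simulation configs give vacuous output", {
  cfg <- simulation_config(0, dist_fixed(300), 0.01, seed = 1)
  expect_length(sample_fibers(cfg), 0)
  cfg <- simulation_config(5, dist_fixed(300), 0, seed = 1)
  fib <- sample_fibers(cfg)
  expect_length(fib, 5)
  expect_true(all(vapply(fib, function(f) length(f$units), 0L) == 0L))
})

test_that("origin counts follow the Poisson intensity", {
  # mean rate * length = 0.005 * 400 = 2 origins per fiber; a small explicit
  # separation keeps the placement feasible so rejection does not thin counts
  cfg <- simulation_config(2000, dist_fixed(400), 0.005,
                           speed_kb_min = dist_normal(0.5, 0.04),
                           min_origin_sep_kb = 10, seed = 71)
  fib <- sample_fibers(cfg)
  n_org <- vapply(fib, function(f) length(f$units), 0L)
  se <- sqrt(2 / 2000)
  expect_lt(abs(mean(n_org) - 2), 3 * se)
})

test_that("labeled segments conserve the interval swept by active forks", {
  set.seed(11)
  for (i in 1:50) {
    stalls <- sample(c(Inf, -Inf, runif(1, 0, 60)), 2, replace = TRUE)
    # origins far from both ends: the swept interval (at most 225 kb per arm)
    # never reaches a fiber boundary, so no clipping obscures conservation
    u <- replication_unit(runif(1, 300, 700), runif(1, -30, 25),
                          runif(1, 0.5, 2.5), runif(1, 0.5, 2.5),
                          stalls[1], stalls[2])
    s <- apply_labeling(u, 1000, proto)
    for (side in c("left", "right")) {
      ll <- fork_label_lengths(u[[paste0(side, "_fork")]], u$t_fire_min, proto)
      ss <- if (side == "right")
        s[s$start_kb >= u$origin_pos_kb - 1e-9, , drop = FALSE]
      else s[s$end_kb <= u$origin_pos_kb + 1e-9, , drop = FALSE]
      # labeled length equals distance run inside the two pulses
      expect_equal(sum(ss$end_kb - ss$start_kb), ll[["idu"]] + ll[["cldu"]],
                   tolerance = 1e-10)
      if (nrow(ss)) {
        # track starts where pre-labeling replication ended, no internal gaps
        prox <- if (side == "right") min(ss$start_kb) else max(ss$end_kb)
        expect_equal(abs(prox - u$origin_pos_kb), ll[["pre"]], tolerance = 1e-10)
        expect_equal(max(ss$end_kb) - min(ss$start_kb),
                     sum(ss$end_kb - ss$start_kb), tolerance = 1e-10)
      }
    }
  }
})

test_that("equal speeds without stalling give mirror-image tracks", {
  set.seed(12)
  for (i in 1:20) {
    v <- runif(1, 0.5, 2.5)
    u <- replication_unit(500, runif(1, -30, 25), v, v)
    s <- apply_labeling(u, 1000, proto)
    for (ch in c("IdU", "CldU")) {
      g <- s[s$channel == ch, , drop = FALSE]
      left <- g[g$end_kb <= 500 + 1e-9, ]
      right <- g[g$start_kb >= 500 - 1e-9, ]
      expect_equal(sum(left$end_kb - left$start_kb),
                   sum(right$end_kb - right$start_kb), tolerance = 1e-10)
    }
  }
})

test_that("dead-fork fraction follows 2q/(1+q) among labeled units", {
  q <- 0.3
  cfg <- uncensored_config(1500, seed = 5, p_dead = q)
  units <- all_units(sample_fibers(cfg))
  dead <- vapply(units, function(u)
    c(is.infinite(u$left_fork$stall_time_min) && u$left_fork$stall_time_min < 0,
      is.infinite(u$right_fork$stall_time_min) && u$right_fork$stall_time_min < 0),
    logical(2))
  n_dead <- colSums(dead)
  labeled <- sum(n_dead < 2)
  frac_one <- sum(n_dead == 1) / labeled
  expected <- 2 * q / (1 + q)
  se <- sqrt(expected * (1 - expected) / labeled)
  expect_lt(abs(frac_one - expected), 3 * se)
})

test_that("ground-truth tables round-trip losslessly", {
  cfg <- simulation_config(10, dist_fixed(300), 1 / 200, c(-20, 10),
                           p_dead = 0.3, stall_rate_per_min = 0.01, seed = 9)
  fib <- sample_fibers(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_truth(fib, path)
  back <- read_truth(path)
  expect_length(back, length(fib))
  for (i in seq_along(fib)) {
    expect_equal(back[[i]]$fiber_id, fib[[i]]$fiber_id)
    expect_equal(back[[i]]$length_kb, fib[[i]]$length_kb)
    expect_equal(back[[i]]$units, fib[[i]]$units, ignore_attr = TRUE)
  }
  # empty set still writes a parseable header-only file
  empty <- sample_fibers(simulation_config(0, dist_fixed(100), 0.1, seed = 1))
  export_truth(empty, path)
  expect_length(read_truth(path), 0)
  expect_error(export_truth(fib, file.path(tempdir(), "no_dir", "x.tsv")),
               "no_dir", class = "combfork_data_error")
})
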