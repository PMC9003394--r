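test_that("square-wave frame sequences have the analytic half-cycle structure", {
  # f = 5 at 60 fps: period 12 frames, 6 of each sign
  s <- binary_stimulus_sequence(5, 60, 12)
  expect_identical(s$frames, c(rep(1L, 6), rep(-1L, 6)))

  # f = 15 at 60 fps: 2 frames per half-cycle
  s <- binary_stimulus_sequence(15, 60, 4)
  expect_identical(s$frames, c(1L, 1L, -1L, -1L))

  # f = 6 at 60 fps over 600 frames: exactly 60 full cycles, zero mean,
  # sign-change count matches brute-force evaluation of the square wave
  s <- binary_stimulus_sequence(6, 60, 600)
  expect_equal(mean(s$frames), 0)
  expect_equal(sum(diff(s$frames) != 0), 2 * 60 - 1)
  # analytic reference: period 10 frames, 5 per half-cycle, 60 full cycles
  ref <- rep(c(rep(1L, 5), rep(-1L, 5)), 60)
  expect_identical(s$frames, ref)
})

test_that("frame sequences only hold +1/-1 and are periodic when f divides Rr", {
  for (f in c(3, 5, 6, 10, 15)) {
    s <- binary_stimulus_sequence(f, 60, 240)
    expect_true(all(s$frames %in% c(-1L, 1L)))
    lag <- 60 / f  # one period in frames
    expect_identical(s$frames[seq_len(240 - lag)],
                     s$frames[(lag + 1):240])
  }
})

test_that("unrenderable or invalid sequences are rejected", {
  expect_error(binary_stimulus_sequence(31, 60, 10), "refresh_rate/2")
  expect_error(binary_stimulus_sequence(-5, 60, 10), "positive")
  expect_error(binary_stimulus_sequence(5, 60, 0), "n_frames")
})

test_that("frequency ceiling is refresh rate over minimum half-cycle frames", {
  expect_equal(max_target_frequency(60, 3), 20)
  expect_equal(max_target_frequency(60, 6), 10)
  expect_equal(max_target_frequency(120, 4), 30)
  expect_error(max_target_frequency(60, 0), "positive integer")
})

test_that("midpoints bisect neighbouring base frequencies with the minimal margin", {
  mg <- compute_midpoints(c(5, 6, 7, 8, 9))
  expect_equal(mg$midpoints, c(5.5, 6.5, 7.5, 8.5, 9.5))
  expect_equal(mg$margin, 0.5)

  mg <- compute_midpoints(c(10, 12))
  expect_equal(mg$midpoints, c(11, 13))
  expect_equal(mg$margin, 1)

  mg <- compute_midpoints(c(5, 6, 8, 11, 15))
  expect_equal(mg$midpoints, c(5.5, 7, 9.5, 13, 15.5))
  expect_equal(mg$margin, 0.5)

  expect_error(compute_midpoints(c(5, 5, 6)), "strictly increasing")
  expect_error(compute_midpoints(c(7, 6)), "strictly increasing")
  expect_error(compute_midpoints(5), "at least two")
})

test_that("dual-frequency assignment reproduces the canonical five-target plan", {
  plan <- assign_dual_frequencies(c(5, 6, 7, 8, 9))
  got <- sprintf("(%g,%g)", plan$pairs$a, plan$pairs$b)
  expect_setequal(got, c("(5,8.5)", "(7,5.5)", "(8,6.5)", "(9,7.5)", "(6,9.5)"))
  expect_equal(plan$pairs$b[plan$pairs$a == 9], 7.5)

  plan2 <- assign_dual_frequencies(c(10, 11, 12, 13, 14))
  got2 <- sprintf("(%g,%g)", plan2$pairs$a, plan2$pairs$b)
  expect_setequal(got2, c("(10,13.5)", "(12,10.5)", "(13,11.5)",
                          "(14,12.5)", "(11,14.5)"))
})

test_that("fewer than five targets are refused", {
  expect_error(assign_dual_frequencies(c(5, 6, 7, 8)), "N >= 5")
})

test_that("a/b values are permutations of base/midpoint frequencies and all distinct", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    f <- sort(5 + cumsum(runif(n, 0.4, 1.6)))
    plan <- assign_dual_frequencies(f)
    expect_equal(sort(plan$pairs$a), f)
    expect_equal(sort(plan$pairs$b), sort(plan$midpoints))
    expect_equal(anyDuplicated(c(plan$base, plan$midpoints)), 0L)
    expect_true(adjacency_audit(plan)$pass)
  }
})

test_that("the adjacency audit flags a plan with a doubly-adjacent target pair", {
  # Swapping the first two midpoints creates targets (5, 6.5) and (6, 5.5)
  # that share two cross adjacencies: 5~5.5 (g1 neighbours f1) and
  # 6~6.5 (g2 neighbours f2). Brute-force enumeration of the adjacency
  # relation {(f_i, g_i), (f_{i+1}, g_i), (f_N, g_N)} confirms the count.
  f <- c(5, 6, 7, 8, 9)
  mg <- compute_midpoints(f)
  bad <- list(base = f, midpoints = mg$midpoints, margin = mg$margin,
              pairs = data.frame(target = 1:5, a = f,
                                 b = c(6.5, 5.5, 7.5, 8.5, 9.5)))
  audit <- adjacency_audit(bad)
  expect_false(audit$pass)
  cnt12 <- audit$counts[audit$counts$target_i == 1 & audit$counts$target_j == 2,
                        "shared_adjacencies"]
  expect_equal(cnt12, 2)
})
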