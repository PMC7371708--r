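# Trajectory reading, preprocessing and movement metrics

test_that("fixes round-trip losslessly through CSV", {
  b <- simulate_experiment(sim_config(n_animal_years = 2, rng_seed = 13))
  dir <- tempfile(); write_experiment(b, dir)
  fx <- read_fixes(file.path(dir, "fixes.csv"))
  expect_equal(nrow(fx), nrow(b$fixes))
  expect_equal(fx$timestamp, b$fixes$timestamp)
  expect_equal(fx$x, b$fixes$x, tolerance = 1e-9)
  sc <- read_schedule(file.path(dir, "schedule.csv"))
  expect_equal(sc$closure_start, b$schedule$closure_start)
  # second write of what was read is byte-identical (write -> read -> write)
  p2 <- tempfile(fileext = ".csv")
  write_fixes(fx, p2)
  expect_identical(readLines(file.path(dir, "fixes.csv")), readLines(p2))
  unlink(dir, recursive = TRUE); unlink(p2)
})

test_that("malformed fix files are rejected with informative errors", {
  fx <- make_fixes(cbind(0:2, 0))
  p <- tempfile(fileext = ".csv")
  write_fixes(fx, p)
  ok <- read_fixes(p)
  expect_equal(nrow(ok), 3)
  expect_equal(length(unique(ok$animal_year_id)), 1)

  dup <- fx; dup$timestamp[2] <- dup$timestamp[1]
  write_fixes(dup, p)
  expect_error(read_fixes(p), "T1", class = "fs_parse_error")

  bad_sex <- fx; bad_sex$sex <- "X"
  write_fixes(bad_sex, p)
  expect_error(read_fixes(p), "sex", class = "fs_parse_error")

  bad_cols <- fx; bad_cols$x <- NULL
  write.csv(bad_cols, p, row.names = FALSE)
  expect_error(read_fixes(p), "missing columns", class = "fs_parse_error")
  unlink(p)
})

test_that("resettlement is the first re-entry after leaving the capture radius", {
  r <- 61.2
  # distances from capture: 10, 200, 300, 40 -> re-entry at the 4th fix
  fx <- make_fixes(cbind(c(10, 200, 300, 40), 0))
  expect_equal(detect_resettlement(fx, c(0, 0), r), fx$timestamp[4])
  # never leaves the radius -> first fix time
  fx2 <- make_fixes(cbind(c(10, 20, 30), 0))
  expect_equal(detect_resettlement(fx2, c(0, 0), r), fx2$timestamp[1])
  # leaves and never returns -> unusable
  fx3 <- make_fixes(cbind(c(10, 200, 300), 0))
  expect_error(detect_resettlement(fx3, c(0, 0), r), class = "fs_no_resettlement")
})

test_that("phase truncation removes leading excess and is idempotent", {
  # 16-day pre-closure with complete hourly fixes: exactly 48 leading fixes go
  sched <- make_schedule(days = c(16, 14, 14))
  n <- 44 * 24
  fx <- make_fixes(cbind(seq_len(n), 0))
  tr <- truncate_phases(fx, sched)
  expect_equal(sum(tr$phase == "pre"), 336)
  expect_equal(sum(tr$phase == "closure"), 336)
  expect_equal(sum(tr$phase == "post"), 336)
  expect_equal(nrow(fx) - nrow(tr), 48)
  expect_equal(min(tr$timestamp), fx$timestamp[1] + 48 * 3600)

  # exactly 14-day phases are unchanged
  sched14 <- make_schedule(days = c(14, 14, 14))
  fx14 <- make_fixes(cbind(seq_len(42 * 24), 0))
  tr14 <- truncate_phases(fx14, sched14)
  expect_equal(nrow(tr14), nrow(fx14))

  # idempotence
  tr2 <- truncate_phases(tr, sched)
  expect_equal(tr2, tr)

  # a raw phase below target is an explicit failure
  expect_error(truncate_phases(fx, make_schedule(days = c(13, 14, 14))),
               class = "fs_short_phase")
})

test_that("steps and turning angles follow the stated geometry conventions", {
  st <- compute_steps(make_fixes(rbind(c(0, 0), c(3, 4))))
  expect_equal(st$s, 5)
  expect_equal(nrow(st), 1)  # |steps| = |fixes| - 1

  st <- compute_steps(make_fixes(rbind(c(0, 0), c(1, 0), c(2, 0))))
  expect_equal(st$theta[2], 0)

  # left turn is positive (counterclockwise), wrapped to (-pi, pi]
  st <- compute_steps(make_fixes(rbind(c(0, 0), c(1, 0), c(1, 1))))
  expect_equal(st$theta[2], pi / 2)

  # zero-length step: theta missing there, heading carried for the next turn
  st <- compute_steps(make_fixes(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))))
  expect_true(is.na(st$theta[2]))
  expect_equal(st$theta[3], 0)
})

test_that("gaps break turning-angle and lag chains but are never interpolated", {
  fx <- make_fixes(rbind(c(0, 0), c(1, 0), c(2, 0), c(4, 0), c(5, 0)))
  fx <- fx[-3, ]  # one missing hourly slot
  st <- compute_steps(fx)
  expect_equal(st$gap, c(FALSE, TRUE, FALSE))
  expect_true(is.na(st$theta[2]))  # step across the hole has no hourly turn
  st <- lag_features(st, lags = 1)
  expect_true(is.na(st$s_lag1[2]))
})

test_that("movement transforms match their closed forms", {
  st <- data.frame(animal_year_id = "T1", s = c(5, 0.1),
                   theta = c(pi / 2, pi / 4), gap = FALSE, slot = 1:2)
  tr <- transform_movement(st)
  expect_equal(tr$phi[1], 0)                    # |theta|/pi = 0.5, logit = 0
  expect_equal(tr$phi[2], log(1 / 3), tolerance = 1e-12)
  expect_equal(tr$log_s[1], log(5))
  expect_equal(tr$log_s[2], 0)                  # floored at s_min = 1 m

  st$theta <- c(0, pi)
  tr <- transform_movement(st, eps = 1e-6)
  expect_equal(tr$phi[1], qlogis(1e-6))
  expect_equal(tr$phi[2], qlogis(1 - 1e-6))
})

test_that("lagged features equal the series shifted by the lag", {
  set.seed(4)
  fx <- make_fixes(cbind(cumsum(rnorm(60, 0, 30)), cumsum(rnorm(60, 0, 30))))
  st <- lag_features(compute_steps(fx), lags = c(1, 2))
  # positions 1..59; lag-1 of step t is step t-1 once both exist and are
  # complete (theta defined from the 2nd step onward)
  expect_equal(st$s_lag1[4:59], st$s[3:58])
  expect_true(is.na(st$s_lag1[2]))  # source step has no defined turn
})

test_that("a complete 1008-slot series yields 982 modelled steps at lag 24", {
  set.seed(11)
  fx <- make_fixes(cbind(cumsum(rnorm(1008, 0, 40)), cumsum(rnorm(1008, 0, 40))),
                   phase = "pre")
  st <- lag_features(transform_movement(compute_steps(fx)))
  h <- data.frame(animal_year_id = "T1", h_fs = 0.5)
  meta <- data.frame(animal_year_id = "T1", animal_id = "T1", sex = "F")
  tab <- build_movement_table(st, h, meta)
  expect_equal(nrow(tab), 1008 - 1 - 1 - 24)
})

test_that("a series shorter than the longest lag warns and yields no rows", {
  fx <- make_fixes(cbind(1:20, 0), phase = "pre")
  st <- transform_movement(compute_steps(fx))
  expect_warning(st <- lag_features(st), "shorter")
  h <- data.frame(animal_year_id = "T1", h_fs = 0.5)
  meta <- data.frame(animal_year_id = "T1", animal_id = "T1", sex = "F")
  expect_equal(nrow(build_movement_table(st, h, meta)), 0)
})

test_that("step lengths and absolute turns are invariant under rigid motions", {
  set.seed(8)
  xy <- cbind(cumsum(rnorm(50, 0, 30)), cumsum(rnorm(50, 0, 30)))
  a <- 0.83; R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  xy2 <- sweep(xy %*% t(R), 2, c(-1234.5, 987.1), "+")
  s1 <- compute_steps(make_fixes(xy)); s2 <- compute_steps(make_fixes(xy2))
  expect_equal(s1$s, s2$s, tolerance = 1e-9)
  expect_equal(abs(s1$theta), abs(s2$theta), tolerance = 1e-9)
})

test_that("population mean displacement matches the generative mean within error", {
  an <- default_analysis()
  # modal mix of the three gamma means brackets the realised population mean
  expect_gt(an$l, 10)
  expect_lt(an$l, 150)
  st <- an$steps[!an$steps$gap, ]
  expect_equal(an$l, mean(st$s), tolerance = 1e-12)
})
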