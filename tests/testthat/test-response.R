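# Cycle averaging, sinusoid fitting and the population/event angle analyses.

fld20 <- cr_field(0.01, 1, frames_per_cycle = 20)
tgrid <- function(fld, ncyc) (0:(fld$frames_per_cycle * ncyc - 1)) /
  fld$frames_per_cycle * (2 * pi / fld$omega)

test_that("cycle averaging folds series onto one period", {
  ca <- cycle_average(rep(7, 200), fld20)
  expect_equal(ca$mean, rep(7, 20))
  expect_identical(ca$n_cycles, 10L)

  t <- tgrid(fld20, 10)
  y <- sin(fld20$omega * t)
  ca2 <- cycle_average(y, fld20)
  expect_equal(ca2$mean, sin(fld20$omega * ca2$phase_time))

  expect_error(cycle_average(rep(1, 205), fld20), "largest usable prefix is 200")
  expect_error(cycle_average(rep(1, 10), fld20), "shorter than one cycle")
})

test_that("phase-point standard errors shrink as 1/sqrt(cycles)", {
  set.seed(2)
  t1 <- tgrid(fld20, 64); t2 <- tgrid(fld20, 256)
  se1 <- mean(cycle_average(sin(fld20$omega * t1) + rnorm(length(t1)), fld20)$se)
  se2 <- mean(cycle_average(sin(fld20$omega * t2) + rnorm(length(t2)), fld20)$se)
  expect_equal(se1 / se2, 2, tolerance = 0.15)
})

test_that("sinusoid fits are exact on noiseless inputs", {
  t <- tgrid(fld20, 5)
  f1 <- fit_sinusoid(cycle_average(2 * sin(fld20$omega * t), fld20))
  expect_equal(f1$A, 2, tolerance = 1e-12)
  expect_lt(abs(f1$B), 1e-12)

  f2 <- fit_sinusoid(cycle_average(0.5 * cos(fld20$omega * t) + 90, fld20))
  expect_equal(f2$B, 0.5, tolerance = 1e-12)
  expect_lt(abs(f2$A), 1e-12)
  expect_equal(f2$offset, 90, tolerance = 1e-10)

  expect_error(fit_sinusoid(c(1, 2, 3), omega = 1, times = 1:3),
               "at least 4 phase points")
})

test_that("cycle-block intervals match the full fit's point estimate", {
  set.seed(5)
  t <- tgrid(fld20, 40)
  y <- 1.5 * sin(fld20$omega * t) - 0.7 * cos(fld20$omega * t) + 90 +
    rnorm(length(t), sd = 3)
  ca <- cycle_average(y, fld20)
  f_iid <- fit_sinusoid(ca)
  f_cyc <- fit_sinusoid(ca, se_method = "cycles", block = 1)
  expect_equal(f_cyc$A, f_iid$A, tolerance = 1e-10)
  expect_equal(f_cyc$B, f_iid$B, tolerance = 1e-10)
  f_blk <- fit_sinusoid(ca, se_method = "cycles", block = 4)
  expect_equal(f_blk$A, f_iid$A, tolerance = 1e-10)
  expect_error(fit_sinusoid(ca, se_method = "cycles", block = 20),
               "at least 3 cycle blocks")
})

test_that("response spectrum recovers tau from analytic Debye amplitudes", {
  tau <- 50; a <- 1.4
  fg <- c(0.8, 1.6, 3.2, 6.4, 12.8, 25.6)
  w <- ghz_to_radps(fg)
  tab <- data.frame(freq_GHz = fg,
                    absA = a / (1 + (w * tau)^2),
                    absB = a * w * tau / (1 + (w * tau)^2))
  rs <- response_spectrum(tab)
  expect_true(rs$converged)
  expect_equal(rs$tau, tau, tolerance = 1e-6)
  expect_equal(rs$amplitude, a, tolerance = 1e-6)
  expect_equal(rs$peak_freq_GHz, 3.2)

  # |B| identically zero -> zero-amplitude fit
  tab0 <- data.frame(freq_GHz = fg, absA = rep(0, 6), absB = rep(0, 6))
  rs0 <- response_spectrum(tab0)
  expect_equal(rs0$amplitude, 0)

  # fewer than 3 frequencies: fit refused, raw table kept
  expect_warning(rs2 <- response_spectrum(tab[1:2, ]), "fewer than 3")
  expect_identical(nrow(rs2$table), 2L)
  expect_false(rs2$converged)
})

test_that("angle-split counts conserve the population at every phase", {
  set.seed(8)
  nfr <- 20 * 30
  frame <- rep(seq_len(nfr), each = 8)
  angle <- runif(length(frame), 0, 180)
  spl <- split_counts_by_angle(frame, angle, nfr, fld20)
  expect_equal(spl$total_above + spl$total_below,
               rep(8 * spl$n_cycles, fld20$frames_per_cycle))

  # all items at 45 degrees: nothing above a 90-degree threshold
  spl45 <- split_counts_by_angle(frame, rep(45, length(frame)), nfr, fld20)
  expect_equal(spl45$total_above, rep(0, 20))
})

test_that("the proportion test is null for uniform draws and flags oversampling", {
  set.seed(12)
  nfr <- 20 * 50
  pop_frame <- rep(seq_len(nfr), each = 30)
  pop_angle <- runif(length(pop_frame), 0, 180)
  spl_pop <- split_counts_by_angle(pop_frame, pop_angle, nfr, fld20)

  sel <- sample(length(pop_frame), 3000)
  spl_ev <- split_counts_by_angle(pop_frame[sel], pop_angle[sel], nfr, fld20)
  pt <- proportion_vs_population_test(spl_ev, spl_pop)
  expect_false(any(pt$flagged))
  # null by construction: all phases consistent with zero excess at ~3 sigma
  expect_true(all(abs(pt$z) < 3.5, na.rm = TRUE))

  # events oversampled 2:1 from the unaligned (> 90 deg) population
  wts <- ifelse(pop_angle > 90, 2, 1)
  sel2 <- sample(length(pop_frame), 3000, prob = wts)
  spl_ev2 <- split_counts_by_angle(pop_frame[sel2], pop_angle[sel2], nfr, fld20)
  pt2 <- proportion_vs_population_test(spl_ev2, spl_pop)
  expect_gt(mean(pt2$excess), 0.1)
  expect_gt(sum(pt2$lo > 0), 10)

  # empty event stream: every phase flagged
  spl_none <- split_counts_by_angle(integer(0), numeric(0), nfr, fld20)
  pt3 <- proportion_vs_population_test(spl_none, spl_pop)
  expect_true(all(pt3$flagged))
})

test_that("event orientation deltas detect a constructed alignment step", {
  set.seed(4)
  fld <- cr_field(0.01, 10, frames_per_cycle = 1000)
  nfr <- 20000; times <- (0:(nfr - 1)) * 0.1
  N <- 50
  angles <- matrix(90 + rnorm(nfr * N, sd = 2), nfr, N)
  evf <- sample(200:(nfr - 200), 150)
  ev <- data.frame(frame = evf, time = times[evf], type = "addition")
  ev$molecules <- lapply(seq_along(evf), function(k) sample.int(N, 1))
  for (k in seq_along(evf)) {
    f0 <- evf[k]; m <- ev$molecules[[k]]
    ii <- (f0 + 1):(f0 + 5)
    angles[ii, m] <- 90 - 8 * sin(fld$omega * times[ii]) + rnorm(5, sd = 2)
  }
  eoc <- event_orientation_change(ev, angles, times, fld, window = 0.5,
                                  types = "addition")
  expect_gt(eoc$dA, 5)
  expect_false(eoc$ci_A_overlap)

  # identical pre/post statistics: delta ~ 0 and CIs overlap
  flat <- matrix(90 + rnorm(nfr * N, sd = 2), nfr, N)
  eoc0 <- event_orientation_change(ev, flat, times, fld, window = 0.5,
                                   types = "addition")
  expect_lt(abs(eoc0$dA), 1)
  expect_true(eoc0$ci_A_overlap)

  # bond-vector sign flip (theta -> 180 - theta) leaves |.| deltas unchanged
  eoc_flip <- event_orientation_change(ev, 180 - angles, times, fld,
                                       window = 0.5, types = "addition")
  expect_equal(eoc_flip$dA, eoc$dA, tolerance = 1e-10)

  # events too close to the boundary are excluded and counted
  ev_edge <- data.frame(frame = c(2L, nfr - 1L),
                        time = times[c(2L, nfr - 1L)], type = "addition")
  ev_edge$molecules <- list(1L, 2L)
  eoc_edge <- event_orientation_change(ev_edge, angles, times, fld,
                                       window = 0.5, types = "addition")
  expect_identical(eoc_edge$n_excluded, 2L)
})
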