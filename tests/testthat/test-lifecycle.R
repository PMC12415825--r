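# Chain tracking, life-cycle events and lifetime statistics.

test_that("a pair forming and dissociating gives one track with birth and death", {
  M <- matrix(0L, 4, 3)
  M[1:2, 2] <- 1L
  trk <- track_chains(M, times = c(0, 0.1, 0.2))
  expect_identical(nrow(trk$tracks), 1L)
  expect_equal(trk$tracks$lifetime, 0.1)
  expect_identical(trk$tracks$closed_by, "death")
  expect_identical(trk$events$type, c("birth", "death"))
  expect_identical(trk$events$molecules[[1]], 1:2)
  expect_identical(trk$events$molecules[[2]], 1:2)
})

test_that("single-molecule joins and leaves are additions and removals", {
  # frames {A,B}, {A,B,C}, {A,B}
  M <- cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L))
  trk <- track_chains(M)
  expect_identical(nrow(trk$tracks), 1L)
  expect_true(trk$tracks$left_truncated)
  expect_true(trk$tracks$censored)
  expect_identical(trk$events$type, c("addition", "removal"))
  expect_identical(unlist(trk$events$molecules), c(3L, 3L))
})

test_that("a track survives complete member turnover", {
  # {A,B} -> {A,B,C} -> {B,C} -> {B,C,D} -> {C,D}: no initial member remains
  M <- cbind(c(1L, 1L, 0L, 0L),
             c(1L, 1L, 1L, 0L),
             c(0L, 1L, 1L, 0L),
             c(0L, 1L, 1L, 1L),
             c(0L, 0L, 1L, 1L))
  trk <- track_chains(M)
  expect_identical(nrow(trk$tracks), 1L)
  expect_identical(sum(trk$events$type == "addition"), 2L)
  expect_identical(sum(trk$events$type == "removal"), 2L)
})

test_that("coalescence and fission are classified as merge and split", {
  # two pairs merge into one 4-chain, which then splits back into two pairs
  M <- cbind(c(1L, 1L, 2L, 2L),
             c(1L, 1L, 1L, 1L),
             c(1L, 1L, 2L, 2L))
  trk <- track_chains(M)
  expect_identical(sum(trk$events$type == "merge"), 1L)
  expect_identical(sum(trk$events$type == "split"), 1L)
  # the merged victim's track closed by merge, not death
  expect_identical(sort(trk$tracks$closed_by),
                   sort(c("censored", "censored", "merge")))
  # no spurious birth/addition bookkeeping
  expect_identical(sum(trk$events$type %in% c("birth", "death", "addition",
                                              "removal")), 0L)
})

test_that("a multi-molecule chain vanishing in one step is a dissolution", {
  M <- cbind(c(1L, 1L, 1L, 0L), c(0L, 0L, 0L, 0L))
  trk <- track_chains(M)
  expect_identical(trk$tracks$closed_by, "dissolution")
})

test_that("tracker reproduces the KMC scripted log exactly (small run)", {
  run <- generate_chain_kmc(n_molecules = 60, t_total = 8, keep_geometry = FALSE,
                            seed = 4)
  trk <- track_chains(run)
  te <- trk$events[order(trk$events$time), ]
  ke <- run$events[order(run$events$time), ]
  expect_identical(nrow(te), nrow(ke))
  expect_identical(te$type, ke$type)
  expect_equal(te$time, ke$time)
  expect_identical(lapply(te$molecules, as.integer),
                   lapply(ke$molecules, as.integer))
})

test_that("size bookkeeping balances additions and removals per track", {
  run <- generate_chain_kmc(n_molecules = 50, t_total = 6, keep_geometry = FALSE,
                            seed = 9)
  trk <- track_chains(run)
  M <- run$membership
  for (tr in trk$tracks$track[1:min(25, nrow(trk$tracks))]) {
    tm <- track_members(trk, run, tr)
    if (length(tm$frames) < 2) next
    ev <- trk$events[trk$events$track == tr, ]
    for (j in 2:length(tm$frames)) {
      ds <- length(tm$members[[j]]) - length(tm$members[[j - 1]])
      f <- tm$frames[j]
      na <- sum(ev$type == "addition" & ev$frame == f)
      nr <- sum(ev$type == "removal" & ev$frame == f)
      expect_identical(ds, na - nr)
    }
  }
})

test_that("births come from two lone molecules and deaths release two", {
  run <- generate_chain_kmc(n_molecules = 50, t_total = 6, keep_geometry = FALSE,
                            seed = 10)
  trk <- track_chains(run)
  M <- run$membership
  ev <- trk$events
  for (k in which(ev$type == "birth")) {
    mols <- ev$molecules[[k]]
    expect_length(mols, 2)
    expect_true(all(M[mols, ev$frame[k] - 1L] == 0L))
  }
  for (k in which(ev$type == "death")) {
    mols <- ev$molecules[[k]]
    expect_length(mols, 2)
    expect_true(all(M[mols, ev$frame[k]] == 0L))
  }
})

test_that("exponential MLE handles censoring per the closed form", {
  expect_equal(fit_lifetime_distribution(rep(1, 20), n_boot = 50)$mean, 1)

  # half censored at a fixed horizon: mean = total time / uncensored count
  d <- c(rep(0.8, 15), rep(2.5, 15))
  cens <- c(rep(FALSE, 15), rep(TRUE, 15))
  fit <- fit_lifetime_distribution(d, cens, n_boot = 50)
  expect_equal(fit$mean, sum(d) / 15)
  expect_identical(fit$n_censored, 15L)

  expect_error(fit_lifetime_distribution(rep(1, 5), rep(TRUE, 5)), "censored")
  expect_error(fit_lifetime_distribution(rep(1, 5)), "at least 10")
})

test_that("the MLE recovers a frame-discretized exponential mean within its CI", {
  set.seed(21)
  d <- round(rexp(1e4, rate = 1 / 2.2) / 0.1) * 0.1
  d <- d[d > 0]
  fit <- fit_lifetime_distribution(d, n_boot = 400)
  expect_gt(2.2, fit$ci[1])
  expect_lt(2.2, fit$ci[2] + 1e-12)
  expect_lt(abs(fit$mean - 2.2) / 2.2, 0.05)
})

test_that("lone intervals measure maximal runs with end censoring", {
  # one molecule lone during frames 3..7 of 10 at 0.1 ps spacing
  M <- matrix(1L, 2, 10)
  M[1, 3:7] <- 0L
  li <- lone_intervals(M, times = (0:9) * 0.1)
  li1 <- li[li$molecule == 1, ]
  expect_identical(nrow(li1), 1L)
  expect_equal(li1$duration, 0.5)
  expect_false(li1$censored)

  # lone at the trajectory end -> censored
  M2 <- matrix(1L, 1, 10)
  M2[1, 8:10] <- 0L
  li2 <- lone_intervals(M2, times = (0:9) * 0.1)
  expect_true(li2$censored)
  expect_equal(li2$duration, 0.2)
})

test_that("KMC lone episodes match the membership-derived episode set", {
  run <- generate_chain_kmc(n_molecules = 40, t_total = 5, keep_geometry = FALSE,
                            seed = 15)
  li <- lone_intervals(run)
  # every uncensored episode must end exactly at a birth/addition involving it
  ev <- run$events
  joins <- ev[ev$type %in% c("birth", "addition"), ]
  key <- paste(unlist(lapply(seq_len(nrow(joins)), function(k)
    paste(joins$molecules[[k]], signif(joins$time[k], 12)))))
  got <- li[!li$censored, ]
  ends <- got$start_time + got$duration
  expect_true(all(paste(got$molecule, signif(ends, 12)) %in% key))
})

test_that("lifetime-resolved profiles are flat for constant metrics and ramp for ramps", {
  M <- matrix(0L, 3, 12)
  M[1:2, 3:10] <- 1L
  trk <- track_chains(M, times = (0:11) * 0.1)
  const <- matrix(0.5, 12, 3)
  prof <- lifetime_resolved_metric(trk, M, const, bins = 5,
                                   tracks = trk$tracks$track)
  expect_equal(prof$mean, rep(0.5, 5))
  ramp <- matrix(0, 12, 3)
  ramp[3:10, ] <- matrix((0:7) / 7, 8, 3)
  prof2 <- lifetime_resolved_metric(trk, M, ramp, bins = 4,
                                    tracks = trk$tracks$track)
  expect_equal(prof2$mean, prof2$s)
})
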