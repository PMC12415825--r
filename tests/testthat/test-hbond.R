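# Geometric hydrogen-bond detection and chain partitioning.

# two methanol-like molecules with a prescribed O-H...O geometry: the donor
# hydroxyl points at the acceptor oxygen, then the hydroxyl is rotated away
# by `offset_deg` about the donor oxygen
hbond_pair_frame <- function(r_HO = 1.8, r_OO = 2.8, offset_deg = 0) {
  Od <- c(8, 10, 10); Oa <- Od + c(r_OO, 0, 0)
  phi <- offset_deg * pi / 180
  Hd <- Od + 0.95 * c(cos(phi), sin(phi), 0)
  pos <- rbind(Od + c(0, -1.43, 0), Od, Hd,
               Oa + c(0, -1.43, 0), Oa, Oa + 0.95 * c(0, 1, 0))
  list(frame = cr_frame(pos, box = rep(24, 3)),
       topology = cr_topology(rep(c("C", "O", "H"), 2)))
}

test_that("a well-formed donor-acceptor pair yields exactly one edge", {
  px <- hbond_pair_frame()       # H...O = 1.85, O-O = 2.8, angle 180
  g <- detect_hbonds(px$frame, px$topology)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$donor, 1L)
  expect_identical(g$edges$acceptor, 2L)
  expect_gt(g$edges$angle, 140)

  # hydroxyl rotated 90 degrees away: alignment violated, no bond
  g90 <- detect_hbonds(hbond_pair_frame(offset_deg = 90)$frame, px$topology)
  expect_identical(nrow(g90$edges), 0L)
})

test_that("criteria cutoffs act individually", {
  px <- hbond_pair_frame(r_OO = 3.8)   # O-O beyond 3.5
  expect_identical(nrow(detect_hbonds(px$frame, px$topology)$edges), 0L)
  px2 <- hbond_pair_frame()
  strict <- hbond_criteria(r_HO_max = 1.5)
  expect_identical(nrow(detect_hbonds(px2$frame, px2$topology, strict)$edges), 0L)
  expect_error(hbond_criteria(angle_min = 200), "angle_min")
  expect_error(hbond_criteria(r_OO_max = -1), "positive")
})

test_that("minimum image validity is enforced against the box", {
  px <- hbond_pair_frame()
  small <- cr_frame(px$frame$positions, box = c(24, 24, 6))
  expect_error(detect_hbonds(small, px$topology), "half the smallest box edge")
})

test_that("cell-list and brute-force detectors agree exactly on random fixtures", {
  for (s in 1:10) {
    rf <- random_fixture(50, seed = s)
    g_cell <- detect_hbonds(rf$frame, rf$topology, method = "cell")
    g_brute <- detect_hbonds(rf$frame, rf$topology, method = "brute")
    expect_identical(g_cell$edges, g_brute$edges)
    expect_gt(nrow(g_cell$edges), 0)   # non-trivial comparison
  }
})

test_that("degree caps hold after best-acceptor resolution", {
  for (s in c(7, 21, 33)) {
    rf <- random_fixture(80, box = c(16, 16, 16), p_aim = 0.9, seed = s)
    g <- detect_hbonds(rf$frame, rf$topology)
    expect_lte(max(tabulate(g$edges$donor, g$n_molecules)), 1)
    expect_lte(max(tabulate(g$edges$acceptor, g$n_molecules)), 2)
  }
})

test_that("find_chains partitions molecules into chains and lone sets", {
  # empty graph on 10 molecules
  g0 <- structure(list(n_molecules = 10L,
                       edges = data.frame(donor = integer(0),
                                          acceptor = integer(0),
                                          r_HO = numeric(0), r_OO = numeric(0),
                                          angle = numeric(0)),
                       criteria = hbond_criteria()),
                  class = "cr_hbond_graph")
  p0 <- find_chains(g0)
  expect_length(p0$chains, 0)
  expect_length(p0$lone, 10)
  expect_partition_ok(p0)

  # path A->B->C plus isolated D
  fx <- generate_fixture(list(list(type = "chain", size = 3), list(type = "lone")))
  p <- find_chains(detect_hbonds(fx$frame, fx$topology))
  expect_length(p$chains, 1)
  expect_identical(p$chains[[1]]$size, 3L)
  expect_identical(p$chains[[1]]$branches, 0L)
  expect_identical(p$lone, fx$expected_lone)
  expect_partition_ok(p)

  # star: center accepting 2 and donating 1 -> one chain of 4, one branch node
  fs <- generate_fixture(list(list(type = "star")))
  ps <- find_chains(detect_hbonds(fs$frame, fs$topology))
  expect_length(ps$chains, 1)
  expect_identical(ps$chains[[1]]$size, 4L)
  expect_identical(ps$chains[[1]]$branches, 1L)
  expect_partition_ok(ps)
})

test_that("partition property holds on random fixtures", {
  for (s in 1:8) {
    rf <- random_fixture(40, seed = 100 + s)
    p <- find_chains(detect_hbonds(rf$frame, rf$topology))
    expect_partition_ok(p)
  }
})

test_that("chain census reports lone fractions and handles degenerate inputs", {
  expect_error(chain_census(list()), "empty")
  fx <- generate_fixture(list(list(type = "lone"), list(type = "lone")))
  p_all_lone <- find_chains(detect_hbonds(fx$frame, fx$topology))
  cen <- chain_census(list(p_all_lone, p_all_lone))
  expect_equal(cen$lone_fraction, c(1, 1))
  expect_equal(cen$n_chains, c(0, 0))

  fx2 <- generate_fixture(list(list(type = "chain", size = 5)))
  p_span <- find_chains(detect_hbonds(fx2$frame, fx2$topology))
  cen2 <- chain_census(list(p_span))
  expect_equal(cen2$lone_fraction, 0)
  expect_equal(cen2$n_chains, 1)
  expect_equal(cen2$max_size, 5)
})

test_that("census from a compact membership series matches the partition route", {
  run <- generate_chain_kmc(n_molecules = 40, t_total = 4, keep_geometry = TRUE,
                            seed = 13)
  cen_series <- chain_census(run)
  f <- 5
  kf <- kmc_frame(run, f)
  p <- find_chains(detect_hbonds(kf$frame, kf$topology))
  expect_equal(cen_series$n_chains[f], length(p$chains))
  expect_equal(cen_series$lone_fraction[f], length(p$lone) / 40)
})
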