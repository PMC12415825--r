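# Trajectory data model, readers and per-frame observables.

test_that("a single-molecule extended-XYZ resolves topology and bonds", {
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(methanol_extxyz(), path)
  traj <- read_trajectory(path)
  expect_length(traj$frames, 1)
  expect_identical(traj$topology$n_molecules, 1L)
  # OH: oxygen atom 5 -> the H after it (atom 6); CO: carbon 1 -> oxygen 5
  expect_equal(unname(traj$topology$oh_bonds[1, ]), c(5L, 6L))
  expect_equal(unname(traj$topology$co_bonds[1, ]), c(1L, 5L))
  expect_equal(traj$frames[[1]]$box, c(20, 20, 20))
})

test_that("malformed and inconsistent frames raise structural errors", {
  lines <- c(methanol_extxyz(), methanol_extxyz()[1:7])  # frame 2 truncated
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(lines, path)
  expect_error(read_trajectory(path), "frame 2")

  # frame 2 with a different atom count parses but fails the consistency check
  frame2 <- c("5",
              'Lattice="20 0 0 0 20 0 0 0 20" Properties=species:S:1:pos:R:3',
              methanol_extxyz()[3:7])
  writeLines(c(methanol_extxyz(), frame2), path)
  expect_error(read_trajectory(path), "frame 2")
})

test_that("triclinic boxes are rejected with a clear error", {
  lines <- methanol_extxyz()
  lines[2] <- 'Lattice="20 1 0 0 20 0 0 0 20" Properties=species:S:1:pos:R:3'
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(lines, path)
  expect_error(read_trajectory(path), "triclinic")
  expect_error(cr_frame(matrix(0, 1, 3), box = c(20, 1, 0, 0, 20, 0, 0, 0, 20)),
               "triclinic")
})

test_that("write/read round-trip preserves positions, box and electrostatics", {
  fld <- cr_field(0.005, 40, frames_per_cycle = 5)
  traj <- generate_rotor_trajectory(n_molecules = 8, tau = 2, field = fld,
                                    n_cycles = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(traj, path)
  back <- read_trajectory(path)
  expect_length(back$frames, length(traj$frames))
  for (f in c(1, 5, 10)) {
    expect_equal(back$frames[[f]]$positions, traj$frames[[f]]$positions,
                 tolerance = 1e-8)
    expect_equal(back$frames[[f]]$box, traj$frames[[f]]$box, tolerance = 1e-8)
    expect_equal(back$frames[[f]]$charges, traj$frames[[f]]$charges)
    expect_equal(back$frames[[f]]$dipoles_static, traj$frames[[f]]$dipoles_static,
                 tolerance = 1e-8)
  }
  expect_identical(back$topology$oh_bonds, traj$topology$oh_bonds)
})

test_that("Tinker ARC frames parse with a periodic box line", {
  lines <- c("3  methanol fragment",
             "18.0 18.0 18.0 90.0 90.0 90.0",
             "1 C 1.000 1.000 1.000 1 2",
             "2 O 2.400 1.000 1.000 2 1 3",
             "3 H 2.800 1.800 1.200 3 2",
             "3  methanol fragment",
             "18.0 18.0 18.0 90.0 90.0 90.0",
             "1 C 1.100 1.000 1.000 1 2",
             "2 O 2.500 1.000 1.000 2 1 3",
             "3 H 2.900 1.800 1.200 3 2")
  path <- withr::local_tempfile(fileext = ".arc")
  writeLines(lines, path)
  traj <- read_trajectory(path)   # format guessed from extension
  expect_length(traj$frames, 2)
  expect_equal(traj$frames[[2]]$positions[1, 1], 1.1)
  expect_equal(traj$frames[[1]]$box, c(18, 18, 18))
  expect_identical(traj$topology$n_molecules, 1L)
})

test_that("box polarization matches hand examples and the brute-force oracle", {
  f1 <- cr_frame(matrix(c(0, 0, 2), 1, 3), box = c(10, 10, 10), charges = 1)
  expect_equal(unname(box_polarization(f1)), c(0, 0, 2))

  f2 <- cr_frame(matrix(c(1, 2, 3), 1, 3), box = c(10, 10, 10), charges = 0,
                 dipoles_static = matrix(c(0, 0, 0.5), 1, 3),
                 dipoles_induced = matrix(c(0, 0, 0.1), 1, 3))
  expect_equal(unname(box_polarization(f2)), c(0, 0, 0.6))

  set.seed(9)
  n <- 1500   # 500 methanol-like molecules' worth of atoms
  f3 <- cr_frame(matrix(runif(3 * n, 0, 30), n, 3), box = rep(30, 3),
                 charges = runif(n, -0.5, 0.5),
                 dipoles_static = matrix(rnorm(3 * n, sd = 0.1), n, 3),
                 dipoles_induced = matrix(rnorm(3 * n, sd = 0.02), n, 3))
  expect_equal(unname(box_polarization(f3)), brute_polarization(f3))
})

test_that("molecule polarization is origin-independent only when neutral", {
  # point dipole on the oxygen of a rigid neutral molecule
  f <- cr_frame(rbind(c(1, 1, 1), c(2, 1, 1)), box = rep(10, 3),
                charges = c(0, 0),
                dipoles_static = rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(unname(molecule_polarization(f, 1:2)), c(0, 0, 1))

  # neutral pair of opposite charges: translation leaves P unchanged
  f1 <- cr_frame(rbind(c(0, 0, 0), c(0, 0, 1)), box = rep(20, 3),
                 charges = c(-0.4, 0.4))
  f2 <- cr_frame(rbind(c(5, 0, 0), c(5, 0, 1)), box = rep(20, 3),
                 charges = c(-0.4, 0.4))
  expect_equal(molecule_polarization(f1, 1:2), molecule_polarization(f2, 1:2))

  # charged fragment: warning raised; centroid convention makes the result
  # translation-invariant even though the lab-frame sum would shift by q*dr
  f3 <- cr_frame(matrix(c(1, 1, 1), 1, 3), box = rep(20, 3), charges = 0.3)
  f4 <- cr_frame(matrix(c(6, 1, 1), 1, 3), box = rep(20, 3), charges = 0.3)
  expect_warning(p3 <- molecule_polarization(f3, 1), "net charge")
  expect_warning(p4 <- molecule_polarization(f4, 1), "net charge")
  expect_equal(p3, p4)
  # the raw lab-frame sums do differ by q*dr, which is the origin dependence
  expect_equal(0.3 * 6 - 0.3 * 1, 0.3 * 5)
})

test_that("bond angles to the axis follow the closed forms", {
  mk <- function(hpos) {
    pos <- rbind(c(5, 5, 3.57), c(5, 5, 5), hpos)   # C, O, H
    cr_frame(pos, box = rep(10, 3))
  }
  top <- cr_topology(c("C", "O", "H"))
  expect_equal(bond_angle_to_axis(mk(c(5, 5, 5.95)), top, "OH"), 0)
  expect_equal(bond_angle_to_axis(mk(c(5, 5, 4.05)), top, "OH"), 180)
  expect_equal(bond_angle_to_axis(mk(c(5 + 0.95 / sqrt(2), 5, 5 + 0.95 / sqrt(2))),
                                  top, "OH"), 45)
  # CO bond: C -> O along +z here
  expect_equal(bond_angle_to_axis(mk(c(5, 5, 5.95)), top, "CO"), 0)

  # rigid translation and rotation about the axis leave the angle unchanged
  base <- mk(c(5 + 0.95 / sqrt(2), 5, 5 + 0.95 / sqrt(2)))
  shifted <- cr_frame(base$positions + matrix(c(1, 2, 0.5), 3, 3, byrow = TRUE),
                      box = rep(10, 3))
  expect_equal(bond_angle_to_axis(shifted, top, "OH"),
               bond_angle_to_axis(base, top, "OH"))
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- cr_frame(base$positions %*% t(R), box = rep(10, 3))
  expect_equal(bond_angle_to_axis(rotated, top, "OH"),
               bond_angle_to_axis(base, top, "OH"))
})

test_that("bond vectors use the minimum image across the boundary", {
  # O at the +x face, H wrapped to the -x side: bond points +x, not -x
  pos <- rbind(c(9.0, 5, 5), c(9.8, 5, 5), c(0.15, 5, 5))
  f <- cr_frame(pos, box = rep(10, 3))
  top <- cr_topology(c("C", "O", "H"))
  expect_equal(bond_angle_to_axis(f, top, "OH", axis = c(1, 0, 0)), 0)
})

test_that("box polarization equals the sum over molecule polarizations", {
  fld <- cr_field(0, 40, frames_per_cycle = 5)
  traj <- generate_rotor_trajectory(n_molecules = 12, tau = 2, field = fld,
                                    n_cycles = 1, seed = 5)
  fr <- traj$frames[[3]]
  total <- box_polarization(fr)
  permol <- Reduce(`+`, lapply(traj$topology$molecules,
                               function(m) molecule_polarization(fr, m)))
  expect_equal(total, permol)
})
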