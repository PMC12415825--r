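# Independent oracles used across test files.

# brute-force per-atom polarization sum (plain loop, no vectorization)
brute_polarization <- function(frame) {
  p <- c(0, 0, 0)
  n <- nrow(frame$positions)
  for (i in seq_len(n)) {
    q <- if (is.null(frame$charges)) 0 else frame$charges[i]
    for (a in 1:3) {
      p[a] <- p[a] + q * frame$positions[i, a]
      if (!is.null(frame$dipoles_static)) p[a] <- p[a] + frame$dipoles_static[i, a]
      if (!is.null(frame$dipoles_induced)) p[a] <- p[a] + frame$dipoles_induced[i, a]
    }
  }
  p
}

# discrete Ornstein-Uhlenbeck series with exact autocorrelation exp(-t/tau)
ou_series <- function(n, tau, dt, sd = 1, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau)
  as.numeric(stats::filter(stats::rnorm(n, sd = sd * sqrt(1 - a^2)), a,
                           method = "recursive"))
}

# single-molecule extended-XYZ text (6-atom methanol layout)
methanol_extxyz <- function() {
  c("6",
    'Lattice="20 0 0 0 20 0 0 0 20" Properties=species:S:1:pos:R:3 Time=0',
    "C 1.000 1.000 1.000",
    "H 0.500 1.800 1.000",
    "H 0.500 0.200 1.000",
    "H 1.500 1.000 1.900",
    "O 2.400 1.000 1.000",
    "H 2.800 1.800 1.200")
}

expect_partition_ok <- function(p) {
  sizes <- vapply(p$chains, `[[`, integer(1), "size")
  expect_identical(sum(sizes) + length(p$lone), p$n_molecules)
  expect_true(all(sizes >= 2))
  if (length(p$chains))
    expect_setequal(c(unlist(lapply(p$chains, `[[`, "members")), p$lone),
                    seq_len(p$n_molecules))
}
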