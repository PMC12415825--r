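## Rotational Brownian dipole ensemble.
##
## N independent rigid methanol-like dipoles whose orientations u_i (unit
## vectors) evolve by overdamped rotational diffusion on the sphere under the
## torque of an applied field E(t) = E0 sin(wt) z_hat:
##     du = (mu D_r / kB T) (E - (u.E) u) dt + sqrt(2 D_r dt) P_t xi
## (Euler-Maruyama with tangent-plane noise P_t xi and renormalization).
## The equilibrium distribution is Boltzmann in -mu.E; at E0 = 0 orientations
## are isotropic; the linear-response susceptibility is single-Debye with
## time constant tau = 1/(2 D_r). This ensemble stands in for molecular
## dynamics wherever a known ground truth is needed; it makes no attempt to
## reproduce methanol's thermodynamics.

#' Generate a rotational Brownian dipole ensemble trajectory
#'
#' @param n_molecules number of independent dipoles.
#' @param tau target Debye time constant in ps; the rotational diffusion
#'   constant is `D_r = 1/(2 tau)` (rad^2/ps). Supply either `tau` or `D_r`.
#' @param D_r rotational diffusion constant (rad^2/ps); overrides `tau`.
#' @param dipole molecular dipole magnitude (e*Angstrom).
#' @param field a [cr_field()]; use `amplitude = 0` (any nominal frequency)
#'   for a field-free control run. The field axis must be +z.
#' @param n_cycles number of field cycles to record after warm-up.
#' @param warmup_cycles cycles discarded before recording; default covers at
#'   least 5 tau so the oscillating steady state is reached.
#' @param temperature temperature in K.
#' @param dt_max maximum integration substep (ps); `NULL` (default) picks
#'   `min(0.5, 0.05/D_r)` automatically. The actual substep divides the frame
#'   spacing. Stability requires `D_r * dt <= 0.05`, so an explicit `dt_max`
#'   violating that bound is refused.
#' @param density molecular number density (molecules/Angstrom^3) fixing the
#'   cubic box volume; default matches liquid methanol at ambient conditions.
#' @param store `"aggregates"` keeps per-frame ensemble aggregates only
#'   (box dipole and mean hydroxyl angle); `"angles"` additionally keeps the
#'   frames x molecules matrix of OH angles; `"orientations"` also keeps the
#'   z-components of all orientations.
#' @param seed RNG seed; identical seeds give identical output.
#' @return an object of class `cr_rotor_run`: list with `times` (ps), `P`
#'   (frames x 3 box dipole, e*Angstrom), `Pz` (its z-column), `mean_theta`
#'   (ensemble-mean OH
#'   angle, degrees), optional `theta` / `uz` matrices, `field`, and `truth`
#'   (list: `tau`, `D_r`, `chi0`, `volume`, `box`, `n_molecules`, `dipole`,
#'   `temperature`).
#' @export
generate_rotor_ensemble <- function(n_molecules = 500, tau = 50, D_r = NULL,
                                    dipole = 0.35, field,
                                    n_cycles = 100, warmup_cycles = NULL,
                                    temperature = 300, dt_max = NULL,
                                    density = 0.0149,
                                    store = c("aggregates", "angles",
                                              "orientations"),
                                    seed = 1L) {
  store <- match.arg(store)
  if (is.null(D_r)) D_r <- 1 / (2 * tau) else tau <- 1 / (2 * D_r)
  if (D_r <= 0) stop("rotational diffusion constant must be positive")
  if (!all(abs(field$axis - c(0, 0, 1)) < 1e-12))
    stop("rotor ensemble supports a +z field axis only")
  period <- 2 * pi / field$omega
  fpc <- field$frames_per_cycle
  frame_dt <- period / fpc
  if (!is.null(dt_max) && D_r * dt_max > 0.05)
    stop(sprintf("timestep too large for D_r (D_r*dt = %.3g > 0.05): unstable",
                 D_r * dt_max))
  if (is.null(dt_max)) dt_max <- min(0.5, 0.05 / D_r)
  n_sub <- max(1L, ceiling(frame_dt / dt_max))
  dt <- frame_dt / n_sub
  if (is.null(warmup_cycles))
    warmup_cycles <- max(1L, ceiling(5 * tau / period))
  set.seed(seed)

  N <- n_molecules
  kT <- cr_constants$kB * temperature
  volume <- N / density
  box <- rep(volume^(1 / 3), 3)
  # isotropic initial orientations
  u <- matrix(stats::rnorm(3 * N), N, 3)
  u <- u / sqrt(rowSums(u^2))

  gam <- dipole * D_r * dt / kT
  sig <- sqrt(2 * D_r * dt)
  E0 <- field$amplitude; w <- field$omega

  step <- function(u, t) {
    Ez <- E0 * sin(w * t)
    xi <- matrix(stats::rnorm(3 * N), N, 3)
    dot <- xi[, 1] * u[, 1] + xi[, 2] * u[, 2] + xi[, 3] * u[, 3]
    xi <- xi - dot * u
    if (Ez != 0) {
      u <- u + gam * Ez * (cbind(0, 0, 1)[rep(1, N), ] - u[, 3] * u) + sig * xi
    } else {
      u <- u + sig * xi
    }
    u / sqrt(rowSums(u^2))
  }

  # warm-up (whole cycles keep the recorded phase origin at a zero-crossing)
  t <- -warmup_cycles * period
  for (k in seq_len(warmup_cycles * fpc * n_sub)) {
    u <- step(u, t)
    t <- t + dt
  }
  t <- 0  # avoid accumulated round-off at the phase origin

  nf <- n_cycles * fpc
  times <- (seq_len(nf) - 1) * frame_dt
  P <- matrix(0, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
  mean_theta <- numeric(nf)
  theta_mat <- if (store != "aggregates")
    matrix(NA_real_, nf, N) else NULL
  uz_mat <- if (store == "orientations") matrix(NA_real_, nf, N) else NULL
  for (f in seq_len(nf)) {
    P[f, ] <- dipole * colSums(u)
    th <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
    mean_theta[f] <- mean(th)
    if (!is.null(theta_mat)) theta_mat[f, ] <- th
    if (!is.null(uz_mat)) uz_mat[f, ] <- u[, 3]
    for (k in seq_len(n_sub)) {
      u <- step(u, t)
      t <- t + dt
    }
  }
  chi0 <- N * dipole^2 / (3 * cr_constants$eps0 * volume * kT)
  structure(list(times = times, P = P, Pz = P[, 3], mean_theta = mean_theta,
                 theta = theta_mat, uz = uz_mat,
                 field = field,
                 truth = list(tau = tau, D_r = D_r, chi0 = chi0,
                              volume = volume, box = box,
                              n_molecules = N, dipole = dipole,
                              temperature = temperature),
                 final_u = u, seed = seed),
            class = "cr_rotor_run")
}

#' @export
print.cr_rotor_run <- function(x, ...) {
  cat(sprintf("<cr_rotor_run> %d dipoles x %d frames at %.4g GHz (E0 = %g V/A)\n",
              x$truth$n_molecules, length(x$times),
              radps_to_ghz(x$field$omega), x$field$amplitude))
  cat(sprintf("  ground truth: tau = %g ps, chi0 = %.4g\n",
              x$truth$tau, x$truth$chi0))
  invisible(x)
}

#' Materialize a rotor run as a full trajectory
#'
#' Runs the same rotational Brownian dynamics as
#' [generate_rotor_ensemble()] but keeps explicit frames: oxygens on a cubic
#' lattice, the hydroxyl hydrogen at 0.95 Angstrom along the orientation
#' vector, the carbon opposite, and the molecular dipole as a static point
#' dipole on the oxygen. Memory grows with frames x atoms, so this is meant
#' for short runs (round-trip and plumbing tests); long response runs use
#' the aggregate store of [generate_rotor_ensemble()].
#'
#' @param n_molecules,tau,D_r,dipole,field,n_cycles,warmup_cycles,temperature,dt_max,density,seed
#'   as in [generate_rotor_ensemble()].
#' @return a [cr_trajectory()] with static dipoles set, plus the run's
#'   ground truth in `attr(, "truth")`.
#' @export
generate_rotor_trajectory <- function(n_molecules = 20, tau = 5, D_r = NULL,
                                      dipole = 0.35, field, n_cycles = 2,
                                      warmup_cycles = NULL, temperature = 300,
                                      dt_max = NULL, density = 0.0149,
                                      seed = 1L) {
  if (is.null(D_r)) D_r <- 1 / (2 * tau)
  period <- 2 * pi / field$omega
  fpc <- field$frames_per_cycle
  frame_dt <- period / fpc
  if (!is.null(dt_max) && D_r * dt_max > 0.05)
    stop(sprintf("timestep too large for D_r (D_r*dt = %.3g > 0.05): unstable",
                 D_r * dt_max))
  if (is.null(dt_max)) dt_max <- min(0.5, 0.05 / D_r)
  n_sub <- max(1L, ceiling(frame_dt / dt_max))
  dt <- frame_dt / n_sub
  if (is.null(warmup_cycles))
    warmup_cycles <- max(1L, ceiling(5 / (2 * D_r) / period))
  set.seed(seed)
  N <- n_molecules
  kT <- cr_constants$kB * temperature
  volume <- N / density
  L <- volume^(1 / 3)
  ng <- ceiling(N^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(ng), y = seq_len(ng),
                                z = seq_len(ng)))[seq_len(N), ] - 0.5
  O_pos <- grid * (L / ng)
  u <- matrix(stats::rnorm(3 * N), N, 3)
  u <- u / sqrt(rowSums(u^2))
  gam <- dipole * D_r * dt / kT
  sig <- sqrt(2 * D_r * dt)
  E0 <- field$amplitude; w <- field$omega
  step <- function(u, t) {
    Ez <- E0 * sin(w * t)
    xi <- matrix(stats::rnorm(3 * N), N, 3)
    dot <- rowSums(xi * u)
    xi <- xi - dot * u
    u <- u + sig * xi
    if (Ez != 0) u <- u + gam * Ez * (cbind(0, 0, 1)[rep(1, N), ] - u[, 3] * u)
    u / sqrt(rowSums(u^2))
  }
  t <- -warmup_cycles * period
  for (k in seq_len(warmup_cycles * fpc * n_sub)) { u <- step(u, t); t <- t + dt }
  t <- 0
  nf <- n_cycles * fpc
  frames <- vector("list", nf)
  elements <- rep(c("C", "O", "H"), N)
  for (f in seq_len(nf)) {
    pos <- matrix(0, 3 * N, 3)
    idx <- 3 * (seq_len(N) - 1L)
    pos[idx + 1L, ] <- O_pos - 1.43 * u   # C
    pos[idx + 2L, ] <- O_pos              # O
    pos[idx + 3L, ] <- O_pos + 0.95 * u   # H
    dsta <- matrix(0, 3 * N, 3)
    dsta[idx + 2L, ] <- dipole * u
    frames[[f]] <- cr_frame(pos, rep(L, 3), time = (f - 1) * frame_dt,
                            charges = rep(0, 3 * N), dipoles_static = dsta)
    for (k in seq_len(n_sub)) { u <- step(u, t); t <- t + dt }
  }
  traj <- cr_trajectory(frames, topology = cr_topology(elements), field = field)
  attr(traj, "truth") <- list(tau = 1 / (2 * D_r), D_r = D_r, volume = volume,
                              dipole = dipole, temperature = temperature)
  traj
}
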