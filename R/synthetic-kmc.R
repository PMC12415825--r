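## Kinetic Monte Carlo chain dynamics with a scripted event log.
##
## Molecules exchange between a lone pool and linear hydrogen-bonded chains
## via four canonical events: birth (two lone molecules bond), addition
## (a lone molecule joins a chain end), removal (an end molecule detaches),
## and death (the final pair dissociates). The process is a continuous-time
## Markov chain built so that two episode laws hold *exactly*:
##
##  - Lone episodes are Exp(tau_lone): every lone molecule carries a
##    self-exit hazard lam = (1/tau_lone)/(1 + p_birth) and is additionally
##    grabbed as a birth partner (uniformly among the other lone molecules)
##    at rate lam * p_birth, so the total exit hazard is 1/tau_lone
##    regardless of system state.
##  - Chain lifetimes are Exp(tau_chain): every chain carries a constant
##    death hazard 1/tau_chain from birth, at any size. When death fires on
##    a chain of size s > 2 the generator emits s-2 removal events at
##    epsilon-spaced times immediately before the pair death, so every
##    logged event stays canonical.
##
## Chains also shed end molecules at a churn rate while size > 2. Frames are
## event-synchronous by default (one frame per event, stamped at the event
## time), which makes tracker-vs-log comparisons and episode durations
## exact; a uniform-grid sampling mode is also provided. Geometry is
## realized on demand: each chain lies on a straight line with O-O spacing
## 2.8 Angstrom and hydroxyls pointing along the chain; components are
## separated by 6 Angstrom gaps, so the default hydrogen-bond criteria
## recover the KMC bond graph with wide margins.

#' Generate kinetic Monte Carlo chain dynamics
#'
#' @param n_molecules number of molecules.
#' @param tau_chain mean chain lifetime (ps); the death hazard is
#'   `1/tau_chain`.
#' @param tau_lone mean lone-episode duration (ps).
#' @param p_birth probability that a lone molecule's exit starts a new chain
#'   (with a partner grabbed from the lone pool) rather than joining an
#'   existing chain.
#' @param churn_rate per-chain rate (1/ps) of shedding an end molecule while
#'   the chain has more than two members.
#' @param t_total simulated time after warm-up (ps).
#' @param warmup equilibration time (ps) before logging starts; episodes in
#'   progress at the end of warm-up restart their clocks there, which leaves
#'   both exponential episode laws intact (memorylessness).
#' @param sampling `"event"` (one frame per event; exact) or `"uniform"`.
#' @param timestep frame spacing (ps) for `sampling = "uniform"`.
#' @param keep_geometry frame indices for which chain ordering is retained so
#'   [kmc_frame()] can realize coordinates; `TRUE` keeps all, `FALSE` none.
#' @param seed RNG seed.
#' @return an object of class `cr_kmc_run`: list with `times`, `membership`
#'   (N x F integer matrix, 0 = lone), `events` (data.frame: `time`, `type`,
#'   `chain`, plus `molecules` list column), `geometry` (per-kept-frame
#'   ordered chain member lists), `spec` (all rates and the exposed ground
#'   truths `tau_chain`, `tau_lone`), `box`.
#' @export
generate_chain_kmc <- function(n_molecules = 200, tau_chain = 2.2,
                               tau_lone = 0.3, p_birth = 0.2,
                               churn_rate = 2, t_total = 25,
                               warmup = 5, sampling = c("event", "uniform"),
                               timestep = 0.01, keep_geometry = 200L,
                               seed = 1L) {
  sampling <- match.arg(sampling)
  if (tau_chain <= 0 || tau_lone <= 0) stop("lifetimes must be positive")
  if (p_birth <= 0 || p_birth > 1) stop("p_birth must be in (0, 1]")
  set.seed(seed)
  N <- n_molecules
  lam_self <- (1 / tau_lone) / (1 + p_birth)
  delta <- 1 / tau_chain
  eps <- 1e-6

  # mutable state
  state <- integer(N)                  # 0 = lone, else chain id
  chains <- vector("list", 64L)        # chain id -> ordered member vector
  alive <- integer(0)                  # alive chain ids
  next_chain <- 0L

  # logs (post-warmup)
  ev_t <- numeric(0); ev_type <- character(0); ev_chain <- integer(0)
  ev_mols <- list()
  fr_t <- numeric(0); fr_state <- list(); fr_geom <- list()
  logging <- FALSE
  keep_frame <- if (isTRUE(keep_geometry)) function(k) TRUE
    else if (isFALSE(keep_geometry)) function(k) FALSE
    else if (length(keep_geometry) == 1L) function(k) k <= keep_geometry
    else function(k) k %in% keep_geometry

  log_event <- function(t, type, chain, mols) {
    if (!logging) return(invisible())
    k <- length(ev_t) + 1L
    ev_t[k] <<- t; ev_type[k] <<- type; ev_chain[k] <<- chain
    ev_mols[[k]] <<- sort(mols)
  }
  snap_frame <- function(t) {
    if (!logging) return(invisible())
    k <- length(fr_t) + 1L
    fr_t[k] <<- t
    fr_state[[k]] <<- state
    if (keep_frame(k))
      fr_geom[[as.character(k)]] <<- lapply(alive, function(c) chains[[c]])
  }

  do_birth <- function(t, i, j) {
    next_chain <<- next_chain + 1L
    if (next_chain > length(chains)) length(chains) <<- 2L * length(chains)
    chains[[next_chain]] <<- c(i, j)
    alive <<- c(alive, next_chain)
    state[c(i, j)] <<- next_chain
    log_event(t, "birth", next_chain, c(i, j))
    snap_frame(t)
  }
  do_addition <- function(t, i, c) {
    if (stats::runif(1) < 0.5) chains[[c]] <<- c(i, chains[[c]])
    else chains[[c]] <<- c(chains[[c]], i)
    state[i] <<- c
    log_event(t, "addition", c, i)
    snap_frame(t)
  }
  do_removal <- function(t, c) {
    mem <- chains[[c]]
    i <- if (stats::runif(1) < 0.5) mem[1] else mem[length(mem)]
    chains[[c]] <<- setdiff(mem, i)
    state[i] <<- 0L
    log_event(t, "removal", c, i)
    snap_frame(t)
  }
  do_death <- function(t, c) {
    # shed down to the final pair, then die
    while (length(chains[[c]]) > 2L) {
      do_removal(t, c)
      t <- t + eps
    }
    mem <- chains[[c]]
    state[mem] <<- 0L
    alive <<- setdiff(alive, c)
    chains[c] <<- list(NULL)
    log_event(t, "death", c, mem)
    snap_frame(t)
    t
  }

  t <- -warmup
  t_end <- t_total
  while (t < t_end) {
    n_lone <- sum(state == 0L)
    n_ch <- length(alive)
    big <- alive[vapply(alive, function(c) length(chains[[c]]) > 2L, logical(1))]
    r_lone <- n_lone * lam_self
    r_death <- n_ch * delta
    r_churn <- length(big) * churn_rate
    R <- r_lone + r_death + r_churn
    if (R <= 0) stop("total rate vanished (no molecules?)")
    t_next <- t + stats::rexp(1, R)
    if (!logging && t_next >= 0) {
      logging <- TRUE
      snap_frame(0)      # initial frame at the start of the logged window
    }
    if (t_next >= t_end) break
    t <- t_next
    pick <- stats::runif(1) * R
    if (pick < r_lone) {
      lone <- which(state == 0L)
      i <- lone[sample.int(length(lone), 1L)]
      birth <- stats::runif(1) < p_birth
      if ((birth || n_ch == 0L) && length(lone) >= 2L) {
        j <- setdiff(lone, i)[sample.int(length(lone) - 1L, 1L)]
        do_birth(t, i, j)
      } else if (n_ch >= 1L) {
        c <- alive[sample.int(n_ch, 1L)]
        do_addition(t, i, c)
      }
      # (n_ch == 0 and only one lone molecule: exit impossible, re-queued)
    } else if (pick < r_lone + r_death) {
      c <- alive[sample.int(n_ch, 1L)]
      t <- do_death(t, c)
    } else {
      c <- big[sample.int(length(big), 1L)]
      do_removal(t, c)
    }
  }
  snap_frame(t_end)      # closing frame (censors open episodes)

  times <- fr_t
  membership_raw <- do.call(cbind, fr_state)
  # densify chain labels per frame (global KMC ids -> 1..k within frame)
  M <- membership_raw
  for (f in seq_len(ncol(M))) {
    col <- M[, f]; pos <- col > 0L
    if (any(pos)) M[pos, f] <- match(col[pos], sort(unique(col[pos])))
  }

  geometry <- fr_geom

  events <- data.frame(time = ev_t, type = ev_type, chain = ev_chain)
  events$molecules <- ev_mols
  spec <- list(n_molecules = N, tau_chain = tau_chain, tau_lone = tau_lone,
               p_birth = p_birth, churn_rate = churn_rate,
               lam_self = lam_self, death_rate = delta,
               t_total = t_total, warmup = warmup, sampling = sampling,
               seed = seed)
  run <- structure(list(times = times, membership = M,
                        membership_chain_ids = membership_raw,
                        events = events, geometry = geometry,
                        spec = spec,
                        box = c(6 * N + 12, 20, 20)),
                   class = "cr_kmc_run")
  if (sampling == "uniform") run <- kmc_resample_uniform(run, timestep)
  run
}

## resample an event-synchronous run onto a uniform grid (piecewise-constant
## state; events between grid points are then no longer individually visible)
kmc_resample_uniform <- function(run, timestep) {
  tg <- seq(0, run$spec$t_total, by = timestep)
  idx <- findInterval(tg, run$times)
  run$membership <- run$membership[, idx, drop = FALSE]
  run$membership_chain_ids <- run$membership_chain_ids[, idx, drop = FALSE]
  geom <- list()
  for (g in seq_along(tg)) {
    key <- as.character(idx[g])
    if (key %in% names(run$geometry)) geom[[as.character(g)]] <- run$geometry[[key]]
  }
  run$geometry <- geom
  run$times <- tg
  run$spec$timestep <- timestep
  run
}

#' @export
print.cr_kmc_run <- function(x, ...) {
  cat(sprintf("<cr_kmc_run> %d molecules x %d frames (%s sampling), %d events\n",
              nrow(x$membership), ncol(x$membership), x$spec$sampling,
              nrow(x$events)))
  print(table(x$events$type))
  cat(sprintf("  ground truth: tau_chain = %g ps, tau_lone = %g ps\n",
              x$spec$tau_chain, x$spec$tau_lone))
  invisible(x)
}

#' Realize the geometry of one KMC frame
#'
#' Lays the frame's components along the x axis: chain members at 2.8
#' Angstrom O-O spacing with each donor hydroxyl pointing at the next
#' oxygen, terminal and lone hydroxyls pointing along +y, and 6 Angstrom
#' gaps between components. Under the default [hbond_criteria()] the
#' detected graph equals the KMC bond graph exactly.
#'
#' @param run a `cr_kmc_run`.
#' @param frame frame index (must be among the run's kept-geometry frames).
#' @return list with `frame` (a [cr_frame()]) and `topology`.
#' @export
kmc_frame <- function(run, frame) {
  geom <- run$geometry[[as.character(frame)]]
  if (is.null(geom) && !(as.character(frame) %in% names(run$geometry)))
    stop("no geometry kept for frame ", frame,
         "; regenerate with keep_geometry covering it")
  N <- nrow(run$membership)
  in_chain <- sort(unlist(geom))
  lone <- setdiff(seq_len(N), in_chain)
  O <- matrix(0, N, 3); Hdir <- matrix(0, N, 3)
  cursor <- 3
  for (mem in geom) {
    s <- length(mem)
    O[mem, 1] <- cursor + 2.8 * (seq_len(s) - 1)
    O[mem, 2] <- 10; O[mem, 3] <- 10
    if (s > 1) Hdir[mem[-s], 1] <- 1           # donors point at the next O
    Hdir[mem[s], 2] <- 1                       # terminal acceptor points +y
    cursor <- cursor + 2.8 * (s - 1) + 6
  }
  for (i in lone) {
    O[i, ] <- c(cursor, 10, 10)
    Hdir[i, 2] <- 1
    cursor <- cursor + 6
  }
  pos <- matrix(0, 3 * N, 3)
  idx <- 3 * (seq_len(N) - 1L)
  pos[idx + 1L, ] <- O + matrix(c(0, -1.43, 0), N, 3, byrow = TRUE)  # C
  pos[idx + 2L, ] <- O
  pos[idx + 3L, ] <- O + 0.95 * Hdir                                 # H
  list(frame = cr_frame(pos, run$box, time = run$times[frame]),
       topology = cr_topology(rep(c("C", "O", "H"), N)))
}

#' Expected hydrogen-bond edges of a KMC frame
#'
#' @param run a `cr_kmc_run`.
#' @param frame frame index among the kept-geometry frames.
#' @return data.frame `donor`, `acceptor` (molecule ids) implied by the KMC
#'   bond graph.
#' @export
kmc_expected_edges <- function(run, frame) {
  geom <- run$geometry[[as.character(frame)]]
  out <- lapply(geom, function(mem) {
    s <- length(mem)
    if (s < 2) return(NULL)
    data.frame(donor = mem[-s], acceptor = mem[-1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(donor = integer(0), acceptor = integer(0))
  else out[order(out$donor), , drop = FALSE]
}
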