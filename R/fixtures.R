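## Exact geometric hydrogen-bond fixtures.
##
## Builds single frames whose detected hydrogen-bond graph equals a
## prescribed topology exactly under the default criteria, with comfortable
## margins (no knife-edge distances or angles): bonded O-O 2.8 Angstrom and
## O-H...O alignment 180 degrees, non-bonded oxygens >= 3.9 Angstrom apart.

#' Build a frame realizing a prescribed hydrogen-bond topology
#'
#' @param components list of component specs, each a list with `type` one of
#'   `"lone"` (a single unbonded molecule), `"chain"` (a linear chain; field
#'   `size` >= 2) or `"star"` (4 molecules: a center that donates one bond
#'   and accepts two, giving one branch point).
#' @param gap spacing between consecutive components along x (Angstrom); the
#'   default 8 keeps lone molecules far beyond all cutoffs.
#' @return list with `frame`, `topology`, `expected_edges` (data.frame
#'   `donor`, `acceptor` molecule ids), `expected_chains` (list of member
#'   vectors) and `expected_lone` (integer vector).
#' @export
generate_fixture <- function(components, gap = 8) {
  if (gap < 4.5) stop("unrealizable spec: component gap below the non-bond margin")
  O <- NULL; Hdir <- NULL
  edges <- data.frame(donor = integer(0), acceptor = integer(0))
  exp_chains <- list(); exp_lone <- integer(0)
  next_id <- 0L
  cursor <- 4
  place <- function(o, h) {
    O <<- rbind(O, o); Hdir <<- rbind(Hdir, h)
    next_id <<- next_id + 1L
    next_id
  }
  for (comp in components) {
    ty <- if (is.character(comp)) comp else comp$type
    if (ty == "lone") {
      id <- place(c(cursor, 10, 10), c(0, 1, 0))
      exp_lone <- c(exp_lone, id)
      cursor <- cursor + gap
    } else if (ty == "chain") {
      s <- comp$size
      if (is.null(s) || s < 2) stop("unrealizable spec: chain needs size >= 2")
      ids <- integer(s)
      for (k in seq_len(s)) {
        h <- if (k < s) c(1, 0, 0) else c(0, 1, 0)
        ids[k] <- place(c(cursor + 2.8 * (k - 1), 10, 10), h)
      }
      edges <- rbind(edges, data.frame(donor = ids[-s], acceptor = ids[-1]))
      exp_chains[[length(exp_chains) + 1L]] <- ids
      cursor <- cursor + 2.8 * (s - 1) + gap
    } else if (ty == "star") {
      # center at c0 donates +x to m2; m3 (-x side) and m4 (+y side) donate
      # into the center's two acceptor slots
      c0 <- c(cursor + 2.8, 10, 10)
      id_center <- place(c0, c(1, 0, 0))
      id_m2 <- place(c0 + c(2.8, 0, 0), c(0, 1, 0))
      id_m3 <- place(c0 + c(-2.8, 0, 0), c(1, 0, 0))
      id_m4 <- place(c0 + c(0, 2.8, 0), c(0, -1, 0))
      edges <- rbind(edges,
                     data.frame(donor = c(id_center, id_m3, id_m4),
                                acceptor = c(id_m2, id_center, id_center)))
      exp_chains[[length(exp_chains) + 1L]] <- c(id_center, id_m2, id_m3, id_m4)
      cursor <- cursor + 2.8 * 2 + gap
    } else {
      stop("unknown component type: ", ty)
    }
  }
  N <- next_id
  box <- c(max(cursor + 4, 25), 24, 24)
  pos <- matrix(0, 3 * N, 3)
  idx <- 3 * (seq_len(N) - 1L)
  pos[idx + 1L, ] <- O + matrix(c(0, 0, -1.43), N, 3, byrow = TRUE)  # C below
  pos[idx + 2L, ] <- O
  pos[idx + 3L, ] <- O + 0.95 * Hdir
  list(frame = cr_frame(pos, box, time = 0),
       topology = cr_topology(rep(c("C", "O", "H"), N)),
       expected_edges = edges[order(edges$donor), , drop = FALSE],
       expected_chains = exp_chains,
       expected_lone = exp_lone)
}

#' Random non-overlapping molecule placements for detector stress tests
#'
#' Scatters methanol-like molecules with random hydroxyl orientations in a
#' periodic box, rejecting oxygen placements closer than a minimum distance,
#' and returns the frame and topology. The resulting hydrogen-bond graph is
#' unknown by construction: pairs land on either side of the criteria, which
#' is exactly what the brute-force/cell-list equivalence check wants.
#'
#' @param n_molecules number of molecules.
#' @param box length-3 box (Angstrom).
#' @param min_OO minimum allowed O-O distance (Angstrom).
#' @param p_aim probability that a hydroxyl is aimed at a random nearby
#'   oxygen (with angular jitter) instead of uniformly; raises the bond
#'   density so detector comparisons see nontrivial graphs.
#' @param seed RNG seed.
#' @return list with `frame` and `topology`.
#' @export
random_fixture <- function(n_molecules = 50, box = c(18, 18, 18),
                           min_OO = 2.4, p_aim = 0.5, seed = 1L) {
  set.seed(seed)
  N <- n_molecules
  O <- matrix(NA_real_, N, 3)
  placed <- 0L; tries <- 0L
  while (placed < N) {
    tries <- tries + 1L
    if (tries > 20000L) stop("generation error: density too high to realize placements")
    cand <- stats::runif(3) * box
    if (placed > 0L) {
      d <- min_image(O[seq_len(placed), , drop = FALSE] -
                       matrix(cand, placed, 3, byrow = TRUE), box)
      if (min(rowSums(d^2)) < min_OO^2) next
    }
    placed <- placed + 1L
    O[placed, ] <- cand
  }
  u <- matrix(stats::rnorm(3 * N), N, 3)
  u <- u / sqrt(rowSums(u^2))
  for (i in seq_len(N)) {
    if (stats::runif(1) >= p_aim) next
    d <- min_image(O - matrix(O[i, ], N, 3, byrow = TRUE), box)
    r <- sqrt(rowSums(d^2)); r[i] <- Inf
    near <- which(r < 4)
    if (!length(near)) next
    j <- near[sample.int(length(near), 1L)]
    aim <- d[j, ] / r[j] + 0.25 * stats::rnorm(3)
    u[i, ] <- aim / sqrt(sum(aim^2))
  }
  pos <- matrix(0, 3 * N, 3)
  idx <- 3 * (seq_len(N) - 1L)
  pos[idx + 1L, ] <- O - 1.43 * u
  pos[idx + 2L, ] <- O
  pos[idx + 3L, ] <- O + 0.95 * u
  list(frame = cr_frame(pos, box, time = 0),
       topology = cr_topology(rep(c("C", "O", "H"), N)))
}
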