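## Geometric hydrogen-bond detection and chain partitioning.
##
## A donor molecule d is hydrogen-bonded to an acceptor molecule a when
##   dist(H_d, O_a) <= r_HO_max,  dist(O_d, O_a) <= r_OO_max,  and the
##   O_d - H_d ... O_a angle (at the hydrogen) >= angle_min.
## Each molecule donates at most one bond (one hydroxyl H) and accepts at
## most two (the oxygen's two lone pairs), so graph degree <= 3. Multiple
## qualifying acceptors for a donor are resolved to the geometrically best
## (smallest H...O distance, then lowest molecule id); an oxygen over-
## subscribed by more than two donors keeps its two best donors by the same
## ordering.

#' Hydrogen-bond geometric criteria
#'
#' @param r_HO_max donor-H to acceptor-O distance cutoff (Angstrom).
#' @param r_OO_max donor-O to acceptor-O distance cutoff (Angstrom).
#' @param angle_min minimum O-H...O alignment angle at the hydrogen (degrees).
#' @return an object of class `cr_hbond_criteria`.
#' @export
hbond_criteria <- function(r_HO_max = 2.6, r_OO_max = 3.5, angle_min = 140) {
  if (r_HO_max <= 0 || r_OO_max <= 0) stop("distance cutoffs must be positive")
  if (angle_min <= 0 || angle_min > 180) stop("angle_min must lie in (0, 180]")
  structure(list(r_HO_max = r_HO_max, r_OO_max = r_OO_max,
                 angle_min = angle_min),
            class = "cr_hbond_criteria")
}

## all candidate donor->acceptor pairs with O-O distance <= cutoff,
## found through a cell list over oxygen positions
oxygen_pairs_cell <- function(O, box, cutoff) {
  n <- nrow(O)
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))
  # fold positions into the primary box for binning only
  Ow <- O %% matrix(box, n, 3, byrow = TRUE)
  ix <- pmin(ncell[1] - 1L, as.integer(Ow[, 1] / box[1] * ncell[1]))
  iy <- pmin(ncell[2] - 1L, as.integer(Ow[, 2] / box[2] * ncell[2]))
  iz <- pmin(ncell[3] - 1L, as.integer(Ow[, 3] / box[3] * ncell[3]))
  cell <- ix + ncell[1] * (iy + ncell[2] * iz)
  ord <- order(cell)
  cells <- split(ord, cell[ord])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  from <- integer(0); to <- integer(0)
  key <- function(cx, cy, cz) cx + ncell[1] * (cy + ncell[2] * cz)
  for (cname in names(cells)) {
    c0 <- as.integer(cname)
    cz <- c0 %/% (ncell[1] * ncell[2])
    cy <- (c0 %% (ncell[1] * ncell[2])) %/% ncell[1]
    cx <- c0 %% ncell[1]
    mem <- cells[[cname]]
    neigh <- unique(key((cx + offs[, 1]) %% ncell[1],
                        (cy + offs[, 2]) %% ncell[2],
                        (cz + offs[, 3]) %% ncell[3]))
    cand <- unlist(cells[as.character(neigh)], use.names = FALSE)
    if (is.null(cand)) next
    from <- c(from, rep(mem, each = length(cand)))
    to <- c(to, rep(cand, times = length(mem)))
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (!length(from)) return(cbind(donor = integer(0), acceptor = integer(0)))
  d <- min_image(O[to, , drop = FALSE] - O[from, , drop = FALSE], box)
  keep <- rowSums(d^2) <= cutoff^2
  cbind(donor = from[keep], acceptor = to[keep])
}

oxygen_pairs_brute <- function(O, box, cutoff) {
  n <- nrow(O)
  from <- rep(seq_len(n), each = n)
  to <- rep(seq_len(n), times = n)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  d <- min_image(O[to, , drop = FALSE] - O[from, , drop = FALSE], box)
  keep <- rowSums(d^2) <= cutoff^2
  cbind(donor = from[keep], acceptor = to[keep])
}

#' Detect hydrogen bonds in a frame
#'
#' Applies the geometric criteria under the minimum-image convention and
#' resolves multi-acceptor conflicts to the geometrically best acceptor per
#' donor and at most two donors per acceptor.
#'
#' @param frame a [cr_frame()].
#' @param topology a [cr_topology()] with resolved hydroxyl groups.
#' @param criteria an [hbond_criteria()].
#' @param method `"cell"` for a cell-list neighbour search (default) or
#'   `"brute"` for the all-pairs reference; both return identical graphs.
#' @return an object of class `cr_hbond_graph`: a list with `n_molecules`,
#'   `edges` (data.frame donor, acceptor, r_HO, r_OO, angle) and the
#'   `criteria` used.
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria(),
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  if (criteria$r_OO_max > min(frame$box) / 2)
    stop("r_OO_max exceeds half the smallest box edge; minimum image is invalid")
  nm <- topology$n_molecules
  O <- frame$positions[topology$oh_bonds[, 1], , drop = FALSE]
  H <- frame$positions[topology$oh_bonds[, 2], , drop = FALSE]
  pairs <- if (method == "brute" || nm < 30L)
    oxygen_pairs_brute(O, frame$box, criteria$r_OO_max)
  else
    oxygen_pairs_cell(O, frame$box, criteria$r_OO_max)
  empty <- data.frame(donor = integer(0), acceptor = integer(0),
                      r_HO = numeric(0), r_OO = numeric(0), angle = numeric(0))
  if (!nrow(pairs)) {
    return(structure(list(n_molecules = nm, edges = empty, criteria = criteria),
                     class = "cr_hbond_graph"))
  }
  don <- pairs[, 1]; acc <- pairs[, 2]
  dOO <- min_image(O[acc, , drop = FALSE] - O[don, , drop = FALSE], frame$box)
  r_OO <- sqrt(rowSums(dOO^2))
  dHOa <- min_image(O[acc, , drop = FALSE] - H[don, , drop = FALSE], frame$box)
  r_HO <- sqrt(rowSums(dHOa^2))
  dHOd <- min_image(O[don, , drop = FALSE] - H[don, , drop = FALSE], frame$box)
  # angle at H between H->O_donor and H->O_acceptor
  cosang <- rowSums(dHOd * dHOa) /
    (sqrt(rowSums(dHOd^2)) * pmax(r_HO, 1e-12))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- r_HO <= criteria$r_HO_max & r_OO <= criteria$r_OO_max &
    ang >= criteria$angle_min
  ed <- data.frame(donor = don[keep], acceptor = acc[keep],
                   r_HO = r_HO[keep], r_OO = r_OO[keep], angle = ang[keep])
  if (nrow(ed)) {
    # best acceptor per donor: smallest r_HO, then lowest acceptor id
    ed <- ed[order(ed$donor, ed$r_HO, ed$acceptor), , drop = FALSE]
    ed <- ed[!duplicated(ed$donor), , drop = FALSE]
    # cap acceptors at two donors: keep the two best by r_HO, then donor id
    ed <- ed[order(ed$acceptor, ed$r_HO, ed$donor), , drop = FALSE]
    rank <- stats::ave(ed$r_HO, ed$acceptor, FUN = seq_along)
    ed <- ed[rank <= 2, , drop = FALSE]
    ed <- ed[order(ed$donor), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- empty
  }
  structure(list(n_molecules = nm, edges = ed, criteria = criteria),
            class = "cr_hbond_graph")
}

#' @export
print.cr_hbond_graph <- function(x, ...) {
  cat(sprintf("<cr_hbond_graph> %d molecules, %d hydrogen bonds\n",
              x$n_molecules, nrow(x$edges)))
  invisible(x)
}

#' Partition a hydrogen-bond graph into chains and lone molecules
#'
#' Connected components of size >= 2 are chains (branched components count as
#' single chains); isolated molecules are lone. The chain list plus the lone
#' set always partition the molecule set.
#'
#' @param graph a `cr_hbond_graph` from [detect_hbonds()].
#' @return a list of class `cr_chain_partition` with `chains` (list of lists:
#'   `members`, `size`, `branches` counting nodes of total degree >= 3,
#'   `edges`), `lone` (integer vector), `membership` (length-n integer vector,
#'   0 for lone molecules, otherwise chain index).
#' @export
find_chains <- function(graph) {
  nm <- graph$n_molecules
  ed <- graph$edges
  # union-find over molecules
  parent <- seq_len(nm)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(ed)) for (k in seq_len(nrow(ed))) {
    a <- find(ed$donor[k]); b <- find(ed$acceptor[k])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(nm), find, integer(1))
  comp <- match(root, unique(root))
  sizes <- tabulate(comp)
  deg <- tabulate(ed$donor, nm) + tabulate(ed$acceptor, nm)
  chain_ids <- which(sizes >= 2)
  membership <- integer(nm)
  chains <- vector("list", length(chain_ids))
  for (j in seq_along(chain_ids)) {
    mem <- which(comp == chain_ids[j])
    membership[mem] <- j
    esub <- ed[ed$donor %in% mem, , drop = FALSE]
    chains[[j]] <- list(members = mem, size = length(mem),
                        branches = sum(deg[mem] >= 3),
                        edges = esub[, c("donor", "acceptor")])
  }
  lone <- which(membership == 0L)
  stopifnot(sum(vapply(chains, `[[`, integer(1), "size")) + length(lone) == nm)
  structure(list(chains = chains, lone = lone, membership = membership,
                 n_molecules = nm),
            class = "cr_chain_partition")
}

#' @export
print.cr_chain_partition <- function(x, ...) {
  cat(sprintf("<cr_chain_partition> %d chains, %d lone of %d molecules\n",
              length(x$chains), length(x$lone), x$n_molecules))
  invisible(x)
}

#' Per-frame census of the chain population
#'
#' @param partitions list of `cr_chain_partition`, one per frame, or any
#'   compact form accepted by [as_partition_series()] (then
#'   `branch_fraction` is `NA`: branching needs edge information).
#' @param times optional frame times (ps).
#' @return data.frame with one row per frame: `time`, `n_chains`,
#'   `n_lone`, `lone_fraction`, `mean_size`, `max_size`, `branch_fraction`
#'   (fraction of chains containing at least one branch point).
#' @export
chain_census <- function(partitions, times = NULL) {
  if (length(partitions) == 0L) stop("empty trajectory: no partitions supplied")
  if (!(is.list(partitions) && !is.null(partitions[[1]]) &&
        inherits(partitions[[1]], "cr_chain_partition"))) {
    ps <- as_partition_series(partitions, times)
    M <- ps$membership
    rows <- lapply(seq_len(ncol(M)), function(f) {
      col <- M[, f]
      nch <- max(col, 0L)
      sizes <- if (nch) tabulate(col[col > 0L], nch) else integer(0)
      data.frame(time = ps$times[f], n_chains = nch,
                 n_lone = sum(col == 0L),
                 lone_fraction = mean(col == 0L),
                 mean_size = if (nch) mean(sizes) else NA_real_,
                 max_size = if (nch) max(sizes) else NA_integer_,
                 branch_fraction = NA_real_)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(times)) times <- seq_along(partitions) - 1
  rows <- lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    sizes <- vapply(p$chains, `[[`, integer(1), "size")
    branched <- vapply(p$chains, function(c) c$branches > 0, logical(1))
    data.frame(time = times[i],
               n_chains = length(p$chains),
               n_lone = length(p$lone),
               lone_fraction = length(p$lone) / p$n_molecules,
               mean_size = if (length(sizes)) mean(sizes) else NA_real_,
               max_size = if (length(sizes)) max(sizes) else NA_integer_,
               branch_fraction = if (length(sizes)) mean(branched) else NA_real_)
  })
  do.call(rbind, rows)
}
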