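## Chain identity tracking and life-cycle statistics.
##
## Identity rule: a chain (connected component) at frame t+1 continues the
## track of the component at frame t with which it shares the largest member
## overlap (ties -> lowest track id). Molecules entering from the lone pool
## are additions, molecules leaving to the lone pool are removals; a new
## two-molecule component whose members were both lone is a birth, and a
## track whose final pair dissociates into two lone molecules is a death.
## Coalescence or fission of multi-molecule components beyond single-molecule
## exchange is recorded as merge/split (and excluded from birth/death
## statistics); a multi-molecule component vanishing in one step is flagged
## "dissolution". A track may end sharing no molecule with its initial pair.

#' Track chain identity across frames and classify life-cycle events
#'
#' @param partitions per-frame partitions: a list of `cr_chain_partition`, a
#'   `cr_kmc_run`, or anything [as_partition_series()] accepts.
#' @param times frame times in ps (defaults to the series' own times).
#' @return an object of class `cr_tracking`: a list with
#'   \describe{
#'     \item{tracks}{data.frame: `track`, `birth_frame`, `birth_time`,
#'       `end_frame`, `end_time`, `lifetime`, `censored` (alive at the final
#'       frame), `left_truncated` (already alive at the first frame),
#'       `closed_by` (death/dissolution/merge/censored).}
#'     \item{events}{data.frame: `frame`, `time`, `type`, `track`, plus a
#'       `molecules` list column of molecule ids.}
#'     \item{track_of_comp}{per-frame integer vectors mapping component index
#'       to track id.}
#'   }
#' @export
track_chains <- function(partitions, times = NULL) {
  ps <- as_partition_series(partitions, times)
  M <- ps$membership
  times <- ps$times
  nf <- ncol(M)
  if (nf < 1L) stop("need at least one frame of partitions")
  N <- nrow(M)

  n_alloc <- 256L
  tr_birth <- integer(n_alloc); tr_left <- logical(n_alloc)
  tr_end <- rep(NA_integer_, n_alloc); tr_closed <- rep(NA_character_, n_alloc)
  next_track <- 0L
  e_alloc <- 1024L; n_ev <- 0L
  ev_frame <- integer(e_alloc); ev_type <- character(e_alloc)
  ev_track <- integer(e_alloc); ev_mols <- vector("list", e_alloc)
  track_of_comp <- vector("list", nf)

  add_event <- function(frame, type, track, mols) {
    n_ev <<- n_ev + 1L
    if (n_ev > e_alloc) {
      e_alloc <<- e_alloc * 2L
      length(ev_frame) <<- e_alloc; length(ev_type) <<- e_alloc
      length(ev_track) <<- e_alloc; length(ev_mols) <<- e_alloc
    }
    ev_frame[n_ev] <<- frame; ev_type[n_ev] <<- type
    ev_track[n_ev] <<- track; ev_mols[[n_ev]] <<- sort(mols)
  }
  new_track <- function(frame, left_truncated) {
    next_track <<- next_track + 1L
    if (next_track > n_alloc) {
      n_alloc <<- n_alloc * 2L
      length(tr_birth) <<- n_alloc; length(tr_left) <<- n_alloc
      length(tr_end) <<- n_alloc; length(tr_closed) <<- n_alloc
    }
    tr_birth[next_track] <<- frame
    tr_left[next_track] <<- left_truncated
    tr_end[next_track] <<- NA_integer_
    tr_closed[next_track] <<- NA_character_
    next_track
  }

  members_of <- function(m) {
    pos <- which(m > 0L)
    out <- vector("list", max(m[pos], 0L))
    if (length(pos)) {
      spl <- split(pos, m[pos])
      out[as.integer(names(spl))] <- spl
    }
    out
  }

  m_prev <- M[, 1]
  mem_prev_list <- members_of(m_prev)
  nprev <- length(mem_prev_list)
  tmap_prev <- integer(nprev)
  for (j in seq_len(nprev)) tmap_prev[j] <- new_track(1L, TRUE)
  track_of_comp[[1]] <- tmap_prev

  for (f in seq_len(nf - 1L)) {
    m_cur <- M[, f + 1L]
    mem_cur_list <- members_of(m_cur)
    ncur <- length(mem_cur_list)
    nprev <- length(tmap_prev)
    tmap_cur <- integer(ncur)

    # per cur comp: prev comp of each overlapping member (with multiplicity)
    prev_by_cur <- vector("list", ncur)
    both <- which(m_prev > 0L & m_cur > 0L)
    if (length(both)) {
      spl <- split(m_prev[both], m_cur[both])
      prev_by_cur[as.integer(names(spl))] <- spl
    }
    ov <- function(d, c) sum(prev_by_cur[[c]] == d)

    # predecessor of each cur comp: prev comp with max overlap, tie -> lowest track id
    pred <- integer(ncur)
    for (c in seq_len(ncur)) {
      ds <- prev_by_cur[[c]]
      if (is.null(ds)) next
      cnt <- tabulate(ds)
      best <- which(cnt == max(cnt))
      pred[c] <- best[which.min(tmap_prev[best])]
    }
    # continuation target of each prev comp among cur comps that chose it
    cont <- integer(nprev)
    claimed <- which(pred > 0L)
    if (length(claimed)) {
      by_pred <- split(claimed, pred[claimed])
      for (nm in names(by_pred)) {
        d <- as.integer(nm); cs <- by_pred[[nm]]
        if (length(cs) == 1L) { cont[d] <- cs; next }
        o <- vapply(cs, function(c) ov(d, c), integer(1))
        cont[d] <- cs[which.max(o)]
      }
    }

    for (c in seq_len(ncur)) {
      d <- pred[c]
      if (d == 0L) {
        mem <- mem_cur_list[[c]]
        tmap_cur[c] <- new_track(f + 1L, FALSE)
        if (length(mem) == 2L && all(m_prev[mem] == 0L))
          add_event(f + 1L, "birth", tmap_cur[c], mem)
        else
          add_event(f + 1L, "emergence", tmap_cur[c], mem)
      } else if (cont[d] == c) {
        tmap_cur[c] <- tmap_prev[d]
        # inflows: from the lone pool, or hopping from a persisting chain
        mem <- mem_cur_list[[c]]
        src <- m_prev[mem]
        if (!all(src == d)) {
          for (i in mem[src == 0L])
            add_event(f + 1L, "addition", tmap_cur[c], i)
          for (i in mem[src != 0L & src != d]) {
            d2 <- m_prev[i]
            if (cont[d2] != 0L) {
              add_event(f + 1L, "removal", tmap_prev[d2], i)
              add_event(f + 1L, "addition", tmap_cur[c], i)
            }
          }
        }
      } else {
        tmap_cur[c] <- new_track(f + 1L, FALSE)
        add_event(f + 1L, "split", tmap_cur[c], mem_cur_list[[c]])
      }
    }
    # outflows to the lone pool, and track endings
    for (d in seq_len(nprev)) {
      mem_prev <- mem_prev_list[[d]]
      dest <- m_cur[mem_prev]
      if (cont[d] != 0L) {
        if (any(dest == 0L))
          for (i in mem_prev[dest == 0L])
            add_event(f + 1L, "removal", tmap_prev[d], i)
        next
      }
      tr <- tmap_prev[d]
      if (all(dest == 0L)) {
        if (length(mem_prev) == 2L) {
          add_event(f + 1L, "death", tr, mem_prev)
          tr_closed[tr] <- "death"
        } else {
          add_event(f + 1L, "dissolution", tr, mem_prev)
          tr_closed[tr] <- "dissolution"
        }
      } else {
        add_event(f + 1L, "merge", tr, mem_prev)
        tr_closed[tr] <- "merge"
        for (i in mem_prev[dest == 0L]) add_event(f + 1L, "removal", tr, i)
      }
      tr_end[tr] <- f + 1L
    }
    track_of_comp[[f + 1L]] <- tmap_cur
    tmap_prev <- tmap_cur
    m_prev <- m_cur
    mem_prev_list <- mem_cur_list
  }

  length(tr_birth) <- next_track; length(tr_left) <- next_track
  length(tr_end) <- next_track; length(tr_closed) <- next_track
  open <- is.na(tr_end)
  tr_end[open] <- nf
  tr_closed[open] <- "censored"
  tracks <- data.frame(
    track = seq_len(next_track),
    birth_frame = tr_birth,
    birth_time = times[tr_birth],
    end_frame = tr_end,
    end_time = times[tr_end],
    lifetime = times[tr_end] - times[tr_birth],
    censored = open,
    left_truncated = tr_left,
    closed_by = tr_closed
  )
  events <- data.frame(frame = ev_frame[seq_len(n_ev)],
                       time = times[ev_frame[seq_len(n_ev)]],
                       type = ev_type[seq_len(n_ev)],
                       track = ev_track[seq_len(n_ev)])
  events$molecules <- ev_mols[seq_len(n_ev)]
  structure(list(tracks = tracks, events = events,
                 track_of_comp = track_of_comp, times = times,
                 n_molecules = N),
            class = "cr_tracking")
}

#' @export
print.cr_tracking <- function(x, ...) {
  cat(sprintf("<cr_tracking> %d tracks, %d events over %d frames\n",
              nrow(x$tracks), nrow(x$events), length(x$track_of_comp)))
  print(table(x$events$type))
  invisible(x)
}

#' Member sets of one track through its life
#'
#' @param tracking a `cr_tracking` from [track_chains()].
#' @param partitions the partitions the tracking was built from (any form
#'   accepted by [as_partition_series()]).
#' @param track track id.
#' @return list with `frames` (indices), `times`, and `members` (list of
#'   integer vectors).
#' @export
track_members <- function(tracking, partitions, track) {
  ps <- as_partition_series(partitions)
  frames <- integer(0); members <- list()
  for (f in seq_along(tracking$track_of_comp)) {
    j <- match(track, tracking$track_of_comp[[f]])
    if (!is.na(j)) {
      frames <- c(frames, f)
      members[[length(members) + 1L]] <- which(ps$membership[, f] == j)
    }
  }
  list(frames = frames, times = tracking$times[frames], members = members)
}

#' Exponential lifetime fit with right-censoring
#'
#' Maximum-likelihood mean of an exponential lifetime distribution under
#' right-censoring: `mean = total observed time / number of uncensored
#' endings`. Reports a bootstrap 95% CI and a Kolmogorov-Smirnov statistic of
#' the uncensored durations against the fitted exponential.
#'
#' @param durations numeric vector of episode durations (ps).
#' @param censored logical vector: `TRUE` where the episode was cut off by the
#'   end of the observation window.
#' @param n_boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @return an object of class `cr_lifetime_fit`: list with `mean`, `ci`,
#'   `n`, `n_censored`, `ks_statistic`, `ks_p`.
#' @export
fit_lifetime_distribution <- function(durations, censored = NULL,
                                      n_boot = 1000, conf = 0.95) {
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  stopifnot(length(censored) == length(durations))
  if (all(censored)) stop("all durations are censored; mean is unidentifiable")
  if (sum(!censored) < 10L) stop("need at least 10 uncensored durations")
  mean_hat <- sum(durations) / sum(!censored)
  n <- length(durations)
  tot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- sum(!censored[idx])
    if (d == 0L) NA_real_ else sum(durations[idx]) / d
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(tot, c(alpha, 1 - alpha), na.rm = TRUE))
  ks <- suppressWarnings(
    stats::ks.test(durations[!censored], "pexp", rate = 1 / mean_hat))
  structure(list(mean = mean_hat, ci = ci, conf = conf,
                 n = n, n_censored = sum(censored),
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value),
            class = "cr_lifetime_fit")
}

#' @export
print.cr_lifetime_fit <- function(x, ...) {
  cat(sprintf("<cr_lifetime_fit> mean %.4g ps  %.0f%% CI [%.4g, %.4g]  (n = %d, %d censored)\n",
              x$mean, 100 * x$conf, x$ci[1], x$ci[2], x$n, x$n_censored))
  cat(sprintf("  KS vs exponential: D = %.4g (p = %.3g)\n",
              x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Chain lifetimes from a tracking result
#'
#' Extracts per-track lifetimes suitable for [fit_lifetime_distribution()].
#' Tracks ending by merge or dissolution are excluded by default (they are
#' not deaths); tracks alive at the final frame are censored. Left-truncated
#' tracks (alive at the first frame) are retained: for an exponential
#' lifetime law the residual life from the window start has the same
#' distribution, so they enter as ordinary episodes.
#'
#' @param tracking a `cr_tracking`.
#' @param include_merges include tracks closed by merge/dissolution.
#' @return data.frame with `track`, `duration`, `censored`.
#' @export
chain_lifetimes <- function(tracking, include_merges = FALSE) {
  tr <- tracking$tracks
  keep <- tr$closed_by %in% c("death", "censored")
  if (include_merges) keep <- keep | tr$closed_by %in% c("merge", "dissolution")
  data.frame(track = tr$track[keep], duration = tr$lifetime[keep],
             censored = tr$censored[keep])
}

#' Lone-molecule episodes
#'
#' Maximal runs of lone status per molecule. An episode spanning frames
#' `a..b` has duration `t[b+1] - t[a]` (the time at which the molecule is
#' next seen bonded); episodes still lone at the final frame are censored
#' with duration `t[nf] - t[a]`.
#'
#' @param partitions partitions in any form accepted by
#'   [as_partition_series()].
#' @param times frame times (ps).
#' @return data.frame with `molecule`, `start_time`, `duration`, `censored`.
#' @export
lone_intervals <- function(partitions, times = NULL) {
  ps <- as_partition_series(partitions, times)
  M <- ps$membership; times <- ps$times
  nf <- ncol(M); N <- nrow(M)
  out_mol <- integer(0); out_start <- numeric(0)
  out_dur <- numeric(0); out_cens <- logical(0)
  for (i in seq_len(N)) {
    r <- rle(M[i, ] == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      cens <- b == nf
      dur <- if (cens) times[nf] - times[a] else times[b + 1L] - times[a]
      out_mol <- c(out_mol, i); out_start <- c(out_start, times[a])
      out_dur <- c(out_dur, dur); out_cens <- c(out_cens, cens)
    }
  }
  data.frame(molecule = out_mol, start_time = out_start,
             duration = out_dur, censored = out_cens)
}

#' Metric profile over normalized track lifetime
#'
#' Averages a per-molecule observable over each track's members, maps each
#' track's frames onto normalized lifetime s in [0, 1], interpolates onto
#' common bin centers and averages across tracks. Used to test whether, e.g.,
#' the hydroxyl angle trends over a chain's life.
#'
#' @param tracking a `cr_tracking`.
#' @param partitions the partitions the tracking was built from.
#' @param metric frames x molecules numeric matrix of the observable.
#' @param bins number of normalized-lifetime bins.
#' @param tracks optional subset of track ids (default: all uncensored).
#' @return data.frame with `s` (bin centers), `mean`, `se`, `n_tracks`.
#' @export
lifetime_resolved_metric <- function(tracking, partitions, metric, bins = 10,
                                     tracks = NULL) {
  ps <- as_partition_series(partitions)
  if (is.null(tracks))
    tracks <- tracking$tracks$track[!tracking$tracks$censored]
  centers <- (seq_len(bins) - 0.5) / bins
  acc <- matrix(NA_real_, length(tracks), bins)
  for (k in seq_along(tracks)) {
    tm <- track_members(tracking, ps, tracks[k])
    if (length(tm$frames) < 1L) next
    vals <- vapply(seq_along(tm$frames), function(j) {
      mean(metric[tm$frames[j], tm$members[[j]]])
    }, numeric(1))
    if (length(vals) == 1L) {
      acc[k, ] <- vals
    } else {
      s <- (tm$times - tm$times[1]) / (tm$times[length(tm$times)] - tm$times[1])
      acc[k, ] <- stats::approx(s, vals, xout = centers, rule = 2)$y
    }
  }
  ok <- rowSums(is.na(acc)) == 0
  acc <- acc[ok, , drop = FALSE]
  data.frame(s = centers,
             mean = colMeans(acc),
             se = apply(acc, 2, stats::sd) / sqrt(nrow(acc)),
             n_tracks = nrow(acc))
}
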