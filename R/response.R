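## Cycle averaging and in-phase/quadrature response fitting.
##
## A metric time series sampled at frames_per_cycle points per field period
## is folded onto one period: the i-th frame of every cycle is averaged,
## giving <theta>_cyc(t) on a single-period phase grid. That average cycle is
## fit to
##     <theta>_cyc = A sin(wt) + B cos(wt) + C
## by linear least squares; A is the in-phase (real) response, B the
## quadrature (imaginary) response. Because the sign of both depends on the
## bond-vector convention, |A| and |B| are reported alongside the signed
## values. The constant C absorbs the nonzero baseline (bond angles oscillate
## about ~90 degrees). The phase origin is t = 0 at a field zero-crossing
## going positive; cycles are aligned by simulation bookkeeping, not by
## fitting.

#' Fold a time series onto the field cycle
#'
#' Requires the series length to be an integer multiple of
#' `field$frames_per_cycle`, with the first sample at the phase origin.
#' Field-free control series are folded the same way at a nominal frequency.
#'
#' @param series numeric vector sampled at `frames_per_cycle` points per
#'   period.
#' @param field a [cr_field()] (its `frames_per_cycle` and `omega` are used).
#' @return an object of class `cr_cycle_average`: list with `phase_time` (ps
#'   within one period), `mean`, `se`, `n_cycles`, `omega`,
#'   `frames_per_cycle`.
#' @export
cycle_average <- function(series, field) {
  fpc <- field$frames_per_cycle
  n <- length(series)
  if (n < fpc) stop("series shorter than one cycle")
  if (n %% fpc != 0L)
    stop(sprintf(
      "series length %d is not a whole number of cycles of %d frames; largest usable prefix is %d frames",
      n, fpc, fpc * (n %/% fpc)))
  ncyc <- n %/% fpc
  m <- matrix(series, nrow = fpc)
  mu <- rowMeans(m)
  se <- if (ncyc > 1) apply(m, 1, stats::sd) / sqrt(ncyc) else rep(NA_real_, fpc)
  period <- 2 * pi / field$omega
  structure(list(phase_time = (seq_len(fpc) - 1) / fpc * period,
                 mean = mu, se = se, n_cycles = ncyc,
                 cycles = m,
                 omega = field$omega, frames_per_cycle = fpc),
            class = "cr_cycle_average")
}

#' @export
print.cr_cycle_average <- function(x, ...) {
  cat(sprintf("<cr_cycle_average> %d phase points x %d cycles at %.4g GHz\n",
              x$frames_per_cycle, x$n_cycles, radps_to_ghz(x$omega)))
  invisible(x)
}

#' Fit an average cycle to A sin(wt) + B cos(wt) + C
#'
#' Linear least squares on the sin/cos basis plus a constant offset. The fit
#' is exact (to machine precision) on noiseless sinusoids. Confidence
#' intervals come from the residual variance assuming independent phase-point
#' errors (`se_method = "iid"`), or from a Newey-West heteroskedasticity- and
#' autocorrelation-consistent estimate (`"hac"`) appropriate when the folded
#' noise is serially correlated across phase points, as it is when folding
#' slow equilibrium fluctuations.
#'
#' @param avg a `cr_cycle_average`, or a numeric vector of metric values.
#' @param omega angular frequency (rad/ps); taken from `avg` when folding
#'   metadata is present.
#' @param times sample times (ps) when `avg` is a plain vector.
#' @param conf confidence level for the intervals.
#' @param se_method `"iid"` assumes independent phase-point errors; `"hac"`
#'   uses Newey-West standard errors; `"cycles"` fits each block of
#'   consecutive cycles separately and takes a t-interval over the block
#'   estimates (the point estimate is unchanged), which is robust to serial
#'   correlation of the folded noise once blocks exceed the correlation
#'   time. `"cycles"` requires a `cr_cycle_average` input.
#' @param block number of consecutive cycles per block for
#'   `se_method = "cycles"`.
#' @return an object of class `cr_sinusoid_fit`: list with `A`, `B`,
#'   `offset`, `absA`, `absB`, `ci_A`, `ci_B`, `se_A`, `se_B`,
#'   `residual_rms`, `omega`, `n`.
#' @export
fit_sinusoid <- function(avg, omega = NULL, times = NULL, conf = 0.95,
                         se_method = c("iid", "hac", "cycles"), block = 1L) {
  se_method <- match.arg(se_method)
  if (inherits(avg, "cr_cycle_average")) {
    y <- avg$mean
    times <- avg$phase_time
    if (is.null(omega)) omega <- avg$omega
  } else {
    y <- as.numeric(avg)
    if (is.null(times) || is.null(omega))
      stop("times and omega are required when avg is a plain vector")
    if (se_method == "cycles")
      stop("se_method 'cycles' needs a cr_cycle_average input")
  }
  if (length(y) < 4L)
    stop("need at least 4 phase points to fit A, B and an offset")
  s <- sin(omega * times); c <- cos(omega * times)
  fit <- stats::lm(y ~ s + c)
  cf <- stats::coef(fit)
  if (se_method == "cycles") {
    ncyc <- avg$n_cycles
    nb <- ncyc %/% block
    if (nb < 3L) stop("need at least 3 cycle blocks for se_method 'cycles'")
    X <- cbind(1, s, c)
    XtXinv_Xt <- solve(crossprod(X), t(X))
    est <- vapply(seq_len(nb), function(b) {
      yb <- rowMeans(avg$cycles[, ((b - 1) * block + 1):(b * block),
                                drop = FALSE])
      as.numeric(XtXinv_Xt %*% yb)
    }, numeric(3))
    se <- apply(est, 1, stats::sd) / sqrt(nb)
    names(se) <- c("(Intercept)", "s", "c")
    # point estimate from the blocks actually used (equals the full fit when
    # block divides the cycle count)
    cf <- rowMeans(est); names(cf) <- names(se)
    tq <- stats::qt(1 - (1 - conf) / 2, df = nb - 1)
  } else {
    V <- if (se_method == "hac") sandwich::NeweyWest(fit, prewhite = FALSE)
         else stats::vcov(fit)
    se <- sqrt(diag(V))
    tq <- stats::qt(1 - (1 - conf) / 2, df = fit$df.residual)
  }
  A <- unname(cf["s"]); B <- unname(cf["c"])
  structure(list(A = A, B = B, offset = unname(cf["(Intercept)"]),
                 absA = abs(A), absB = abs(B),
                 se_A = unname(se["s"]), se_B = unname(se["c"]),
                 ci_A = A + c(-1, 1) * tq * unname(se["s"]),
                 ci_B = B + c(-1, 1) * tq * unname(se["c"]),
                 conf = conf, se_method = se_method,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 omega = omega, n = length(y)),
            class = "cr_sinusoid_fit")
}

#' @export
print.cr_sinusoid_fit <- function(x, ...) {
  cat(sprintf("<cr_sinusoid_fit> at %.4g GHz (n = %d, %s SEs)\n",
              radps_to_ghz(x$omega), x$n, x$se_method))
  cat(sprintf("  A = %+.5g  [%.5g, %.5g]\n", x$A, x$ci_A[1], x$ci_A[2]))
  cat(sprintf("  B = %+.5g  [%.5g, %.5g]\n", x$B, x$ci_B[1], x$ci_B[2]))
  cat(sprintf("  offset = %.5g, residual RMS = %.3g\n", x$offset, x$residual_rms))
  invisible(x)
}

#' Frequency dependence of the response amplitudes with a Debye-form fit
#'
#' Collects |A| and |B| across applied-field frequencies and fits the
#' single-relaxation (Debye) forms
#' \eqn{|A|(\omega) = a/(1+\omega^2\tau^2)} and
#' \eqn{|B|(\omega) = a\,\omega\tau/(1+\omega^2\tau^2)} jointly, returning
#' the relaxation time tau and amplitude a. |B| peaks at
#' \eqn{\omega\tau = 1}; |A| is sigmoidal.
#'
#' @param fits named list of `cr_sinusoid_fit` (any names), or a data.frame
#'   with columns `freq_GHz`, `absA`, `absB`.
#' @return an object of class `cr_response_spectrum`: list with `table`
#'   (freq_GHz, omega, absA, absB), `tau` (ps), `amplitude`, `peak_freq_GHz`
#'   (grid frequency of max |B|), `fitted` (model values), `converged`.
#' @export
response_spectrum <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- data.frame(freq_GHz = fits$freq_GHz,
                      omega = ghz_to_radps(fits$freq_GHz),
                      absA = fits$absA, absB = fits$absB)
  } else {
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(freq_GHz = radps_to_ghz(f$omega), omega = f$omega,
                 absA = f$absA, absB = f$absB)))
  }
  tab <- tab[order(tab$omega), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab, tau = NA_real_, amplitude = NA_real_,
              peak_freq_GHz = tab$freq_GHz[which.max(tab$absB)],
              fitted = NULL, converged = FALSE)
  if (nrow(tab) < 3L) {
    warning("fewer than 3 frequencies: Debye fit refused, raw table returned")
    return(structure(out, class = "cr_response_spectrum"))
  }
  if (max(tab$absB) <= 0) {
    out$tau <- NA_real_; out$amplitude <- 0; out$converged <- TRUE
    return(structure(out, class = "cr_response_spectrum"))
  }
  w <- tab$omega
  model <- function(p) {
    a <- exp(p[1]); tau <- exp(p[2])
    c(a / (1 + (w * tau)^2), a * w * tau / (1 + (w * tau)^2))
  }
  obs <- c(tab$absA, tab$absB)
  tau0 <- 1 / w[which.max(tab$absB)]
  a0 <- max(2 * max(tab$absB), max(tab$absA))
  res <- minpack.lm::nls.lm(par = log(c(a0, tau0)),
                            fn = function(p) obs - model(p))
  p <- res$par
  out$amplitude <- exp(p[1]); out$tau <- exp(p[2])
  out$fitted <- data.frame(freq_GHz = tab$freq_GHz,
                           absA = model(p)[seq_len(nrow(tab))],
                           absB = model(p)[nrow(tab) + seq_len(nrow(tab))])
  out$converged <- res$info %in% 1:4
  structure(out, class = "cr_response_spectrum")
}

#' @export
print.cr_response_spectrum <- function(x, ...) {
  cat(sprintf("<cr_response_spectrum> %d frequencies; |B| peak at %.4g GHz\n",
              nrow(x$table), x$peak_freq_GHz))
  if (is.finite(x$tau))
    cat(sprintf("  Debye fit: tau = %.4g ps, amplitude = %.4g (peak 1/(2 pi tau) = %.4g GHz)\n",
                x$tau, x$amplitude, radps_to_ghz(1 / x$tau)))
  invisible(x)
}

#' Per-phase counts of items split by an angle threshold
#'
#' Counts items (chains, or life-cycle events) per frame whose mean hydroxyl
#' angle to the field axis is above/below a threshold, then folds the two
#' count series onto the field cycle. Conservation holds by construction:
#' above + below equals the total count at every phase.
#'
#' @param frame integer vector: frame index of each item (1-based).
#' @param angle numeric vector: each item's (chain-mean) OH angle, degrees.
#' @param n_frames total number of frames in the series.
#' @param field a [cr_field()].
#' @param threshold split angle in degrees.
#' @return list of class `cr_angle_split`: `above`/`below`
#'   (`cr_cycle_average` of per-frame counts), `total_above`/`total_below`
#'   (summed counts per phase), `threshold`, `n_cycles`.
#' @export
split_counts_by_angle <- function(frame, angle, n_frames, field,
                                  threshold = 90) {
  stopifnot(length(frame) == length(angle))
  cnt_above <- tabulate(frame[angle > threshold], n_frames)
  cnt_below <- tabulate(frame[angle <= threshold], n_frames)
  ca_above <- cycle_average(cnt_above, field)
  ca_below <- cycle_average(cnt_below, field)
  structure(list(above = ca_above, below = ca_below,
                 total_above = ca_above$mean * ca_above$n_cycles,
                 total_below = ca_below$mean * ca_below$n_cycles,
                 threshold = threshold, n_cycles = ca_above$n_cycles),
            class = "cr_angle_split")
}

#' Do events over/under-sample the unaligned population?
#'
#' Per phase point, compares the fraction of events on the "above-threshold"
#' side of the angle split with the same fraction in the extant population.
#' Under the null that events are drawn uniformly from the population the
#' excess is zero; e.g. for chains to die preferentially when unaligned, the
#' unaligned fraction of deaths must exceed the unaligned fraction of the
#' chain population.
#'
#' @param event_split a `cr_angle_split` of the event counts.
#' @param population_split a `cr_angle_split` of the population counts on the
#'   same phase grid.
#' @param conf confidence level.
#' @return data.frame per phase: `phase_time`, `event_frac`, `pop_frac`,
#'   `excess`, `se`, `z`, `lo`, `hi`, `flagged` (zero events or population at
#'   that phase).
#' @export
proportion_vs_population_test <- function(event_split, population_split,
                                          conf = 0.95) {
  if (length(event_split$total_above) != length(population_split$total_above))
    stop("event and population splits must share a phase grid")
  ea <- event_split$total_above; eb <- event_split$total_below
  pa <- population_split$total_above; pb <- population_split$total_below
  ne <- ea + eb; np <- pa + pb
  flagged <- ne == 0 | np == 0
  pe <- ifelse(ne > 0, ea / ne, NA_real_)
  pp <- ifelse(np > 0, pa / np, NA_real_)
  se <- sqrt(pe * (1 - pe) / pmax(ne, 1) + pp * (1 - pp) / pmax(np, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  excess <- pe - pp
  data.frame(phase_time = event_split$above$phase_time,
             event_frac = pe, pop_frac = pp, excess = excess, se = se,
             z = excess / ifelse(se > 0, se, NA_real_),
             lo = excess - z * se, hi = excess + z * se,
             flagged = flagged)
}

#' Orientation response just before and just after life-cycle events
#'
#' For each event type, pools the hydroxyl angles of the molecules involved
#' over a pre-window (just before the event) and a post-window (just after),
#' bins each pooled sample by field phase, fits the sin/cos response
#' separately to the two windows, and reports
#' \eqn{\Delta A = |A_f| - |A_i|} (and the analogous \eqn{\Delta B}) with a
#' CI-overlap indicator. Events whose windows cross the trajectory boundary
#' are excluded and counted.
#'
#' @param events data.frame with `frame`, `time`, `type` and a `molecules`
#'   list column (as produced by [track_chains()]).
#' @param angles frames x molecules matrix of OH angles (degrees).
#' @param times frame times (ps).
#' @param field a [cr_field()].
#' @param window half-window length in ps on each side of the event.
#' @param types event types to analyse.
#' @param conf confidence level.
#' @return data.frame per event type: `type`, `n_events`, `n_excluded`,
#'   `A_i`, `B_i`, `A_f`, `B_f`, `dA`, `dB`, `ci_A_overlap`, `ci_B_overlap`.
#' @export
event_orientation_change <- function(events, angles, times, field,
                                     window = 0.5,
                                     types = c("birth", "death",
                                               "addition", "removal"),
                                     conf = 0.95) {
  period <- 2 * pi / field$omega
  fpc <- field$frames_per_cycle
  nf <- length(times)
  bin_fit <- function(t, y) {
    phase <- (t %% period) / period
    bin <- pmin(fpc, floor(phase * fpc) + 1L)
    mu <- tapply(y, bin, mean)
    bt <- (as.numeric(names(mu)) - 0.5) / fpc * period
    if (length(mu) < 4L) return(NULL)
    fit_sinusoid(as.numeric(mu), omega = field$omega, times = bt, conf = conf)
  }
  rows <- lapply(types, function(ty) {
    ev <- events[events$type == ty, , drop = FALSE]
    pre_t <- numeric(0); pre_y <- numeric(0)
    post_t <- numeric(0); post_y <- numeric(0)
    excluded <- 0L
    for (k in seq_len(nrow(ev))) {
      t0 <- ev$time[k]
      if (t0 - window < times[1] || t0 + window > times[nf]) {
        excluded <- excluded + 1L
        next
      }
      mols <- ev$molecules[[k]]
      ipre <- which(times >= t0 - window & times < t0)
      ipost <- which(times > t0 & times <= t0 + window)
      for (m in mols) {
        pre_t <- c(pre_t, times[ipre]); pre_y <- c(pre_y, angles[ipre, m])
        post_t <- c(post_t, times[ipost]); post_y <- c(post_y, angles[ipost, m])
      }
    }
    fi <- bin_fit(pre_t, pre_y); ff <- bin_fit(post_t, post_y)
    if (is.null(fi) || is.null(ff)) {
      return(data.frame(type = ty, n_events = nrow(ev) - excluded,
                        n_excluded = excluded,
                        A_i = NA_real_, B_i = NA_real_, A_f = NA_real_,
                        B_f = NA_real_, dA = NA_real_, dB = NA_real_,
                        ci_A_overlap = NA, ci_B_overlap = NA))
    }
    overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
    # CI of |x| from CI of x
    absci <- function(ci) {
      if (ci[1] <= 0 && ci[2] >= 0) c(0, max(abs(ci))) else sort(abs(ci))
    }
    data.frame(type = ty, n_events = nrow(ev) - excluded,
               n_excluded = excluded,
               A_i = fi$A, B_i = fi$B, A_f = ff$A, B_f = ff$B,
               dA = ff$absA - fi$absA, dB = ff$absB - fi$absB,
               ci_A_overlap = overlap(absci(fi$ci_A), absci(ff$ci_A)),
               ci_B_overlap = overlap(absci(fi$ci_B), absci(ff$ci_B)))
  })
  do.call(rbind, rows)
}
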