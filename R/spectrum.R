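## Equilibrium dielectric spectrum from polarization fluctuations.
##
## Classical linear response: with the box-dipole fluctuation autocorrelation
## C(t) = <dP(0) dP(t)> (mean removed) and its normalized form
## Chat(t) = C(t)/C(0), the frequency-dependent susceptibility is
##     chi(omega) = chi0 * [ 1 - i omega \int_0^inf Chat(t) e^{-i omega t} dt ]
## with the static value chi0 = <dP^2>/(3 eps0 V kB T) for the isotropic
## (vector) correlation, or <dP_a^2>/(eps0 V kB T) for a single component.
## For Chat = exp(-t/tau) this is the single-Debye form chi0/(1 + i omega tau)
## with the loss peak at omega tau = 1. Units: P in e*Angstrom, V in
## Angstrom^3, T in K; chi is dimensionless (eps = 1 + chi).

#' Autocorrelation of a polarization series
#'
#' FFT-based unbiased estimate of \eqn{\langle\delta P(0)\,\delta P(t)\rangle}
#' with the series mean removed. For a matrix input the component
#' correlations are summed (vector autocorrelation).
#'
#' @param P numeric vector (one component) or n x 3 matrix.
#' @param dt frame spacing in ps.
#' @param max_lag maximum lag in frames; default 10% of the series length.
#' @param normalize if `TRUE`, scale so C(0) = 1.
#' @return data.frame with `t` (ps) and `C`; attributes `C0` (the lag-0
#'   variance) and `dt`.
#' @export
polarization_autocorrelation <- function(P, dt, max_lag = NULL,
                                         normalize = FALSE) {
  if (is.data.frame(P)) P <- as.matrix(P)
  if (!is.matrix(P)) P <- matrix(P, ncol = 1)
  n <- nrow(P)
  if (is.null(max_lag)) max_lag <- max(1L, floor(n / 10))
  if (max_lag >= n) stop("series shorter than requested maximum lag")
  acov <- numeric(max_lag + 1L)
  nfft <- stats::nextn(2L * n)
  for (k in seq_len(ncol(P))) {
    x <- P[, k] - mean(P[, k])
    fx <- stats::fft(c(x, rep(0, nfft - n)))
    s <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / nfft
    acov <- acov + s[seq_len(max_lag + 1L)] / (n - 0:max_lag)
  }
  C0 <- acov[1]
  if (normalize) {
    if (C0 <= 0) acov[] <- 0 else acov <- acov / C0
  }
  out <- data.frame(t = (0:max_lag) * dt, C = acov)
  attr(out, "C0") <- C0
  attr(out, "dt") <- dt
  out
}

#' Dielectric spectrum from a polarization autocorrelation function
#'
#' Evaluates the one-sided Fourier-Laplace transform of the normalized
#' correlation function on a log-spaced frequency grid and scales by the
#' static susceptibility from the lag-0 variance.
#'
#' @param acf_df data.frame from [polarization_autocorrelation()] (columns
#'   `t`, `C`); need not be normalized.
#' @param temperature temperature in K.
#' @param volume box volume in Angstrom^3.
#' @param component `"single"` when the correlation is of one Cartesian
#'   component (prefactor \eqn{\langle\delta P_\alpha^2\rangle/(\epsilon_0 V
#'   k_B T)}), `"isotropic"` for the full vector correlation (additional
#'   factor 1/3).
#' @param freq_GHz frequency grid in GHz (default log-spaced 0.05-500 GHz).
#' @param decay_check warn if |C| has not decayed below this fraction of C(0)
#'   at the window end (truncation bias).
#' @return an object of class `cr_spectrum`: data.frame with `freq_GHz`,
#'   `omega`, `chi_real`, `chi_imag`; attributes `chi0`, `C0`.
#' @export
fdt_spectrum <- function(acf_df, temperature, volume,
                         component = c("single", "isotropic"),
                         freq_GHz = NULL, decay_check = 0.05) {
  component <- match.arg(component)
  dt_s <- if (length(acf_df$t) > 1) acf_df$t[2] - acf_df$t[1] else 1
  f_nyq <- radps_to_ghz(pi / dt_s)
  if (is.null(freq_GHz)) {
    freq_GHz <- 10^seq(log10(0.05), log10(min(500, f_nyq)), length.out = 120)
  } else if (any(freq_GHz > f_nyq)) {
    warning(sprintf(
      "dropping %d frequencies above the correlation Nyquist limit (%.3g GHz)",
      sum(freq_GHz > f_nyq), f_nyq))
    freq_GHz <- freq_GHz[freq_GHz <= f_nyq]
  }
  t <- acf_df$t; C <- acf_df$C
  C0 <- attr(acf_df, "C0")
  if (is.null(C0)) C0 <- C[1]
  if (C0 <= 0) {
    sp <- data.frame(freq_GHz = freq_GHz, omega = ghz_to_radps(freq_GHz),
                     chi_real = 0, chi_imag = 0)
    attr(sp, "chi0") <- 0; attr(sp, "C0") <- C0
    class(sp) <- c("cr_spectrum", "data.frame")
    return(sp)
  }
  Chat <- C / C[1]
  tail_mag <- mean(abs(Chat[max(1, length(Chat) - 9):length(Chat)]))
  if (tail_mag > decay_check)
    warning(sprintf(
      "correlation function not decayed at window end (|C|/C0 ~ %.2g); truncation bias of the same order expected",
      tail_mag))
  nfac <- if (component == "isotropic") 3 else 1
  chi0 <- C0 / (nfac * cr_constants$eps0 * volume *
                  cr_constants$kB * temperature)
  omega <- ghz_to_radps(freq_GHz)
  # one-sided transform of the piecewise-linear interpolant of Chat
  # (Filon-type: exact per segment, so accuracy is set by the sampling of
  # Chat, not by omega*dt)
  n <- length(t)
  h <- diff(t)
  c0 <- Chat[-n]; c1 <- Chat[-1]; t0 <- t[-n]
  lap <- vapply(omega, function(w) {
    if (w == 0) return(complex(real = sum((c0 + c1) / 2 * h)))
    a <- 1i * w
    ah <- a * h
    small <- Mod(ah) < 1e-3
    I0 <- ifelse(small, h * (1 - ah / 2 + ah^2 / 6), (1 - exp(-ah)) / a)
    I1 <- ifelse(small, h^2 * (1 / 2 - ah / 3 + ah^2 / 8),
                 (1 - (1 + ah) * exp(-ah)) / a^2)
    s <- (c1 - c0) / h
    sum(exp(-a * t0) * (c0 * I0 + s * I1))
  }, complex(1))
  chi <- chi0 * (1 - 1i * omega * lap)
  sp <- data.frame(freq_GHz = freq_GHz, omega = omega,
                   chi_real = Re(chi), chi_imag = -Im(chi))
  if (any(sp$chi_imag < -1e-3 * chi0))
    warning("raw spectrum has negative loss at some frequencies (estimator noise)")
  attr(sp, "chi0") <- chi0
  attr(sp, "C0") <- C0
  class(sp) <- c("cr_spectrum", "data.frame")
  sp
}

#' Fit a sum of Debye relaxation modes to a complex spectrum
#'
#' Nonlinear least squares of
#' \eqn{\chi(\omega) = \sum_k \Delta\epsilon_k/(1 + i\omega\tau_k) +
#' \epsilon_\infty} to the complex spectrum, with multi-start initialization
#' from the loss-peak positions. The slowest mode's time constant is reported
#' as the Debye relaxation time `tau_D`.
#'
#' @param spectrum a `cr_spectrum` (or data.frame with `omega`, `chi_real`,
#'   `chi_imag`).
#' @param n_modes number of relaxation modes (>= 1).
#' @param eps_inf_init initial high-frequency offset.
#' @return an object of class `cr_debye_fit`: list with `modes` (data.frame
#'   `delta_eps`, `tau`), `eps_inf`, `tau_D`, `residual`, `converged`.
#' @export
fit_relaxation_modes <- function(spectrum, n_modes = 1, eps_inf_init = 0) {
  if (n_modes < 1) stop("n_modes must be >= 1")
  w <- spectrum$omega
  obs <- complex(real = spectrum$chi_real, imaginary = -spectrum$chi_imag)
  model <- function(p) {
    de <- exp(p[seq_len(n_modes)])
    tau <- exp(p[n_modes + seq_len(n_modes)])
    einf <- p[2 * n_modes + 1]
    val <- rep(complex(real = einf, imaginary = 0), length(w))
    for (k in seq_len(n_modes)) val <- val + de[k] / (1 + 1i * w * tau[k])
    val
  }
  resid <- function(p) {
    d <- obs - model(p)
    c(Re(d), Im(d))
  }
  # initialize from loss-peak positions: local maxima of chi_imag, largest first
  li <- spectrum$chi_imag
  ord <- order(li, decreasing = TRUE)
  peaks <- ord[seq_len(min(n_modes, length(ord)))]
  tau0 <- 1 / w[peaks]
  if (length(tau0) < n_modes)
    tau0 <- c(tau0, rep(tau0[length(tau0)] / 10, n_modes - length(tau0)))
  de0 <- rep(max(2 * max(li), max(spectrum$chi_real) / n_modes), n_modes)
  starts <- list(c(log(de0), log(tau0), eps_inf_init))
  # alternative start: log-spaced taus spanning the grid
  starts[[2]] <- c(log(de0),
                   log(10^seq(log10(1 / max(w)), log10(1 / min(w)),
                              length.out = n_modes + 2)[1 + seq_len(n_modes)]),
                   eps_inf_init)
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("relaxation-mode fit failed to converge from all starts")
  p <- best$par
  de <- exp(p[seq_len(n_modes)]); tau <- exp(p[n_modes + seq_len(n_modes)])
  ord <- order(tau, decreasing = TRUE)
  structure(list(modes = data.frame(delta_eps = de[ord], tau = tau[ord]),
                 eps_inf = p[2 * n_modes + 1],
                 tau_D = max(tau),
                 residual = sqrt(best$deviance / (2 * length(w))),
                 converged = best$info %in% 1:4),
            class = "cr_debye_fit")
}

#' @export
print.cr_debye_fit <- function(x, ...) {
  cat(sprintf("<cr_debye_fit> %d mode(s), eps_inf = %.4g, tau_D = %.4g ps\n",
              nrow(x$modes), x$eps_inf, x$tau_D))
  for (k in seq_len(nrow(x$modes)))
    cat(sprintf("  mode %d: delta_eps = %.4g, tau = %.4g ps (loss peak at %.4g GHz)\n",
                k, x$modes$delta_eps[k], x$modes$tau[k],
                radps_to_ghz(1 / x$modes$tau[k])))
  invisible(x)
}

#' Evaluate a fitted Debye model on a frequency grid
#'
#' @param fit a `cr_debye_fit`.
#' @param freq_GHz frequencies in GHz.
#' @return data.frame `freq_GHz`, `chi_real`, `chi_imag`.
#' @export
debye_model_spectrum <- function(fit, freq_GHz) {
  w <- ghz_to_radps(freq_GHz)
  val <- rep(complex(real = fit$eps_inf, imaginary = 0), length(w))
  for (k in seq_len(nrow(fit$modes)))
    val <- val + fit$modes$delta_eps[k] / (1 + 1i * w * fit$modes$tau[k])
  data.frame(freq_GHz = freq_GHz, chi_real = Re(val), chi_imag = -Im(val))
}

#' Susceptibility point from an in-field polarization fit
#'
#' Converts the (A, B) sinusoid fit of the box-dipole component along the
#' field axis, from a run driven by \eqn{E(t) = E_0\sin(\omega t)}, into a
#' complex susceptibility: \eqn{\chi' = A/(\epsilon_0 E_0 V)},
#' \eqn{\chi'' = -B/(\epsilon_0 E_0 V)} (positive loss for a passive medium).
#' This is the direct-field counterpart of [fdt_spectrum()] and enables the
#' two-route consistency check.
#'
#' @param fit a `cr_sinusoid_fit` of the box dipole (e*Angstrom).
#' @param field a [cr_field()] with `amplitude > 0`.
#' @param volume box volume in Angstrom^3.
#' @return list with `freq_GHz`, `chi_real`, `chi_imag`, and propagated
#'   `se_real`, `se_imag`.
#' @export
susceptibility_from_direct_field <- function(fit, field, volume) {
  if (field$amplitude <= 0)
    stop("direct-field susceptibility requires a nonzero field amplitude")
  scale <- 1 / (cr_constants$eps0 * field$amplitude * volume)
  list(freq_GHz = radps_to_ghz(fit$omega),
       chi_real = fit$A * scale,
       chi_imag = -fit$B * scale,
       se_real = fit$se_A * scale,
       se_imag = fit$se_B * scale)
}

#' Interpolate a spectrum at given frequencies
#'
#' Log-frequency linear interpolation of the real and imaginary parts.
#'
#' @param spectrum a `cr_spectrum`.
#' @param freq_GHz frequencies in GHz.
#' @return data.frame `freq_GHz`, `chi_real`, `chi_imag`.
#' @export
interpolate_spectrum <- function(spectrum, freq_GHz) {
  lf <- log10(spectrum$freq_GHz)
  data.frame(
    freq_GHz = freq_GHz,
    chi_real = stats::approx(lf, spectrum$chi_real, log10(freq_GHz))$y,
    chi_imag = stats::approx(lf, spectrum$chi_imag, log10(freq_GHz))$y)
}
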