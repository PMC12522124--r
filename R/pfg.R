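# Gyromagnetic ratios (rad s^-1 T^-1) for nuclei used in diffusion NMR.
.gyromagnetic <- c("1H" = 2.6752218744e8, "2H" = 4.10662791e7,
                   "19F" = 2.518148e8, "31P" = 1.08394e8)

#' Gyromagnetic ratio lookup
#'
#' @param nucleus Nucleus label, e.g. \code{"1H"}.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
gyromagnetic_ratio <- function(nucleus = "1H") {
  if (!nucleus %in% names(.gyromagnetic))
    stop(sprintf("unknown nucleus '%s'; known: %s", nucleus,
                 paste(names(.gyromagnetic), collapse = ", ")))
  unname(.gyromagnetic[[nucleus]])
}

#' Pulsed-field-gradient pulse sequence
#'
#' @param Delta Diffusion (observation) time in s.
#' @param delta Gradient pulse length in s; must be < \code{Delta}.
#' @param g Gradient amplitude in T/m.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default 1H).
#' @return An object of class \code{pulse_sequence}.
#' @examples
#' pulse_sequence(Delta = 0.1, delta = 0.002, g = 0.5)
#' @export
pulse_sequence <- function(Delta, delta, g = 0, gamma = gyromagnetic_ratio("1H")) {
  stopifnot(Delta > 0, delta > 0, gamma > 0, g >= 0)
  if (!(delta < Delta)) stop("gradient pulse length 'delta' must be < 'Delta'")
  structure(list(Delta = Delta, delta = delta, g = g, gamma = gamma),
            class = "pulse_sequence")
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf("<pulse_sequence> Delta = %g ms, delta = %g ms, g = %g T/m, gamma = %g rad/s/T\n",
              x$Delta * 1e3, x$delta * 1e3, x$g, x$gamma))
  invisible(x)
}

#' Diffusion wavenumber q = gamma * delta * g
#'
#' @param seq A \code{\link{pulse_sequence}}.
#' @param g Optional gradient override (T/m).
#' @return q in rad/m.
#' @export
wavenumber <- function(seq, g = seq$g) seq$gamma * seq$delta * g

#' Echo attenuation of a freely diffusing species
#'
#' Default form \code{exp(-q^2 Delta D)} with \code{q = gamma delta g};
#' the Stejskal-Tanner form \code{exp(-q^2 (Delta - delta/3) D)} is available
#' via \code{stejskal_tanner = TRUE} (a sub-percent correction when
#' \code{delta << Delta}).
#'
#' @param D Diffusion coefficient in m^2/s, >= 0.
#' @param seq A \code{\link{pulse_sequence}}.
#' @param g Optional gradient override (T/m).
#' @param stejskal_tanner Logical; use the (Delta - delta/3) effective time.
#' @return Intensity ratio I(q)/I(0) in (0, 1].
#' @examples
#' sq <- pulse_sequence(0.1, 0.002, g = 0.5)
#' echo_attenuation(1e-10, sq)
#' @export
echo_attenuation <- function(D, seq, g = seq$g, stejskal_tanner = FALSE) {
  stopifnot(all(D >= 0))
  q <- wavenumber(seq, g)
  t_eff <- if (stejskal_tanner) seq$Delta - seq$delta / 3 else seq$Delta
  exp(-q^2 * t_eff * D)
}

#' Echo decay container
#'
#' @param q2 Squared wavenumber axis (rad^2/m^2), non-negative increasing.
#' @param intensity Normalized intensities (first point normalizes to 1).
#' @param errors Optional per-point uncertainties.
#' @return An object of class \code{echo_decay}.
#' @export
echo_decay <- function(q2, intensity, errors = NULL) {
  stopifnot(length(q2) == length(intensity), all(q2 >= 0))
  if (is.unsorted(q2)) stop("'q2' must be non-decreasing")
  if (!is.null(errors)) stopifnot(length(errors) == length(q2), all(errors > 0))
  structure(list(q2 = as.numeric(q2), intensity = as.numeric(intensity),
                 errors = errors), class = "echo_decay")
}

#' Fit a diffusion coefficient from an echo decay
#'
#' Weighted linear regression of \code{ln I} against \code{q^2 Delta};
#' the slope is \code{-D}.  Non-positive intensities are excluded with a
#' warning.  With per-point errors \code{sigma_I} the log-intensities are
#' weighted by \code{(I/sigma_I)^2}; the weights are iteratively refined
#' from the fitted curve rather than the noisy measurements, which removes
#' the weight-noise correlation bias of a single pass.
#'
#' @param decay An \code{\link{echo_decay}}.
#' @param Delta Diffusion time in s.
#' @return List with \code{D} (m^2/s), \code{D_err} (standard error) and
#'   \code{n_used}.
#' @export
fit_diffusion <- function(decay, Delta) {
  stopifnot(Delta > 0)
  ok <- decay$intensity > 0
  if (any(!ok)) warning(sprintf("%d non-positive intensities excluded", sum(!ok)))
  if (sum(ok) < 3) stop("need at least 3 positive intensities")
  x <- decay$q2[ok] * Delta
  y <- log(decay$intensity[ok])
  has_err <- !is.null(decay$errors)
  w <- if (has_err) (decay$intensity[ok] / decay$errors[ok])^2 else rep(1, sum(ok))
  fit <- stats::lm(y ~ x, weights = w)
  if (has_err) {
    for (it in 1:2) {   # reweight from the fitted, noise-free curve
      I_hat <- exp(stats::fitted(fit))
      fit <- stats::lm(y ~ x, weights = (I_hat / decay$errors[ok])^2)
    }
  }
  sm <- summary(fit)$coefficients
  list(D = -unname(sm["x", "Estimate"]), D_err = unname(sm["x", "Std. Error"]),
       n_used = sum(ok))
}

#' Select the gradient suppressing the free-polymer signal
#'
#' Finds the smallest gradient amplitude at which the free species'
#' echo attenuation falls to the requested suppression fraction, so the
#' fixed-gradient kinetic measurement sees (almost) only LUV-integrated
#' polymer.  Inverts the exponential attenuation in closed form.
#'
#' @param D_free Free-polymer diffusion coefficient (m^2/s).
#' @param seq A \code{\link{pulse_sequence}}.
#' @param suppression Target residual attenuation of the free species,
#'   in (0, 1]; default 0.02.
#' @param D_luv LUV diffusion coefficient (m^2/s), must be < \code{D_free}.
#' @param g_max Hardware gradient limit (T/m).
#' @return List with \code{g} (T/m), \code{att_free} and \code{att_luv}
#'   (residual attenuations at that gradient).
#' @export
select_gradient <- function(D_free, seq, suppression = 0.02,
                            D_luv = D_free / 20, g_max = 30) {
  stopifnot(D_free > 0, suppression > 0, suppression <= 1)
  if (!(D_luv < D_free)) stop("need D_luv < D_free (bound species slower)")
  if (suppression >= 1) return(list(g = 0, att_free = 1, att_luv = 1))
  q2_needed <- -log(suppression) / (seq$Delta * D_free)
  g <- sqrt(q2_needed) / (seq$gamma * seq$delta)
  if (g > g_max)
    stop(sprintf("suppression %g unreachable within g_max = %g T/m (needs %.3g T/m)",
                 suppression, g_max, g))
  list(g = g,
       att_free = echo_attenuation(D_free, seq, g = g),
       att_luv = echo_attenuation(D_luv, seq, g = g))
}

#' Kinetic trace container
#'
#' A fixed-gradient time-evolution measurement: intensity of the polymer
#' signal (normalized by its value at the last time) versus time.
#'
#' @param times Strictly increasing times in s.
#' @param intensity Normalized intensities \code{I0(t)/I0(t_max)}.
#' @param sigma Per-point noise standard deviation (scalar or vector).
#' @param seq Optional \code{\link{pulse_sequence}} metadata.
#' @param g Optional gradient used (T/m).
#' @return An object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(times, intensity, sigma = NULL, seq = NULL, g = NULL) {
  stopifnot(length(times) == length(intensity), all(is.finite(intensity)))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- rep_len(as.numeric(sigma), length(times))
    stopifnot(all(sigma > 0))
  }
  structure(list(times = as.numeric(times), intensity = as.numeric(intensity),
                 sigma = sigma, seq = seq, g = g),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, t in [%g, %g] s, sigma ~ %s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$sigma)) "n/a" else format(stats::median(x$sigma))))
  invisible(x)
}

#' Predicted kinetic trace from a model trajectory
#'
#' The fixed-gradient signal is the attenuation-weighted sum of the
#' LUV-integrated and free amplitudes,
#' \code{s(t) = A_luv(t) att(D_luv) + A_free(t) att(D_free)},
#' normalized by its value at the last trajectory time.  With the free
#' species fully suppressed (\code{att(D_free) = 0}) the trace equals
#' \code{\link{integrated_fraction}}.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param seq A \code{\link{pulse_sequence}}.
#' @param D_free,D_luv Diffusion coefficients (m^2/s) of free and
#'   LUV-integrated polymer.
#' @param g Gradient amplitude used (T/m); defaults to \code{seq$g}.
#' @return A \code{\link{kinetic_trace}} (noise-free, \code{sigma = NULL}).
#' @export
trace_from_trajectory <- function(traj, seq, D_free, D_luv, g = seq$g) {
  gm <- attr(traj, "geometry")
  att_f <- echo_attenuation(D_free, seq, g = g)
  att_l <- echo_attenuation(D_luv, seq, g = g)
  A_luv  <- gm$phi_mem * traj$c_m + gm$phi_in * traj$c_i
  A_free <- gm$phi_out * traj$c_o
  s <- A_luv * att_l + A_free * att_f
  denom <- s[length(s)]
  if (!(denom > 0)) stop("zero signal at t_max")
  kinetic_trace(traj$time, s / denom, seq = seq, g = g)
}
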