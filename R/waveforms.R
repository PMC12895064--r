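#' Waveform model families
#'
#' The four waveform families used throughout the package, in a fixed
#' canonical order. `"harmonic"` is the extended harmonic oscillator
#' (a sinusoid with an exponential amplitude-change envelope), `"square"`
#' is a two-component approximation of a digital square wave (carrier plus
#' third harmonic), `"cycloid"` combines a fundamental with its second
#' harmonic to produce asymmetric crests and troughs, and `"transient"` is
#' a periodic gated Gaussian impulse rising from a stable baseline.
#'
#' @return Character vector of the four waveform kind labels.
#' @export
#' @examples
#' waveform_kinds()
waveform_kinds <- function() {
  c("harmonic", "square", "cycloid", "transient")
}

check_kind <- function(kind) {
  kind <- match.arg(kind, waveform_kinds())
  kind
}

# Reject non-finite scalar parameters, naming the offending symbol.
check_finite_params <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate the extended harmonic oscillator waveform
#'
#' Computes `A * exp(gamma * t / 2) * cos(omega * t + phi) + y`: a sinusoid
#' whose amplitude decays (`gamma < 0`, damped), grows (`gamma > 0`,
#' forced) or stays constant (`gamma = 0`, stable) over the sampling
#' window.
#'
#' @param t Time in hours (vectorised).
#' @param A Initial amplitude at `t = 0`, in signal units. Must be >= 0;
#'   a sign flip is expressed through the phase `phi`.
#' @param gamma Amplitude-change coefficient, per hour.
#' @param omega Angular frequency, radians per hour (`2 * pi / period`).
#'   Must be > 0.
#' @param phi Phase shift, radians.
#' @param y Equilibrium (baseline) value, signal units.
#' @return Numeric vector of signal values, same length as `t`.
#' @export
#' @examples
#' wave_harmonic(0:23, A = 2, gamma = -0.02, omega = 2 * pi / 24)
wave_harmonic <- function(t, A, gamma = 0, omega = 2 * pi / 24, phi = 0, y = 0) {
  check_finite_params(A = A, gamma = gamma, omega = omega, phi = phi, y = y)
  if (omega <= 0) stop("parameter `omega` must be > 0", call. = FALSE)
  if (A < 0) stop("parameter `A` must be >= 0 (absorb the sign into `phi`)", call. = FALSE)
  A * exp(gamma * t / 2) * cos(omega * t + phi) + y
}

#' Evaluate the pseudo-square waveform
#'
#' A two-component approximation of a digital square wave: a sinusoidal
#' carrier plus a third-harmonic term with fixed relative amplitude 0.25,
#' `A * exp(gamma * t / 2) * (sin(omega*t + phi) + 0.25 * sin(3*omega*t +
#' 3*phi)) + y`. The amplitude envelope multiplies both components, so
#' `gamma` modulates the whole signal uniformly. The coefficient 0.25 is a
#' constant of the model, not a fitted parameter.
#'
#' @inheritParams wave_harmonic
#' @return Numeric vector of signal values, same length as `t`.
#' @export
#' @examples
#' wave_square(0:23, A = 1, omega = 2 * pi / 24)
wave_square <- function(t, A, gamma = 0, omega = 2 * pi / 24, phi = 0, y = 0) {
  check_finite_params(A = A, gamma = gamma, omega = omega, phi = phi, y = y)
  if (omega <= 0) stop("parameter `omega` must be > 0", call. = FALSE)
  if (A < 0) stop("parameter `A` must be >= 0 (absorb the sign into `phi`)", call. = FALSE)
  A * exp(gamma * t / 2) *
    (sin(omega * t + phi) + 0.25 * sin(3 * omega * t + 3 * phi)) + y
}

#' Evaluate the pseudo-cycloid waveform
#'
#' Combines a fundamental with its second harmonic (double frequency,
#' i.e. an ultradian ~12 h component under a 24 h fundamental):
#' `A * exp(gamma * t / 2) * (-0.5) * (cos(2*omega*t + 2*phi) -
#' 2 * cos(omega*t + phi)) + y`, producing asymmetric crest/trough shapes.
#' The coefficients 0.5 and 2 are constants of the model.
#'
#' @inheritParams wave_harmonic
#' @return Numeric vector of signal values, same length as `t`.
#' @export
#' @examples
#' wave_cycloid(0:23, A = 1, omega = 2 * pi / 24)
wave_cycloid <- function(t, A, gamma = 0, omega = 2 * pi / 24, phi = 0, y = 0) {
  check_finite_params(A = A, gamma = gamma, omega = omega, phi = phi, y = y)
  if (omega <= 0) stop("parameter `omega` must be > 0", call. = FALSE)
  if (A < 0) stop("parameter `A` must be >= 0 (absorb the sign into `phi`)", call. = FALSE)
  A * exp(gamma * t / 2) *
    (-0.5) * (cos(2 * omega * t + 2 * phi) - 2 * cos(omega * t + phi)) + y
}

#' Evaluate the periodic transient (impulse) waveform
#'
#' Models periodic short-lived departures from a stable baseline. With
#' cycle position `u = t mod (2*pi/omega)`, returns
#' `A * exp(-0.5 * ((u - p_tau) / sigma)^2) + y` when `u - p_tau >= 0`
#' and `y` otherwise: a Gaussian impulse of width `sigma` centred at
#' offset `p_tau` within each cycle, gated so the signal sits exactly at
#' baseline before the impulse onset. The transient carries no
#' amplitude-change envelope.
#'
#' @inheritParams wave_harmonic
#' @param p_tau Impulse offset within one cycle, hours; must satisfy
#'   `0 <= p_tau < 2 * pi / omega`.
#' @param sigma Impulse width, hours; must be > 0.
#' @return Numeric vector of signal values, same length as `t`.
#' @export
#' @examples
#' wave_transient(0:47, A = 3, omega = 2 * pi / 24, p_tau = 8, sigma = 1.5)
wave_transient <- function(t, A, omega = 2 * pi / 24, p_tau = 0, sigma = 1, y = 0) {
  check_finite_params(A = A, omega = omega, p_tau = p_tau, sigma = sigma, y = y)
  if (omega <= 0) stop("parameter `omega` must be > 0", call. = FALSE)
  if (sigma <= 0) stop("parameter `sigma` must be > 0", call. = FALSE)
  if (A < 0) stop("parameter `A` must be >= 0", call. = FALSE)
  period <- 2 * pi / omega
  if (p_tau < 0 || p_tau >= period) {
    stop("parameter `p_tau` must satisfy 0 <= p_tau < 2*pi/omega", call. = FALSE)
  }
  u <- t %% period
  ifelse(u - p_tau >= 0, A * exp(-0.5 * ((u - p_tau) / sigma)^2) + y, y)
}

#' Evaluate any waveform family from a named parameter list
#'
#' Dispatches to the evaluator for `kind`. Harmonic, square and cycloid
#' waveforms use parameters `A`, `gamma`, `omega`, `phi`, `y`; the
#' transient uses `A`, `omega`, `p_tau`, `sigma`, `y` (no envelope).
#'
#' @param kind One of `waveform_kinds()`.
#' @param t Time in hours (vectorised).
#' @param params Named list or named numeric vector of parameters.
#' @return Numeric vector of signal values.
#' @export
#' @examples
#' wave_eval("cycloid", 0:23, list(A = 1, gamma = 0, omega = 2 * pi / 24,
#'                                 phi = 0, y = 0))
wave_eval <- function(kind, t, params) {
  kind <- check_kind(kind)
  p <- as.list(params)
  switch(kind,
    harmonic = wave_harmonic(t, A = p$A, gamma = p$gamma %||% 0,
                             omega = p$omega, phi = p$phi %||% 0, y = p$y %||% 0),
    square = wave_square(t, A = p$A, gamma = p$gamma %||% 0,
                         omega = p$omega, phi = p$phi %||% 0, y = p$y %||% 0),
    cycloid = wave_cycloid(t, A = p$A, gamma = p$gamma %||% 0,
                           omega = p$omega, phi = p$phi %||% 0, y = p$y %||% 0),
    transient = wave_transient(t, A = p$A, omega = p$omega,
                               p_tau = p$p_tau %||% 0, sigma = p$sigma %||% 1,
                               y = p$y %||% 0)
  )
}

# Parameter names per family; omega is shared across components within a
# model (the 3*omega and 2*omega terms are hard-locked multiples).
param_names <- function(kind) {
  kind <- check_kind(kind)
  if (kind == "transient") c("A", "omega", "p_tau", "sigma", "y")
  else c("A", "gamma", "omega", "phi", "y")
}
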