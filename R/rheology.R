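#' Phase angle of the complex shear modulus
#'
#' The phase angle \eqn{\varphi = \arctan(G''/G')} of a complex shear
#' modulus \eqn{G^* = G' + iG''} measures how solid-like (\eqn{\varphi = 0})
#' or fluid-like (\eqn{\varphi = \pi/2}) a viscoelastic material is.
#'
#' @param gstar complex vector; storage modulus in the real part (Pa),
#'   loss modulus in the imaginary part (Pa). Both components must be
#'   non-negative and not both zero.
#' @return phase angle(s) in radians, in \eqn{[0, \pi/2]}.
#' @examples
#' phase_angle(complex(real = 500, imaginary = 500)) # pi/4
#' @export
phase_angle <- function(gstar) {
  gp <- Re(gstar)
  gpp <- Im(gstar)
  if (any(gp < 0) || any(gpp < 0)) {
    stop("storage and loss moduli must be non-negative", call. = FALSE)
  }
  if (any(gp == 0 & gpp == 0)) {
    stop("phase angle undefined: storage and loss moduli both zero",
         call. = FALSE)
  }
  atan2(gpp, gp)
}

#' Fluidity from phase angle, and back
#'
#' Fluidity is the normalised phase angle
#' \eqn{(\varphi - \varphi_0)/\varphi_0} with \eqn{\varphi_0 = \pi/4},
#' ranging from \eqn{-1} (pure solid) through 0 (solid--fluid
#' transition) to \eqn{+1} (pure liquid).
#'
#' @param phi phase angle(s) in radians, in \eqn{[0, \pi/2]}.
#' @return dimensionless fluidity in \eqn{[-1, 1]}.
#' @seealso [phase_from_fluidity()] for the inverse map.
#' @export
fluidity_from_phase <- function(phi) {
  .check_range(phi, 0, pi / 2, "phi")
  (phi - pi / 4) / (pi / 4)
}

#' @rdname fluidity_from_phase
#' @param fluidity dimensionless fluidity in \eqn{[-1, 1]}.
#' @export
phase_from_fluidity <- function(fluidity) {
  .check_range(fluidity, -1, 1, "fluidity")
  (fluidity + 1) * pi / 4
}

.check_range <- function(x, lo, hi, name, tol = 1e-12) {
  if (any(!is.finite(x)) || any(x < lo - tol) || any(x > hi + tol)) {
    stop(sprintf("%s must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

#' Convert shear-wave speed to modulus magnitude, and back
#'
#' Uses \eqn{|G^*| = c^2 \rho (1 + \cos\varphi)/2}, the standard
#' conversion between wave speed and shear modulus magnitude for a
#' lossy medium. At \eqn{\varphi = 0} this reduces to the elastic
#' identity \eqn{|G^*| = \rho c^2}.
#'
#' @param c_mps shear-wave speed in m/s (non-negative).
#' @param phi phase angle in radians, in \eqn{[0, \pi/2]}.
#' @param rho density in kg/m^3; the default 1000 is the unit density
#'   1 kg/l conventionally assumed for soft tissue.
#' @return modulus magnitude in Pa.
#' @export
modulus_from_speed <- function(c_mps, phi, rho = 1000) {
  if (any(c_mps < 0)) stop("speed must be non-negative", call. = FALSE)
  if (any(rho <= 0)) stop("density must be positive", call. = FALSE)
  .check_range(phi, 0, pi / 2, "phi")
  c_mps^2 * rho * (1 + cos(phi)) / 2
}

#' @rdname modulus_from_speed
#' @param gabs modulus magnitude \eqn{|G^*|} in Pa (non-negative).
#' @export
speed_from_modulus <- function(gabs, phi, rho = 1000) {
  if (any(gabs < 0)) stop("modulus must be non-negative", call. = FALSE)
  if (any(rho <= 0)) stop("density must be positive", call. = FALSE)
  .check_range(phi, 0, pi / 2, "phi")
  sqrt(2 * gabs / (rho * (1 + cos(phi))))
}

#' Springpot (fractional element) parameters
#'
#' The springpot interpolates between a spring (\eqn{\alpha = 0},
#' shear modulus \eqn{\mu}) and a dashpot (\eqn{\alpha = 1}, viscosity
#' \eqn{\eta}):
#' \deqn{G^*(f) = \mu^{1-\alpha}\,\eta^{\alpha}\,(i 2\pi f)^{\alpha}.}
#' Because \eqn{\mu} and \eqn{\eta} enter only through the product,
#' \eqn{\eta} is fixed to 1 Pa s by convention, leaving a two-parameter
#' model whose phase angle is frequency independent and equals
#' \eqn{\alpha \pi/2}.
#'
#' @param mu shear modulus scale in Pa, strictly positive.
#' @param alpha power-law exponent, in \eqn{[0, 1]}.
#' @param eta viscosity scale in Pa s; fixed to 1 unless deliberately
#'   overridden.
#' @return an object of class `springpot_params`.
#' @export
springpot_params <- function(mu, alpha, eta = 1) {
  stopifnot(length(mu) == 1, length(alpha) == 1, length(eta) == 1)
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  .check_range(alpha, 0, 1, "alpha")
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0", call. = FALSE)
  structure(list(mu = mu, alpha = alpha, eta = eta),
            class = "springpot_params")
}

#' @export
print.springpot_params <- function(x, ...) {
  cat(sprintf("springpot: mu = %.6g Pa, alpha = %.6g, eta = %.3g Pa s\n",
              x$mu, x$alpha, x$eta))
  cat(sprintf("  phase angle = alpha * pi/2 = %.6g rad (fluidity %.6g)\n",
              x$alpha * pi / 2, fluidity_from_phase(x$alpha * pi / 2)))
  invisible(x)
}

#' Springpot complex shear modulus at a frequency
#'
#' @param p a [springpot_params()] object.
#' @param f frequency (or vector of frequencies) in Hz, strictly positive.
#' @return complex modulus (Pa); `Re` is the storage, `Im` the loss part.
#' @export
springpot_modulus <- function(p, f) {
  stopifnot(inherits(p, "springpot_params"))
  if (any(f <= 0)) stop("frequency must be positive", call. = FALSE)
  p$mu^(1 - p$alpha) * p$eta^p$alpha * (2i * pi * f)^p$alpha
}

#' Complex wavenumber of a springpot medium
#'
#' Principal-branch dispersion relation \eqn{k^* = 2\pi f
#' \sqrt{\rho/G^*}}, oriented so that `Re(k) > 0` and `Im(k) >= 0`
#' (attenuation as a positive imaginary part).
#'
#' @inheritParams springpot_modulus
#' @param rho density in kg/m^3.
#' @return complex wavenumber(s) in rad/m.
#' @export
springpot_wavenumber <- function(p, f, rho = 1000) {
  g <- springpot_modulus(p, f)
  k <- 2 * pi * f * sqrt(rho / g)
  # principal sqrt of rho/G* gives Im <= 0 for phi in [0, pi/2]
  complex(real = Re(k), imaginary = abs(Im(k)))
}

#' Wave speed and penetration rate from a complex wavenumber
#'
#' For \eqn{k^* = k' + ik''} at drive frequency \eqn{f}:
#' \eqn{c = 2\pi f / k'} and \eqn{a = f / k''}. A lossless wave
#' (\eqn{k'' = 0}) yields an infinite penetration rate flagged via the
#' `lossless` column.
#'
#' @param k complex wavenumber(s) in rad/m, `Re(k) > 0`, `Im(k) >= 0`.
#' @param f drive frequency(ies) in Hz, positive.
#' @return data.frame with columns `c_mps`, `a_mps`, `lossless`.
#' @export
wavenumber_to_speed_attenuation <- function(k, f) {
  kp <- Re(k)
  kpp <- Im(k)
  if (any(kp <= 0)) stop("invalid wavenumber: Re(k) must be > 0",
                         call. = FALSE)
  if (any(kpp < 0)) stop("invalid wavenumber: Im(k) must be >= 0",
                         call. = FALSE)
  if (any(f <= 0)) stop("frequency must be positive", call. = FALSE)
  lossless <- kpp == 0
  a <- ifelse(lossless, Inf, f / kpp)
  data.frame(c_mps = 2 * pi * f / kp, a_mps = a, lossless = lossless)
}

#' Per-frequency dispersion table
#'
#' Canonical container for multifrequency wave measurements: either the
#' complex wavenumber per frequency or the equivalent speed/penetration
#' pair. Frequencies must be strictly increasing and positive.
#'
#' @param freq_hz frequencies in Hz.
#' @param k optional complex wavenumbers (rad/m).
#' @param c_mps,a_mps optional speed (m/s) and penetration rate (m/s);
#'   used when `k` is not given. `a_mps = Inf` marks a lossless entry.
#' @return data.frame of class `dispersion_table` with columns
#'   `freq_hz`, `c_mps`, `a_mps`, `k_re`, `k_im`, `lossless`.
#' @export
dispersion_table <- function(freq_hz, k = NULL, c_mps = NULL, a_mps = NULL) {
  if (any(freq_hz <= 0) || any(diff(freq_hz) <= 0)) {
    stop("frequencies must be positive and strictly increasing",
         call. = FALSE)
  }
  if (!is.null(k)) {
    stopifnot(length(k) == length(freq_hz))
    ca <- wavenumber_to_speed_attenuation(k, freq_hz)
    out <- data.frame(freq_hz = freq_hz, c_mps = ca$c_mps, a_mps = ca$a_mps,
                      k_re = Re(k), k_im = Im(k), lossless = ca$lossless)
  } else {
    stopifnot(!is.null(c_mps), !is.null(a_mps),
              length(c_mps) == length(freq_hz),
              length(a_mps) == length(freq_hz))
    if (any(c_mps <= 0)) stop("speeds must be positive", call. = FALSE)
    if (any(a_mps <= 0)) stop("penetration rates must be positive",
                              call. = FALSE)
    out <- data.frame(freq_hz = freq_hz, c_mps = c_mps, a_mps = a_mps,
                      k_re = 2 * pi * freq_hz / c_mps,
                      k_im = ifelse(is.infinite(a_mps), 0, freq_hz / a_mps),
                      lossless = is.infinite(a_mps))
  }
  class(out) <- c("dispersion_table", "data.frame")
  out
}

#' Point summary of viscoelastic state at a reference frequency
#'
#' @param c_mps shear-wave speed in m/s.
#' @param a_mps penetration rate in m/s (may be `Inf` for lossless).
#' @param phi phase angle in radians.
#' @param gabs modulus magnitude in Pa.
#' @param rho density in kg/m^3.
#' @param freq_hz the frequency the summary refers to.
#' @return object of class `viscoelastic_summary`.
#' @export
viscoelastic_summary <- function(c_mps, a_mps, phi, gabs, rho = 1000,
                                 freq_hz = NA_real_) {
  .check_range(phi, 0, pi / 2, "phi")
  stopifnot(c_mps >= 0, gabs >= 0, rho > 0)
  structure(list(c_mps = c_mps, a_mps = a_mps, phi = phi,
                 fluidity = fluidity_from_phase(phi), gabs = gabs,
                 rho = rho, freq_hz = freq_hz),
            class = "viscoelastic_summary")
}

#' @export
print.viscoelastic_summary <- function(x, ...) {
  cat(sprintf(paste0("viscoelastic summary at %g Hz: c = %.4g m/s, ",
                     "fluidity = %.4g, |G*| = %.4g Pa, a = %.4g m/s\n"),
              x$freq_hz, x$c_mps, x$fluidity, x$gabs, x$a_mps))
  invisible(x)
}

#' Fit the two-parameter springpot to a dispersion table
#'
#' Minimises the joint relative squared residual of the model-predicted
#' speed \eqn{c(f)} and penetration rate \eqn{a(f)} against the table
#' (lossless entries contribute only a speed residual). The model curves
#' come from the springpot modulus through the dispersion relation
#' \eqn{k^* = 2\pi f\sqrt{\rho/G^*}}. Initial values are closed-form:
#' \eqn{\alpha_0 = 2\bar\varphi/\pi} from the median per-frequency phase
#' implied by \eqn{2\,\mathrm{atan}(k''/k')}, and \eqn{\mu_0} by solving
#' the springpot magnitude at the median frequency.
#'
#' @param d a [dispersion_table()].
#' @param rho density in kg/m^3.
#' @param report_freq frequency (Hz) at which the returned summary is
#'   evaluated; 500 Hz is the conventional mid-band report point for
#'   tabletop gel measurements.
#' @return list with elements `params` ([springpot_params()]),
#'   `summary` ([viscoelastic_summary()]), `objective`, `convergence`
#'   and `message`.
#' @export
fit_springpot <- function(d, rho = 1000, report_freq = 500) {
  stopifnot(inherits(d, "dispersion_table"))
  if (nrow(d) < 3) {
    stop("underdetermined: need at least 3 frequencies to fit a springpot",
         call. = FALSE)
  }
  f <- d$freq_hz
  c_obs <- d$c_mps
  a_obs <- d$a_mps
  # entries with numerically-zero attenuation are treated as lossless
  lossy <- !d$lossless & d$k_im > 1e-9 * d$k_re

  model_ca <- function(mu, alpha) {
    k <- springpot_wavenumber(springpot_params(mu, alpha), f, rho)
    list(c = 2 * pi * f / Re(k),
         a = ifelse(Im(k) > 0, f / Im(k), Inf))
  }
  obj <- function(par) {
    mu <- exp(par[1])
    alpha <- par[2]
    m <- model_ca(mu, alpha)
    r <- (m$c - c_obs) / c_obs
    if (any(lossy)) {
      ra <- (m$a[lossy] - a_obs[lossy]) / a_obs[lossy]
      ra[!is.finite(ra)] <- 1e6 # lossless model against lossy datum
      r <- c(r, ra)
    }
    sum(r^2)
  }

  # closed-form warm start from the per-frequency implied phase
  phi_i <- 2 * atan2(d$k_im, d$k_re)
  alpha0 <- min(max(stats::median(2 * phi_i / pi), 0), 0.99)
  i_med <- which.min(abs(f - stats::median(f)))
  gabs_med <- modulus_from_speed(c_obs[i_med],
                                 min(phi_i[i_med], pi / 2), rho)
  mu0 <- if (alpha0 < 0.995) {
    (gabs_med / (2 * pi * f[i_med])^alpha0)^(1 / (1 - alpha0))
  } else {
    gabs_med
  }
  mu0 <- max(mu0, .Machine$double.xmin)

  fit <- stats::nlminb(c(log(mu0), alpha0), obj,
                       lower = c(-50, 0), upper = c(50, 1),
                       control = list(eval.max = 2000, iter.max = 1000,
                                      rel.tol = 1e-15, x.tol = 1e-14))
  # one polish pass; the objective is smooth and this tightens the optimum
  fit <- stats::nlminb(fit$par, obj, lower = c(-50, 0), upper = c(50, 1),
                       control = list(eval.max = 2000, iter.max = 1000,
                                      rel.tol = 1e-15, x.tol = 1e-14))
  if (!fit$convergence %in% c(0, 1) && fit$objective > 1e-6) {
    stop(sprintf("springpot fit failed to converge: %s (objective %.3g)",
                 fit$message, fit$objective), call. = FALSE)
  }
  params <- springpot_params(exp(fit$par[1]), fit$par[2])
  list(params = params,
       summary = springpot_summary(params, rho = rho,
                                   freq_hz = report_freq),
       objective = fit$objective,
       convergence = fit$convergence,
       message = fit$message)
}

#' Evaluate a springpot as a viscoelastic summary at one frequency
#'
#' @inheritParams springpot_modulus
#' @param rho density in kg/m^3.
#' @param freq_hz evaluation frequency in Hz.
#' @return a [viscoelastic_summary()].
#' @export
springpot_summary <- function(p, rho = 1000, freq_hz = 500) {
  g <- springpot_modulus(p, freq_hz)
  phi <- p$alpha * pi / 2
  k <- springpot_wavenumber(p, freq_hz, rho)
  viscoelastic_summary(
    c_mps = 2 * pi * freq_hz / Re(k),
    a_mps = if (Im(k) > 0) freq_hz / Im(k) else Inf,
    phi = phi, gabs = Mod(g), rho = rho, freq_hz = freq_hz)
}

#' Read / write a dispersion table CSV
#'
#' Accepts either `freq_hz, k_re, k_im` or `freq_hz, c_mps, a_mps`
#' columns (comma separated, `.` decimal, header required). `Inf` in
#' `a_mps` marks lossless entries.
#'
#' @param path file path.
#' @return [read_dispersion_csv()]: a [dispersion_table()].
#' @export
read_dispersion_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("k_re", "k_im") %in% names(x))) {
    dispersion_table(x$freq_hz, k = complex(real = x$k_re,
                                            imaginary = x$k_im))
  } else if (all(c("c_mps", "a_mps") %in% names(x))) {
    dispersion_table(x$freq_hz, c_mps = x$c_mps, a_mps = x$a_mps)
  } else {
    stop("dispersion CSV needs columns freq_hz,k_re,k_im or freq_hz,c_mps,a_mps",
         call. = FALSE)
  }
}

#' @rdname read_dispersion_csv
#' @param d a [dispersion_table()].
#' @export
write_dispersion_csv <- function(d, path) {
  stopifnot(inherits(d, "dispersion_table"))
  utils::write.csv(d[, c("freq_hz", "c_mps", "a_mps")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
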