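#' Radial shear-wave profile in a cylinder
#'
#' Container for a measured (or simulated) axial-displacement profile
#' across the radius of a cylindrical sample driven at one frequency.
#'
#' @param r_m radial sample positions in m, sorted, within `[0, radius_m]`.
#' @param u complex axial displacements (arbitrary units), same length.
#' @param radius_m cylinder radius in m.
#' @param freq_hz drive frequency in Hz.
#' @return object of class `cylinder_profile`.
#' @export
cylinder_profile <- function(r_m, u, radius_m, freq_hz) {
  stopifnot(length(r_m) == length(u), radius_m > 0, freq_hz > 0)
  if (length(r_m) < 8) {
    stop("need at least 8 radial samples", call. = FALSE)
  }
  if (is.unsorted(r_m) || any(r_m < 0) || any(r_m > radius_m + 1e-12)) {
    stop("positions must be sorted within [0, radius]", call. = FALSE)
  }
  structure(list(r_m = r_m, u = as.complex(u), radius_m = radius_m,
                 freq_hz = freq_hz),
            class = "cylinder_profile")
}

#' Forward model: shear waves in a z-infinite cylinder
#'
#' Analytical axial-displacement solution for a driven z-infinite
#' cylinder: \eqn{u(r) = U_0\, J_0(k^* r) / J_0(k^* R)}, so the wall
#' condition \eqn{u(R) = U_0} holds exactly. Evaluation near a zero of
#' \eqn{J_0(k^* R)} (a resonance of the lossless problem) is rejected.
#'
#' @param k complex wavenumber in rad/m.
#' @param radius_m cylinder radius in m.
#' @param r_m radial evaluation positions in m.
#' @param u0 complex drive amplitude at the wall.
#' @return complex displacements at `r_m`.
#' @export
cylinder_profile_forward <- function(k, radius_m, r_m, u0 = 1 + 0i) {
  stopifnot(radius_m > 0)
  denom <- bessel_j0_complex(k * radius_m)
  if (Mod(denom) < 1e-12) {
    stop("resonance: J0(k*R) is numerically zero", call. = FALSE)
  }
  u0 * bessel_j0_complex(k * r_m) / denom
}

#' Fit a complex wavenumber to a cylinder wave profile
#'
#' Least-squares fit of the z-infinite-cylinder forward model to a
#' measured radial profile. The residual stacks real and imaginary
#' parts (phase information is kept); the complex drive amplitude is a
#' nuisance parameter solved linearly at each candidate wavenumber. The
#' Bessel objective is multimodal, so a log-spaced grid over
#' \eqn{k' \in [\pi/2R,\ 20\pi/R]} crossed with
#' \eqn{k''/k' \in \{0.05, 0.2, 0.5\}} seeds a local refinement.
#'
#' @param p a [cylinder_profile()].
#' @param n_grid number of grid points along \eqn{k'}.
#' @param kpp_fracs grid of \eqn{k''/k'} ratios.
#' @param resonance_tol reject solutions with
#'   \eqn{|J_0(k^*R)| <} `resonance_tol` (relative to \eqn{J_0(0)=1}).
#' @return list with `k` (complex, rad/m), `u0`, `objective`,
#'   `convergence`.
#' @export
fit_cylinder_profile <- function(p, n_grid = 72L,
                                 kpp_fracs = c(0.05, 0.2, 0.5),
                                 resonance_tol = 1e-6) {
  stopifnot(inherits(p, "cylinder_profile"))
  R <- p$radius_m
  r <- p$r_m
  u <- p$u

  eval_fit <- function(kp, kpp) {
    k <- complex(real = kp, imaginary = kpp)
    jR <- bessel_j0_complex(k * R)
    if (Mod(jR) < resonance_tol) return(list(obj = Inf))
    m <- bessel_j0_complex(k * r) / jR
    mm <- sum(Mod(m)^2)
    if (mm == 0) return(list(obj = Inf))
    u0 <- sum(u * Conj(m)) / mm
    list(obj = sum(Mod(u - u0 * m)^2), u0 = u0)
  }

  kp_grid <- exp(seq(log(pi / (2 * R)), log(20 * pi / R),
                     length.out = n_grid))
  best <- list(obj = Inf)
  for (kp in kp_grid) {
    for (fr in kpp_fracs) {
      cand <- eval_fit(kp, fr * kp)
      if (cand$obj < best$obj) best <- c(cand, list(kp = kp, kpp = fr * kp))
    }
  }
  if (!is.finite(best$obj)) {
    stop("cylinder fit failed: no admissible grid point", call. = FALSE)
  }

  lower <- c(pi / (4 * R), 0)
  upper <- c(40 * pi / R, 20 * pi / R)
  objfun <- function(par) eval_fit(par[1], par[2])$obj
  fit <- stats::nlminb(c(best$kp, best$kpp), objfun,
                       lower = lower, upper = upper,
                       control = list(eval.max = 4000, iter.max = 2000,
                                      rel.tol = 1e-15, x.tol = 1e-14))
  fit <- stats::nlminb(fit$par, objfun, lower = lower, upper = upper,
                       control = list(eval.max = 4000, iter.max = 2000,
                                      rel.tol = 1e-15, x.tol = 1e-14))
  kp_hat <- fit$par[1]
  kpp_hat <- fit$par[2]
  if (kpp_hat < 1e-9 * kp_hat) kpp_hat <- 0 # numerically lossless
  # k'' = 0 is the legitimate lossless limit; a k' pinned at the box is not
  if (kp_hat <= lower[1] * (1 + 1e-9) || kp_hat >= upper[1] * (1 - 1e-9)) {
    stop(sprintf("cylinder fit pinned at k' bound (k' = %.4g rad/m)",
                 kp_hat), call. = FALSE)
  }
  final <- eval_fit(kp_hat, kpp_hat)
  list(k = complex(real = kp_hat, imaginary = kpp_hat),
       u0 = final$u0, objective = final$obj, convergence = fit$convergence)
}

#' Tabletop MRE pipeline: profiles to springpot summary
#'
#' Fits every per-frequency cylinder profile, converts the fitted
#' wavenumbers to speed and penetration rate, restricts to the fitting
#' band, fits the springpot dispersion model, and reports the
#' viscoelastic summary at the report frequency. Profiles whose fit
#' fails are dropped with a warning; the pipeline errors if fewer than
#' three usable in-band frequencies remain.
#'
#' @param profiles list of [cylinder_profile()] objects (one per
#'   frequency).
#' @param rho density in kg/m^3.
#' @param band numeric length-2 fitting band in Hz (tabletop protocol:
#'   acquisitions cover 200--2000 Hz, the model is fitted on
#'   200--800 Hz).
#' @param report_freq summary frequency in Hz.
#' @return list with `dispersion` (all usable frequencies), `params`,
#'   `summary`, `band`.
#' @export
tabletop_pipeline <- function(profiles, rho = 1000, band = c(200, 800),
                              report_freq = 500) {
  stopifnot(length(band) == 2, band[1] < band[2])
  freqs <- vapply(profiles, function(p) p$freq_hz, numeric(1))
  ord <- order(freqs)
  profiles <- profiles[ord]
  freqs <- freqs[ord]

  ks <- rep(NA_complex_, length(profiles))
  for (i in seq_along(profiles)) {
    fit <- tryCatch(fit_cylinder_profile(profiles[[i]]),
                    error = function(e) {
                      warning(sprintf("profile at %g Hz dropped: %s",
                                      freqs[i], conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) ks[i] <- fit$k
  }
  ok <- !is.na(ks)
  d_all <- dispersion_table(freqs[ok], k = ks[ok])
  in_band <- d_all$freq_hz >= band[1] & d_all$freq_hz <= band[2]
  if (sum(in_band) < 3) {
    stop("fewer than 3 usable frequencies inside the fitting band",
         call. = FALSE)
  }
  d_band <- d_all[in_band, ]
  class(d_band) <- c("dispersion_table", "data.frame")
  sp <- fit_springpot(d_band, rho = rho, report_freq = report_freq)
  list(dispersion = d_all, params = sp$params, summary = sp$summary,
       band = band)
}

#' Read / write a cylinder profile as CSV plus JSON sidecar
#'
#' The CSV carries columns `r_m, u_re, u_im`; the sidecar JSON carries
#' `{radius_m, freq_hz}`.
#'
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return [read_profile_csv()]: a [cylinder_profile()].
#' @export
read_profile_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  cylinder_profile(x$r_m, complex(real = x$u_re, imaginary = x$u_im),
                   radius_m = meta$radius_m, freq_hz = meta$freq_hz)
}

#' @rdname read_profile_csv
#' @param p a [cylinder_profile()].
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "cylinder_profile"))
  utils::write.csv(data.frame(r_m = p$r_m, u_re = Re(p$u), u_im = Im(p$u)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(radius_m = p$radius_m, freq_hz = p$freq_hz),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
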