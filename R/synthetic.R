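# Seeded generators for every input the pipeline consumes. All
# generators are deterministic under a fixed seed and attach enough
# ground truth to score downstream estimators without re-derivation.

#' Scenario presets for tabletop gel measurements
#'
#' Named springpot parameter sets matching measured collagen-gel
#' states: pure rat-tail collagen (solid-leaning network), pure
#' bovine-skin collagen (fluid-leaning, clustered network), and a
#' glutaraldehyde-crosslinked 1:2 rat/bovine mix (stiff and strongly
#' solid). Parameters are back-computed so that the springpot
#' reproduces the measured (speed, fluidity) pair at 500 Hz.
#'
#' @param name one of `"rat_tail"`, `"bovine_skin"`,
#'   `"crosslinked_mix"`.
#' @param rho density in kg/m^3.
#' @return a [springpot_params()] object with attribute `target`
#'   (list: `c_mps`, `fluidity`, `freq_hz`).
#' @export
gel_scenario <- function(name = c("rat_tail", "bovine_skin",
                                  "crosslinked_mix"),
                         rho = 1000) {
  name <- match.arg(name)
  tgt <- switch(name,
                rat_tail = list(c_mps = 0.542, fluidity = -0.176),
                bovine_skin = list(c_mps = 0.64, fluidity = 0.350),
                crosslinked_mix = list(c_mps = 1.09, fluidity = -0.754))
  tgt$freq_hz <- 500
  p <- springpot_from_target(tgt$c_mps, tgt$fluidity,
                             freq_hz = tgt$freq_hz, rho = rho)
  attr(p, "target") <- tgt
  p
}

#' Springpot parameters hitting a (speed, fluidity) target
#'
#' Analytic inversion: \eqn{\alpha = (fluidity + 1)/2}, then \eqn{\mu}
#' from the springpot magnitude matching the modulus implied by the
#' speed--modulus conversion at the target frequency.
#'
#' @param c_mps target shear-wave speed in m/s.
#' @param fluidity target fluidity.
#' @param freq_hz target frequency in Hz.
#' @param rho density in kg/m^3.
#' @return a [springpot_params()] object.
#' @export
springpot_from_target <- function(c_mps, fluidity, freq_hz = 500,
                                  rho = 1000) {
  alpha <- (fluidity + 1) / 2
  phi <- phase_from_fluidity(fluidity)
  gabs <- modulus_from_speed(c_mps, phi, rho)
  mu <- if (alpha < 1) (gabs / (2 * pi * freq_hz)^alpha)^(1 / (1 - alpha))
  else gabs
  springpot_params(mu, alpha)
}

#' Generate a springpot dispersion table
#'
#' Forward-evaluates the springpot dispersion relation on a frequency
#' grid (tabletop protocol default: 200 Hz to 2 kHz in 100 Hz steps)
#' and applies multiplicative lognormal noise of the stated relative
#' sd to the speed and penetration magnitudes -- the standard
#' magnitude-noise idiom. A pure spring (`alpha = 0`) yields lossless
#' entries (`a = Inf`) at every frequency.
#'
#' @param p a [springpot_params()] object.
#' @param freqs frequencies in Hz.
#' @param noise relative noise sd (0 = noise free).
#' @param seed integer seed; same seed, same table.
#' @param rho density in kg/m^3.
#' @return a [dispersion_table()] with attribute `truth`.
#' @export
make_dispersion <- function(p, freqs = seq(200, 2000, by = 100),
                            noise = 0, seed = NULL, rho = 1000) {
  stopifnot(all(freqs > 0), noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- springpot_wavenumber(p, freqs, rho)
  ca <- wavenumber_to_speed_attenuation(k, freqs)
  c_mps <- ca$c_mps
  a_mps <- ca$a_mps
  if (noise > 0) {
    sdlog <- sqrt(log(1 + noise^2))
    c_mps <- c_mps * stats::rlnorm(length(freqs), -sdlog^2 / 2, sdlog)
    fin <- is.finite(a_mps)
    a_mps[fin] <- a_mps[fin] *
      stats::rlnorm(sum(fin), -sdlog^2 / 2, sdlog)
  }
  out <- dispersion_table(freqs, c_mps = c_mps, a_mps = a_mps)
  attr(out, "truth") <- list(params = p, rho = rho, noise = noise)
  out
}

#' Generate per-frequency cylinder wave profiles
#'
#' Forward Bessel profiles of a springpot-filled cylinder with
#' additive complex Gaussian noise (sd relative to the RMS profile
#' amplitude). Frequencies whose wall factor \eqn{J_0(k^*R)} sits at a
#' resonance are skipped with a warning. Ground truth (parameters and
#' per-frequency wavenumbers) is attached.
#'
#' @param p a [springpot_params()] object.
#' @param radius_m cylinder radius in m (default 4 mm, a 10 mm-bore
#'   sample tube).
#' @param n_radial number of radial samples (>= 8).
#' @param freqs drive frequencies in Hz.
#' @param noise relative additive complex-noise sd.
#' @param seed integer seed.
#' @param rho density in kg/m^3.
#' @return list of [cylinder_profile()] objects with attribute
#'   `truth`.
#' @export
make_cylinder_profiles <- function(p, radius_m = 0.004, n_radial = 64,
                                   freqs = seq(200, 2000, by = 100),
                                   noise = 0, seed = NULL, rho = 1000) {
  stopifnot(radius_m > 0, n_radial >= 8, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  r <- seq(0, radius_m, length.out = n_radial)
  profiles <- list()
  ks <- complex(0)
  kept <- numeric(0)
  for (f in freqs) {
    k <- springpot_wavenumber(p, f, rho)
    u <- tryCatch(cylinder_profile_forward(k, radius_m, r),
                  error = function(e) NULL)
    if (is.null(u)) {
      warning(sprintf("frequency %g Hz at a cylinder resonance; skipped",
                      f), call. = FALSE)
      next
    }
    if (noise > 0) {
      s <- noise * sqrt(mean(Mod(u)^2))
      u <- u + complex(real = stats::rnorm(n_radial, 0, s / sqrt(2)),
                       imaginary = stats::rnorm(n_radial, 0, s / sqrt(2)))
    }
    profiles[[length(profiles) + 1]] <-
      cylinder_profile(r, u, radius_m, f)
    ks <- c(ks, k)
    kept <- c(kept, f)
  }
  attr(profiles, "truth") <- list(params = p, rho = rho, k = ks,
                                  freq_hz = kept, noise = noise)
  profiles
}

#' Specification of a 2D viscoelastic phantom
#'
#' States the world a phantom emulates: a background medium, one
#' inclusion (disk or fingered star), optional boundary blurring,
#' optional fluid islands inside the inclusion (partial fluidization
#' of a solid tumour), complex measurement noise and the drive
#' frequencies.
#'
#' @param n grid side length in pixels (square grid).
#' @param spacing_m pixel spacing in m.
#' @param background,inclusion lists `(c_mps, fluidity)`.
#' @param shape `"disk"` or `"star"`.
#' @param radius_frac inclusion radius as a fraction of the half-grid.
#' @param n_fingers,finger_amp star-shape parameters (number of
#'   fingers and relative amplitude of the radial modulation).
#' @param blur_sigma_px boundary blur sigma in pixels.
#' @param island_frac fraction of the inclusion to cover with fluid
#'   islands.
#' @param island_fluidity fluidity of the islands.
#' @param noise relative complex noise sd on the wave fields.
#' @param freqs_hz drive frequencies in Hz.
#' @param rho density in kg/m^3.
#' @param seed integer seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 96, spacing_m = 0.0025,
                         background = list(c_mps = 2, fluidity = -0.2),
                         inclusion = list(c_mps = 3, fluidity = -0.2),
                         shape = c("disk", "star"), radius_frac = 0.45,
                         n_fingers = 8, finger_amp = 0.3,
                         blur_sigma_px = 0, island_frac = 0,
                         island_fluidity = 0.3, noise = 0,
                         freqs_hz = c(40, 50, 60), rho = 1000,
                         seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(background$c_mps > 0, inclusion$c_mps > 0,
            blur_sigma_px >= 0, island_frac >= 0, island_frac <= 1)
  .check_range(background$fluidity, -1, 1, "fluidity")
  .check_range(inclusion$fluidity, -1, 1, "fluidity")
  if (radius_frac >= 1) stop("inclusion exceeds grid", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Build a phantom: truth maps, wave fields and masks
#'
#' Constructs the ground-truth parameter maps from the spec (inclusion
#' geometry, optional fluid islands, optional blurred boundary), runs
#' the Helmholtz forward solver per frequency, adds complex noise, and
#' returns everything a downstream test needs: truth maps, the wave
#' field set, the tumour mask, and generator-side feature labels
#' (`heterogeneous`, `front`).
#'
#' @param spec a [phantom_spec()].
#' @return list with `truth` ([parameter_maps()]), `fields`
#'   ([wave_field_set()], `NULL` when `freqs_hz` is empty -- cheap
#'   feature-only phantoms), `mask` (inclusion 0/1 matrix), `labels`
#'   (list with `heterogeneous`, `front`, `island_frac_realised`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  ctr <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), each = n), n, n) # columns
  yy <- matrix(rep(seq_len(n), times = n), n, n) # rows
  dx <- xx - ctr
  dy <- yy - ctr
  rr <- sqrt(dx^2 + dy^2)
  r0 <- spec$radius_frac * (n / 2 - 2)
  mask <- if (spec$shape == "disk") {
    rr <= r0
  } else {
    th <- atan2(dy, dx)
    rr <= r0 * (1 + spec$finger_amp * cos(spec$n_fingers * th)) /
      (1 + spec$finger_amp)
  }

  c_map <- matrix(spec$background$c_mps, n, n)
  fl_map <- matrix(spec$background$fluidity, n, n)
  c_map[mask] <- spec$inclusion$c_mps
  fl_map[mask] <- spec$inclusion$fluidity

  # fluid islands: random disks inside the inclusion until the target
  # coverage fraction is reached
  island_mask <- matrix(FALSE, n, n)
  if (spec$island_frac > 0) {
    target <- spec$island_frac * sum(mask)
    r_isl <- max(2, round(r0 / 6))
    tries <- 0
    while (sum(island_mask & mask) < target && tries < 400) {
      tries <- tries + 1
      cx <- stats::runif(1, ctr - r0, ctr + r0)
      cy <- stats::runif(1, ctr - r0, ctr + r0)
      d2 <- (xx - cx)^2 + (yy - cy)^2
      cand <- d2 <= r_isl^2
      if (!any(cand & mask)) next
      island_mask <- island_mask | (cand & mask)
    }
    fl_map[island_mask] <- spec$island_fluidity
  }

  if (spec$blur_sigma_px > 0) {
    c_map <- gaussian_smooth(c_map, spec$blur_sigma_px)
    fl_map <- gaussian_smooth(fl_map, spec$blur_sigma_px)
  }
  fl_map <- pmax(pmin(fl_map, 1), -1) # matrix first: dims preserved

  truth <- parameter_maps_from_cf(c_map, fl_map, spec$spacing_m,
                                  rho = spec$rho,
                                  masks = list(tumor = mask * 1))
  fields <- if (length(spec$freqs_hz) == 0) NULL else
    lapply(spec$freqs_hz, function(f) {
    u <- helmholtz_forward(truth, f, rho = spec$rho)
    if (spec$noise > 0) {
      s <- spec$noise * sqrt(mean(Mod(u)^2))
      nr <- length(u)
      u <- u + matrix(complex(real = stats::rnorm(nr, 0, s / sqrt(2)),
                              imaginary = stats::rnorm(nr, 0, s / sqrt(2))),
                      nrow(u), ncol(u))
    }
    u
  })
  frac_real <- sum(island_mask & mask) / max(sum(mask), 1)
  labels <- list(
    heterogeneous = frac_real >= 0.1 && frac_real <= 0.9,
    front = if (spec$shape == "star" || spec$blur_sigma_px >= 3)
      "diffuse" else "sharp",
    island_frac_realised = frac_real)
  list(truth = truth,
       fields = if (is.null(fields)) NULL else
         wave_field_set(fields, spec$freqs_hz, spec$spacing_m),
       mask = mask * 1, labels = labels, spec = spec)
}

#' Generate a jammed / unjammed cell-track mixture
#'
#' Jammed tracks are Ornstein-Uhlenbeck-confined walks with a
#' stationary per-axis sd below the cell radius (caged diffusion);
#' unjammed tracks are persistent random walks whose expected maximum
#' displacement over the observation exceeds two cell radii. The
#' requested fraction is realised exactly (`round(n * fraction)`
#' unjammed tracks); truth labels are attached.
#'
#' @param n number of cluster tracks.
#' @param unjammed_frac true fraction of unjammed tracks.
#' @param cell_radius_um cell radius in micrometres.
#' @param caged_sd_um stationary sd of the 3D caged displacement
#'   magnitude (default 3, i.e. 0.3 cell radii); the per-axis sd is
#'   `caged_sd_um / sqrt(3)`.
#' @param speed_um_min migration speed of unjammed cells (um/min).
#' @param duration_min observation length (default 420, a 7 h
#'   experiment imaged every 10 min).
#' @param dt_min frame interval in minutes.
#' @param persistence direction correlation per frame of the
#'   persistent walk, in `[0, 1)`.
#' @param n_stroma additional stroma-tagged single-cell tracks.
#' @param seed integer seed.
#' @return list of [cell_track()] with attribute `truth` (character
#'   labels).
#' @export
make_tracks <- function(n = 50, unjammed_frac = 0.3, cell_radius_um = 10,
                        caged_sd_um = 3, speed_um_min = 0.25,
                        duration_min = 420, dt_min = 10,
                        persistence = 0.9, n_stroma = 0, seed = NULL) {
  stopifnot(unjammed_frac >= 0, unjammed_frac <= 1, dt_min > 0)
  if (!is.null(seed)) set.seed(seed)
  nt <- floor(duration_min / dt_min) + 1
  t_min <- seq(0, by = dt_min, length.out = nt)
  n_un <- round(n * unjammed_frac)
  labels <- c(rep("unjammed", n_un), rep("jammed", n - n_un))

  ou_track <- function() {
    tau <- 30 # min; caging correlation time
    lam <- exp(-dt_min / tau)
    s_axis <- caged_sd_um / sqrt(3)
    sstep <- s_axis * sqrt(1 - lam^2)
    x <- matrix(0, nt, 3)
    for (i in 2:nt) x[i, ] <- lam * x[i - 1, ] + stats::rnorm(3, 0, sstep)
    sweep(x, 2, x[1, ]) + matrix(stats::rnorm(3, 0, 20), nt, 3,
                                 byrow = TRUE)
  }
  prw_track <- function() {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    x <- matrix(0, nt, 3)
    for (i in 2:nt) {
      dir <- persistence * dir + (1 - persistence) * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      step <- speed_um_min * dt_min * stats::rlnorm(1, -0.02, 0.2)
      x[i, ] <- x[i - 1, ] + step * dir
    }
    x + matrix(stats::rnorm(3, 0, 20), nt, 3, byrow = TRUE)
  }

  tracks <- vector("list", n + n_stroma)
  for (i in seq_len(n)) {
    xyz <- if (labels[i] == "unjammed") prw_track() else ou_track()
    tracks[[i]] <- cell_track(sprintf("cell_%03d", i), t_min, xyz,
                              "cluster")
  }
  for (j in seq_len(n_stroma)) {
    # slow single-cell migration through the ECM
    xyz <- ou_track() * 0.5
    tracks[[n + j]] <- cell_track(sprintf("stroma_%03d", j), t_min, xyz,
                                  "stroma")
  }
  attr(tracks, "truth") <- c(labels, rep("stroma", n_stroma))
  tracks
}
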