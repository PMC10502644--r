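#' Co-registered viscoelastic parameter maps
#'
#' Holds pointwise-consistent 2D maps of modulus magnitude, phase
#' angle, fluidity and shear-wave speed on a common grid. The fluidity
#' grid is the normalised phase applied pointwise and the speed grid
#' follows the speed--modulus conversion, so only `gabs` and `phi` are
#' stored independently.
#'
#' @param gabs matrix of \eqn{|G^*|} in Pa, strictly positive.
#' @param phi matrix of phase angles in rad, in \eqn{[0, \pi/2]}.
#' @param spacing_m pixel spacing in m.
#' @param rho density in kg/m^3.
#' @param masks optional named list of 0/1 matrices (ROIs).
#' @return object of class `parameter_maps` with elements `gabs`,
#'   `phi`, `fluidity`, `c_mps`, `spacing_m`, `rho`, `masks`.
#' @export
parameter_maps <- function(gabs, phi, spacing_m, rho = 1000,
                           masks = list()) {
  stopifnot(is.matrix(gabs), is.matrix(phi),
            all(dim(gabs) == dim(phi)), spacing_m > 0, rho > 0)
  ok <- !is.na(phi)
  .check_range(phi[ok], 0, pi / 2, "phi")
  if (any(gabs[!is.na(gabs)] < 0)) stop("|G*| must be >= 0", call. = FALSE)
  fluidity <- (phi - pi / 4) / (pi / 4)
  c_mps <- sqrt(2 * gabs / (rho * (1 + cos(phi))))
  structure(list(gabs = gabs, phi = phi, fluidity = fluidity,
                 c_mps = c_mps, spacing_m = spacing_m, rho = rho,
                 masks = masks),
            class = "parameter_maps")
}

#' Build parameter maps from speed and fluidity grids
#'
#' Convenience constructor used by the phantom generator: phase from
#' fluidity pointwise, modulus magnitude from the speed conversion.
#'
#' @param c_mps matrix of shear-wave speeds in m/s, strictly positive.
#' @param fluidity matrix of fluidities in \eqn{[-1, 1]}.
#' @inheritParams parameter_maps
#' @return a [parameter_maps()] object.
#' @export
parameter_maps_from_cf <- function(c_mps, fluidity, spacing_m, rho = 1000,
                                   masks = list()) {
  phi <- phase_from_fluidity(fluidity)
  dim(phi) <- dim(fluidity)
  gabs <- c_mps^2 * rho * (1 + cos(phi)) / 2
  parameter_maps(gabs, phi, spacing_m, rho = rho, masks = masks)
}

#' Multifrequency set of complex wave fields
#'
#' @param fields list of complex matrices (one per frequency), all the
#'   same dimension.
#' @param freqs_hz frequencies in Hz, one per field.
#' @param spacing_m pixel spacing in m.
#' @return object of class `wave_field_set`.
#' @export
wave_field_set <- function(fields, freqs_hz, spacing_m) {
  stopifnot(length(fields) == length(freqs_hz), length(fields) >= 1,
            spacing_m > 0)
  d <- dim(fields[[1]])
  for (f in fields) stopifnot(is.matrix(f), all(dim(f) == d))
  fields <- lapply(fields, function(m) {
    storage.mode(m) <- "complex"
    attributes(m) <- list(dim = dim(m)) # drop solver metadata
    m
  })
  structure(list(fields = fields, freqs_hz = freqs_hz,
                 spacing_m = spacing_m),
            class = "wave_field_set")
}

#' Finite-difference Helmholtz forward solver
#'
#' Solves the scalar heterogeneous Helmholtz equation
#' \deqn{\nabla^2 u + \frac{\rho\,(2\pi f)^2}{G^*(x,y)}\,u = 0}
#' on the map grid with a unit Dirichlet drive on one edge and damped
#' sponge layers (quadratic ramp of an imaginary wavenumber
#' perturbation over `sponge_px` pixels) backed by homogeneous
#' Dirichlet conditions on the remaining edges. The sparse complex
#' system is solved exactly as an equivalent real block system, so the
#' discrete residual is at direct-solver level.
#'
#' @param truth a [parameter_maps()] object with strictly positive
#'   modulus everywhere.
#' @param f drive frequency in Hz.
#' @param rho density in kg/m^3 (defaults to the maps' density).
#' @param drive_edge one of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param sponge_px sponge width in pixels.
#' @param sponge_strength peak relative imaginary perturbation of the
#'   squared wavenumber inside the sponge.
#' @return complex matrix of displacements, same dimension as the maps,
#'   with attribute `residual` (relative discrete residual norm).
#' @export
helmholtz_forward <- function(truth, f, rho = NULL,
                              drive_edge = c("left", "right", "top",
                                             "bottom"),
                              sponge_px = 8L, sponge_strength = 3) {
  stopifnot(inherits(truth, "parameter_maps"), f > 0)
  drive_edge <- match.arg(drive_edge)
  if (is.null(rho)) rho <- truth$rho
  nr <- nrow(truth$gabs)
  nc <- ncol(truth$gabs)
  if (nr < 32 || nc < 32) stop("grid must be at least 32x32", call. = FALSE)
  if (any(!is.finite(truth$gabs)) || any(truth$gabs <= 0)) {
    stop("singular system: modulus map must be strictly positive",
         call. = FALSE)
  }
  h <- truth$spacing_m
  gstar <- truth$gabs * exp(1i * truth$phi)
  omega <- 2 * pi * f

  # quadratic damping ramp on the three non-drive edges
  ramp <- function(idx, n) {
    d <- pmin(idx - 1, n - idx)
    pmin(1, pmax(0, (sponge_px - d) / sponge_px))^2
  }
  ry <- ramp(seq_len(nr), nr)
  rx <- ramp(seq_len(nc), nc)
  s <- outer(ry, rep(1, nc)) # top+bottom
  s <- pmax(s, outer(rep(1, nr), rx)) # all four edges
  # no sponge on the drive edge
  drive_cols <- switch(drive_edge, left = 1L, right = nc, NA)
  drive_rows <- switch(drive_edge, top = 1L, bottom = nr, NA)
  if (drive_edge %in% c("left", "right")) {
    cols <- if (drive_edge == "left") seq_len(sponge_px) else
      nc - seq_len(sponge_px) + 1L
    s[, cols] <- pmax(outer(ry, rep(1, sponge_px)), 0)
  } else {
    rows <- if (drive_edge == "top") seq_len(sponge_px) else
      nr - seq_len(sponge_px) + 1L
    s[rows, ] <- pmax(outer(rep(1, sponge_px), rx), 0)
  }

  q <- rho * omega^2 / gstar * (1 + 1i * sponge_strength * s)

  # boundary values: unit drive on the chosen edge, 0 elsewhere
  ubc <- matrix(0 + 0i, nr, nc)
  if (!is.na(drive_cols)) ubc[, drive_cols] <- 1 + 0i
  if (!is.na(drive_rows)) ubc[drive_rows, ] <- 1 + 0i

  interior_i <- 2:(nr - 1)
  interior_j <- 2:(nc - 1)
  ni <- length(interior_i)
  nj <- length(interior_j)
  n <- ni * nj
  idx <- matrix(0L, nr, nc)
  idx[interior_i, interior_j] <- matrix(seq_len(n), ni, nj)

  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  b <- complex(n)
  ig <- rep(interior_i, times = nj)
  jg <- rep(interior_j, each = ni)
  p <- idx[cbind(ig, jg)]
  diag_v <- -4 / h^2 + q[cbind(ig, jg)]
  ii <- c(ii, p); jj <- c(jj, p); vv <- c(vv, diag_v)
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    inb <- ig + off[1]
    jnb <- jg + off[2]
    pn <- idx[cbind(inb, jnb)]
    inner <- pn > 0
    ii <- c(ii, p[inner]); jj <- c(jj, pn[inner])
    vv <- c(vv, rep(1 / h^2, sum(inner)))
    bd <- !inner
    if (any(bd)) {
      b[p[bd]] <- b[p[bd]] - ubc[cbind(inb[bd], jnb[bd])] / h^2
    }
  }

  # real block system [Ar -Ai; Ai Ar] [ur; ui] = [br; bi]
  ii2 <- c(ii, ii, ii + n, ii + n)
  jj2 <- c(jj, jj + n, jj, jj + n)
  vv2 <- c(Re(vv), -Im(vv), Im(vv), Re(vv))
  A <- Matrix::sparseMatrix(i = ii2, j = jj2, x = vv2,
                            dims = c(2L * n, 2L * n))
  rhs <- c(Re(b), Im(b))
  sol <- Matrix::solve(A, rhs)
  uz <- complex(real = sol[seq_len(n)], imaginary = sol[n + seq_len(n)])

  u <- ubc
  u[cbind(ig, jg)] <- uz

  res <- A %*% sol - rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(Mod(ubc)^2)), 1e-300)
  attr(u, "residual") <- rel
  u
}

#' MDEV-style magnitude inversion of multifrequency wave fields
#'
#' Multifrequency direct inversion of the Helmholtz equation in
#' magnitude representation. Pointwise, with \eqn{\Delta} the 5-point
#' discrete Laplacian of the (Gaussian pre-smoothed) fields:
#' \deqn{|G^*| = \rho \frac{\sum_f (2\pi f)^2 |u_f|}{\sum_f |\Delta
#' u_f|}, \qquad \varphi = \arccos\left(\frac{-\sum_f \mathrm{Re}
#' (\Delta u_f\,\overline{u_f})}{\sum_f |\Delta u_f|\,|u_f|}\right).}
#' The arccos argument is clamped to \eqn{[0, 1]} so that noisy pixels
#' stay inside the physical phase range \eqn{[0, \pi/2]}.
#' Fluidity and speed maps follow pointwise. A two-pixel margin and
#' pixels whose Laplacian energy falls below `valid_rel` of the map
#' maximum are masked `NA`; recovered maps are invariant to a common
#' amplitude rescaling of all fields.
#'
#' @param w a [wave_field_set()]; multifrequency compounding expects
#'   at least 2 frequencies (a single-frequency set is inverted with a
#'   warning).
#' @param rho density in kg/m^3.
#' @param sigma_smooth Gaussian pre-smoothing sigma in pixels (the
#'   Laplacian amplifies noise; 1 px mirrors common MDEV practice).
#' @param valid_rel relative Laplacian-energy threshold below which a
#'   pixel is masked.
#' @param margin_px border width masked out (Laplacian support).
#' @return a [parameter_maps()] object with a `valid` mask.
#' @export
mdev_invert <- function(w, rho = 1000, sigma_smooth = 1,
                        valid_rel = 1e-9, margin_px = 2L) {
  stopifnot(inherits(w, "wave_field_set"))
  if (length(w$fields) < 2) {
    warning("single-frequency inversion: multifrequency compounding needs >= 2",
            call. = FALSE)
  }
  h <- w$spacing_m
  num_g <- den_g <- num_p <- den_p <- 0
  for (i in seq_along(w$fields)) {
    u <- gaussian_smooth(w$fields[[i]], sigma_smooth)
    lap <- laplacian5(u, h)
    om2 <- (2 * pi * w$freqs_hz[i])^2
    num_g <- num_g + om2 * Mod(u)
    den_g <- den_g + Mod(lap)
    num_p <- num_p - Re(lap * Conj(u))
    den_p <- den_p + Mod(lap) * Mod(u)
  }
  nr <- nrow(den_g)
  nc <- ncol(den_g)
  valid <- matrix(TRUE, nr, nc)
  valid[c(seq_len(margin_px), nr - seq_len(margin_px) + 1L), ] <- FALSE
  valid[, c(seq_len(margin_px), nc - seq_len(margin_px) + 1L)] <- FALSE
  thr <- valid_rel * max(den_g[valid][is.finite(den_g[valid])], 0)
  valid <- valid & is.finite(den_g) & den_g > thr & den_p > 0
  if (!any(valid)) {
    stop(structure(class = c("fluidmre_inversion_failure", "error",
                             "condition"),
                   list(message = "inversion failure: all pixels invalid",
                        call = NULL)))
  }
  gabs <- matrix(NA_real_, nr, nc)
  phi <- matrix(NA_real_, nr, nc)
  gabs[valid] <- rho * num_g[valid] / den_g[valid]
  phi[valid] <- acos(pmin(1, pmax(0, num_p[valid] / den_p[valid])))
  maps <- parameter_maps(gabs, phi, spacing_m = h, rho = rho,
                         masks = list(valid = valid * 1))
  maps
}

#' Frequency-compounded wave-speed map from local phase gradients
#'
#' Simplified plane-wave surrogate for wavenumber-based inversions:
#' the local wavenumber per frequency is the magnitude of the phase
#' gradient, computed without unwrapping via
#' \eqn{\nabla\arg u = \mathrm{Im}(\overline{u}\,\nabla u)/|u|^2};
#' then \eqn{c_f = 2\pi f / |\nabla\arg u_f|} and frequencies are
#' compounded by an amplitude-weighted average.
#'
#' @param w a [wave_field_set()].
#' @param floor_rel pixels whose phase-gradient magnitude is below
#'   `floor_rel` times the in-plane median are masked.
#' @return numeric matrix of compounded speeds (m/s) with `NA` at
#'   masked pixels.
#' @export
gradient_speed_map <- function(w, floor_rel = 1e-3) {
  stopifnot(inherits(w, "wave_field_set"))
  h <- w$spacing_m
  num <- den <- 0
  for (i in seq_along(w$fields)) {
    u <- w$fields[[i]]
    nr <- nrow(u)
    nc <- ncol(u)
    gx <- gy <- matrix(NA_complex_, nr, nc)
    gy[2:(nr - 1), ] <- (u[3:nr, ] - u[1:(nr - 2), ]) / (2 * h)
    gx[, 2:(nc - 1)] <- (u[, 3:nc] - u[, 1:(nc - 2)]) / (2 * h)
    a2 <- Mod(u)^2
    px <- Im(Conj(u) * gx) / a2
    py <- Im(Conj(u) * gy) / a2
    kmag <- sqrt(px^2 + py^2)
    kfloor <- floor_rel * stats::median(kmag, na.rm = TRUE)
    cmap <- 2 * pi * w$freqs_hz[i] / kmag
    cmap[!is.finite(cmap) | kmag < kfloor] <- NA
    wgt <- Mod(u)
    wgt[is.na(cmap)] <- 0
    cmap[is.na(cmap)] <- 0
    num <- num + wgt * cmap
    den <- den + wgt
  }
  out <- num / den
  out[den == 0] <- NA
  out
}

#' Write / read a wave-field container
#'
#' Plain-text array container: a directory with `manifest.json`
#' (`freqs_hz`, `spacing_m`, `dims`) and per-frequency CSV matrices of
#' the real and imaginary parts.
#'
#' @param w a [wave_field_set()].
#' @param dir directory path (created if absent).
#' @return [read_wave_fields()]: a [wave_field_set()].
#' @export
write_wave_fields <- function(w, dir) {
  stopifnot(inherits(w, "wave_field_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(freqs_hz = w$freqs_hz,
                            spacing_m = w$spacing_m,
                            dims = dim(w$fields[[1]])),
                       file.path(dir, "manifest.json"), digits = NA)
  for (i in seq_along(w$fields)) {
    utils::write.table(Re(w$fields[[i]]),
                       file.path(dir, sprintf("field_%02d_re.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(Im(w$fields[[i]]),
                       file.path(dir, sprintf("field_%02d_im.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_wave_fields
#' @export
read_wave_fields <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  fields <- lapply(seq_along(meta$freqs_hz), function(i) {
    re <- as.matrix(utils::read.table(
      file.path(dir, sprintf("field_%02d_re.csv", i)), sep = ","))
    im <- as.matrix(utils::read.table(
      file.path(dir, sprintf("field_%02d_im.csv", i)), sep = ","))
    m <- re + 1i * im
    dimnames(m) <- NULL
    m
  })
  wave_field_set(fields, meta$freqs_hz, meta$spacing_m)
}
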