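# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Power-series J0: sum_m (-1)^m (z^2/4)^m / (m!)^2, 30 terms — valid
# and machine-accurate for the small |z| it is used with.
j0_series <- function(z, n_terms = 30) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z^2) / 4
  for (m in seq_len(n_terms - 1)) {
    term <- term * q / m^2
    out <- out + term
  }
  out
}

# Isoperimetric roughness of the star shape r(theta) = r0(1 + a cos(n
# theta)) by adaptive quadrature of the exact perimeter and area.
star_roughness_analytic <- function(r0, amp, n_fingers) {
  per <- stats::integrate(function(th) {
    r <- r0 * (1 + amp * cos(n_fingers * th))
    dr <- -r0 * amp * n_fingers * sin(n_fingers * th)
    sqrt(r^2 + dr^2)
  }, 0, 2 * pi, subdivisions = 2000L, rel.tol = 1e-10)$value
  area <- stats::integrate(function(th) {
    (r0 * (1 + amp * cos(n_fingers * th)))^2 / 2
  }, 0, 2 * pi, rel.tol = 1e-10)$value
  per^2 / (4 * pi * area)
}

# Median of a map restricted to an interior window (sponge + mask
# margins excluded).
interior_median <- function(m, margin = 24) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  vals <- m[(margin + 1):(n1 - margin), (margin + 1):(n2 - margin)]
  stats::median(vals[!is.na(vals)])
}

# Disk mask and step fluidity map used by several feature tests.
disk_fixture <- function(n = 128, radius = 40, lo = -0.5, hi = 0.5) {
  ctr <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), each = n), n, n)
  yy <- matrix(rep(seq_len(n), times = n), n, n)
  mask <- (xx - ctr)^2 + (yy - ctr)^2 <= radius^2
  fl <- matrix(lo, n, n)
  fl[mask] <- hi
  list(mask = mask, fluidity = fl, xx = xx, yy = yy, ctr = ctr)
}
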