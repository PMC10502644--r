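#' Classify fluidity into solid / transitional / fluid regimes
#'
#' A fluidity value is labelled `solid` below the lower threshold,
#' `fluid` above the upper threshold and `transitional` in between.
#' The default thresholds of \eqn{\pm 0.1} reproduce the regime labels
#' of the packaged meta-analysis table from its per-entity means; they
#' are configuration, not constants, since a clinically validated cut
#' (e.g. by ROC analysis) may refine them.
#'
#' @param fluidity numeric vector in \eqn{[-1, 1]}.
#' @param thresholds numeric length-2 `(low, high)`, `low < high`.
#' @return factor with levels `solid`, `transitional`, `fluid`.
#' @export
regime_classify <- function(fluidity, thresholds = c(-0.1, 0.1)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  .check_range(fluidity, -1, 1, "fluidity")
  out <- ifelse(fluidity < thresholds[1], "solid",
                ifelse(fluidity > thresholds[2], "fluid", "transitional"))
  factor(out, levels = c("solid", "transitional", "fluid"))
}

#' Regime label with optional borderline dual labels
#'
#' Convention used for reporting: a mean within `borderline` of a
#' threshold gets a dual label such as `"solid/transitional"`. This is
#' a configurable reporting convention, not a rule of the scheme.
#'
#' @inheritParams regime_classify
#' @param borderline half-width of the dual-label band around each
#'   threshold; `0` disables dual labels.
#' @return character vector of labels.
#' @export
regime_label <- function(fluidity, thresholds = c(-0.1, 0.1),
                         borderline = 0.03) {
  base <- as.character(regime_classify(fluidity, thresholds))
  if (borderline > 0) {
    near_lo <- abs(fluidity - thresholds[1]) <= borderline
    near_hi <- abs(fluidity - thresholds[2]) <= borderline
    base[near_lo] <- "solid/transitional"
    base[near_hi] <- "transitional/fluid"
  }
  base
}

#' Spatial heterogeneity of a fluidity map
#'
#' Score: Shannon entropy (nats) of the occupancy fractions of the
#' three fluidity regimes inside the ROI. The map is flagged
#' heterogeneous when at least two regimes each occupy at least
#' `min_frac` of the ROI. Both quantities depend only on occupancy
#' fractions, so they are invariant under spatial shuffling and robust
#' to resolution.
#'
#' @param fluidity numeric matrix of fluidities.
#' @param roi optional logical/0-1 matrix selecting the region of
#'   interest; default: all non-`NA` pixels.
#' @param thresholds regime thresholds, see [regime_classify()].
#' @param min_frac minimum per-regime occupancy for the flag.
#' @return list with `score` (nats), `heterogeneous` (flag) and
#'   `fractions` (named numeric of length 3).
#' @export
heterogeneity_score <- function(fluidity, roi = NULL,
                                thresholds = c(-0.1, 0.1),
                                min_frac = 0.1) {
  if (is.null(roi)) roi <- !is.na(fluidity)
  roi <- roi > 0 & !is.na(fluidity)
  vals <- fluidity[roi]
  if (length(vals) == 0) stop("empty ROI", call. = FALSE)
  reg <- regime_classify(vals, thresholds)
  p <- as.numeric(table(reg)) / length(vals)
  names(p) <- levels(reg)
  nz <- p[p > 0]
  list(score = -sum(nz * log(nz)),
       heterogeneous = sum(p >= min_frac) >= 2,
       fractions = p)
}

# Marching-squares contours of a 0/1 mask. Presmoothing with a 1 px
# Gaussian removes the stairstep perimeter bias of binary contours
# (~12% -> ~1% for a digitized disk).
.mask_contours <- function(mask, presmooth = 1) {
  m <- gaussian_smooth(mask * 1, presmooth)
  grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                          z = m, levels = 0.5)
}

.poly_perimeter <- function(ct) {
  sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2))
}

.poly_area <- function(ct) {
  x <- ct$x
  y <- ct$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Tumour-front texture assessment
#'
#' Combines a shape metric and a profile metric of the tumour boundary
#' on a fluidity map:
#' * roughness: isoperimetric quotient `perimeter^2 / (4 pi area)` of
#'   the mask contour (1 for a disk, larger for fingered boundaries);
#' * gradient width: mean distance, along boundary normals, over which
#'   the fluidity traverses from 25% to 75% of the tumour--background
#'   contrast.
#'
#' The front is labelled `diffuse` when roughness exceeds
#' `roughness_thresh` or the gradient width exceeds `width_thresh_px`
#' pixels; otherwise `sharp`. The OR-combination errs toward
#' sensitivity, since fingering and border blurring are distinct
#' signatures of infiltrative spreading.
#'
#' @param fluidity numeric matrix of fluidities.
#' @param mask logical/0-1 tumour mask, nonempty with nonempty
#'   complement.
#' @param spacing_m pixel spacing in m.
#' @param roughness_thresh roughness above which the front is diffuse.
#' @param width_thresh_px gradient width (pixels) above which the
#'   front is diffuse.
#' @param n_normals number of boundary normals to probe.
#' @param probe_len_px half-length of each normal probe in pixels.
#' @param presmooth Gaussian sigma (px) applied to the mask before
#'   contouring; 1 px removes the stairstep perimeter bias of binary
#'   marching squares.
#' @return object of class `front_assessment`: list with `label`,
#'   `roughness`, `gradient_width_px`, `gradient_width_m`,
#'   `n_normals_used`.
#' @export
front_texture <- function(fluidity, mask, spacing_m = 1,
                          roughness_thresh = 1.5, width_thresh_px = 3,
                          n_normals = 120L, probe_len_px = 12,
                          presmooth = 1) {
  mask <- mask > 0
  if (!any(mask) || all(mask)) {
    stop("mask must be nonempty with nonempty complement", call. = FALSE)
  }
  if (any(mask[c(1, nrow(mask)), ]) || any(mask[, c(1, ncol(mask))])) {
    warning("mask touches the image edge; affected normals excluded",
            call. = FALSE)
  }
  cts <- .mask_contours(mask, presmooth)
  if (length(cts) == 0) stop("no contour found for mask", call. = FALSE)
  per <- sum(vapply(cts, .poly_perimeter, numeric(1)))
  area <- sum(vapply(cts, .poly_area, numeric(1)))
  roughness <- per^2 / (4 * pi * area)

  # gradient width along normals of the largest contour
  main <- cts[[which.max(vapply(cts, .poly_area, numeric(1)))]]
  x <- main$x
  y <- main$y
  npt <- length(x)
  pick <- unique(round(seq(1, npt, length.out = min(n_normals, npt))))
  lo_med <- stats::median(fluidity[!mask], na.rm = TRUE)
  hi_med <- stats::median(fluidity[mask], na.rm = TRUE)
  contrast <- hi_med - lo_med
  widths <- numeric(0)
  if (abs(contrast) > 1e-12) {
    ts <- seq(-probe_len_px, probe_len_px, by = 0.25)
    q25 <- lo_med + 0.25 * contrast
    q75 <- lo_med + 0.75 * contrast
    for (i in pick) {
      i2 <- if (i < npt) i + 1L else 1L
      tx <- x[i2] - x[i]
      ty <- y[i2] - y[i]
      nrm <- sqrt(tx^2 + ty^2)
      if (nrm == 0) next
      nxv <- -ty / nrm
      nyv <- tx / nrm
      rr <- x[i] + ts * nxv
      cc <- y[i] + ts * nyv
      if (any(rr < 1 | rr > nrow(fluidity) | cc < 1 | cc > ncol(fluidity))) {
        next # normal leaves the image
      }
      prof <- .bilinear(fluidity, rr, cc)
      if (any(is.na(prof))) next
      # orient the probe from background to tumour
      if (prof[1] > prof[length(prof)]) prof <- rev(prof)
      if (contrast < 0) prof <- rev(prof)
      frac <- (prof - lo_med) / contrast
      i25 <- which(frac >= 0.25)[1]
      i75 <- which(frac >= 0.75)[1]
      if (is.na(i25) || is.na(i75) || i75 <= i25) next
      widths <- c(widths, (i75 - i25) * 0.25)
    }
  }
  gw <- if (length(widths)) mean(widths) else NA_real_
  label <- if (roughness > roughness_thresh ||
               (is.finite(gw) && gw > width_thresh_px)) "diffuse" else "sharp"
  structure(list(label = label, roughness = roughness,
                 gradient_width_px = gw,
                 gradient_width_m = gw * spacing_m,
                 n_normals_used = length(widths)),
            class = "front_assessment")
}

#' @export
print.front_assessment <- function(x, ...) {
  cat(sprintf("front: %s (roughness %.3f, gradient width %.2f px, %d normals)\n",
              x$label, x$roughness, x$gradient_width_px, x$n_normals_used))
  invisible(x)
}

#' Saffman-Taylor interfacial stability criterion for a tumour front
#'
#' A growing tumour pushing into its host behaves like one viscous
#' phase displacing another; the interface is predicted unstable
#' (viscous fingering) when
#' \deqn{\frac{\sin\varphi_{tumor}}{\sin\varphi_{control}} <
#' \frac{|G^*_{control}|}{|G^*_{tumor}|}.}
#'
#' @param phi_tumor,phi_control phase angles in rad, in
#'   \eqn{(0, \pi/2]}; a zero control phase leaves the criterion
#'   undefined.
#' @param g_tumor,g_control modulus magnitudes in Pa, positive.
#' @return logical flag: `TRUE` when the boundary is predicted
#'   unstable.
#' @export
saffman_taylor_unstable <- function(phi_tumor, phi_control,
                                    g_tumor, g_control) {
  .check_range(phi_tumor, 0, pi / 2, "phi_tumor")
  .check_range(phi_control, 0, pi / 2, "phi_control")
  if (any(sin(phi_control) == 0)) {
    stop("criterion undefined: sin(phi_control) = 0", call. = FALSE)
  }
  if (any(g_tumor <= 0) || any(g_control <= 0)) {
    stop("moduli must be positive", call. = FALSE)
  }
  sin(phi_tumor) / sin(phi_control) < g_control / g_tumor
}

#' Saffman-Taylor criterion from speed / fluidity summaries
#'
#' Convenience wrapper converting `(c, fluidity)` pairs to phase angle
#' and modulus magnitude before applying [saffman_taylor_unstable()].
#'
#' @param c_tumor,c_control shear-wave speeds in m/s.
#' @param fl_tumor,fl_control fluidities in \eqn{[-1, 1]}.
#' @param rho density in kg/m^3.
#' @return logical flag.
#' @export
saffman_taylor_from_cf <- function(c_tumor, fl_tumor, c_control,
                                   fl_control, rho = 1000) {
  pt <- phase_from_fluidity(fl_tumor)
  pc <- phase_from_fluidity(fl_control)
  saffman_taylor_unstable(pt, pc,
                          modulus_from_speed(c_tumor, pt, rho),
                          modulus_from_speed(c_control, pc, rho))
}
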