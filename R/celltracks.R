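#' A 3D cell trajectory
#'
#' @param cell_id identifier.
#' @param t_min strictly increasing time points in minutes (>= 2).
#' @param xyz_um numeric matrix (n x 3) of positions in micrometres.
#' @param region `"cluster"` (dense cancer-cell cluster) or
#'   `"stroma"` (single cells in the stroma-like region, to which the
#'   caging criterion does not apply).
#' @return object of class `cell_track`.
#' @export
cell_track <- function(cell_id, t_min, xyz_um,
                       region = c("cluster", "stroma")) {
  region <- match.arg(region)
  xyz_um <- as.matrix(xyz_um)
  stopifnot(ncol(xyz_um) == 3, nrow(xyz_um) == length(t_min),
            length(t_min) >= 2, all(is.finite(xyz_um)),
            all(diff(t_min) > 0))
  structure(list(cell_id = cell_id, t_min = t_min, xyz_um = xyz_um,
                 region = region),
            class = "cell_track")
}

#' Displacement from the track origin over time
#'
#' @param track a [cell_track()].
#' @return data.frame with columns `t_min` and `d_um`, the Euclidean
#'   distance from the first position (`d_um[1] == 0`).
#' @export
displacement_series <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  rel <- sweep(track$xyz_um, 2, track$xyz_um[1, ])
  data.frame(t_min = track$t_min, d_um = sqrt(rowSums(rel^2)))
}

#' Jammed / unjammed classification of a cluster track
#'
#' A cell inside a dense cluster is unjammed when its maximum
#' displacement from the origin exceeds one cell radius -- the caging
#' scale of jammed, solid-like clusters. Maximum (not end-to-end)
#' displacement is used because caged motion can end near its start.
#' The criterion applies only to cluster cells; stroma-tagged single
#' cells get `"not_applicable"`.
#'
#' @param track a [cell_track()].
#' @param cell_radius_um cell radius in micrometres (default 10).
#' @return `"jammed"`, `"unjammed"` or `"not_applicable"`.
#' @export
classify_track <- function(track, cell_radius_um = 10) {
  stopifnot(inherits(track, "cell_track"), cell_radius_um > 0)
  if (track$region == "stroma") return("not_applicable")
  d <- displacement_series(track)$d_um
  if (max(d) > cell_radius_um) "unjammed" else "jammed"
}

#' Fraction of unjammed cells in a track ensemble
#'
#' @param tracks list of [cell_track()] objects.
#' @param cell_radius_um cell radius in micrometres.
#' @param conf confidence level of the Wilson score interval.
#' @return list with `fraction`, `n_applicable`, `n_unjammed`,
#'   `ci` (Wilson interval, length 2).
#' @export
unjammed_fraction <- function(tracks, cell_radius_um = 10, conf = 0.95) {
  labels <- vapply(tracks, classify_track, character(1),
                   cell_radius_um = cell_radius_um)
  applicable <- labels != "not_applicable"
  n <- sum(applicable)
  if (n == 0) stop("no applicable (cluster) tracks", call. = FALSE)
  x <- sum(labels == "unjammed")
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(fraction = p, n_applicable = n, n_unjammed = x,
       ci = c(max(0, centre - half), min(1, centre + half)))
}

#' Read / write cell tracks as TSV
#'
#' Columns: `cell_id, t_min, x_um, y_um, z_um, region`.
#'
#' @param path file path.
#' @return [read_tracks_tsv()]: list of [cell_track()] objects.
#' @export
read_tracks_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lapply(split(x, x$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    cell_track(d$cell_id[1], d$t_min,
               cbind(d$x_um, d$y_um, d$z_um), d$region[1])
  })
}

#' @rdname read_tracks_tsv
#' @param tracks list of [cell_track()] objects.
#' @export
write_tracks_tsv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(cell_id = tr$cell_id, t_min = tr$t_min,
               x_um = tr$xyz_um[, 1], y_um = tr$xyz_um[, 2],
               z_um = tr$xyz_um[, 3], region = tr$region)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
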