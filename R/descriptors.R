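#' Scalar time series container
#'
#' @param time_ps Frame times in ps, strictly increasing.
#' @param value Values (A or unitless).
#' @param label Short series label.
#' @return A `scalar_series` data.frame with columns `time_ps`, `value`.
#' @export
scalar_series <- function(time_ps, value, label = "") {
  if (length(time_ps) != length(value)) {
    gtb_shape_error("time and value lengths differ")
  }
  if (length(time_ps) > 1 && any(diff(time_ps) <= 0)) {
    gtb_shape_error("times must be strictly increasing")
  }
  out <- data.frame(time_ps = time_ps, value = value)
  attr(out, "label") <- label
  class(out) <- c("scalar_series", "data.frame")
  out
}

#' @export
print.scalar_series <- function(x, ...) {
  cat("<scalar_series '", attr(x, "label"), "'> ", nrow(x), " points, mean ",
      fmt_num(mean(x$value)), ", range [", fmt_num(min(x$value)), ", ",
      fmt_num(max(x$value)), "]\n", sep = "")
  invisible(x)
}

#' Per-frame C-alpha RMSD against a fixed reference
#'
#' Each frame is first superposed on the reference over `fit_selection`, then
#' the RMSD is measured over `measure_selection`. Setting both selections to
#' one domain gives the per-domain RMSD that reports exclusively on that
#' domain's internal structure; setting `measure_selection` to the residues of
#' one secondary-structure class within a domain (while fitting on the domain)
#' gives the per-ss-class RMSD.
#'
#' @param traj A `calpha_trajectory`.
#' @param reference A `structure_model`, frame index, or `n x 3` matrix
#'   (typically the crystal structure).
#' @param fit_selection,measure_selection Residue-number selections
#'   (default: all residues).
#' @param fit Set `FALSE` to skip superposition and measure directly.
#' @return A `scalar_series` of RMSD (A) per frame.
#' @export
rmsd_series <- function(traj, reference = 1, fit_selection = NULL,
                        measure_selection = NULL, fit = TRUE) {
  ref <- reference_coords(traj, reference)
  fsel <- residue_index(traj, fit_selection)
  msel <- residue_index(traj, measure_selection)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    if (fit) x <- apply_transform(x, kabsch_fit(x, ref, fsel))
    sqrt(sum((x[msel, , drop = FALSE] - ref[msel, , drop = FALSE])^2) /
           length(msel))
  }, numeric(1))
  scalar_series(frame_times(traj), vals, "rmsd")
}

#' Fraction of frames per RMSD band
#'
#' Bands are the half-open intervals below the first edge, between
#' consecutive edges, and at/above the last edge.
#'
#' @param series A `scalar_series` (e.g. from [rmsd_series()]).
#' @param edges Strictly increasing band edges in A (default `c(2, 3)`).
#' @return Named numeric vector of percentages summing to 100.
#' @export
rmsd_band_fractions <- function(series, edges = c(2, 3)) {
  if (nrow(series) == 0) gtb_shape_error("empty series")
  if (length(edges) < 1 || any(diff(edges) <= 0)) {
    gtb_argument_error("edges must be strictly increasing")
  }
  breaks <- c(-Inf, edges, Inf)
  cnt <- table(cut(series$value, breaks, right = FALSE))
  pct <- 100 * as.numeric(cnt) / nrow(series)
  names(pct) <- c(sprintf("<%g", edges[1]),
                  if (length(edges) > 1)
                    sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
                  sprintf(">=%g", edges[length(edges)]))
  pct
}

#' Per-residue C-alpha RMSF
#'
#' Root-mean-square fluctuation of each residue about its mean position,
#' `sqrt(mean(|r_i - <r_i>|^2))` with 3D displacement norms. The trajectory
#' must already be aligned (see [align_to_mean()]).
#'
#' @param aligned_traj An aligned `calpha_trajectory` with >= 2 frames.
#' @return An `rmsf_profile` data.frame: `chain`, `resnum`, `resname`, `rmsf`.
#' @export
rmsf_profile <- function(aligned_traj) {
  if (n_frames(aligned_traj) < 2) {
    gtb_shape_error("RMSF undefined for a single-frame trajectory")
  }
  mu <- mean_structure(aligned_traj)
  dev <- sweep(aligned_traj$coords, c(2, 3), mu)
  msf <- apply(dev^2, 2, sum) / n_frames(aligned_traj)
  out <- cbind(aligned_traj$residues, rmsf = sqrt(msf))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Flag flexible regions from an RMSF profile
#'
#' Maximal contiguous runs of residues whose RMSF exceeds the threshold,
#' annotated with the domain and secondary-structure classes they span.
#'
#' @param profile An `rmsf_profile`.
#' @param threshold RMSF threshold in A (default 2.0).
#' @param domains Optional `domain_map` for annotation.
#' @param ss Optional `ss_annotation` for annotation.
#' @return data.frame with columns `start`, `end`, `n_res`, `max_rmsf`,
#'   `domains`, `ss_classes` (one row per run; zero rows if none).
#' @export
flag_flexible_regions <- function(profile, threshold = 2.0, domains = NULL,
                                  ss = NULL) {
  if (threshold <= 0) gtb_argument_error("threshold must be positive")
  hot <- profile$rmsf > threshold
  if (!any(hot)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_res = integer(0), max_rmsf = numeric(0),
                      domains = character(0), ss_classes = character(0)))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- do.call(rbind, lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    resn <- profile$resnum[i]
    dlab <- if (is.null(domains)) NA_character_ else
      paste(sort(unique(stats::na.omit(domain_of(domains, resn)))),
            collapse = ",")
    slab <- if (is.null(ss)) NA_character_ else
      paste(sort(unique(ss$class[match(resn, ss$resnum)])), collapse = ",")
    data.frame(start = resn[1], end = resn[length(resn)],
               n_res = length(resn), max_rmsf = max(profile$rmsf[i]),
               domains = dlab, ss_classes = slab)
  }))
  rownames(out) <- NULL
  out
}

#' Per-frame C-alpha radius of gyration
#'
#' Unweighted RMS distance of the C-alpha atoms from their centroid; no
#' alignment is needed since the quantity is rigid-motion invariant.
#'
#' @param traj A `calpha_trajectory`.
#' @return A `scalar_series` of RGYR (A) per frame.
#' @export
rgyr_series <- function(traj) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    xc <- sweep(x, 2, colMeans(x))
    sqrt(sum(xc^2) / nrow(x))
  }, numeric(1))
  scalar_series(frame_times(traj), vals, "rgyr")
}

#' Pearson correlation of two scalar series
#'
#' @param a,b `scalar_series` of equal length (>= 3) with nonzero variance.
#' @return Pearson r in `[-1, 1]`.
#' @export
series_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || nrow(a) < 3) {
    gtb_shape_error("series must have equal length >= 3")
  }
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
    gtb_degeneracy_error("zero variance in series")
  }
  stats::cor(a$value, b$value)
}

#' Per-frame inter-domain centroid distance
#'
#' Euclidean distance between the unweighted C-alpha centroids of two
#' domains; the standard open/closed order parameter for hinged proteins.
#'
#' @param traj A `calpha_trajectory`.
#' @param domain_map A `domain_map`.
#' @param a,b Domain labels (default `N` and `C`).
#' @return A `scalar_series` of distances (A).
#' @export
interdomain_distance_series <- function(traj, domain_map, a = "N", b = "C") {
  ia <- residue_index(traj, domain_residues(domain_map, a))
  ib <- residue_index(traj, domain_residues(domain_map, b))
  ca <- apply(traj$coords[, ia, , drop = FALSE], c(1, 3), mean)
  cb <- apply(traj$coords[, ib, , drop = FALSE], c(1, 3), mean)
  scalar_series(frame_times(traj), sqrt(rowSums((ca - cb)^2)),
                sprintf("dist_%s_%s", a, b))
}

#' Gaussian kernel density of a distance series
#'
#' Density estimated on a uniform grid spanning `min - 3*bw` to `max + 3*bw`
#' and renormalised to integrate to 1 on that grid. Modes are local maxima
#' whose density exceeds 5% of the global maximum (suppressing kernel
#' ripples; configurable).
#'
#' @param series A `scalar_series` with >= 10 points.
#' @param bandwidth Gaussian kernel sd in A.
#' @param mode_threshold Minimum mode height as a fraction of the global
#'   maximum (default 0.05).
#' @param n_grid Number of grid points (default 512).
#' @return A `distance_density` list: `grid` (A), `density` (1/A) and
#'   `modes` (data.frame `location`, `density`).
#' @export
distance_density <- function(series, bandwidth, mode_threshold = 0.05,
                             n_grid = 512) {
  x <- series$value
  if (length(x) < 10) gtb_shape_error("need >= 10 points for density")
  if (bandwidth <= 0) gtb_argument_error("bandwidth must be positive")
  d <- stats::density(x, bw = bandwidth, kernel = "gaussian",
                      from = min(x) - 3 * bandwidth,
                      to = max(x) + 3 * bandwidth, n = n_grid)
  dens <- d$y / trapz(d$x, d$y)
  is_max <- c(FALSE, dens[2:(n_grid - 1)] > dens[1:(n_grid - 2)] &
                dens[2:(n_grid - 1)] >= dens[3:n_grid], FALSE)
  keep <- is_max & dens > mode_threshold * max(dens)
  modes <- data.frame(location = d$x[keep], density = dens[keep])
  structure(list(grid = d$x, density = dens, modes = modes),
            class = "distance_density")
}

#' @export
print.distance_density <- function(x, ...) {
  cat("<distance_density> ", length(x$grid), " grid points, ",
      nrow(x$modes), " mode(s) at ",
      paste(fmt_num(x$modes$location, 3), collapse = ", "), " A\n", sep = "")
  invisible(x)
}

#' Lowess smoothing of a scalar series
#'
#' Classic tricube-weighted local linear regression with two robustness
#' iterations, evaluated on the input time grid.
#'
#' @param series A `scalar_series` with >= 5 points.
#' @param fraction Smoother span in (0, 1] (default 0.3).
#' @return The smoothed `scalar_series`.
#' @export
lowess_smooth <- function(series, fraction = 0.3) {
  if (fraction <= 0 || fraction > 1) {
    gtb_argument_error("fraction must be in (0, 1]")
  }
  if (nrow(series) < 5) gtb_shape_error("need >= 5 points to smooth")
  sm <- stats::lowess(series$time_ps, series$value, f = fraction, iter = 2,
                      delta = 0)
  scalar_series(sm$x, sm$y, paste0(attr(series, "label"), "_lowess"))
}

#' Export a scalar series as TSV
#'
#' @param series A `scalar_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an RMSF profile as TSV
#'
#' @param profile An `rmsf_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
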