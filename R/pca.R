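#' Quasiharmonic PCA of an aligned C-alpha trajectory
#'
#' Eigendecomposition of the covariance of the flattened Cartesian C-alpha
#' coordinates about their mean. Computed through the SVD of the centred
#' coordinate matrix, which yields the same nonzero spectrum as the full
#' `3M x 3M` eigenproblem (or its frames-by-frames dual) for any frame count.
#' Each eigenvector's sign is fixed so that its largest-magnitude loading is
#' positive, making projections reproducible across linear-algebra backends.
#'
#' @param aligned_traj An aligned `calpha_trajectory` (see [align_to_mean()])
#'   with at least 2 frames.
#' @param K Number of components to retain for eigenvectors/projections
#'   (default: full rank, `min(3M, n_frames)`).
#' @return A `traj_pca` object with elements `mean_coords` (`n x 3`),
#'   `eigenvectors` (`3M x K`, orthonormal), `eigenvalues` (A^2, descending,
#'   full spectrum), `variance_fractions` (percent, full spectrum),
#'   `projections` (`frames x K`, A), plus the residue table and frame
#'   interval carried from the trajectory.
#' @export
pca_fit <- function(aligned_traj, K = NULL) {
  nf <- n_frames(aligned_traj); nr <- n_residues(aligned_traj)
  if (nf < 2) gtb_shape_error("PCA needs at least 2 frames")
  X <- matrix(aligned_traj$coords, nrow = nf)   # frames x 3M (x-block, y, z)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  lambda <- s$d^2 / (nf - 1)
  rank_max <- min(nf, 3 * nr)
  K <- as.integer(K %||% rank_max)
  if (K < 1 || K > rank_max) {
    gtb_argument_error(sprintf("K must be in 1..%d", rank_max))
  }
  V <- s$v[, seq_len(K), drop = FALSE]
  flip <- vapply(seq_len(K),
                 function(k) V[which.max(abs(V[, k])), k] < 0, logical(1))
  V[, flip] <- -V[, flip]
  proj <- Xc %*% V
  structure(list(
    mean_coords = matrix(mu, nrow = nr, dimnames = list(NULL, c("x", "y", "z"))),
    eigenvectors = V,
    eigenvalues = lambda,
    variance_fractions = 100 * lambda / sum(lambda),
    projections = proj,
    residues = aligned_traj$residues,
    frame_interval_ps = aligned_traj$frame_interval_ps),
    class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  k <- min(3, ncol(x$eigenvectors))
  cat("<traj_pca> ", nrow(x$projections), " frames, ",
      nrow(x$mean_coords), " residues\n", sep = "")
  cat("  variance fractions PC1..PC", k, ": ",
      paste(sprintf("%.1f%%", x$variance_fractions[seq_len(k)]),
            collapse = ", "),
      " (top-3 total ", sprintf("%.1f%%", sum(x$variance_fractions[1:min(3,
        length(x$variance_fractions))])), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.traj_pca <- function(object, n = 10, ...) {
  k <- min(n, length(object$eigenvalues))
  data.frame(component = seq_len(k),
             eigenvalue_A2 = object$eigenvalues[seq_len(k)],
             variance_pct = object$variance_fractions[seq_len(k)],
             cumulative_pct = cumsum(object$variance_fractions)[seq_len(k)])
}

# Project coordinate frames (n_frames x n_res x 3 array or one n x 3 matrix)
# onto the retained components.
pca_project <- function(model, coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  X <- matrix(coords, nrow = dim(coords)[1])
  sweep(X, 2, as.numeric(model$mean_coords)) %*% model$eigenvectors
}

#' Interpolated trajectory along one principal component
#'
#' Builds synthetic frames `mean + t * eigenvector_k` with `t` linearly
#' spaced between the minimum and maximum observed projections on component
#' `k`, through an even number of steps; the first and last frames are the
#' two extreme displacements.
#'
#' @param model A `traj_pca`.
#' @param component Component index `k`.
#' @param steps Even number of frames (>= 2).
#' @return A `calpha_trajectory` of the interpolated frames.
#' @export
pc_interpolation <- function(model, component = 1, steps = 10) {
  if (steps < 2 || steps %% 2 != 0) {
    gtb_argument_error("steps must be an even integer >= 2")
  }
  if (component < 1 || component > ncol(model$eigenvectors)) {
    gtb_argument_error("component outside retained range")
  }
  p <- model$projections[, component]
  t_seq <- seq(min(p), max(p), length.out = steps)
  v <- model$eigenvectors[, component]
  nr <- nrow(model$mean_coords)
  coords <- array(NA_real_, dim = c(steps, nr, 3))
  for (j in seq_len(steps)) {
    coords[j, , ] <- model$mean_coords + matrix(t_seq[j] * v, nrow = nr)
  }
  calpha_trajectory(coords, model$residues, model$frame_interval_ps)
}

octant_names <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

# Sign triple -> octant number. Zero projections count as positive.
# (+,+,+)=I (-,+,+)=II (-,-,+)=III (+,-,+)=IV and V..VIII mirror with PC3 < 0.
octant_of <- function(p1, p2, p3) {
  s1 <- p1 >= 0; s2 <- p2 >= 0; s3 <- p3 >= 0
  quad <- ifelse(s1 & s2, 1L, ifelse(!s1 & s2, 2L, ifelse(!s1 & !s2, 3L, 4L)))
  quad + ifelse(s3, 0L, 4L)
}

# Strict sign changes of a series, ignoring exact zeros.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Octant trace of the top three principal components
#'
#' Labels every frame with the sign octant of its (PC1, PC2, PC3)
#' projections, and summarises occupancy, octant-to-octant transitions and
#' per-component zero crossings — the conformational-hierarchy readout.
#'
#' @param model A `traj_pca` with at least 3 retained components.
#' @return An `octant_trace` list: `labels` (integer 1-8 per frame, with
#'   roman-numeral names), `occupancy` (percent per octant, sums to 100),
#'   `transitions` (data.frame `frame`, `from`, `to`), `zero_crossings`
#'   (counts for PC1-PC3).
#' @export
octant_trace <- function(model) {
  if (ncol(model$eigenvectors) < 3) {
    gtb_argument_error("octant trace needs K >= 3 components")
  }
  P <- model$projections
  labels <- octant_of(P[, 1], P[, 2], P[, 3])
  occ <- 100 * tabulate(labels, 8) / length(labels)
  names(occ) <- octant_names
  chg <- which(labels[-1] != labels[-length(labels)])
  transitions <- data.frame(frame = chg + 1L,
                            from = octant_names[labels[chg]],
                            to = octant_names[labels[chg + 1L]])
  zc <- vapply(1:3, function(k) count_zero_crossings(P[, k]), integer(1))
  names(zc) <- c("PC1", "PC2", "PC3")
  structure(list(labels = structure(labels,
                                    names = octant_names[labels]),
                 occupancy = occ, transitions = transitions,
                 zero_crossings = zc),
            class = "octant_trace")
}

#' @export
print.octant_trace <- function(x, ...) {
  cat("<octant_trace> ", length(x$labels), " frames, ",
      nrow(x$transitions), " transitions\n", sep = "")
  cat("  occupancy (%):",
      paste(sprintf("%s=%.1f", names(x$occupancy), x$occupancy),
            collapse = " "), "\n")
  cat("  zero crossings:",
      paste(sprintf("%s=%d", names(x$zero_crossings), x$zero_crossings),
            collapse = " "), "\n")
  invisible(x)
}

#' Export PCA projections and octant labels as TSV
#'
#' Columns: `frame`, `time_ps`, `pc1`, `pc2`, `pc3`, `octant`.
#'
#' @param model A `traj_pca` (K >= 3).
#' @param trace Matching `octant_trace` (computed if missing).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_projections_tsv <- function(model, path, trace = NULL) {
  trace <- trace %||% octant_trace(model)
  nf <- nrow(model$projections)
  df <- data.frame(frame = seq_len(nf),
                   time_ps = (seq_len(nf) - 1) * model$frame_interval_ps,
                   pc1 = model$projections[, 1],
                   pc2 = model$projections[, 2],
                   pc3 = model$projections[, 3],
                   octant = octant_names[trace$labels])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
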