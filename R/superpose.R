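#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' deviations between `mobile` and `reference` over a fitted subset of points.
#' The reflection branch of the SVD solution is corrected so the returned
#' rotation always has determinant +1.
#'
#' The transform maps row-vector coordinates as
#' `aligned = coords %*% rotation + translation`.
#'
#' @param mobile,reference `n x 3` coordinate matrices (A).
#' @param fit_selection Integer indices of the rows used for fitting
#'   (default: all rows). At least 3 non-collinear points are required.
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length 3) and `rmsd` (the minimised
#'   RMSD over the fitted selection, A).
#' @export
kabsch_fit <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    gtb_shape_error("mobile and reference must be matching n x 3 matrices")
  }
  sel <- fit_selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3) {
    gtb_degeneracy_error("need at least 3 points in the fit selection")
  }
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # Collinear selections leave the rotation about the line undetermined.
  dp <- svd(Pc, nu = 0, nv = 0)$d
  dq <- svd(Qc, nu = 0, nv = 0)$d
  if (dp[2] < 1e-8 * max(1, dp[1]) || dq[2] < 1e-8 * max(1, dq[1])) {
    gtb_degeneracy_error("fit selection is collinear")
  }
  H <- crossprod(Pc, Qc)              # maximise tr(R' H) over rotations R
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cq - cp %*% R
  dev <- Pc %*% R - Qc
  rmsd <- sqrt(sum(dev^2) / nrow(P))
  structure(list(rotation = R, translation = as.numeric(tr), rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd over fit:", fmt_num(x$rmsd), "A\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param transform A `rigid_transform` from [kabsch_fit()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% transform$rotation, 2,
        -transform$translation, FUN = "-")
}

# Reference coordinates for a trajectory's residues: from a structure_model
# (matched on chain+resnum CA), a frame index, or an n x 3 matrix.
reference_coords <- function(traj, reference) {
  if (inherits(reference, "structure_model")) {
    ca <- ca_atoms(reference)
    key_t <- paste(traj$residues$chain, traj$residues$resnum)
    key_r <- paste(ca$residues$chain, ca$residues$resnum)
    m <- match(key_t, key_r)
    if (anyNA(m)) {
      gtb_selection_error("reference structure lacks CA for some trajectory residues")
    }
    return(ca$coords[m, , drop = FALSE])
  }
  if (length(reference) == 1 && is.numeric(reference)) {
    return(frame_coords(traj, reference))
  }
  m <- as.matrix(reference)
  if (nrow(m) != n_residues(traj) || ncol(m) != 3) {
    gtb_shape_error("reference matrix does not match trajectory residues")
  }
  m
}

#' Superpose every trajectory frame onto a fixed reference
#'
#' Each frame is fitted independently by [kabsch_fit()] over `fit_selection`;
#' the resulting transform is applied to all residues of the frame.
#'
#' @param traj A `calpha_trajectory`.
#' @param reference A `structure_model`, a frame index into `traj`, or an
#'   `n_residues x 3` matrix.
#' @param fit_selection Residue-number selection used for fitting
#'   (default: all residues).
#' @return The aligned `calpha_trajectory`.
#' @export
align_trajectory <- function(traj, reference = 1, fit_selection = NULL) {
  ref <- reference_coords(traj, reference)
  sel <- residue_index(traj, fit_selection)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    tf <- kabsch_fit(frame_coords(traj, f), ref, sel)
    out[f, , ] <- apply_transform(frame_coords(traj, f), tf)
  }
  calpha_trajectory(out, traj$residues, traj$frame_interval_ps)
}

#' Mean structure of a trajectory
#'
#' @param traj A `calpha_trajectory` (normally already aligned).
#' @return `n_residues x 3` matrix of per-residue mean coordinates.
#' @export
mean_structure <- function(traj) {
  apply(traj$coords, c(2, 3), mean)
}

#' Align a trajectory to its own mean structure
#'
#' The quasiharmonic convention used before RMSF, PCA and DCC: align all
#' frames to frame 1, compute the mean structure, then realign all frames to
#' that mean (one iteration).
#'
#' @param traj A `calpha_trajectory`.
#' @param fit_selection Residue-number selection used for fitting.
#' @return The aligned `calpha_trajectory`, with the final mean structure
#'   attached as attribute `"mean"`.
#' @export
align_to_mean <- function(traj, fit_selection = NULL) {
  a1 <- align_trajectory(traj, reference = 1, fit_selection = fit_selection)
  a2 <- align_trajectory(a1, reference = mean_structure(a1),
                         fit_selection = fit_selection)
  attr(a2, "mean") <- mean_structure(a2)
  a2
}
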