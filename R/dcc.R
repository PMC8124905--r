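#' Dynamic cross-correlation matrix of C-alpha fluctuations
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with `dr_i = r_i - <r_i>`,
#' 3D displacement dot products averaged over frames. Residues with zero
#' fluctuation get a zeroed row/column (1 on the diagonal) with a warning so
#' the matrix stays well-formed.
#'
#' @param aligned_traj An aligned `calpha_trajectory` (see [align_to_mean()])
#'   with >= 2 frames.
#' @return A `dcc_matrix`: list with `values` (`n x n`, in `[-1, 1]`,
#'   symmetric, unit diagonal) and the trajectory `residues` table.
#' @export
dcc_matrix <- function(aligned_traj) {
  nf <- n_frames(aligned_traj)
  if (nf < 2) gtb_shape_error("DCC needs at least 2 frames")
  mu <- mean_structure(aligned_traj)
  dev <- sweep(aligned_traj$coords, c(2, 3), mu)   # frames x n x 3
  # covariance of displacement vectors: sum over the three Cartesian blocks
  cov <- (crossprod(dev[, , 1]) + crossprod(dev[, , 2]) +
            crossprod(dev[, , 3])) / nf
  msf <- diag(cov)
  dead <- msf <= 0
  if (any(dead)) {
    warning(sum(dead), " residue(s) with zero fluctuation; correlations zeroed",
            call. = FALSE)
    msf[dead] <- 1
  }
  vals <- cov / sqrt(outer(msf, msf))
  if (any(dead)) {
    vals[dead, ] <- 0
    vals[, dead] <- 0
  }
  diag(vals) <- 1
  structure(list(values = vals, residues = aligned_traj$residues),
            class = "dcc_matrix")
}

#' @export
print.dcc_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("<dcc_matrix> ", nrow(x$values), " residues; off-diagonal range [",
      fmt_num(min(off), 3), ", ", fmt_num(max(off), 3), "], mean ",
      fmt_num(mean(off), 3), "\n", sep = "")
  invisible(x)
}

#' Difference of two DCC matrices
#'
#' Elementwise `a - b` over identical residue sets, e.g. wild type minus
#' mutant to localise lost anticorrelated motion.
#'
#' @param a,b `dcc_matrix` objects over the same residues.
#' @return A symmetric matrix of correlation differences with zero diagonal.
#' @export
dcc_difference <- function(a, b) {
  if (!identical(unname(as.list(a$residues[c("chain", "resnum")])),
                 unname(as.list(b$residues[c("chain", "resnum")])))) {
    gtb_shape_error("DCC matrices cover different residue sets")
  }
  a$values - b$values
}

#' Mine distal anticorrelated nonionizable residues
#'
#' The candidate rule: a residue qualifies if it (i) lies in a different
#' domain than the active-site residue it pairs with, (ii) is anticorrelated
#' (`C <= corr_cutoff`) to at least one site residue, (iii) is at least
#' `min_dist` A from every site residue in the reference structure,
#' (iv) optionally lies within `max_donor_dist` A of a donor-site residue,
#' and (v) has an allowed (nonionizable) residue name. Distances are C-alpha
#' distances on the static reference structure, not per-frame.
#'
#' @param dcc A `dcc_matrix`.
#' @param structure The reference `structure_model` (crystal coordinates).
#' @param domain_map A `domain_map`.
#' @param site_residues Residue numbers of the (acceptor) binding-site
#'   residues.
#' @param corr_cutoff Anticorrelation cutoff, `<= 0` (default -0.4).
#' @param min_dist Minimum distance to the acceptor site in A (default 25).
#' @param donor_site,max_donor_dist Optional donor-site residue numbers and
#'   maximum allowed distance to them (A).
#' @param allowed_classes Allowed residue names
#'   (default [nonionizable_classes()]).
#' @return A `candidate_residues` data.frame sorted by most-negative
#'   correlation: `chain`, `resnum`, `resname`, `partner`, `correlation`,
#'   `dist_site_A`, `residue_class`.
#' @export
mine_candidates <- function(dcc, structure, domain_map, site_residues,
                            corr_cutoff = -0.4, min_dist = 25,
                            donor_site = NULL, max_donor_dist = NULL,
                            allowed_classes = nonionizable_classes()) {
  if (length(site_residues) == 0) gtb_config_error("site_residues is empty")
  if (corr_cutoff > 0) gtb_config_error("corr_cutoff must be <= 0")
  if (min_dist <= 0) gtb_config_error("min_dist must be positive")
  res <- dcc$residues
  site_idx <- match(site_residues, res$resnum)
  if (anyNA(site_idx)) {
    gtb_config_error(paste0("site residue(s) not in DCC: ",
                            paste(site_residues[is.na(site_idx)],
                                  collapse = ", ")))
  }
  ca <- ca_atoms(structure)
  pos <- ca$coords[match(res$resnum, ca$residues$resnum), , drop = FALSE]
  if (anyNA(pos)) {
    gtb_config_error("reference structure lacks CA for some DCC residues")
  }
  dists_to <- function(targets) {
    ti <- match(targets, res$resnum)
    if (anyNA(ti)) gtb_config_error("donor-site residue(s) not in structure")
    d <- vapply(ti, function(j) sqrt(rowSums(sweep(pos, 2, pos[j, ])^2)),
                numeric(nrow(pos)))
    apply(d, 1, min)
  }
  min_site_dist <- dists_to(site_residues)
  donor_ok <- rep(TRUE, nrow(res))
  if (!is.null(donor_site) && !is.null(max_donor_dist)) {
    donor_ok <- dists_to(donor_site) <= max_donor_dist
  }
  dom <- domain_of(domain_map, res$resnum)
  site_dom <- dom[site_idx]
  out <- list()
  for (i in seq_len(nrow(res))) {
    if (!res$resname[i] %in% allowed_classes) next
    if (is.na(dom[i])) next
    if (min_site_dist[i] < min_dist) next
    if (!donor_ok[i]) next
    cors <- dcc$values[i, site_idx]
    ok <- which(cors <= corr_cutoff & dom[i] != site_dom & i != site_idx)
    if (length(ok) == 0) next
    best <- ok[which.min(cors[ok])]
    out[[length(out) + 1]] <- data.frame(
      chain = res$chain[i], resnum = res$resnum[i],
      resname = res$resname[i], partner = site_residues[best],
      correlation = cors[best], dist_site_A = min_site_dist[i],
      residue_class = res$resname[i], stringsAsFactors = FALSE)
  }
  out <- if (length(out) == 0) {
    data.frame(chain = character(0), resnum = integer(0),
               resname = character(0), partner = integer(0),
               correlation = numeric(0), dist_site_A = numeric(0),
               residue_class = character(0))
  } else {
    do.call(rbind, out)
  }
  out <- out[order(out$correlation), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_residues", "data.frame")
  out
}

#' Export a DCC matrix as dense TSV
#'
#' Residue ids (`chain:resnum`) label the header row and first column.
#'
#' @param dcc A `dcc_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dcc_tsv <- function(dcc, path) {
  ids <- paste0(dcc$residues$chain, ":", dcc$residues$resnum)
  m <- dcc$values
  dimnames(m) <- list(ids, ids)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
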