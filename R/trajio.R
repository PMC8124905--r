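#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (HETATM are ignored) into a `structure_model`. Alternate
#' locations are resolved by keeping the highest-occupancy record, ties broken
#' by file order. Insertion codes are not supported and raise an error, as do
#' duplicate atoms remaining after altloc resolution.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @return A `structure_model`: a list with element `atoms`, a data.frame with
#'   columns `chain`, `resnum`, `resname`, `atom`, `x`, `y`, `z`.
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "gtbdyn")
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) gtb_io_error(paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) gtb_format_error(paste0("not parseable as PDB: ", path))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) gtb_format_error(paste0("no ATOM records in ", path))
  ins <- at$insert
  if (any(!is.na(ins) & ins != "")) {
    gtb_format_error("insertion codes are not supported")
  }
  at$chain[is.na(at$chain)] <- " "
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    a <- alt[idx]
    if (anyDuplicated(a)) {
      gtb_format_error(paste0(
        "duplicate atom record for residue ", at$resno[idx[1]],
        " atom ", at$elety[idx[1]]))
    }
    idx[which.max(occ[idx])]  # which.max takes the first on ties
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    gtb_format_error("non-finite coordinates in PDB")
  }
  atoms <- data.frame(
    chain = at$chain, resnum = at$resno, resname = at$resid,
    atom = at$elety, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ca <- sum(x$atoms$atom == "CA")
  cat("<structure_model> ", nrow(x$atoms), " atoms, ", ca,
      " CA, chains: ", paste(unique(x$atoms$chain), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

# C-alpha subset of a structure: residue table + n x 3 coordinate matrix.
ca_atoms <- function(structure) {
  a <- structure$atoms[structure$atoms$atom == "CA", , drop = FALSE]
  list(
    residues = data.frame(chain = a$chain, resnum = a$resnum,
                          resname = a$resname, stringsAsFactors = FALSE),
    coords = as.matrix(a[, c("x", "y", "z")]))
}

#' Construct a C-alpha trajectory object
#'
#' @param coords Numeric array of dimension `n_frames x n_residues x 3` (A).
#' @param residues data.frame with columns `chain`, `resnum`, `resname`, one
#'   row per residue, in coordinate order (identical across frames).
#' @param frame_interval_ps Time between saved frames in picoseconds
#'   (default 240).
#' @return An object of class `calpha_trajectory`.
#' @export
calpha_trajectory <- function(coords, residues, frame_interval_ps = 240) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    gtb_shape_error("coords must be an n_frames x n_residues x 3 array")
  }
  if (dim(coords)[1] < 1 || dim(coords)[2] < 2) {
    gtb_shape_error("trajectory needs >= 1 frame and >= 2 residues")
  }
  if (anyNA(coords) || !all(is.finite(coords))) {
    gtb_shape_error("trajectory coordinates must be finite")
  }
  if (nrow(residues) != dim(coords)[2]) {
    gtb_shape_error("residue table does not match coordinate dimension")
  }
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    gtb_argument_error("frame_interval_ps must be positive")
  }
  structure(list(coords = coords,
                 residues = as.data.frame(residues),
                 frame_interval_ps = frame_interval_ps),
            class = "calpha_trajectory")
}

#' @export
print.calpha_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<calpha_trajectory> ", d[1], " frames x ", d[2], " residues, ",
      x$frame_interval_ps, " ps/frame\n", sep = "")
  invisible(x)
}

n_frames   <- function(traj) dim(traj$coords)[1]
n_residues <- function(traj) dim(traj$coords)[2]

# Frame times in ps (frame 1 at t = 0).
frame_times <- function(traj) {
  (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ps
}

# n x 3 coordinate matrix of one frame.
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset trajectory frames
#'
#' @param traj A `calpha_trajectory`.
#' @param idx Integer frame indices (kept in the given order).
#' @return A `calpha_trajectory` with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0 || any(idx < 1 | idx > n_frames(traj))) {
    gtb_selection_error("frame indices out of range")
  }
  calpha_trajectory(traj$coords[idx, , , drop = FALSE], traj$residues,
                    traj$frame_interval_ps)
}

#' Select residues from a trajectory
#'
#' Returns the sub-trajectory of residues whose residue numbers fall in the
#' given selection, preserving the original residue order.
#'
#' @param traj A `calpha_trajectory`.
#' @param selection Residue numbers, a `c(lo, hi)` range, or a list of ranges.
#' @return A `calpha_trajectory` restricted to the selected residues.
#' @export
select_residues <- function(traj, selection) {
  want <- resolve_ranges(selection)
  keep <- which(traj$residues$resnum %in% want)
  if (length(keep) == 0) {
    gtb_selection_error("selection does not intersect trajectory residues")
  }
  calpha_trajectory(traj$coords[, keep, , drop = FALSE],
                    traj$residues[keep, , drop = FALSE],
                    traj$frame_interval_ps)
}

# Residue-index resolver used by analysis stages: selection -> integer
# positions into the trajectory residue order (NULL -> all residues).
residue_index <- function(traj, selection = NULL) {
  if (is.null(selection)) return(seq_len(n_residues(traj)))
  keep <- which(traj$residues$resnum %in% resolve_ranges(selection))
  if (length(keep) == 0) {
    gtb_selection_error("selection does not intersect trajectory residues")
  }
  keep
}

#' Write a trajectory in the plain-text xyztable format
#'
#' Format: a header line `#frames N residues M interval_ps T`, then one
#' whitespace-separated line per residue per frame:
#' `frame_index chain resnum resname x y z`, frames contiguous and ascending.
#'
#' @param traj A `calpha_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_xyztable <- function(traj, path) {
  nf <- n_frames(traj); nr <- n_residues(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#frames %d residues %d interval_ps %.6g",
                     nf, nr, traj$frame_interval_ps), con)
  res <- traj$residues
  fr  <- rep(seq_len(nf), each = nr)
  xyz <- matrix(aperm(traj$coords, c(3, 2, 1)), nrow = 3)  # 3 x (nr*nf)
  lines <- sprintf("%d %s %d %s %.6f %.6f %.6f",
                   fr, rep(res$chain, nf), rep(res$resnum, nf),
                   rep(res$resname, nf), xyz[1, ], xyz[2, ], xyz[3, ])
  writeLines(lines, con)
  invisible(path)
}

read_xyztable <- function(path) {
  if (!file.exists(path)) gtb_io_error(paste0("file not found: ", path))
  header <- readLines(path, n = 1)
  hm <- regmatches(header, regexec(
    "^#frames\\s+(\\d+)\\s+residues\\s+(\\d+)\\s+interval_ps\\s+([0-9.eE+-]+)",
    header))[[1]]
  if (length(hm) != 4) {
    gtb_format_error("xyztable header malformed (expected '#frames N residues M interval_ps T')")
  }
  nf <- as.integer(hm[2]); nr <- as.integer(hm[3]); dt <- as.numeric(hm[4])
  tab <- tryCatch(
    utils::read.table(path, skip = 1,
                      col.names = c("frame", "chain", "resnum", "resname",
                                    "x", "y", "z"),
                      colClasses = c("integer", "character", "integer",
                                     "character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) gtb_format_error(paste0("xyztable body malformed: ",
                                                conditionMessage(e))))
  if (nrow(tab) != nf * nr) {
    bad <- ceiling((nrow(tab) + 1) / nr)
    if (nrow(tab) > nf * nr) bad <- nf
    gtb_format_error(sprintf(
      "xyztable truncated or overlong: expected %d rows, got %d (around frame %d)",
      nf * nr, nrow(tab), bad))
  }
  fidx <- matrix(tab$frame, nrow = nr)
  expect_fr <- rep(seq.int(fidx[1, 1], length.out = nf), each = nr)
  if (!all(tab$frame == expect_fr)) {
    bad <- which(tab$frame != expect_fr)[1]
    gtb_format_error(sprintf(
      "xyztable frames not contiguous/ascending at row %d (frame %d)",
      bad, tab$frame[bad]))
  }
  first <- tab[seq_len(nr), c("chain", "resnum", "resname")]
  for (f in seq_len(nf)[-1]) {
    blk <- tab[(f - 1L) * nr + seq_len(nr), c("chain", "resnum", "resname")]
    if (!identical(unname(as.list(blk)), unname(as.list(first)))) {
      gtb_format_error(sprintf("residue order differs in frame %d", f))
    }
  }
  coords <- aperm(array(c(tab$x, tab$y, tab$z), dim = c(nr, nf, 3)),
                  c(2, 1, 3))
  calpha_trajectory(coords, first, dt)
}

#' Read a coordinate trajectory and extract the C-alpha subset
#'
#' Supported formats: `xyztable` (plain-text, self-describing; see
#' [write_xyztable()]) and `dcd` (binary, C-alpha extraction driven by the
#' topology). XTC input is not supported and raises a format error.
#'
#' @param path Trajectory file path.
#' @param topology A `structure_model` used for atom counts, residue metadata
#'   and C-alpha extraction. Optional for `xyztable` (metadata is in-file), in
#'   which case residue counts are still cross-checked when supplied.
#' @param format One of `"xyztable"`, `"dcd"`, `"xtc"`.
#' @param frame_interval_ps Frame spacing in ps for formats that do not carry
#'   it (dcd); default 240.
#' @return A `calpha_trajectory` in file frame order, coordinates in Angstrom.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("xyztable", "dcd", "xtc"),
                            frame_interval_ps = 240) {
  format <- match.arg(format)
  if (format == "xtc") {
    gtb_format_error("XTC input is not supported; convert to DCD or xyztable")
  }
  if (!file.exists(path)) gtb_io_error(paste0("file not found: ", path))
  if (format == "xyztable") {
    traj <- read_xyztable(path)
    if (!is.null(topology)) {
      ca <- ca_atoms(topology)
      if (nrow(ca$residues) != n_residues(traj)) {
        gtb_shape_error(sprintf(
          "xyztable has %d residues but topology has %d CA atoms",
          n_residues(traj), nrow(ca$residues)))
      }
    }
    return(traj)
  }
  # DCD: frames x (3 * n_atoms) matrix from bio3d; CA columns via topology.
  if (is.null(topology)) gtb_argument_error("dcd input requires a topology")
  xyz <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) gtb_format_error(paste0("DCD unreadable: ",
                                                conditionMessage(e))))
  natom_file <- ncol(xyz) / 3
  natom_top <- nrow(topology$atoms)
  if (natom_file != natom_top) {
    gtb_shape_error(sprintf("DCD has %d atoms but topology has %d",
                            natom_file, natom_top))
  }
  ca_idx <- which(topology$atoms$atom == "CA")
  if (length(ca_idx) == 0) gtb_format_error("topology has no CA atoms")
  cols <- as.vector(rbind(3 * (ca_idx - 1) + 1,
                          3 * (ca_idx - 1) + 2,
                          3 * (ca_idx - 1) + 3))
  sub <- xyz[, cols, drop = FALSE]
  nf <- nrow(sub); nr <- length(ca_idx)
  coords <- aperm(array(t(sub), dim = c(3, nr, nf)), c(3, 2, 1))
  res <- topology$atoms[ca_idx, c("chain", "resnum", "resname")]
  calpha_trajectory(coords, res, frame_interval_ps)
}

#' Write a C-alpha-only PDB topology for a trajectory
#'
#' Companion topology writer used by the synthetic generator and the CLI
#' `simulate` subcommand; coordinates are taken from one trajectory frame.
#'
#' @param traj A `calpha_trajectory`.
#' @param path Output PDB path.
#' @param frame Frame index providing the coordinates (default 1).
#' @return Invisibly, `path`.
#' @export
write_ca_pdb <- function(traj, path, frame = 1) {
  xyz <- frame_coords(traj, frame)
  res <- traj$residues
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(res)), res$resname, res$chain, res$resnum,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
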