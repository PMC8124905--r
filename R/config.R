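#' Define a domain decomposition
#'
#' Maps domain labels to inclusive residue-number ranges. `N` and `C` are
#' mandatory; the linker `L` and spine `S` are optional. Residues outside all
#' ranges are simply unassigned: they take part in global analyses but are
#' excluded from per-domain ones.
#'
#' @param N,C,L,S Ranges for each domain: a `c(lo, hi)` pair, a list of such
#'   pairs, or `NULL` (L and S only).
#' @return A `domain_map` object.
#' @examples
#' domain_map(N = c(1, 152), L = c(153, 179), C = c(180, 322))
#' @export
domain_map <- function(N, C, L = NULL, S = NULL) {
  norm <- function(x) {
    if (is.null(x)) return(NULL)
    if (!is.list(x)) x <- list(x)
    m <- do.call(rbind, lapply(x, function(r) {
      if (length(r) != 2 || r[2] < r[1]) {
        gtb_config_error("domain ranges must be c(lo, hi) with hi >= lo")
      }
      as.integer(r)
    }))
    colnames(m) <- c("lo", "hi")
    m[order(m[, 1]), , drop = FALSE]
  }
  doms <- list(N = norm(N), L = norm(L), C = norm(C), S = norm(S))
  doms <- doms[!vapply(doms, is.null, logical(1))]
  if (!all(c("N", "C") %in% names(doms))) {
    gtb_config_error("domain map must define both N and C domains")
  }
  for (lab in names(doms)) {
    m <- doms[[lab]]
    if (nrow(m) > 1) {
      o <- m[order(m[, 1]), , drop = FALSE]
      if (any(o[-1, 1] <= o[-nrow(o), 2])) {
        gtb_config_error(paste0("overlapping ranges within domain ", lab))
      }
    }
  }
  res <- lapply(doms, function(m) {
    unlist(lapply(seq_len(nrow(m)), function(i) seq.int(m[i, 1], m[i, 2])))
  })
  all_res <- unlist(res)
  if (anyDuplicated(all_res)) {
    gtb_config_error("residue assigned to more than one domain")
  }
  structure(list(ranges = doms, residues = res), class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map>\n")
  for (lab in names(x$ranges)) {
    m <- x$ranges[[lab]]
    cat(" ", lab, ": ",
        paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ", "),
        " (", length(x$residues[[lab]]), " residues)\n", sep = "")
  }
  invisible(x)
}

#' Residue numbers belonging to one domain
#'
#' @param map A `domain_map`.
#' @param label Domain label, one of the labels present in the map.
#' @return Integer vector of residue numbers.
#' @export
domain_residues <- function(map, label) {
  if (!label %in% names(map$residues)) {
    gtb_config_error(paste0("domain label not in map: ", label))
  }
  map$residues[[label]]
}

# Domain label of each residue number (NA if unassigned).
domain_of <- function(map, resnum) {
  out <- rep(NA_character_, length(resnum))
  for (lab in names(map$residues)) {
    out[resnum %in% map$residues[[lab]]] <- lab
  }
  out
}

ss_classes <- c("helix", "sheet", "three_ten", "loop")

#' Per-residue secondary-structure annotation
#'
#' Secondary structure is supplied, never computed: the classes are taken from
#' the crystal-structure assignment in the run configuration.
#'
#' @param resnum Integer residue numbers.
#' @param class Character vector of classes, one of `helix`, `sheet`,
#'   `three_ten`, `loop`.
#' @return An `ss_annotation` data.frame with columns `resnum`, `class`.
#' @export
ss_annotation <- function(resnum, class) {
  if (length(resnum) != length(class)) {
    gtb_config_error("resnum and class lengths differ")
  }
  if (!all(class %in% ss_classes)) {
    gtb_config_error(paste0("unknown ss class; allowed: ",
                            paste(ss_classes, collapse = ", ")))
  }
  if (anyDuplicated(resnum)) {
    gtb_config_error("residue annotated with more than one ss class")
  }
  structure(data.frame(resnum = as.integer(resnum), class = class,
                       stringsAsFactors = FALSE),
            class = c("ss_annotation", "data.frame"))
}

# Check every trajectory residue is annotated exactly once.
validate_ss_coverage <- function(ss, traj) {
  missing <- setdiff(traj$residues$resnum, ss$resnum)
  if (length(missing) > 0) {
    gtb_config_error(paste0("residues without ss annotation: ",
                            paste(utils::head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

# Residues ionizable at physiological pH; the complement defines the
# "nonionizable" candidate classes used by mine_candidates().
ionizable_residues <- c("ASP", "GLU", "LYS", "ARG", "HIS")

standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Default nonionizable residue classes
#'
#' All standard amino acids except Asp, Glu, Lys, Arg and His.
#' @return Character vector of 3-letter residue names.
#' @export
nonionizable_classes <- function() {
  setdiff(standard_residues, ionizable_residues)
}

run_config_known_keys <- c(
  "structure", "trajectory", "trajectory_format", "frame_interval_ps",
  "stride", "seed", "domains", "ss", "active_site", "mining", "pca",
  "density_bandwidth", "lowess_fraction", "rmsd_band_edges",
  "kinetics_data", "kinetics_reference")

#' Read and validate a run configuration
#'
#' The configuration is a YAML file with keys `structure`, `trajectory`,
#' `domains` (label -> list of `[lo, hi]` ranges), `ss` (class -> list of
#' ranges), `active_site` (residue numbers), `mining` (`corr_cutoff`,
#' `min_dist`, `max_donor_dist`, `donor_site`, `allowed_classes`), `pca`
#' (`n_components`), `density_bandwidth`, `lowess_fraction`,
#' `rmsd_band_edges`, `frame_interval_ps`, `stride`, `seed` and optional
#' `kinetics_data` / `kinetics_reference`. Unknown keys produce a warning,
#' not an error. Relative paths are resolved against the config directory.
#'
#' @param path Path to the YAML config.
#' @return A `run_config` list with validated, default-filled fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) gtb_io_error(paste0("config not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    gtb_format_error(paste0("config not parseable: ",
                                            conditionMessage(e))))
  unknown <- setdiff(names(raw), run_config_known_keys)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path, mustWork = TRUE))
  respath <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  if (is.null(raw$trajectory)) {
    gtb_config_error("config field 'trajectory' is missing")
  }
  if (is.null(raw$domains)) gtb_config_error("config field 'domains' is missing")
  # YAML 1.1 readers turn the bare keys N/Y into booleans; undo that so the
  # domain labels survive a round trip.
  names(raw$domains)[names(raw$domains) == "FALSE"] <- "N"
  names(raw$domains)[names(raw$domains) == "TRUE"] <- "Y"
  dm <- domain_map(N = raw$domains$N, C = raw$domains$C,
                   L = raw$domains$L, S = raw$domains$S)
  ss <- NULL
  if (!is.null(raw$ss)) {
    resn <- integer(0); cls <- character(0)
    for (k in names(raw$ss)) {
      r <- resolve_ranges(raw$ss[[k]])
      resn <- c(resn, r); cls <- c(cls, rep(k, length(r)))
    }
    ss <- ss_annotation(resn, cls)
  }
  mining <- raw$mining %||% list()
  mining <- list(
    corr_cutoff     = mining$corr_cutoff %||% -0.4,
    min_dist        = mining$min_dist %||% 25,
    max_donor_dist  = mining$max_donor_dist,
    donor_site      = mining$donor_site,
    allowed_classes = mining$allowed_classes %||% nonionizable_classes())
  if (mining$corr_cutoff > 0) {
    gtb_config_error("mining corr_cutoff must be <= 0")
  }
  if (mining$min_dist <= 0) gtb_config_error("mining min_dist must be positive")
  bw <- raw$density_bandwidth %||% 0.5
  lf <- raw$lowess_fraction %||% 0.3
  stride <- raw$stride %||% 1
  if (bw <= 0 || lf <= 0 || lf > 1 || stride < 1) {
    gtb_config_error("thresholds must be positive (bandwidth, lowess fraction, stride)")
  }
  cfg <- list(
    structure = respath(raw$structure),
    trajectory = respath(raw$trajectory),
    trajectory_format = raw$trajectory_format %||% "xyztable",
    frame_interval_ps = raw$frame_interval_ps %||% 240,
    stride = as.integer(stride),
    seed = raw$seed %||% 1L,
    domains = dm,
    ss = ss,
    active_site = raw$active_site,
    mining = mining,
    pca = list(n_components = (raw$pca$n_components %||% 3)),
    density_bandwidth = bw,
    lowess_fraction = lf,
    rmsd_band_edges = raw$rmsd_band_edges %||% c(2, 3),
    kinetics_data = respath(raw$kinetics_data),
    kinetics_reference = respath(raw$kinetics_reference))
  class(cfg) <- "run_config"
  cfg
}
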