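# Synthetic two-domain hinge trajectories.
#
# Two rigid pseudo-domains (ideal alpha-helical C-alpha spirals, 3.8 A
# consecutive spacing) radiate from a pivot at the linker; domain B rotates
# about the pivot by a hinge angle gamma(t) and twists about its own axis by
# phi(t); the linker stretches between the fixed end of A and the moving
# start of B. Isotropic Gaussian noise is added per residue per frame,
# amplified in designated loop ranges.

helix_rise <- 1.5      # A per residue along the axis
helix_radius <- 2.3    # A; with 100 deg/residue gives ~3.8 A CA-CA spacing
helix_turn <- 100 * pi / 180

# Ideal helical spiral of n residues with axis +z starting at the origin.
helix_local <- function(n) {
  t <- seq_len(n) - 1
  cbind(helix_radius * cos(t * helix_turn),
        helix_radius * sin(t * helix_turn),
        helix_rise * t)
}

# Rotation matrix about the y axis (maps +z to (sin g, 0, cos g)).
rot_y <- function(g) {
  matrix(c(cos(g), 0, -sin(g),
           0, 1, 0,
           sin(g), 0, cos(g)), nrow = 3, byrow = TRUE)
}

# Rodrigues rotation about a unit axis.
rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Specification for a synthetic hinge trajectory
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: a 120-residue protein (54 + 12-residue linker + 54), 2000 frames at
#' 240 ps, a 15-degree hinge oscillation with a 400-frame period, an
#' 8-degree twist with a 2000-frame period, 0.3 A isotropic noise tripled in
#' the linker (loop) region, and closed/open inter-domain centroid distances
#' of 9 and 24 A.
#'
#' @param n_res_domain_a,n_res_domain_b,n_res_linker Residue counts (>= 3).
#' @param hinge_amplitude,twist_amplitude Amplitudes in degrees (>= 0).
#' @param hinge_period,twist_period Periods in frames (>= 4).
#' @param noise_sigma Isotropic Gaussian noise sd per coordinate (A).
#' @param noise_ar1 Lag-1 autocorrelation of the noise in time (default 0,
#'   i.e. frames independent; the stationary sd stays `noise_sigma`).
#' @param loop_residue_ranges Ranges treated as loops (default: the linker).
#' @param loop_noise_multiplier Noise multiplier in loop ranges.
#' @param n_frames Number of frames.
#' @param frame_interval_ps Frame spacing (ps).
#' @param mode `"oscillate"` (open-form hinge oscillation about the open
#'   distance) or `"relax"` (logistic closed-to-open ramp).
#' @param relax_changepoint_frame Midpoint frame of the relax ramp.
#' @param relax_tau Logistic time constant of the ramp (frames).
#' @param open_distance,closed_distance Planted inter-domain centroid
#'   distances (A).
#' @param seed Integer seed fixing the full output.
#' @return A validated `hinge_spec` list.
#' @export
hinge_spec <- function(n_res_domain_a = 54, n_res_domain_b = 54,
                       n_res_linker = 12,
                       hinge_amplitude = 15, hinge_period = 400,
                       twist_amplitude = 8, twist_period = 2000,
                       noise_sigma = 0.3, noise_ar1 = 0,
                       loop_residue_ranges = NULL,
                       loop_noise_multiplier = 3,
                       n_frames = 2000, frame_interval_ps = 240,
                       mode = c("oscillate", "relax"),
                       relax_changepoint_frame = NULL,
                       relax_tau = NULL,
                       open_distance = 24, closed_distance = 9,
                       seed = 1) {
  mode <- match.arg(mode)
  if (min(n_res_domain_a, n_res_domain_b, n_res_linker) < 3) {
    gtb_spec_error("all residue counts must be >= 3")
  }
  if (hinge_period < 4 || twist_period < 4) {
    gtb_spec_error("periods must be >= 4 frames")
  }
  if (hinge_amplitude < 0 || twist_amplitude < 0 || noise_sigma < 0) {
    gtb_spec_error("amplitudes and noise must be >= 0")
  }
  if (noise_ar1 < 0 || noise_ar1 >= 1) {
    gtb_spec_error("noise_ar1 must be in [0, 1)")
  }
  if (n_frames < 2) gtb_spec_error("n_frames must be >= 2")
  if (closed_distance <= 2 * helix_radius) {
    gtb_spec_error("closed_distance inside the domain radius: impossible geometry")
  }
  if (open_distance <= closed_distance) {
    gtb_spec_error("open_distance must exceed closed_distance")
  }
  spec <- list(
    n_res_domain_a = n_res_domain_a, n_res_domain_b = n_res_domain_b,
    n_res_linker = n_res_linker,
    hinge_amplitude = hinge_amplitude, hinge_period = hinge_period,
    twist_amplitude = twist_amplitude, twist_period = twist_period,
    noise_sigma = noise_sigma, noise_ar1 = noise_ar1,
    loop_residue_ranges = loop_residue_ranges,
    loop_noise_multiplier = loop_noise_multiplier,
    n_frames = n_frames, frame_interval_ps = frame_interval_ps,
    mode = mode,
    relax_changepoint_frame = relax_changepoint_frame %||% (n_frames %/% 2),
    relax_tau = relax_tau %||% max(4, n_frames %/% 20),
    open_distance = open_distance, closed_distance = closed_distance,
    seed = seed)
  class(spec) <- "hinge_spec"
  spec
}

# Geometry shared by the generator: base pieces and the frame builder.
hinge_geometry <- function(spec) {
  gap <- 3
  na <- spec$n_res_domain_a; nb <- spec$n_res_domain_b
  nl <- spec$n_res_linker
  hel_a <- sweep(helix_local(na), 2, c(0, 0, gap), FUN = "+")
  hel_b0 <- sweep(helix_local(nb), 2, c(0, 0, gap), FUN = "+")  # before hinge
  cen_b0 <- colMeans(hel_b0)
  r_a <- sqrt(sum(colMeans(hel_a)^2))
  r_b <- sqrt(sum(cen_b0^2))
  angle_for <- function(d) {
    arg <- (r_a^2 + r_b^2 - d^2) / (2 * r_a * r_b)
    if (arg < -1 || arg > 1) {
      gtb_spec_error(sprintf(
        "requested inter-domain distance %.3g A unreachable: impossible geometry", d))
    }
    acos(arg)
  }
  gamma_open <- angle_for(spec$open_distance)
  gamma_closed <- angle_for(spec$closed_distance)
  # One noiseless frame at hinge angle gamma and twist phi (radians).
  build <- function(gamma, phi) {
    b <- hel_b0
    if (phi != 0) {
      b <- sweep(sweep(b, 2, cen_b0) %*% t(rot_axis(c(0, 0, 1), phi)),
                 2, cen_b0, FUN = "+")
    }
    b <- b %*% t(rot_y(gamma))
    a_end <- hel_a[na, ]
    b_start <- b[1, ]
    w <- seq_len(nl) / (nl + 1)
    link <- sweep(outer(w, b_start - a_end), 2, a_end, FUN = "+")
    rbind(hel_a, link, b)
  }
  list(gamma_open = gamma_open, gamma_closed = gamma_closed,
       r_a = r_a, r_b = r_b, build = build,
       idx_a = seq_len(na), idx_l = na + seq_len(nl),
       idx_b = na + nl + seq_len(nb))
}

# Residue metadata: ionizable names throughout except two glycines in
# domain B — the planted distal candidate (last residue, far from the site)
# and a near-site control (the B residue closest to the site, anticorrelated
# but inside the distance cutoff). The "active site" is three positively
# charged residues at the middle of domain A, where the hinge lever arm
# makes the inter-domain anticorrelation strongest.
hinge_residues <- function(spec, site_res, control_res) {
  n <- spec$n_res_domain_a + spec$n_res_linker + spec$n_res_domain_b
  resname <- rep(c("ARG", "ASP", "LYS", "GLU"), length.out = n)
  resname[site_res] <- c("ARG", "LYS", "ARG")
  resname[control_res] <- "GLY"  # control: anticorrelated but proximal
  resname[n] <- "GLY"            # planted distal candidate
  data.frame(chain = "A", resnum = seq_len(n), resname = resname,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-domain hinge trajectory with ground truth
#'
#' See [hinge_spec()] for the motion model. The returned ground truth
#' records the planted collective-mode vectors (hinge and twist, expressed
#' in the mean-superposed frame in which PCA operates), per-frame hinge and
#' twist angles, the planted noiseless inter-domain centroid distances, the
#' active-site residues and the planted anticorrelated candidate pair, the
#' reference (crystal-like) structure and the matching domain map and
#' secondary-structure annotation.
#'
#' @param spec A `hinge_spec`.
#' @return A list with elements `trajectory` (`calpha_trajectory`),
#'   `reference` (a C-alpha `structure_model` of the noiseless reference
#'   conformation), and `ground_truth` (list; see Details).
#' @export
generate_hinge_trajectory <- function(spec) {
  if (!inherits(spec, "hinge_spec")) spec <- do.call(hinge_spec, spec)
  geo <- hinge_geometry(spec)
  site_res <- spec$n_res_domain_a %/% 2 + c(-2L, 0L, 2L)
  n <- spec$n_res_domain_a + spec$n_res_linker + spec$n_res_domain_b
  nf <- spec$n_frames
  t <- seq_len(nf) - 1
  amp_h <- spec$hinge_amplitude * pi / 180
  amp_t <- spec$twist_amplitude * pi / 180
  if (spec$mode == "oscillate") {
    gamma0 <- geo$gamma_open
    gamma <- gamma0 + amp_h * sin(2 * pi * t / spec$hinge_period)
    gamma_ref <- gamma0
  } else {
    ramp <- stats::plogis((t - spec$relax_changepoint_frame) / spec$relax_tau)
    gamma <- geo$gamma_closed + (geo$gamma_open - geo$gamma_closed) * ramp
    gamma_ref <- geo$gamma_closed
  }
  phi <- amp_t * sin(2 * pi * t / spec$twist_period)
  if (min(gamma) <= 0) {
    gtb_spec_error("hinge amplitude drives the domains through each other")
  }

  # Reference (crystal-like) conformation; the near-site control glycine is
  # the domain-B residue closest to the site in this structure.
  ref_coords <- geo$build(gamma_ref, 0)
  site_dists <- vapply(geo$idx_b, function(i)
    min(sqrt(colSums((t(ref_coords[site_res, , drop = FALSE]) -
                        ref_coords[i, ])^2))), numeric(1))
  control_res <- geo$idx_b[which.min(site_dists)]
  res <- hinge_residues(spec, site_res, control_res)

  loop_ranges <- spec$loop_residue_ranges %||%
    list(c(geo$idx_l[1], geo$idx_l[length(geo$idx_l)]))
  loop_res <- resolve_ranges(loop_ranges)
  sigma <- rep(spec$noise_sigma, n)
  sigma[res$resnum %in% loop_res] <-
    spec$noise_sigma * spec$loop_noise_multiplier

  coords <- array(NA_real_, dim = c(nf, n, 3))
  centroids_dist <- numeric(nf)
  rho <- spec$noise_ar1 %||% 0
  with_seed(spec$seed, {
    prev <- matrix(0, n, 3)
    for (f in seq_len(nf)) {
      base <- geo$build(gamma[f], phi[f])
      centroids_dist[f] <- sqrt(sum((colMeans(base[geo$idx_a, , drop = FALSE]) -
                                     colMeans(base[geo$idx_b, , drop = FALSE]))^2))
      eps <- matrix(stats::rnorm(3 * n, sd = rep(sigma, 3)), ncol = 3)
      # AR(1) in time with stationary sd = sigma (rho = 0: independent frames)
      prev <- if (rho > 0) {
        if (f == 1) eps else rho * prev + sqrt(1 - rho^2) * eps
      } else eps
      coords[f, , ] <- base + prev
    }
  })
  traj <- calpha_trajectory(coords, res, spec$frame_interval_ps)

  reference <- structure(list(
    atoms = data.frame(chain = res$chain, resnum = res$resnum,
                       resname = res$resname, atom = "CA",
                       x = ref_coords[, 1], y = ref_coords[, 2],
                       z = ref_coords[, 3], stringsAsFactors = FALSE),
    path = NA_character_), class = "structure_model")

  # Planted mode vectors in the frame PCA sees: differentiate the noiseless
  # motion through the same mean-structure superposition.
  mode_vector <- function(perturb) {
    delta <- 0.01
    tri <- array(NA_real_, dim = c(3, n, 3))
    for (j in 1:3) tri[j, , ] <- perturb((j - 2) * delta)
    tt <- align_to_mean(calpha_trajectory(tri, res, 1))
    v <- as.numeric(matrix(tt$coords[3, , ] - tt$coords[1, , ], ncol = 3))
    v / sqrt(sum(v^2))
  }
  gamma_mid <- if (spec$mode == "oscillate") gamma_ref else
    (geo$gamma_open + geo$gamma_closed) / 2
  hinge_mode <- mode_vector(function(d) geo$build(gamma_mid + d, 0))
  twist_mode <- mode_vector(function(d) geo$build(gamma_mid, d))

  na <- spec$n_res_domain_a; nl <- spec$n_res_linker
  dm <- domain_map(N = c(1, na), L = c(na + 1, na + nl),
                   C = c(na + nl + 1, n))
  ss <- ss_annotation(seq_len(n),
                      ifelse(seq_len(n) %in% geo$idx_l, "loop", "helix"))
  gt <- list(
    hinge_mode = hinge_mode, twist_mode = twist_mode,
    hinge_angles_deg = gamma * 180 / pi,
    twist_angles_deg = phi * 180 / pi,
    planted_distances = centroids_dist,
    site_residues = as.integer(site_res),
    planted_candidate = as.integer(n),
    control_candidate = as.integer(control_res),
    donor_site = as.integer((n - 5):(n - 1)),
    loop_residues = loop_res,
    noise_sigma = spec$noise_sigma,
    changepoint_frame = if (spec$mode == "relax")
      spec$relax_changepoint_frame else NA_integer_,
    spec = spec)
  list(trajectory = traj, reference = reference, domain_map = dm,
       ss = ss, ground_truth = gt)
}

#' Write a synthetic fixture set to a directory
#'
#' Emits the xyztable trajectory, a companion C-alpha PDB topology of the
#' reference conformation, a ready-to-run YAML analysis config and the
#' ground truth (structured text), the fixture set consumed by the CLI and
#' the test suite.
#'
#' @param sim Output of [generate_hinge_trajectory()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trajectory = file.path(dir, "trajectory.xyz"),
    structure = file.path(dir, "reference.pdb"),
    config = file.path(dir, "config.yaml"),
    ground_truth = file.path(dir, "ground_truth.yaml"))
  write_xyztable(sim$trajectory, paths$trajectory)
  ref <- sim$reference$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(ref)), ref$resname, ref$chain, ref$resnum,
    ref$x, ref$y, ref$z)
  writeLines(c(lines, "END"), paths$structure)
  gt <- sim$ground_truth
  dm <- sim$domain_map$ranges
  cfg <- list(
    structure = "reference.pdb",
    trajectory = "trajectory.xyz",
    trajectory_format = "xyztable",
    frame_interval_ps = sim$trajectory$frame_interval_ps,
    seed = gt$spec$seed,
    domains = lapply(dm, function(m)
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))),
    ss = list(helix = list(c(1, gt$spec$n_res_domain_a),
                           c(gt$spec$n_res_domain_a + gt$spec$n_res_linker + 1,
                             n_residues(sim$trajectory))),
              loop = list(c(gt$spec$n_res_domain_a + 1,
                            gt$spec$n_res_domain_a + gt$spec$n_res_linker))),
    active_site = gt$site_residues,
    mining = list(corr_cutoff = -0.4, min_dist = 25),
    pca = list(n_components = 3),
    density_bandwidth = 0.5,
    lowess_fraction = 0.3)
  yaml::write_yaml(cfg, paths$config)
  yaml::write_yaml(list(
    site_residues = gt$site_residues,
    planted_candidate = gt$planted_candidate,
    control_candidate = gt$control_candidate,
    donor_site = gt$donor_site,
    changepoint_frame = gt$changepoint_frame,
    hinge_angles_deg = gt$hinge_angles_deg,
    twist_angles_deg = gt$twist_angles_deg,
    planted_distances = gt$planted_distances,
    hinge_mode = gt$hinge_mode,
    twist_mode = gt$twist_mode), paths$ground_truth)
  invisible(paths)
}

#' Generate a synthetic Michaelis-Menten dataset
#'
#' Rates follow the MM equation with multiplicative lognormal noise of the
#' stated coefficient of variation (mean-one noise), deterministically seeded.
#'
#' @param kcat Turnover number (1/s).
#' @param Km Michaelis constant (M).
#' @param concs Substrate concentrations (M).
#' @param noise_cv Coefficient of variation of the noise (0 for exact rates).
#' @param seed Integer seed.
#' @return data.frame with columns `conc_M`, `rate_per_s`.
#' @export
generate_mm_dataset <- function(kcat, Km, concs, noise_cv = 0, seed = 1) {
  if (kcat <= 0 || Km <= 0) gtb_argument_error("parameters must be positive")
  v <- kcat * concs / (Km + concs)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    v <- with_seed(seed,
                   v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog))
  }
  data.frame(conc_M = concs, rate_per_s = v)
}
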