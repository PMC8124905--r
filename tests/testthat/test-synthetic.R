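test_that("generator is seed-deterministic and degenerates to a static chain", {
  sp <- hinge_spec(n_res_domain_a = 10, n_res_domain_b = 10,
                   n_res_linker = 4, n_frames = 50,
                   closed_distance = 6, open_distance = 12, seed = 5)
  a <- generate_hinge_trajectory(sp)
  b <- generate_hinge_trajectory(sp)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  c <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 10, n_res_domain_b = 10, n_res_linker = 4,
    n_frames = 50, closed_distance = 6, open_distance = 12, seed = 6))
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))

  quiet <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 10, n_res_domain_b = 10, n_res_linker = 4,
    n_frames = 50, hinge_amplitude = 0, twist_amplitude = 0,
    closed_distance = 6, open_distance = 12, noise_sigma = 0, seed = 5))
  expect_equal(rmsd_series(quiet$trajectory, quiet$reference)$value,
               rep(0, 50), tolerance = 1e-9)
  expect_equal(rmsf_profile(quiet$trajectory)$rmsf, rep(0, 24),
               tolerance = 1e-9)
  dser <- interdomain_distance_series(quiet$trajectory, quiet$domain_map)
  expect_equal(diff(range(dser$value)), 0, tolerance = 1e-9)

  # AR(1) noise hook: correlates consecutive frames, keeps stationary sd
  ar <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 10, n_res_domain_b = 10, n_res_linker = 4,
    n_frames = 2000, hinge_amplitude = 0, twist_amplitude = 0,
    closed_distance = 6, open_distance = 12, noise_ar1 = 0.8, seed = 5))
  x <- ar$trajectory$coords[, 5, 1]
  x <- x - mean(x)
  lag1 <- sum(x[-1] * x[-length(x)]) / sum(x^2)
  expect_equal(lag1, 0.8, tolerance = 0.05)
  expect_equal(stats::sd(x), 0.3, tolerance = 0.1)
})

test_that("consecutive C-alpha spacing and planted geometry are physical", {
  sim <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 20, n_res_domain_b = 20, n_res_linker = 6,
    noise_sigma = 0, hinge_amplitude = 0, twist_amplitude = 0,
    n_frames = 2, seed = 1))
  x <- matrix(sim$trajectory$coords[1, , ], ncol = 3)
  spacing <- sqrt(rowSums((x[2:20, ] - x[1:19, ])^2))  # within domain A
  expect_equal(spacing, rep(3.8, 19), tolerance = 0.02)
  expect_error(generate_hinge_trajectory(hinge_spec(closed_distance = 1)),
               class = "gtb_spec_error")
  expect_error(
    generate_hinge_trajectory(hinge_spec(open_distance = 1e4)),
    class = "gtb_spec_error")
})

test_that("relax mode plants a bimodal closed/open distance distribution", {
  sim <- generate_hinge_trajectory(hinge_spec(
    mode = "relax", n_res_domain_a = 30, n_res_domain_b = 30,
    n_res_linker = 8, n_frames = 800, seed = 11))
  ds <- interdomain_distance_series(sim$trajectory, sim$domain_map)
  dd <- distance_density(ds, 0.5)
  expect_equal(nrow(dd$modes), 2)
  expect_equal(sort(dd$modes$location), c(9, 24), tolerance = 0.06)
  # planted noiseless distances bracket the same modes
  expect_equal(min(sim$ground_truth$planted_distances), 9, tolerance = 0.01)
  expect_equal(max(sim$ground_truth$planted_distances), 24, tolerance = 0.01)
})

test_that("relax mode yields a biphasic global RMSD with the knee at the changepoint", {
  sim <- generate_hinge_trajectory(hinge_spec(
    mode = "relax", n_res_domain_a = 30, n_res_domain_b = 30,
    n_res_linker = 8, n_frames = 800, relax_changepoint_frame = 400,
    seed = 12))
  glob <- rmsd_series(sim$trajectory, sim$reference)
  sm <- lowess_smooth(glob, 0.3)
  mid <- (min(sm$value) + max(sm$value)) / 2
  knee_frame <- which(sm$value >= mid)[1]
  expect_lt(abs(knee_frame - 400), 0.1 * 400)
  # while per-domain RMSD stays at the noise floor throughout
  for (lab in c("N", "C")) {
    sel <- domain_residues(sim$domain_map, lab)
    dser <- rmsd_series(sim$trajectory, sim$reference,
                        fit_selection = sel, measure_selection = sel)
    expect_lt(max(dser$value), 3 * sim$ground_truth$noise_sigma)
  }
  expect_gt(max(glob$value), 5 * sim$ground_truth$noise_sigma)
})

test_that("oscillate-mode ground truth drives end-to-end recovery", {
  sim <- small_oscillate_sim()
  gt <- sim$ground_truth
  al <- align_to_mean(sim$trajectory)
  m <- pca_fit(al, K = 3)
  expect_gt(abs(sum(m$eigenvectors[, 1] * gt$hinge_mode)), 0.95)
  d <- dcc_matrix(al)
  i <- match(gt$site_residues[2], d$residues$resnum)
  j <- match(gt$planted_candidate, d$residues$resnum)
  expect_lt(d$values[i, j], -0.5)
  # hinge angles follow the planted sinusoid
  sp <- gt$spec
  expect_equal(gt$hinge_angles_deg,
               mean(gt$hinge_angles_deg) + sp$hinge_amplitude *
                 sin(2 * pi * (seq_len(sp$n_frames) - 1) / sp$hinge_period),
               tolerance = 1e-6)
})

test_that("fixture writing round-trips through the config and trajectory readers", {
  d <- withr::local_tempdir()
  sim <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 10, n_res_domain_b = 10, n_res_linker = 4,
    n_frames = 30, closed_distance = 6, open_distance = 12, seed = 3))
  paths <- write_synthetic_fixture(sim, d)
  expect_true(all(file.exists(unlist(paths))))
  cfg <- read_run_config(paths$config)
  topo <- read_structure(cfg$structure)
  tr <- read_trajectory(cfg$trajectory, topo, format = "xyztable")
  expect_equal(tr$coords, sim$trajectory$coords, tolerance = 1e-6)
  expect_equal(nrow(topo$atoms), n_residues(sim$trajectory))
  gt_file <- yaml::read_yaml(paths$ground_truth)
  expect_equal(gt_file$planted_candidate,
               sim$ground_truth$planted_candidate)
})
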