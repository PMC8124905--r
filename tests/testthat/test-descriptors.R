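test_that("rmsd_series matches closed forms and a brute-force oracle", {
  # static trajectory -> identically zero
  base <- matrix(rnorm(15, sd = 3), ncol = 3)
  coords <- array(rep(base, each = 4), c(4, 5, 3))
  res <- data.frame(chain = "A", resnum = 1:5, resname = "ALA")
  tr <- calpha_trajectory(coords, res, 10)
  expect_equal(rmsd_series(tr, base)$value, rep(0, 4), tolerance = 1e-10)

  # single displaced residue among M: RMSD = d / sqrt(M)
  d <- 2.4; M <- 5
  coords2 <- coords
  coords2[2, 3, 1] <- coords2[2, 3, 1] + d
  tr2 <- calpha_trajectory(coords2, res, 10)
  ser <- rmsd_series(tr2, base, fit_selection = c(1, 2, 4, 5),
                     measure_selection = NULL)
  expect_equal(ser$value[2], d / sqrt(M), tolerance = 1e-9)

  # random trajectory vs double-loop recomputation after the same fit
  withr::local_seed(7)
  tr3 <- make_tiny_traj(nf = 4, nr = 5, sd = 1)
  ref <- frame_coords(tr3, 1)
  got <- rmsd_series(tr3, ref)
  al <- align_trajectory(tr3, ref)
  want <- vapply(1:4, function(f) brute_rmsd(frame_coords(al, f), ref),
                 numeric(1))
  expect_equal(got$value, want, tolerance = 1e-10)
})

test_that("rmsd band fractions count half-open bands and always total 100%", {
  ser <- scalar_series(1:4, c(1, 1, 3.5, 2.5))
  expect_equal(unname(rmsd_band_fractions(ser, c(2, 3))), c(50, 25, 25))
  low <- scalar_series(1:5, rep(0.5, 5))
  expect_equal(unname(rmsd_band_fractions(low, c(2, 3))[1]), 100)
  withr::local_seed(8)
  u <- scalar_series(1:10000, runif(10000, 0, 4))
  fr <- rmsd_band_fractions(u, c(2, 3))
  expect_equal(unname(fr), c(50, 25, 25), tolerance = 0.04)
  for (i in 1:5) {
    x <- scalar_series(1:50, rexp(50))
    expect_equal(sum(rmsd_band_fractions(x, c(0.5, 1, 2))), 100,
                 tolerance = 1e-9)
  }
})

test_that("rmsf reproduces closed forms for static, sinusoidal and Gaussian motion", {
  res <- data.frame(chain = "A", resnum = 1:3, resname = "ALA")
  base <- matrix(rnorm(9), ncol = 3)
  static <- calpha_trajectory(array(rep(base, each = 10), c(10, 3, 3)),
                              res, 1)
  expect_equal(rmsf_profile(static)$rmsf, rep(0, 3), tolerance = 1e-12)
  expect_error(rmsf_profile(subset_frames(static, 1)),
               class = "gtb_shape_error")

  # residue 2 oscillating along x over exact full periods: rmsf = a/sqrt(2)
  a <- 1.7; nT <- 8; Tf <- 50
  coords <- array(rep(base, each = nT * Tf), c(nT * Tf, 3, 3))
  coords[, 2, 1] <- coords[, 2, 1] +
    a * sin(2 * pi * (0:(nT * Tf - 1)) / Tf)
  osc <- calpha_trajectory(coords, res, 1)
  prof <- rmsf_profile(osc)
  expect_equal(prof$rmsf[2], a / sqrt(2), tolerance = 1e-9)
  expect_equal(prof$rmsf[c(1, 3)], c(0, 0), tolerance = 1e-12)

  # isotropic Gaussian jitter: rmsf ~ sigma * sqrt(3)
  withr::local_seed(9)
  sigma <- 0.8
  coords2 <- array(rep(base, each = 10000), c(10000, 3, 3)) +
    array(rnorm(10000 * 9, sd = sigma), c(10000, 3, 3))
  jit <- calpha_trajectory(coords2, res, 1)
  expect_equal(rmsf_profile(jit)$rmsf, rep(sigma * sqrt(3), 3),
               tolerance = 0.03)
})

test_that("flexible-region flagging recovers planted high-noise loops", {
  prof <- structure(data.frame(chain = "A", resnum = 1:10, resname = "ALA",
                               rmsf = c(1, 1, 1, 1, 3, 3, 3, 1, 1, 1)),
                    class = c("rmsf_profile", "data.frame"))
  runs <- flag_flexible_regions(prof, 2)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end), c(5, 7))
  expect_equal(nrow(flag_flexible_regions(prof, 5)), 0)

  # generator with quiet hinge: only the 3x-noise linker exceeds threshold
  sim <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 20, n_res_domain_b = 20, n_res_linker = 6,
    hinge_amplitude = 0, twist_amplitude = 0, n_frames = 300, seed = 21))
  prof2 <- rmsf_profile(align_to_mean(sim$trajectory))
  sigma <- sim$ground_truth$noise_sigma
  runs2 <- flag_flexible_regions(prof2, 2 * sigma * sqrt(3),
                                 domains = sim$domain_map, ss = sim$ss)
  expect_equal(nrow(runs2), 1)
  expect_equal(sort(seq(runs2$start, runs2$end)),
               sort(sim$ground_truth$loop_residues))
  expect_equal(runs2$domains, "L")
  expect_equal(runs2$ss_classes, "loop")
})

test_that("rgyr closed forms, oracle agreement and rigid-motion invariance", {
  res <- data.frame(chain = "A", resnum = 1:2, resname = "ALA")
  coincident <- calpha_trajectory(array(0, c(2, 2, 3)), res, 1)
  expect_equal(rgyr_series(coincident)$value, c(0, 0))
  two <- array(0, c(1, 2, 3)); two[1, 2, 3] <- 6
  expect_equal(rgyr_series(calpha_trajectory(two, res, 1))$value, 3)

  withr::local_seed(10)
  tr <- make_tiny_traj(nf = 3, nr = 9)
  got <- rgyr_series(tr)$value
  want <- vapply(1:3, function(f) brute_rgyr(frame_coords(tr, f)),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  moved <- tr$coords
  for (f in 1:3) {
    moved[f, , ] <- sweep(matrix(tr$coords[f, , ], ncol = 3) %*%
                            random_rotation(), 2, rnorm(3, sd = 20),
                          FUN = "+")
  }
  tr2 <- calpha_trajectory(moved, tr$residues, 1)
  expect_equal(rgyr_series(tr2)$value, got, tolerance = 1e-9)
})

test_that("series correlation matches the textbook formula and flags zero variance", {
  a <- scalar_series(1:20, rnorm(20))
  expect_equal(series_correlation(a, scalar_series(1:20, 2 * a$value + 1)), 1)
  expect_equal(series_correlation(a, scalar_series(1:20, -a$value)), -1)
  withr::local_seed(11)
  x <- rnorm(30); y <- rnorm(30)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(series_correlation(scalar_series(1:30, x),
                                  scalar_series(1:30, y)),
               r_manual, tolerance = 1e-12)
  expect_error(series_correlation(a, scalar_series(1:20, rep(1, 20))),
               class = "gtb_degeneracy_error")
})

test_that("inter-domain distances are centroid distances, invariant to rigid motion", {
  res <- data.frame(chain = "A", resnum = 1:4, resname = "ALA")
  dm <- domain_map(N = c(1, 2), C = c(3, 4))
  coords <- array(0, c(1, 4, 3))
  coords[1, 2, 1] <- 2; coords[1, 4, 1] <- 2       # both centroids at (1,0,0)
  tr <- calpha_trajectory(coords, res, 1)
  expect_equal(interdomain_distance_series(tr, dm)$value, 0)
  coords[1, 3:4, 3] <- coords[1, 3:4, 3] + 10
  tr <- calpha_trajectory(coords, res, 1)
  expect_equal(interdomain_distance_series(tr, dm)$value, 10)
  withr::local_seed(12)
  R <- random_rotation()
  coords[1, , ] <- sweep(matrix(coords[1, , ], ncol = 3) %*% R, 2,
                         c(5, -2, 9), FUN = "+")
  expect_equal(interdomain_distance_series(
    calpha_trajectory(coords, res, 1), dm)$value, 10, tolerance = 1e-9)
  expect_error(interdomain_distance_series(tr, dm, a = "S"),
               class = "gtb_config_error")
})

test_that("distance densities integrate to one and locate planted mixture modes", {
  const <- scalar_series(1:50, rep(7, 50))
  d1 <- distance_density(const, 0.5)
  expect_equal(trapz(d1$grid, d1$density), 1, tolerance = 1e-3)
  expect_equal(nrow(d1$modes), 1)
  expect_equal(d1$modes$location, 7, tolerance = 0.05)

  withr::local_seed(13)
  x <- c(rnorm(500, 9, 0.5), rnorm(500, 24, 0.5))
  d2 <- distance_density(scalar_series(seq_along(x), x), 0.5)
  expect_equal(nrow(d2$modes), 2)
  expect_equal(sort(d2$modes$location), c(9, 24), tolerance = 0.3)
  expect_equal(trapz(d2$grid, d2$density), 1, tolerance = 1e-3)
  for (i in 1:3) {
    y <- scalar_series(1:200, rexp(200, 1 / 5))
    dd <- distance_density(y, 0.8)
    expect_equal(trapz(dd$grid, dd$density), 1, tolerance = 1e-3)
  }
})

test_that("lowess smoothing is exact on constants and lines", {
  const <- scalar_series(1:20, rep(3.3, 20))
  expect_equal(lowess_smooth(const, 0.5)$value, rep(3.3, 20),
               tolerance = 1e-10)
  lin <- scalar_series(1:40, 0.5 * (1:40) + 2)
  expect_equal(lowess_smooth(lin, 1)$value, lin$value, tolerance = 1e-8)
  expect_error(lowess_smooth(lin, 0), class = "gtb_argument_error")
})
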