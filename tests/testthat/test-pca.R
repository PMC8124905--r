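test_that("pca_fit recovers a planted sinusoidal collective mode", {
  withr::local_seed(14)
  nr <- 20; nf <- 600
  base <- matrix(rnorm(nr * 3, sd = 5), ncol = 3)
  v <- rnorm(nr * 3); v <- v / sqrt(sum(v^2))
  amp <- 3; sigma <- 0.2
  proj_t <- amp * sin(2 * pi * (0:(nf - 1)) / 150)
  coords <- array(NA_real_, c(nf, nr, 3))
  for (f in 1:nf) {
    coords[f, , ] <- base + matrix(proj_t[f] * v, ncol = 3) +
      rnorm(nr * 3, sd = sigma)
  }
  tr <- calpha_trajectory(coords, data.frame(chain = "A", resnum = 1:nr,
                                             resname = "ALA"), 1)
  m <- pca_fit(tr)   # no alignment: the planted mode is the test target
  expect_gt(abs(sum(m$eigenvectors[, 1] * v)), 0.95)
  planted_fraction <- 100 * (amp^2 / 2) / (amp^2 / 2 + 3 * nr * sigma^2)
  expect_equal(m$variance_fractions[1], planted_fraction, tolerance = 0.07)
})

test_that("pca spectra obey rank, trace and orthonormality contracts", {
  withr::local_seed(15)
  tr2 <- make_tiny_traj(nf = 2, nr = 6)
  m2 <- pca_fit(tr2)
  expect_equal(sum(m2$eigenvalues > 1e-10 * m2$eigenvalues[1]), 1)

  tr <- make_tiny_traj(nf = 12, nr = 5)
  m <- pca_fit(tr)
  X <- matrix(tr$coords, nrow = 12)
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-6 * sum(m$eigenvalues))
  expect_equal(sum(m$variance_fractions), 100, tolerance = 1e-6)
  expect_equal(crossprod(m$eigenvectors),
               diag(ncol(m$eigenvectors)), tolerance = 1e-8)
  expect_equal(colMeans(m$projections), rep(0, ncol(m$projections)),
               tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(m$eigenvalues > -1e-10))
  # full-rank reconstruction reproduces every frame
  rec <- m$projections %*% t(m$eigenvectors)
  rebuilt <- sweep(rec, 2, -as.numeric(m$mean_coords), FUN = "-")
  expect_equal(rebuilt, X, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pca agrees with an independent implementation on random data", {
  withr::local_seed(16)
  tr <- make_tiny_traj(nf = 40, nr = 6)
  al <- align_to_mean(tr)
  m <- pca_fit(al)
  xyz <- matrix(NA_real_, 40, 18)
  for (r in 1:6) xyz[, (r - 1) * 3 + (1:3)] <- al$coords[, r, ]
  pb <- bio3d::pca.xyz(xyz)
  expect_equal(m$eigenvalues[1:10], pb$L[1:10], tolerance = 1e-8)
  # leading eigenvector agrees up to sign (mind the coordinate ordering)
  v_ours <- matrix(m$eigenvectors[, 1], ncol = 3)
  v_bio <- matrix(pb$U[, 1], ncol = 3, byrow = TRUE)
  expect_equal(abs(sum(v_ours * v_bio)), 1, tolerance = 1e-8)
})

test_that("pc interpolation spans the projection extremes linearly", {
  withr::local_seed(17)
  tr <- make_tiny_traj(nf = 30, nr = 5)
  m <- pca_fit(tr, K = 4)
  expect_error(pc_interpolation(m, 1, steps = 5),
               class = "gtb_argument_error")
  p <- m$projections[, 2]
  two <- pc_interpolation(m, 2, steps = 2)
  lo <- m$mean_coords + matrix(min(p) * m$eigenvectors[, 2], ncol = 3)
  hi <- m$mean_coords + matrix(max(p) * m$eigenvectors[, 2], ncol = 3)
  expect_equal(matrix(two$coords[1, , ], ncol = 3), lo, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(matrix(two$coords[2, , ], ncol = 3), hi, tolerance = 1e-10,
               ignore_attr = TRUE)
  # re-projection recovers the interpolated scalars; other PCs stay at 0
  steps <- 6
  interp <- pc_interpolation(m, 2, steps = steps)
  reproj <- matrix(interp$coords, nrow = steps)
  reproj <- sweep(reproj, 2, as.numeric(m$mean_coords)) %*% m$eigenvectors
  expect_equal(reproj[, 2], seq(min(p), max(p), length.out = steps),
               tolerance = 1e-8)
  expect_equal(reproj[, c(1, 3, 4)],
               matrix(0, steps, 3), tolerance = 1e-8, ignore_attr = TRUE)
  # midpoints of the path sit at projection midpoints (linearity)
  expect_equal(reproj[3, 2] + reproj[4, 2], reproj[1, 2] + reproj[6, 2],
               tolerance = 1e-8)
})

test_that("octant labels, occupancy, transitions and crossings match a counting oracle", {
  fake_model <- function(P) {
    structure(list(projections = P, eigenvectors = matrix(0, 9, 3)),
              class = "traj_pca")
  }
  allpos <- fake_model(matrix(abs(rnorm(60)) + 0.1, ncol = 3))
  tr_all <- octant_trace(allpos)
  expect_equal(unname(tr_all$occupancy["I"]), 100)
  expect_equal(nrow(tr_all$transitions), 0)

  # sinusoidal PC1 over 3 full periods crosses zero six times
  t <- 0:600
  P <- cbind(sin(2 * pi * t / 200 + 0.001), 1 + 0 * t, 1 + 0 * t)
  expect_equal(unname(octant_trace(fake_model(P))$zero_crossings["PC1"]), 6)

  withr::local_seed(18)
  for (i in 1:5) {
    P <- matrix(rnorm(300), ncol = 3)
    got <- octant_trace(fake_model(P))
    want <- oracle_octants(P)
    expect_equal(unname(as.integer(got$labels)), want$labels)
    expect_equal(unname(got$occupancy), want$occupancy)
    expect_equal(nrow(got$transitions), want$n_transitions)
    expect_equal(unname(got$zero_crossings), want$zero_crossings)
    expect_equal(sum(got$occupancy), 100, tolerance = 1e-9)
    # occupancy invariant under uniform scaling of projections
    expect_equal(octant_trace(fake_model(P * 17))$occupancy, got$occupancy)
  }
})

test_that("slow and fast planted modes keep their frequency order in PC crossings", {
  # noise-free two-mode hinge: crossing counts reflect the planted periods
  sim <- generate_hinge_trajectory(hinge_spec(
    n_res_domain_a = 30, n_res_domain_b = 30, n_res_linker = 8,
    n_frames = 600, hinge_period = 150, twist_period = 600,
    noise_sigma = 0, seed = 19))
  m <- pca_fit(align_to_mean(sim$trajectory), K = 3)
  zc <- octant_trace(m)$zero_crossings
  expect_equal(unname(zc["PC1"]), 2 * 600 / 150, tolerance = 1)
  expect_lt(zc["PC2"], zc["PC1"])  # slower twist crosses less often
})
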