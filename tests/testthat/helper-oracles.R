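# Independent oracles and fixture builders. Everything here is deliberately
# naive (grid searches, double loops) and shares no code with the package
# implementation paths it checks.

# Rotation matrix from an axis-angle vector (Rodrigues formula, written out
# independently of the package's internal helper).
aa_to_rot <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  a <- r / th
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * tcrossprod(a)
}

# Minimal superposition RMSD by brute-force search over rotation space:
# a coarse axis-angle grid followed by shrinking local refinements.
oracle_min_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(r) sqrt(sum((Pc %*% t(aa_to_rot(r)) - Qc)^2) / nrow(P))
  best_r <- c(0, 0, 0); best <- f(best_r)
  g <- seq(-pi, pi, by = 0.4)
  for (x in g) for (y in g) for (z in g) {
    v <- c(x, y, z)
    if (sum(v^2) <= (pi + 0.4)^2) {
      val <- f(v)
      if (val < best) { best <- val; best_r <- v }
    }
  }
  step <- 0.4
  for (it in 1:7) {
    step <- step / 3
    g <- seq(-2, 2) * step
    for (x in g) for (y in g) for (z in g) {
      v <- best_r + c(x, y, z)
      val <- f(v)
      if (val < best) { best <- val; best_r <- v }
    }
  }
  best
}

random_rotation <- function() {
  aa_to_rot(stats::runif(3, -pi, pi) * stats::runif(1))
}

# Direct double-loop RMSD between one frame and a reference (no fitting).
brute_rmsd <- function(X, R) {
  tot <- 0
  for (i in seq_len(nrow(X))) tot <- tot + sum((X[i, ] - R[i, ])^2)
  sqrt(tot / nrow(X))
}

brute_rgyr <- function(X) {
  ctr <- colMeans(X)
  tot <- 0
  for (i in seq_len(nrow(X))) tot <- tot + sum((X[i, ] - ctr)^2)
  sqrt(tot / nrow(X))
}

# Direct double-loop DCC of an aligned coordinate array (frames x n x 3).
brute_dcc <- function(coords) {
  nf <- dim(coords)[1]; nr <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(NA_real_, nr, nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      num <- 0; di <- 0; dj <- 0
      for (f in seq_len(nf)) {
        a <- coords[f, i, ] - mu[i, ]
        b <- coords[f, j, ] - mu[j, ]
        num <- num + sum(a * b)
        di <- di + sum(a * a)
        dj <- dj + sum(b * b)
      }
      C[i, j] <- num / sqrt(di * dj)
    }
  }
  C
}

# Literal octant bookkeeping from a frames x 3 projection matrix.
oracle_octants <- function(P) {
  lab <- integer(nrow(P))
  for (f in seq_len(nrow(P))) {
    s <- ifelse(P[f, ] >= 0, "+", "-")
    key <- paste(s, collapse = "")
    lab[f] <- switch(key,
                     "+++" = 1L, "-++" = 2L, "--+" = 3L, "+-+" = 4L,
                     "++-" = 5L, "-+-" = 6L, "---" = 7L, "+--" = 8L)
  }
  occ <- numeric(8)
  for (k in 1:8) occ[k] <- 100 * sum(lab == k) / length(lab)
  trans <- 0
  for (f in 2:length(lab)) if (lab[f] != lab[f - 1]) trans <- trans + 1
  zc <- integer(3)
  for (k in 1:3) {
    s <- sign(P[, k]); s <- s[s != 0]
    zc[k] <- sum(s[-1] != s[-length(s)])
  }
  list(labels = lab, occupancy = occ, n_transitions = trans,
       zero_crossings = zc)
}

# Trapezoid integral on a grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Small random trajectory around a random rigid base structure.
make_tiny_traj <- function(nf = 5, nr = 6, sd = 0.5, interval = 10) {
  base <- matrix(stats::rnorm(nr * 3, sd = 4), ncol = 3)
  coords <- array(NA_real_, c(nf, nr, 3))
  for (f in seq_len(nf)) coords[f, , ] <- base + stats::rnorm(nr * 3, sd = sd)
  calpha_trajectory(coords,
                    data.frame(chain = "A", resnum = seq_len(nr),
                               resname = "ALA"),
                    interval)
}

# Hand-written PDB text builder (CA-only unless atom names given).
write_test_pdb <- function(path, resnum, xyz, resname = "ALA", chain = "A",
                           atom = "CA", occ = 1, alt = "") {
  n <- length(resnum)
  resname <- rep_len(resname, n); chain <- rep_len(chain, n)
  atom <- rep_len(atom, n); occ <- rep_len(occ, n); alt <- rep_len(alt, n)
  lines <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
    seq_len(n), atom, alt, resname, chain, resnum,
    xyz[, 1], xyz[, 2], xyz[, 3], occ)
  writeLines(c(lines, "END"), path)
  path
}

# Shared small synthetic instances (cached per test run).
small_oscillate_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_hinge_trajectory(hinge_spec(
        n_res_domain_a = 30, n_res_domain_b = 30, n_res_linker = 8,
        n_frames = 400, hinge_period = 100, twist_period = 400, seed = 7))
    }
    cache
  }
})
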