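# Langevin window generation and WHAM free-energy reconstruction.

test_that("Langevin windows are deterministic per seed and respect equipartition", {
  pot <- make_potential("flat")
  w1 <- langevin_windows(pot, centers = 0, k = 5, n_steps = 50000,
                         dt = 0.002, seed = 9)
  w2 <- langevin_windows(pot, centers = 0, k = 5, n_steps = 50000,
                         dt = 0.002, seed = 9)
  expect_identical(w1[[1]]$samples, w2[[1]]$samples)
  # harmonic bias alone: sample variance kT/k within 10%
  expect_equal(stats::var(w1[[1]]$samples), 1 / 5, tolerance = 0.1)
  # free diffusion spreads: displacement variance grows with lag
  wf <- langevin_windows(pot, centers = 0, k = 0, n_steps = 20000,
                         dt = 0.002, seed = 4, burn_in = 0)
  x <- wf[[1]]$samples
  v_short <- stats::var(x[1:1000] - x[1])
  v_long <- stats::var(x[1:10000] - x[1])
  expect_gt(v_long, v_short)
  # stability guard
  expect_error(langevin_windows(pot, 0, k = 100, dt = 0.01),
               class = "monomix_invalid_argument")
})

test_that("a single unbiased window with even samples yields a flat profile", {
  w <- umbrella_window(0, 0, seq(-1, 1, length.out = 20001))
  pmf <- wham(list(w), grid = c(-1, 1, 20))
  expect_lt(max(pmf$G) - min(pmf$G), 0.05)
})

test_that("WHAM recovers a harmonic free-energy surface within 0.1 kT RMSE", {
  pot <- make_potential("harmonic", kappa = 2)
  w <- langevin_windows(pot, centers = seq(-3, 3, 0.5), k = 10,
                        n_steps = 60000, dt = 0.005, seed = 11)
  pmf <- wham(w, grid = c(-3.2, 3.2, 64))
  expect_true(attr(pmf, "converged"))
  sel <- !is.na(pmf$G) & abs(pmf$x) <= 2
  ref <- 0.5 * 2 * pmf$x[sel]^2
  expect_lt(sqrt(mean((pmf$G[sel] - (ref - min(ref)))^2)), 0.1)
})

test_that("WHAM recovers a double-well barrier within 5%", {
  a <- 0.5; b <- 1.5
  pot <- make_potential("double_well", a = a, b = b)
  w <- langevin_windows(pot, centers = seq(-2.4, 2.4, 0.2), k = 12,
                        n_steps = 1e5, dt = 0.005, seed = 5)
  pmf <- wham(w, grid = c(-2.5, 2.5, 101))
  barrier <- pmf$G[which.min(abs(pmf$x))]
  expect_equal(barrier, a * b^4, tolerance = 0.05)
  # minima near +/- b
  expect_equal(abs(pmf$x[which.min(pmf$G)]), b, tolerance = 0.1)
})

test_that("WHAM output is invariant under window permutation and well-behaved in iteration", {
  pot <- make_potential("harmonic", kappa = 2)
  w <- langevin_windows(pot, centers = seq(-2, 2, 0.5), k = 8,
                        n_steps = 20000, dt = 0.005, seed = 2)
  p1 <- wham(w, grid = c(-2.2, 2.2, 44))
  p2 <- wham(rev(w), grid = c(-2.2, 2.2, 44))
  expect_equal(p1$G, p2$G, tolerance = 1e-4)
  # residual is non-increasing once iteration settles
  rh <- attr(p1, "residual_history")
  expect_true(all(diff(rh[-(1:10)]) <= 1e-12))
})

test_that("the converged estimate is self-consistent under per-window reweighting", {
  pot <- make_potential("harmonic", kappa = 2)
  w <- langevin_windows(pot, centers = seq(-2, 2, 0.5), k = 10,
                        n_steps = 1e5, dt = 0.005, seed = 6)
  grid <- c(-2.2, 2.2, 44)
  pmf <- wham(w, grid = grid)
  P <- attr(pmf, "P")
  i <- 5  # a central window
  U <- 0.5 * w[[i]]$k * (pmf$x - w[[i]]$center)^2
  q <- P * exp(-U); q <- q / sum(q)
  breaks <- seq(grid[1], grid[2], length.out = grid[3] + 1)
  h <- tabulate(findInterval(w[[i]]$samples, breaks, rightmost.closed = TRUE),
                grid[3])
  h <- h / sum(h)
  keep <- h > 0 & q > 0
  kl <- sum(h[keep] * log(h[keep] / q[keep]))
  expect_lt(kl, 0.05)
})

test_that("degenerate inputs are handled: empty bins masked, disjoint windows flagged", {
  pot <- make_potential("harmonic", kappa = 2)
  w <- langevin_windows(pot, centers = c(-1, 1), k = 50, n_steps = 5000,
                        dt = 0.001, seed = 3)
  pmf <- suppressWarnings(wham(w, grid = c(-5, 5, 100), max_iter = 500))
  expect_true(any(is.na(pmf$G)))          # unreachable bins stay undefined
  expect_true(all(is.finite(pmf$G[!is.na(pmf$G)])))
  # two windows with no histogram overlap are flagged: their relative
  # free energies cannot be tied together
  set.seed(12)
  wa <- umbrella_window(-3, 5, rnorm(500, -3, 0.1))
  wb <- umbrella_window(3, 5, rnorm(500, 3, 0.1))
  expect_warning(wham(list(wa, wb), grid = c(-4, 4, 80), max_iter = 200),
                 "overlap")
})

test_that("free-energy differences read off the profile correctly", {
  pot <- make_potential("harmonic", kappa = 2)
  w <- langevin_windows(pot, centers = seq(-3, 3, 0.5), k = 10,
                        n_steps = 60000, dt = 0.005, seed = 11)
  pmf <- wham(w, grid = c(-3.2, 3.2, 64))
  expect_equal(unname(delta_g(pmf, c(-0.5, 0.5), c(-0.5, 0.5))["kT"]), 0)
  dg <- delta_g(pmf, c(-0.1, 0.1), c(1.9, 2.1))
  expect_equal(unname(dg["kT"]), 4, tolerance = 0.1)     # (1/2) * 2 * 2^2
  expect_equal(unname(dg["kJ_mol"]), unname(dg["kT"]) * kT_kJ_mol(),
               tolerance = 1e-10)
  # monotone growth away from the minimum
  d1 <- delta_g(pmf, c(-0.1, 0.1), c(0.9, 1.1))["kT"]
  d2 <- delta_g(pmf, c(-0.1, 0.1), c(1.9, 2.1))["kT"]
  expect_gt(d2, d1)
  expect_error(delta_g(pmf, c(-0.1, 0.1), c(50, 60)), "no defined")
})

test_that("window files and manifests round-trip with exact unit conversion", {
  pot <- make_potential("harmonic", kappa = 1)
  w <- langevin_windows(pot, centers = c(-1, 0, 1), k = 4, n_steps = 2000,
                        dt = 0.005, seed = 8)
  dir <- file.path(tempdir(), "wham-windows")
  manifest <- write_window_manifest(w, dir)
  back <- read_window_manifest(manifest)
  expect_identical(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$center, w[[i]]$center)
    expect_equal(back[[i]]$k, w[[i]]$k, tolerance = 1e-9)
    expect_equal(back[[i]]$samples, w[[i]]$samples, tolerance = 1e-9)
  }
  # the k header on disk is in kJ/mol/nm^2 (GROMACS convention)
  hdr <- readLines(file.path(dir, "window_001.dat"), n = 2)
  k_disk <- as.numeric(strsplit(hdr[2], " ")[[1]][2])
  expect_equal(k_disk, 4 * kT_kJ_mol() * 100, tolerance = 1e-6)
})
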