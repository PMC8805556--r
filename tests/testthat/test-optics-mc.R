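# Photon-transport Monte Carlo: analytic limits, conservation, determinism.

test_that("Henyey-Greenstein sampling matches its closed-form inverse CDF", {
  # isotropic case is uniform: cos = 2u - 1
  expect_equal(sample_hg_cosine(0, 0.75), 0.5)
  expect_equal(sample_hg_cosine(0, c(0, 0.5)), c(-1, 0))

  # brute-force CDF-inversion oracle: integrate the HG density numerically
  # and invert with uniroot, independent of the sampler's algebra
  hg_pdf <- function(x, g) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * x)^1.5
  hg_cdf <- function(x, g)
    stats::integrate(hg_pdf, -1, x, g = g, rel.tol = 1e-12)$value
  for (g in c(0.5, -0.3, 0.9)) {
    for (u in c(0.1, 0.5, 0.9)) {
      ref <- uniroot(function(x) hg_cdf(x, g) - u, c(-1 + 1e-12, 1 - 1e-12),
                     tol = 1e-12)$root
      expect_equal(sample_hg_cosine(g, u), ref, tolerance = 1e-9)
    }
  }

  # analytic mean of the HG density equals g
  n <- 2e5
  u <- runif(n)
  for (g in c(-0.5, 0, 0.5, 0.9)) {
    x <- sample_hg_cosine(g, u)
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - g), 3 * se + 1e-12)
  }

  expect_error(sample_hg_cosine(1, 0.5), "anisotropy")
  expect_error(tissue_optics(0.1, 1, g = -1), "anisotropy")
})

test_that("every transport run conserves energy through the explicit ledger", {
  geo <- probe_geometry()
  gs <- grid_spec(extent = 400, voxel_edge = 20)
  for (opt in list(optics_preset("blue475"), tissue_optics(0, 5, 0.5),
                   tissue_optics(2, 0, 0))) {
    fl <- simulate_illumination(geo, opt, gs, n_packets = 2e4, seed = 3)
    total <- sum(fl$values) + fl$escaped_energy + fl$shank_energy +
      fl$window_energy + fl$roulette_residual
    expect_lt(abs(total - fl$launched_power) / fl$launched_power, 1e-9)
  }
  # no absorption: nothing can be deposited
  fl0 <- simulate_illumination(geo, tissue_optics(0, 5, 0.5), gs,
                               n_packets = 2e4, seed = 3)
  expect_identical(sum(fl0$values), 0)
})

test_that("fluence is linear in power and bit-identical under a fixed seed", {
  geo <- probe_geometry()
  gs <- grid_spec(extent = 400, voxel_edge = 20)
  opt <- optics_preset("blue475")
  a <- simulate_illumination(geo, opt, gs, n_packets = 2e4, seed = 11)
  b <- simulate_illumination(geo, opt, gs, n_packets = 2e4, seed = 11)
  expect_identical(a$values, b$values)
  d <- simulate_illumination(geo, opt, gs, n_packets = 2e4, seed = 11,
                             power = 0.6)
  expect_identical(d$values, 2 * a$values)
  e <- simulate_illumination(geo, opt, gs, n_packets = 2e4, seed = 12)
  expect_false(identical(a$values, e$values))
})

test_that("absorption-only axial fluence follows the Beer-Lambert law", {
  # pencil beam straight down the z axis in a purely absorbing medium: the
  # depth of the (single) interaction is exponential with rate mu_a
  geo <- probe_geometry(fiber_tip = c(0, 0, 1e-6), fiber_axis = c(0, 0, 1))
  geo$fiber_core_diameter <- 0
  geo$fiber_half_angle <- 0
  opt <- tissue_optics(mu_a = 5, mu_s = 0, g = 0) # mean free path 200 um
  gs <- grid_spec(extent = 1000, voxel_edge = 10)
  n <- 1e5
  fl <- simulate_illumination(geo, opt, gs, n_packets = n, seed = 5,
                              power = 1)
  prof <- apply(fl$values, 3, sum)
  mu <- 0.005 # um^-1
  z0 <- (seq_len(gs$dims[3]) - 1) * gs$voxel_edge
  expect_frac <- exp(-mu * z0) - exp(-mu * (z0 + gs$voxel_edge))
  se <- sqrt(expect_frac * (1 - expect_frac) / n)
  zscore <- (prof - expect_frac) / se
  expect_lt(max(abs(zscore[1:60])), 3.5) # 60 layers, allow lookelsewhere
})

test_that("transparent-medium acceptance equals the rectangle solid angle", {
  geo <- probe_geometry()
  opt0 <- tissue_optics(0, 0, 0)
  n <- 1e5
  # heights chosen so the single-voxel box footprint (2h) covers the
  # window rectangle
  for (h in c(105, 155, 205)) {
    gs1 <- grid_spec(origin = c(-h, -h, 0), voxel_edge = 2 * h,
                     dims = c(1, 1, 1)) # single voxel centred at (0, 0, h)
    acc <- simulate_acceptance(geo, opt0, gs1, n_packets_per_voxel = n,
                               seed = 7)
    p_ref <- rectangle_solid_angle_fraction(geo$window_size[1],
                                            geo$window_size[2], h)
    se <- sqrt(p_ref * (1 - p_ref) / n)
    expect_lt(abs(as.numeric(acc$values) - p_ref), 3 * se)
  }
})

test_that("acceptance probabilities are valid and the shank occludes", {
  geo <- probe_geometry()
  gs <- grid_spec(extent = 200, voxel_edge = 20)
  acc <- simulate_acceptance(geo, optics_preset("green520"), gs,
                             n_packets_per_voxel = 50, seed = 2)
  expect_true(all(acc$values >= 0 & acc$values <= 1))
  # a downward beam aimed at the shank outside the window is fully absorbed
  # by the shank: nothing reaches the window
  geo2 <- probe_geometry(fiber_tip = c(200, 200, 50),
                         fiber_axis = c(0, 0, -1))
  geo2$fiber_half_angle <- 0
  fl <- simulate_illumination(geo2, tissue_optics(0, 0, 0),
                              grid_spec(extent = 600, voxel_edge = 30),
                              n_packets = 5000, seed = 1, power = 1)
  expect_identical(fl$window_energy, 0)
  expect_equal(fl$shank_energy, 1)
})

test_that("detection volume accumulates the largest products first", {
  gs <- grid_spec(extent = 100, voxel_edge = 10) # 1000 voxels
  flu <- structure(list(values = array(1, gs$dims), origin = gs$origin,
                        voxel_edge = 10, dims = gs$dims),
                   class = c("fluence_grid", "voxel_grid"))
  acc <- structure(list(values = array(1, gs$dims), origin = gs$origin,
                        voxel_edge = 10, dims = gs$dims),
                   class = c("acceptance_grid", "voxel_grid"))
  dv <- detection_volume(flu, acc, quantum_yield = 0.7, fraction = 0.9)
  expect_equal(dv$n_voxels, 900)
  expect_equal(dv$volume_um3, 900 * 1000)

  # single nonzero voxel
  flu1 <- flu
  flu1$values[] <- 0
  flu1$values[5, 5, 5] <- 1
  dv1 <- detection_volume(flu1, acc)
  expect_equal(dv1$volume_um3, 1000)

  # monotone in fraction; fraction = 1 returns the full support
  flu2 <- flu
  flu2$values[] <- runif(1000)
  vols <- vapply(c(0.3, 0.6, 0.9, 1), function(f)
    detection_volume(flu2, acc, fraction = f)$volume_um3, numeric(1))
  expect_true(all(diff(vols) >= 0))
  expect_equal(detection_volume(flu2, acc, fraction = 1)$n_voxels,
               sum(flu2$values > 0))

  # contract errors
  accx <- acc
  accx$voxel_edge <- 20
  expect_error(detection_volume(flu, accx), "congruent")
  flu0 <- flu
  flu0$values[] <- 0
  expect_error(detection_volume(flu0, acc), "degenerate")
})

test_that("stimulation crosstalk is zero without light and shrinks with distance", {
  geo <- probe_geometry()
  expect_identical(stimulation_crosstalk(geo, optics_preset("red625"),
                                         red_power = 0), 0)
  expect_error(stimulation_crosstalk(geo, optics_preset("red625"),
                                     baseline_current = 0),
               "baseline_current")
  gs <- grid_spec(extent = 1400, voxel_edge = 35)
  near <- stimulation_crosstalk(geo, optics_preset("red625"), grid = gs,
                                n_packets = 4e4, seed = 9,
                                red_fiber_tip = c(350, -155, 30))
  far <- stimulation_crosstalk(geo, optics_preset("red625"), grid = gs,
                               n_packets = 4e4, seed = 9,
                               red_fiber_tip = c(650, -155, 30))
  expect_gt(as.numeric(near), as.numeric(far))
})

test_that("accelerated-aging projection follows the 10-degree doubling rule", {
  a <- accelerated_aging_projection(5, 67, 37)
  expect_equal(a$factor, 8)
  expect_equal(a$projected_days, 40)
  b <- accelerated_aging_projection(12, 55, 55)
  expect_equal(b$factor, 1)
  expect_equal(b$projected_days, 12)
  d <- accelerated_aging_projection(5, 47, 37)
  expect_equal(d$factor, 2)
  expect_equal(d$projected_days, 10)
})
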