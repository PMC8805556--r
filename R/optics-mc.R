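#' Sample a Henyey-Greenstein scattering cosine
#'
#' Closed-form inverse-CDF draw of the deflection cosine for the
#' Henyey-Greenstein phase function. For `g = 0` the draw is uniform on
#' \[-1, 1\] (`2u - 1`). Deterministic given `(g, u)`; the same formula is
#' used inside the compiled transport kernel.
#'
#' @param g Anisotropy, -1 < g < 1. The analytic mean scattering cosine
#'   equals `g`.
#' @param u Uniform variates in \[0, 1).
#' @return Scattering cosines in \[-1, 1\].
#' @export
sample_hg_cosine <- function(g, u) {
  if (!is.finite(g) || abs(g) >= 1)
    stop("anisotropy `g` must satisfy -1 < g < 1", call. = FALSE)
  stopifnot(all(u >= 0), all(u < 1))
  cpp_hg_cosine(g, as.numeric(u))
}

window_vec <- function(geometry) {
  c(geometry$window_center[1], geometry$window_center[2],
    geometry$window_size[1] / 2, geometry$window_size[2] / 2)
}

#' Simulate the illumination fluence map
#'
#' Launches photon packets from the excitation-fiber tip (uniform over the
#' core disc, directions uniform in solid angle within the emission cone) and
#' accumulates the energy absorbed in each voxel. Packets crossing the
#' photodiode window or leaving the grid are tallied separately; total energy
#' is conserved exactly via an explicit ledger (see the returned buckets).
#'
#' @param geometry A [probe_geometry()].
#' @param optics A [tissue_optics()].
#' @param grid A [grid_spec()]; must contain the fiber tip.
#' @param n_packets Number of photon packets (>= 1).
#' @param power Launched source power; default 0.3 mW (units carry through to
#'   the fluence values).
#' @param seed Integer seed; identical `(configuration, seed)` give
#'   bit-identical grids. One counter-based RNG stream per packet index, so
#'   the result is independent of scheduling.
#' @param rr_threshold,rr_survival Russian-roulette weight threshold and
#'   survival probability.
#' @return A `fluence_grid` with the absorbed-energy array plus the energy
#'   ledger buckets: `deposited`, `escaped_energy`, `shank_energy`,
#'   `window_energy`, `roulette_residual` (zero-mean), and `launched_power`.
#' @export
simulate_illumination <- function(geometry, optics, grid,
                                  n_packets = 1e5, power = 0.3,
                                  seed = 1,
                                  rr_threshold = 1e-4, rr_survival = 0.1) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(optics, "tissue_optics"),
            inherits(grid, "grid_spec"), n_packets >= 1)
  tip <- geometry$fiber_tip
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$voxel_edge
  if (any(tip < lo) || any(tip > hi))
    stop("grid does not contain the fiber tip", call. = FALSE)
  res <- cpp_simulate_illumination(
    as.integer(n_packets), as.double(seed),
    optics$mu_a / 1000, optics$mu_s / 1000, optics$g, # mm^-1 -> um^-1
    grid$origin, grid$voxel_edge, grid$dims, window_vec(geometry),
    tip, geometry$fiber_axis, geometry$fiber_core_diameter / 2,
    geometry$fiber_half_angle, power, rr_threshold, rr_survival, 0)
  new_voxel_grid(res$values, grid, "fluence_grid",
                 meta = list(launched_power = power,
                             deposited = res$deposited,
                             escaped_energy = res$escaped,
                             shank_energy = res$shank,
                             window_energy = res$window,
                             roulette_residual = res$roulette_residual,
                             seed = seed, n_packets = n_packets))
}

#' Simulate the photodiode acceptance map
#'
#' For each voxel, launches isotropic packets from the voxel centre and
#' records the fraction of launched energy that crosses the photodiode
#' window: the detection probability p(x, y, z) in \[0, 1\]. In a transparent
#' medium this converges to the solid-angle fraction of the window rectangle.
#'
#' @inheritParams simulate_illumination
#' @param n_packets_per_voxel Packets launched per voxel (>= 1).
#' @return An `acceptance_grid` with per-voxel detection probabilities and
#'   the aggregate energy ledger of the underlying transport.
#' @export
simulate_acceptance <- function(geometry, optics, grid,
                                n_packets_per_voxel = 200, seed = 1,
                                rr_threshold = 1e-4, rr_survival = 0.1) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(optics, "tissue_optics"),
            inherits(grid, "grid_spec"), n_packets_per_voxel >= 1)
  res <- cpp_simulate_acceptance(
    as.integer(n_packets_per_voxel), as.double(seed),
    optics$mu_a / 1000, optics$mu_s / 1000, optics$g,
    grid$origin, grid$voxel_edge, grid$dims, window_vec(geometry),
    rr_threshold, rr_survival)
  new_voxel_grid(res$values, grid, "acceptance_grid",
                 meta = list(n_packets_per_voxel = n_packets_per_voxel,
                             seed = seed))
}

#' Fluorescence detection volume
#'
#' Given congruent illumination-fluence and acceptance grids, forms the
#' per-voxel product Phi * eta * p (absorbed excitation energy x fluorophore
#' quantum yield x detection probability), whose grid total is the detected
#' fluorescence energy. Voxels are then accumulated greedily in descending
#' product order (ties broken by lexicographic voxel index) until the stated
#' fraction of the total is reached; the detection volume is the accumulated
#' voxel count times the voxel volume.
#'
#' @param fluence A `fluence_grid` from [simulate_illumination()].
#' @param acceptance An `acceptance_grid` from [simulate_acceptance()] on the
#'   same [grid_spec()].
#' @param quantum_yield Fluorophore quantum yield eta; default 0.7.
#' @param fraction Captured-fluorescence fraction defining the volume;
#'   default 0.9.
#' @return A `detection_volume_result`: `volume_um3`, `n_voxels`,
#'   `voxel_mask` (linear indices, in accumulation order), `total_detected`,
#'   `fraction`, `quantum_yield`.
#' @export
detection_volume <- function(fluence, acceptance,
                             quantum_yield = 0.7, fraction = 0.9) {
  stopifnot(inherits(fluence, "fluence_grid"),
            inherits(acceptance, "acceptance_grid"),
            quantum_yield > 0, quantum_yield <= 1,
            fraction > 0, fraction <= 1)
  if (!grids_congruent(fluence, acceptance))
    stop("fluence and acceptance grids are not congruent", call. = FALSE)
  prod <- as.numeric(fluence$values) * quantum_yield *
    as.numeric(acceptance$values)
  total <- sum(prod)
  if (total <= 0)
    stop("degenerate input: total detected energy is zero", call. = FALSE)
  ord <- order(prod, seq_along(prod), decreasing = c(TRUE, FALSE),
               method = "radix")
  cum <- cumsum(prod[ord])
  n <- which(cum >= fraction * total - 1e-12 * total)[1]
  structure(list(volume_um3 = n * fluence$voxel_edge^3,
                 n_voxels = n,
                 voxel_mask = ord[seq_len(n)],
                 total_detected = total,
                 fraction = fraction,
                 quantum_yield = quantum_yield),
            class = "detection_volume_result")
}

#' @export
print.detection_volume_result <- function(x, ...) {
  cat(sprintf(
    "<detection_volume_result> %g um^3 (%d voxels, %.0f%% of detected fluorescence)\n",
    x$volume_um3, x$n_voxels, 100 * x$fraction))
  invisible(x)
}

#' Stimulation-light crosstalk on the photodiode baseline
#'
#' Propagates red stimulation light from a separately placed stimulation
#' fiber through the tissue and integrates the scattered red power that
#' crosses the photodiode window. The induced photocurrent (window power
#' times the photodiode responsivity at the red wavelength, after the
#' blocking filter) is returned as a fraction of the baseline photocurrent.
#'
#' @param geometry A [probe_geometry()]; `red_fiber_tip`/`red_fiber_axis`
#'   place the stimulation fiber. The default (900 um lateral - the order
#'   of the inter-shank distance in a multi-shank implant - and 400 um
#'   deeper along the shank axis, since the stimulation fiber protrudes
#'   beyond the recording sites) puts the tip about 1 mm from the window,
#'   a representative choice for an under-determined implant geometry.
#' @param optics_red [tissue_optics()] at the stimulation wavelength.
#' @param red_power Stimulation power in W (default 100e-6, i.e. 100 uW).
#' @param responsivity_red Photodiode responsivity to the red light through
#'   the filter (A/W).
#' @param baseline_current Baseline photocurrent (A), > 0.
#' @param grid,n_packets,seed As in [simulate_illumination()].
#' @param red_fiber_tip,red_fiber_axis Stimulation-fiber placement (um).
#' @return Baseline shift as a dimensionless fraction (x100 for percent),
#'   with the underlying `fluence_grid` attached as attribute `"red_field"`.
#' @export
stimulation_crosstalk <- function(geometry, optics_red,
                                  red_power = 100e-6,
                                  responsivity_red = 0.35,
                                  baseline_current = 19.7e-9,
                                  grid = grid_spec(extent = 2200,
                                                   voxel_edge = 25),
                                  n_packets = 2e5, seed = 1,
                                  red_fiber_tip = c(900, 400, 30),
                                  red_fiber_axis = c(0, 1, 0)) {
  stopifnot(red_power >= 0)
  if (baseline_current <= 0)
    stop("baseline_current must be positive", call. = FALSE)
  if (red_power == 0) return(0)
  geo <- geometry
  geo$fiber_tip <- red_fiber_tip
  geo$fiber_axis <- red_fiber_axis / sqrt(sum(red_fiber_axis^2))
  red <- simulate_illumination(geo, optics_red, grid,
                               n_packets = n_packets, power = red_power,
                               seed = seed)
  shift <- red$window_energy * responsivity_red / baseline_current
  attr(shift, "red_field") <- red
  shift
}

#' Accelerated-aging lifetime projection
#'
#' Standard reaction-rate doubling per 10 degrees C: soaking at an elevated
#' temperature accelerates aging by `2^((t_aging - t_body) / 10)` relative to
#' body temperature, so a soak of `soak_days` projects to
#' `soak_days * factor` days in vivo.
#'
#' @param soak_days Soak duration at the elevated temperature (days), > 0.
#' @param t_aging,t_body Soak and body temperatures (degrees C).
#' @return List with `factor` and `projected_days`.
#' @export
accelerated_aging_projection <- function(soak_days, t_aging, t_body = 37) {
  stopifnot(soak_days > 0)
  factor <- 2^((t_aging - t_body) / 10)
  list(factor = factor, projected_days = soak_days * factor)
}

#' Excitation-light blocking of the integrated filter
#'
#' Fraction of the excitation-wavelength response removed by the blocking
#' filter, computed from photodiode responsivities measured with and without
#' the filter at the excitation wavelength.
#'
#' @param resp_unfiltered,resp_filtered Responsivities (A/W) without / with
#'   the filter.
#' @return Blocking percentage, `100 * (1 - resp_filtered/resp_unfiltered)`.
#' @export
excitation_blocking_pct <- function(resp_unfiltered, resp_filtered) {
  stopifnot(resp_unfiltered > 0, resp_filtered >= 0)
  100 * (1 - resp_filtered / resp_unfiltered)
}

#' Noise-equivalent photocurrent of the transimpedance readout
#'
#' Converts an output voltage noise amplitude to the equivalent photodiode
#' current through the transimpedance gain.
#'
#' @param v_noise Voltage noise amplitude (V), e.g. peak-to-peak.
#' @param gain Transimpedance gain (V/A), default 1e7.
#' @return Equivalent current (A) on the same amplitude convention.
#' @export
tia_noise_equivalent_current <- function(v_noise, gain = 1e7) {
  stopifnot(v_noise >= 0, gain > 0)
  v_noise / gain
}

#' Closed-form solid-angle fraction of a rectangle
#'
#' Fraction of the full sphere subtended by an a x b rectangle seen from a
#' point at height h above its centre: `Omega / 4 pi` with
#' `Omega = 4 atan(ab / (2h sqrt(4h^2 + a^2 + b^2)))`. Reference value for
#' the transparent-medium limit of [simulate_acceptance()].
#'
#' @param a,b Rectangle edges (um).
#' @param h Height above the rectangle centre (um), > 0.
#' @return Solid-angle fraction in (0, 0.5).
#' @export
rectangle_solid_angle_fraction <- function(a, b, h) {
  stopifnot(a > 0, b > 0, h > 0)
  4 * atan(a * b / (2 * h * sqrt(4 * h^2 + a^2 + b^2))) / (4 * pi)
}
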