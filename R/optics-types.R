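#' Tissue optical properties
#'
#' Homogeneous optical properties of the medium used by the photon-transport
#' simulators: absorption and scattering coefficients and the
#' Henyey-Greenstein anisotropy.
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s Scattering coefficient (mm^-1), >= 0.
#' @param g Henyey-Greenstein anisotropy, strictly inside (-1, 1).
#' @param wavelength_tag Free-text label, e.g. `"blue475"`.
#' @return An object of class `tissue_optics`.
#' @seealso [optics_preset()] for literature presets.
#' @export
tissue_optics <- function(mu_a, mu_s, g, wavelength_tag = "unspecified") {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1, is.finite(mu_a), mu_a >= 0,
            is.numeric(mu_s), length(mu_s) == 1, is.finite(mu_s), mu_s >= 0)
  if (!is.finite(g) || abs(g) >= 1)
    stop("anisotropy `g` must satisfy -1 < g < 1", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 wavelength_tag = wavelength_tag),
            class = "tissue_optics")
}

#' Literature optical presets for cortical gray matter
#'
#' Named presets for the three wavelengths the probe uses: blue excitation
#' (475 nm), green fluorescence emission (520 nm) and red stimulation light
#' (625 nm). Values are representative literature figures for murine cortical
#' gray matter (mu_a and mu_s in mm^-1); they are deliberately overridable
#' because detection-volume figures depend directly on them.
#'
#' @param wavelength One of `"blue475"`, `"green520"`, `"red625"`.
#' @return A [tissue_optics()] object.
#' @export
optics_preset <- function(wavelength = c("blue475", "green520", "red625")) {
  wavelength <- match.arg(wavelength)
  switch(wavelength,
    blue475  = tissue_optics(mu_a = 0.37, mu_s = 11.0, g = 0.89, "blue475"),
    green520 = tissue_optics(mu_a = 0.20, mu_s = 10.5, g = 0.89, "green520"),
    red625   = tissue_optics(mu_a = 0.07, mu_s = 9.0,  g = 0.89, "red625"))
}

#' Probe geometry
#'
#' The physical scene shared by the optical simulators and the synthetic
#' renderer: the photodiode window lies in the z = 0 plane (the shank
#' surface), tissue occupies z > 0, and all coordinates are micrometres in a
#' right-handed frame with origin at the window centre. The excitation fiber
#' lies along the shank with its tip a fixed distance short of the photodiode
#' edge, and seven electrodes ring the window at 50 um pitch.
#'
#' @param window_center Window centre (um); the frame origin, `c(0, 0, 0)`.
#' @param window_size Width x length of the photodiode window (um).
#' @param fiber_tip Excitation fiber tip (um). Default places the tip
#'   `fiber_edge_offset` before the near window edge, 30 um above the shank
#'   (fiber core centre for a 50/60 um core/cladding fiber lying on the
#'   surface).
#' @param fiber_axis Unit emission axis; default along +y (along the shank).
#' @param fiber_core_diameter Fiber core diameter (um).
#' @param fiber_na,tissue_index Numerical aperture and tissue refractive
#'   index; the emission cone half-angle is `asin(fiber_na / tissue_index)`.
#' @param fiber_edge_offset Distance from the fiber tip to the photodiode
#'   edge (um).
#' @param electrode_sites 7 x 3 matrix of electrode coordinates (um). The
#'   default rings the window boundary at >= 50 um pitch.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(window_center = c(0, 0, 0),
                           window_size = c(49, 150),
                           fiber_tip = NULL,
                           fiber_axis = c(0, 1, 0),
                           fiber_core_diameter = 50,
                           fiber_na = 0.22,
                           tissue_index = 1.36,
                           fiber_edge_offset = 80,
                           electrode_sites = NULL) {
  stopifnot(length(window_center) == 3, length(window_size) == 2,
            all(window_size > 0), fiber_edge_offset > 0,
            fiber_core_diameter > 0)
  fiber_axis <- fiber_axis / sqrt(sum(fiber_axis^2))
  if (is.null(fiber_tip))
    fiber_tip <- window_center +
      c(0, -(window_size[2] / 2 + fiber_edge_offset), 30)
  if (is.null(electrode_sites)) {
    hw <- window_size[1] / 2 # 24.5 for the 49 um window
    electrode_sites <- rbind(
      c(-hw, -50, 0), c(-hw, 0, 0), c(-hw, 50, 0),
      c( hw, -50, 0), c( hw, 0, 0), c( hw, 50, 0),
      c(0, window_size[2] / 2, 0))
  }
  electrode_sites <- as.matrix(electrode_sites)
  stopifnot(ncol(electrode_sites) == 3)
  structure(list(window_center = window_center,
                 window_size = window_size,
                 window_normal = c(0, 0, 1),
                 fiber_tip = fiber_tip,
                 fiber_axis = fiber_axis,
                 fiber_core_diameter = fiber_core_diameter,
                 fiber_half_angle = asin(fiber_na / tissue_index),
                 fiber_edge_offset = fiber_edge_offset,
                 electrode_sites = electrode_sites),
            class = "probe_geometry")
}

#' Voxel grid specification
#'
#' Cubic-voxel grid for fluence and acceptance maps. The grid origin is its
#' minimum corner; the default covers a 1 mm x 1 mm x 1 mm volume of tissue
#' centred laterally on the photodiode window, in 10 um voxels, with its
#' bottom face in the shank plane (z = 0). Voxel membership is half-open
#' (`floor(coord / edge)`).
#'
#' @param extent Edge length of the cubic simulated volume (um) when `origin`
#'   and `dims` are not given.
#' @param voxel_edge Voxel edge (um).
#' @param origin Minimum corner (um); `origin[3]` must be 0 (the transport
#'   kernel anchors the probe plane at z = 0).
#' @param dims Integer voxel counts per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(extent = 1000, voxel_edge = 10,
                      origin = NULL, dims = NULL) {
  stopifnot(voxel_edge > 0)
  if (is.null(dims)) dims <- rep(round(extent / voxel_edge), 3)
  if (is.null(origin))
    origin <- c(-dims[1] * voxel_edge / 2, -dims[2] * voxel_edge / 2, 0)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), length(origin) == 3)
  if (abs(origin[3]) > 1e-9)
    stop("grid must start at the probe plane: origin[3] must be 0",
         call. = FALSE)
  structure(list(origin = origin, voxel_edge = voxel_edge, dims = dims),
            class = "grid_spec")
}

# Shared construction of voxel-grid results.
new_voxel_grid <- function(values, grid, class, meta = list()) {
  arr <- array(values, dim = grid$dims)
  structure(c(list(values = arr, origin = grid$origin,
                   voxel_edge = grid$voxel_edge, dims = grid$dims), meta),
            class = c(class, "voxel_grid"))
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d x %d voxels, edge %g um, origin (%g, %g, %g)\n",
              class(x)[1], x$dims[1], x$dims[2], x$dims[3], x$voxel_edge,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grids_congruent <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$voxel_edge, b$voxel_edge)) &&
    all(a$dims == b$dims)
}
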