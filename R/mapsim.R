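#' Map-simulation parameters
#'
#' @param resolution Target resolution in Angstroms; the Gaussian kernel
#'   width is `sigma = sigma_coeff * resolution`.
#' @param voxel_size Voxel edge in Angstroms.
#' @param padding Angstroms added on each side of the model bounding box
#'   when no template grid is supplied.
#' @param sigma_coeff Dimensionless resolution-to-sigma factor; 0.356 is
#'   the conventional model-blurring choice in the SMOC lineage.
#' @return A `sim_params` list.
#' @export
sim_params <- function(resolution, voxel_size = 1, padding = 5,
                       sigma_coeff = 0.356) {
  if (resolution <= 0) abort("sim_params: resolution must be positive",
                             class = "cryofit_invalid_parameter")
  if (voxel_size <= 0) abort("sim_params: voxel_size must be positive",
                             class = "cryofit_invalid_parameter")
  if (voxel_size > resolution / 2) {
    warn("sim_params: voxel_size exceeds resolution/2; map undersampled")
  }
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 padding = padding, sigma_coeff = sigma_coeff),
            class = "sim_params")
}

ATOMIC_NUMBER <- c(H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, "NA" = 11,
                   MG = 12, P = 15, S = 16, CL = 17, K = 19, CA = 20,
                   MN = 25, FE = 26, CO = 27, NI = 28, CU = 29, ZN = 30,
                   SE = 34, BR = 35, I = 53)

atomic_number <- function(element) {
  z <- ATOMIC_NUMBER[toupper(element)]
  z[is.na(z)] <- 6
  unname(z)
}

#' Simulate a density map from a model
#'
#' Each non-hydrogen atom contributes an isotropic Gaussian of width
#' `sigma = sigma_coeff * resolution`, amplitude proportional to its atomic
#' number (simple Z-weighting; no scattering-factor tables, which overlap
#' scoring does not need).  With `onto` supplied the output grid geometry
#' (spacing, origin, extent) matches it exactly — this is how SMOC puts
#' experimental and simulated density on the same lattice.
#'
#' @param model An [atomic_model()].
#' @param params A [sim_params()].
#' @param onto Optional [density_grid()] template.
#' @return A [density_grid()] with label `"simulated"`.
#' @export
simulate_density <- function(model, params, onto = NULL) {
  atoms <- scoring_atoms(model)
  if (nrow(atoms) == 0L) abort("simulate_density: no heavy atoms")
  sigma <- params$sigma_coeff * params$resolution
  cutoff <- 4 * sigma
  xyz <- model_coords(atoms)
  if (is.null(onto)) {
    lo <- apply(xyz, 2, min) - params$padding
    hi <- apply(xyz, 2, max) + params$padding
    voxel <- rep(params$voxel_size, 3)
    n <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    grid <- density_grid(array(0, n), voxel = voxel, origin = lo,
                         label = "simulated")
  } else {
    grid <- density_grid(array(0, dim(onto$data)), voxel = onto$voxel,
                         origin = onto$origin, label = "simulated")
  }
  d <- dim(grid$data)
  frac <- world_to_index(grid, xyz)
  inside <- frac[, 1] > 0.5 - cutoff / grid$voxel[1] &
            frac[, 1] < d[1] + 0.5 + cutoff / grid$voxel[1] &
            frac[, 2] > 0.5 - cutoff / grid$voxel[2] &
            frac[, 2] < d[2] + 0.5 + cutoff / grid$voxel[2] &
            frac[, 3] > 0.5 - cutoff / grid$voxel[3] &
            frac[, 3] < d[3] + 0.5 + cutoff / grid$voxel[3]
  if (!any(inside)) abort("simulate_density: model entirely outside grid",
                          class = "cryofit_invalid_parameter")
  amp <- atomic_number(atoms$element)
  hw <- ceiling(cutoff / grid$voxel)
  inv2s2 <- 1 / (2 * sigma^2)
  dat <- grid$data
  for (i in which(inside)) {
    ci <- nearest_index(frac[i, , drop = FALSE])[1, ]
    i1 <- pmax(ci - hw, 1L); i2 <- pmin(ci + hw, d)
    if (any(i1 > i2)) next
    ax <- (seq.int(i1[1], i2[1]) - frac[i, 1])^2 * grid$voxel[1]^2
    ay <- (seq.int(i1[2], i2[2]) - frac[i, 2])^2 * grid$voxel[2]^2
    az <- (seq.int(i1[3], i2[3]) - frac[i, 3])^2 * grid$voxel[3]^2
    r2 <- outer(outer(ax, ay, "+"), az, "+")
    dat[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
      dat[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] +
      amp[i] * exp(-r2 * inv2s2)
  }
  grid$data <- dat
  grid
}

# Radial spatial-frequency grid (1/A) for an array of dim d and voxel size v.
freq_grid <- function(d, voxel) {
  f1 <- function(n, v) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / (n * v)
  }
  fx <- f1(d[1], voxel[1]); fy <- f1(d[2], voxel[2]); fz <- f1(d[3], voxel[3])
  sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
}

#' Low-pass filter a density grid
#'
#' Fourier amplitudes beyond `1/resolution` are removed; a raised-cosine
#' edge spanning `edge_width` (as a fraction of the cutoff frequency)
#' immediately below the cutoff avoids ringing.  The mean (DC term) is
#' preserved exactly.  `edge_width = 0` gives a hard cutoff, which is
#' exactly idempotent.
#'
#' @param grid A [density_grid()].
#' @param resolution Cutoff resolution, Angstroms; must be coarser than
#'   twice the largest voxel edge (Nyquist).
#' @param edge_width Fraction of the cutoff frequency over which the
#'   transfer function rolls from 1 to 0 (default 0.1).
#' @return Filtered [density_grid()], same geometry.
#' @export
lowpass_filter <- function(grid, resolution, edge_width = 0.1) {
  if (resolution <= 2 * max(grid$voxel)) {
    abort("lowpass_filter: resolution at or below Nyquist",
          class = "cryofit_invalid_parameter")
  }
  s <- freq_grid(dim(grid$data), grid$voxel)
  sc <- 1 / resolution
  s0 <- sc * (1 - edge_width)
  h <- array(0, dim(s))
  h[s <= s0] <- 1
  edge <- s > s0 & s < sc
  if (any(edge)) {
    h[edge] <- 0.5 * (1 + cos(pi * (s[edge] - s0) / (sc - s0)))
  }
  out <- Re(fft(fft(grid$data) * h, inverse = TRUE)) / length(grid$data)
  density_grid(out, voxel = grid$voxel, origin = grid$origin,
               label = grid$label)
}
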