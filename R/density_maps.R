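#' Real-space density map on the unit cell
#'
#' @param values 3D numeric array of voxel values (x fastest, cell-aligned
#'   axes, origin at the cell origin).
#' @param cell A [unit_cell()].
#' @param label Provenance label.
#' @return Object of class `density_map` with cached `sigma`, the root mean
#'   square of the voxel values (the map sigma used for contouring and
#'   pedestals).
#' @export
density_map <- function(values, cell, label = "") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            inherits(cell, "unit_cell"))
  structure(list(values = values, cell = cell,
                 sigma = sqrt(mean(values^2)), label = label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map '%s': %d x %d x %d voxels, sigma (rms) = %.4g\n",
              x$label, d[1], d[2], d[3], x$sigma))
  invisible(x)
}

#' Choose a synthesis grid for a reflection set
#'
#' Even grid dimensions with spacing at most `d_min / factor` along each cell
#' edge, and always large enough to hold every Fourier coefficient without
#' aliasing.
#'
#' @param refls A [reflection_set()] with cell attached.
#' @param d_min Resolution; defaults to the set's `d_min` attribute or the
#'   smallest d-spacing present.
#' @param factor Oversampling factor (default 3).
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
map_grid <- function(refls, d_min = NULL, factor = 3) {
  cell <- attr(refls, "cell")
  if (is.null(cell)) stop("reflection set carries no cell")
  d_min <- d_min %||% attr(refls, "d_min")
  if (is.null(d_min) || is.na(d_min)) d_min <- min(refls$d)
  len <- c(cell$a, cell$b, cell$c)
  hmax <- vapply(c("h", "k", "l"), function(cn) max(abs(refls[[cn]])), 0)
  n <- pmax(ceiling(len / (d_min / factor)), 2 * hmax + 2)
  as.integer(n + n %% 2)
}

hkl_to_grid_index <- function(hkl, dims) {
  # wrap negative indices into the FFT array; returns linear indices
  i <- hkl[, 1] %% dims[1]
  j <- hkl[, 2] %% dims[2]
  k <- hkl[, 3] %% dims[3]
  1 + i + dims[1] * (j + dims[2] * k)
}

# core synthesis: complex coefficients on the half-sphere -> real map by FFT,
# with Friedel completion and F(000) = 0
synthesize_core <- function(hkl, coeff, cell, dims, label = "") {
  G <- array(0 + 0i, dim = dims)
  G[hkl_to_grid_index(hkl, dims)] <- coeff
  G[hkl_to_grid_index(-hkl, dims)] <- Conj(coeff)
  # rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x): the forward DFT over the
  # h-indexed array evaluated at x = n/N
  rho <- Re(stats::fft(G)) / cell$volume
  density_map(rho, cell, label = label)
}

#' Fourier synthesis of a density map from structure factors
#'
#' Inverse Fourier synthesis `rho(x) = (1/V) sum_hkl F exp(-2 pi i h.x)` with
#' Friedel completion (the half-sphere coefficients and their conjugate mates
#' give a real map). F(000) is treated as 0, so every synthesized map has zero
#' mean.
#'
#' @param refls A [reflection_set()] with amplitudes and phases.
#' @param grid Grid dimensions `c(nx, ny, nz)`; defaults to [map_grid()].
#' @return A [density_map()].
#' @export
synthesize_map <- function(refls, grid = NULL) {
  if (any(is.na(refls$phase))) stop("map synthesis requires phases")
  dims <- grid %||% map_grid(refls)
  cell <- attr(refls, "cell")
  if (is.null(cell)) stop("reflection set carries no cell")
  synthesize_core(as.matrix(refls[, c("h", "k", "l")]), as_complex(refls),
                  cell, dims, label = sprintf("F(%s)", attr(refls, "role")))
}

#' Isomorphous difference Fourier map
#'
#' Synthesizes `FT[(F_obs(activated) - F_obs(reference)) exp(i Phi(reference))]`:
#' the gold-standard map of time-resolved crystallography. Positive features
#' mark density gained on activation, negative features density lost. Only
#' reflections present in both amplitude sets and in the phase set contribute;
#' the number dropped is reported as an attribute. No figure-of-merit
#' weighting is applied.
#'
#' @param F_act Activated-state amplitudes.
#' @param F_ref Reference-state amplitudes.
#' @param phases_ref Reference-state phases (e.g. calculated from the refined
#'   dark model); defaults to `F_ref` when it carries phases.
#' @param grid Grid dimensions; defaults to [map_grid()].
#' @param weighting Only `"none"`.
#' @return A [density_map()] with attribute `n_dropped`.
#' @export
difference_map <- function(F_act, F_ref, phases_ref = NULL, grid = NULL,
                           weighting = "none") {
  weighting <- match.arg(weighting)
  phases_ref <- phases_ref %||% F_ref
  ka <- hkl_key(F_act); kr <- hkl_key(F_ref); kp <- hkl_key(phases_ref)
  common <- Reduce(intersect, list(ka, kr, kp))
  if (length(common) == 0) stop("no Miller indices common to both sets and the phases")
  ia <- match(common, ka); ir <- match(common, kr); ip <- match(common, kp)
  dF <- F_act$F[ia] - F_ref$F[ir]
  ph <- phases_ref$phase[ip]
  if (any(is.na(ph))) stop("reference phases contain NA")
  cell <- attr(phases_ref, "cell") %||% attr(F_ref, "cell")
  rs_tmp <- reflection_set(as.matrix(F_act[ia, c("h", "k", "l")]),
                           amplitude = abs(dF), phase = ph, cell = cell,
                           d_min = attr(F_act, "d_min") %||% NA_real_)
  dims <- grid %||% map_grid(rs_tmp)
  m <- synthesize_core(as.matrix(F_act[ia, c("h", "k", "l")]),
                       complex(modulus = 1, argument = ph) * dF,
                       cell, dims, label = "difference map")
  attr(m, "n_dropped") <- length(ka) + length(kr) - 2 * length(common)
  m
}

#' Scale a map to sigma units
#'
#' Divides every voxel by the map's root-mean-square density so the output has
#' rms 1; contour levels then read directly in sigma. Idempotent after the
#' first application.
#'
#' @param map A [density_map()].
#' @return A [density_map()] with `sigma == 1`.
#' @export
sigma_scale <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (map$sigma == 0) stop("cannot sigma-scale an all-zero map")
  density_map(map$values / map$sigma, map$cell,
              label = paste(map$label, "(sigma-scaled)"))
}

#' Pearson correlation between two maps
#'
#' @param map_a,map_b [density_map()]s on the same grid.
#' @return Pearson correlation of the voxel values, in \[-1, 1\].
#' @export
map_pearson <- function(map_a, map_b) {
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop("maps are on different grids")
  stats::cor(as.vector(map_a$values), as.vector(map_b$values))
}

#' Omit map with optional flat solvent and Polder-style exclusion
#'
#' Computes `F_calc` from the model with the omitted atoms removed, fits a
#' least-squares scale `k = sum(F_obs |F_calc|) / sum(|F_calc|^2)`, and
#' synthesizes `FT[(F_obs - k |F_calc|) exp(i Phi_calc)]`. With the flat
#' solvent enabled, a constant density `k_sol` fills every voxel farther than
#' `r_probe` from any remaining atom and its Fourier transform is added to
#' `F_calc`; a Polder-style exclusion radius removes the solvent from a sphere
#' around the omitted atoms so weak density there is not swamped by the
#' solvent model. Without a solvent model the exclusion radius is a no-op.
#'
#' @param F_obs Observed amplitudes ([reflection_set()]).
#' @param model The current [atomic_model()].
#' @param omit Character vector of atom names to omit (non-empty).
#' @param polder_exclusion_radius Radius in Angstrom around omitted atoms kept
#'   free of solvent, or `NULL`.
#' @param solvent `NULL` (off) or `list(k_sol = , r_probe = )` in electrons per
#'   cubic Angstrom and Angstrom.
#' @param grid Grid dimensions; defaults to [map_grid()] of `F_obs`.
#' @return A [density_map()] with attribute `scale_k`.
#' @export
omit_map <- function(F_obs, model, omit, polder_exclusion_radius = NULL,
                     solvent = NULL, grid = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (length(omit) == 0) stop("omit selection is empty")
  sel <- model$atoms$name %in% omit
  if (!any(sel)) stop("omit selection matches no atom")
  keep_atoms <- model$atoms[!sel, , drop = FALSE]
  if (nrow(keep_atoms) == 0) stop("cannot omit every atom of the model")
  hkl <- as.matrix(F_obs[, c("h", "k", "l")])
  cell <- model$cell
  Fc <- calc_sf_complex(cell, keep_atoms, hkl)
  dims <- grid %||% map_grid(F_obs, d_min = attr(F_obs, "d_min") %||% min(F_obs$d))
  if (!is.null(solvent)) {
    mask <- solvent_mask(cell, keep_atoms, dims, solvent$r_probe)
    if (!is.null(polder_exclusion_radius)) {
      omit_sites <- as.matrix(model$atoms[sel, c("fx", "fy", "fz")])
      excl <- voxels_within(cell, dims, omit_sites, polder_exclusion_radius)
      mask[excl] <- FALSE
    }
    Fc <- Fc + solvent_transform(mask, solvent$k_sol, cell, hkl)
  }
  k <- sum(F_obs$F * Mod(Fc)) / sum(Mod(Fc)^2)
  coeff <- (F_obs$F - k * Mod(Fc)) * complex(modulus = 1, argument = Arg(Fc))
  m <- synthesize_core(hkl, coeff, cell, dims, label = "omit map")
  attr(m, "scale_k") <- k
  m
}

# logical 3D array: TRUE where the flat solvent lives (farther than r_probe
# from every atom, minimum-image distances)
solvent_mask <- function(cell, atoms, dims, r_probe) {
  near <- voxels_within(cell, dims, as.matrix(atoms[, c("fx", "fy", "fz")]),
                        r_probe)
  mask <- array(TRUE, dim = dims)
  mask[near] <- FALSE
  mask
}

# logical array marking voxels whose centers lie within radius of any site
voxels_within <- function(cell, dims, sites, radius) {
  fx <- (seq_len(dims[1]) - 1) / dims[1]
  fy <- (seq_len(dims[2]) - 1) / dims[2]
  fz <- (seq_len(dims[3]) - 1) / dims[3]
  vox <- as.matrix(expand.grid(fx = fx, fy = fy, fz = fz))
  within <- rep(FALSE, nrow(vox))
  sites <- rbind(sites)
  for (s in seq_len(nrow(sites))) {
    d <- vox - matrix(sites[s, ], nrow(vox), 3, byrow = TRUE)
    d <- d - round(d)  # minimum image in fractional space
    dc <- d %*% t(cell$orth)
    within <- within | rowSums(dc^2) <= radius^2
  }
  array(within, dim = dims)
}

# forward transform of a constant-density mask at the given hkl
solvent_transform <- function(mask, k_sol, cell, hkl) {
  dims <- dim(mask)
  rho <- array(0, dim = dims)
  rho[mask] <- k_sol
  Gh <- stats::fft(rho, inverse = TRUE) * cell$volume / prod(dims)
  Gh[hkl_to_grid_index(hkl, dims)]
}
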