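#' Structure factors by direct summation
#'
#' Computes F(hkl) for every reflection of the Friedel half-sphere with
#' d >= d_min by direct summation over atoms,
#' \deqn{F(hkl) = \sum_j occ_j z_j \exp(-B_j s^2/4) \exp(2\pi i\, h\cdot x_j),}
#' with s = 1/d. The scattering model is a constant per-element electron count
#' damped by the isotropic Debye-Waller factor; this keeps synthetic amplitudes
#' reproducible in closed form (no Cromer-Mann form factors).
#'
#' @param model An [atomic_model()].
#' @param d_min Resolution cutoff in Angstrom (> 0).
#' @param hkl Optional explicit Miller-index matrix; defaults to the full
#'   half-sphere at `d_min`.
#' @return A [reflection_set()] of role "calculated" with amplitudes and
#'   phases.
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' m <- atomic_model(cell, atom_table("O", "O", c(0, 0, 0), b_iso = 0))
#' sf <- structure_factors(m, 2.5)
#' all(abs(sf$F - 8) < 1e-12)
#' @export
structure_factors <- function(model, d_min, hkl = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (n_atoms(model) == 0) stop("empty model")
  if (!is.numeric(d_min) || d_min <= 0) stop("d_min must be positive")
  if (is.null(hkl)) hkl <- hkl_half_sphere(model$cell, d_min)
  Fc <- calc_sf_complex(model$cell, model$atoms, hkl)
  reflection_set(hkl, amplitude = Mod(Fc), phase = Arg(Fc),
                 cell = model$cell, d_min = d_min, role = "calculated")
}

# complex structure factors for an atom table at given hkl
calc_sf_complex <- function(cell, atoms, hkl) {
  s2 <- 1 / d_spacing(cell, hkl)^2
  ph <- hkl %*% t(as.matrix(atoms[, c("fx", "fy", "fz")]))   # nrefl x natom
  w <- exp(-outer(s2 / 4, atoms$b_iso)) *
    matrix(atoms$occ * atoms$z, nrow = length(s2), ncol = nrow(atoms), byrow = TRUE)
  as.vector((w * exp(2i * pi * ph)) %*% rep(1, nrow(atoms)))
}

#' Coherent two-state mixing of structure factors
#'
#' Forms the complex linear combination `(1 - f) F_dark + f F_light` per
#' reflection. This is the exact ground truth that structure-factor
#' extrapolation approximates on amplitudes: a crystal in which a fraction `f`
#' of molecules (the crystallographic occupancy) has moved onto the activated
#' conformation scatters as the coherent sum of the two states.
#'
#' @param F_dark,F_light [reflection_set()]s with identical Miller indices and
#'   phases present.
#' @param f Activated-state occupancy in \[0, 1\].
#' @return A [reflection_set()] with recomputed amplitudes and phases.
#' @export
mix_states <- function(F_dark, F_light, f) {
  if (!is.numeric(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  idx <- match_hkl(F_dark, F_light, "hkl sets of the two states")
  z <- (1 - f) * as_complex(F_dark) + f * as_complex(F_light)[idx]
  reflection_set(as.matrix(F_dark[, c("h", "k", "l")]),
                 amplitude = Mod(z), phase = Arg(z),
                 cell = attr(F_dark, "cell"), d_min = attr(F_dark, "d_min"),
                 role = "calculated")
}
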