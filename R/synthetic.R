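#' Toy two-state crystal system
#'
#' Generates a random sparse P1 model (the reference / dark state) and an
#' activated (light) copy in which a subset of atoms is displaced by a fixed
#' Cartesian amplitude in random directions, with optionally perturbed
#' B-factors. The displacement amplitude is kept small relative to the cell so
#' the difference-Fourier linearization and the 1/f occupancy law hold, which
#' is the regime the appraisal tools target.
#'
#' @param seed Seed for the random model.
#' @param n_atoms Number of atoms.
#' @param cell_edge Cubic cell edge in Angstrom.
#' @param displacement Cartesian displacement amplitude (Angstrom) of moved
#'   atoms.
#' @param move_fraction Fraction of atoms that move in the light state.
#' @param b_range Range of B-factors (Angstrom^2).
#' @param water Add a transient water present only in the light state?
#' @return List with `dark` and `light` [atomic_model()]s, `moved` (names of
#'   displaced atoms) and, when `water = TRUE`, `water_site` (fractional
#'   coordinates of the transient water).
#' @export
toy_two_state <- function(seed = 1, n_atoms = 8, cell_edge = 12,
                          displacement = 0.35, move_fraction = 0.5,
                          b_range = c(8, 20), water = FALSE) {
  set.seed(derive_seed(seed, 7L))
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1))
  # spread atoms out to avoid accidental overlap
  frac <- matrix(stats::runif(3 * n_atoms, 0.05, 0.95), n_atoms, 3)
  name <- sprintf("%s%d", ifelse(seq_len(n_atoms) %% 2 == 1, "CA", elements),
                  seq_len(n_atoms))
  b <- stats::runif(n_atoms, b_range[1], b_range[2])
  dark_atoms <- atom_table(name, elements, frac, b_iso = b)
  n_move <- max(1L, round(move_fraction * n_atoms))
  moved <- sort(sample.int(n_atoms, n_move))
  dirs <- matrix(stats::rnorm(3 * n_move), n_move, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  if (n_move > 1) {
    # a uniform translation of all scattering matter is a gauge mode of
    # amplitude-only data in P1 (and lattice contacts pin real molecules), so
    # the generated displacement field is centered: zero net translation over
    # the whole model, mean amplitude over moved atoms = `displacement`
    dirs <- dirs - matrix(colMeans(dirs), n_move, 3, byrow = TRUE)
    dirs <- dirs * displacement / mean(sqrt(rowSums(dirs^2)))
  } else {
    dirs <- dirs * displacement
  }
  light_atoms <- dark_atoms
  shift_frac <- t(cell$frac %*% t(dirs))
  light_atoms[moved, c("fx", "fy", "fz")] <-
    light_atoms[moved, c("fx", "fy", "fz")] + shift_frac
  light_atoms$b_iso <- pmax(2, light_atoms$b_iso + stats::rnorm(n_atoms, 0, 0.5))
  out <- list(dark = atomic_model(cell, dark_atoms, label = "toy dark"),
              light = NULL, moved = name[moved])
  if (water) {
    site <- stats::runif(3, 0.3, 0.7)
    light_atoms <- rbind(light_atoms,
                         atom_table("WAT99", "O", site, b_iso = 12))
    out$water_site <- site
  }
  out$light <- atomic_model(cell, light_atoms, label = "toy light")
  out
}
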