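ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, NA_ = 11, MG = 12, P = 15, S = 16,
               CL = 17, K = 19, CA_ = 20, FE = 26, ZN = 30, SE = 34, BR = 35)

element_electrons <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  # "CA" as an element symbol is calcium; atom *names* CA are carbon and are
  # resolved by the PDB reader, not here
  key[key == "CA"] <- "CA_"
  z <- ELEMENT_Z[key]
  if (any(is.na(z))) stop("unknown element(s): ",
                          paste(unique(element[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Build an atom table
#'
#' Helper assembling the atom data frame used by [atomic_model()]. Each atom
#' carries a role label (e.g. "CA", "O", "WAT"), an element symbol, an electron
#' count, fractional coordinates, an isotropic B-factor (Angstrom^2), an
#' occupancy in \[0, 1\] and a conformer tag ("A" for the reference state, "B"
#' for the activated state).
#'
#' @param name Character vector of atom role labels.
#' @param element Character vector of element symbols.
#' @param frac Numeric matrix (n x 3) of fractional coordinates.
#' @param b_iso Numeric vector of isotropic B-factors (Angstrom^2).
#' @param occ Numeric vector of occupancies in \[0, 1\].
#' @param conformer Character vector of conformer tags ("A" or "B").
#' @param z_electrons Optional integer vector of electron counts; derived from
#'   `element` when missing.
#' @return A data frame with one row per atom.
#' @export
atom_table <- function(name, element, frac, b_iso = 20, occ = 1,
                       conformer = "A", z_electrons = NULL) {
  frac <- rbind(frac)
  n <- length(name)
  stopifnot(nrow(frac) == n)
  if (is.null(z_electrons)) z_electrons <- element_electrons(element)
  out <- data.frame(
    name = as.character(name),
    element = as.character(element),
    z = as.numeric(rep_len(z_electrons, n)),
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    b_iso = rep_len(as.numeric(b_iso), n),
    occ = rep_len(as.numeric(occ), n),
    conformer = rep_len(as.character(conformer), n),
    stringsAsFactors = FALSE
  )
  if (any(out$occ < 0 | out$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(out$b_iso < 0)) stop("B-factors must be non-negative")
  if (any(out$z <= 0)) stop("electron counts must be positive")
  out
}

#' Atomic model in a P1 cell
#'
#' Bundles a [unit_cell()] with an ordered atom table. Atom order is stable and
#' defines the per-atom correspondence used by [rmsd_profile()] and
#' [coordinate_spread()]. Two-state models carry both conformers in one table,
#' tagged "A" (reference, occupancy 1 - f) and "B" (activated, occupancy f).
#'
#' @param cell A [unit_cell()].
#' @param atoms An atom data frame from [atom_table()].
#' @param label Free-text description.
#' @return An object of class `atomic_model`.
#' @examples
#' cell <- unit_cell(15, 15, 15)
#' m <- atomic_model(cell, atom_table(c("CA", "O"), c("C", "O"),
#'                   rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))))
#' @export
atomic_model <- function(cell, atoms, label = "") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  needed <- c("name", "element", "z", "fx", "fy", "fz", "b_iso", "occ", "conformer")
  if (!all(needed %in% names(atoms)))
    stop("atom table is missing columns: ",
         paste(setdiff(needed, names(atoms)), collapse = ", "))
  if (nrow(atoms) == 0) stop("atomic model must contain at least one atom")
  # atoms sharing a name across the two conformers must have complementary
  # (or at least non-overfilled) occupancies
  both <- intersect(atoms$name[atoms$conformer == "A"],
                    atoms$name[atoms$conformer == "B"])
  for (nm in both) {
    s <- sum(atoms$occ[atoms$name == nm])
    if (s > 1 + 1e-6)
      stop(sprintf("conformer occupancies for atom '%s' sum to %.3f > 1", nm, s))
  }
  structure(list(cell = cell, atoms = atoms, label = label),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model '%s': %d atoms (%d conformer A, %d conformer B)\n",
              x$label, nrow(x$atoms), sum(x$atoms$conformer == "A"),
              sum(x$atoms$conformer == "B")))
  print(x$cell)
  invisible(x)
}

#' Number of atoms in a model
#' @param model An [atomic_model()].
#' @return Integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Per-atom displacement profile between two models
#'
#' Computes the Cartesian displacement of every selected atom between two
#' models sharing the same atom ordering, i.e. the per-atom analogue of the
#' rmsd-versus-residue curves used to appraise refined conformational changes
#' against a fixed resting structure.
#'
#' @param model_ref Reference [atomic_model()].
#' @param model_act Comparison model with identical atom ordering and names.
#' @param selection Optional character vector of atom names (exact match) to
#'   restrict the profile; `NULL` keeps every atom.
#' @return A data frame with columns `name`, `conformer` and `displacement`
#'   (Angstrom), with attribute `mean` holding the mean displacement over the
#'   selection.
#' @export
rmsd_profile <- function(model_ref, model_act, selection = NULL) {
  stopifnot(inherits(model_ref, "atomic_model"), inherits(model_act, "atomic_model"))
  a <- model_ref$atoms; b <- model_act$atoms
  if (nrow(a) != nrow(b) || any(a$name != b$name))
    stop("models do not share atom correspondence (order/names differ)")
  keep <- if (is.null(selection)) rep(TRUE, nrow(a)) else a$name %in% selection
  if (!any(keep)) stop("no atoms match the selection")
  dfrac <- as.matrix(b[keep, c("fx", "fy", "fz")]) -
    as.matrix(a[keep, c("fx", "fy", "fz")])
  dcart <- frac_to_cart(model_ref$cell, dfrac)
  out <- data.frame(name = a$name[keep], conformer = a$conformer[keep],
                    displacement = sqrt(rowSums(dcart^2)))
  attr(out, "mean") <- mean(out$displacement)
  out
}

#' Merge two single-state models into one two-conformer model
#'
#' Builds the partial-occupancy representation of a mixed crystal: conformer A
#' is the reference model at occupancy `1 - f`, conformer B the activated model
#' at occupancy `f`.
#'
#' @param model_dark Reference-state model (atoms become conformer "A").
#' @param model_light Activated-state model (atoms become conformer "B").
#' @param f Activated-state occupancy in \[0, 1\].
#' @return A two-conformer [atomic_model()].
#' @export
two_state_model <- function(model_dark, model_light, f) {
  stopifnot(f >= 0, f <= 1)
  if (!cells_equal(model_dark$cell, model_light$cell))
    stop("the two models must share a unit cell")
  a <- model_dark$atoms; b <- model_light$atoms
  a$conformer <- "A"; a$occ <- a$occ * (1 - f)
  b$conformer <- "B"; b$occ <- b$occ * f
  atomic_model(model_dark$cell, rbind(a, b),
               label = sprintf("two-state f=%.3f", f))
}
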