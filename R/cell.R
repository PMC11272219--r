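#' Triclinic unit cell
#'
#' Constructs a P1 unit cell from lengths and angles and precomputes the
#' quantities every other tool needs: the cell volume, the PDB-convention
#' orthogonalization matrix (fractional -> Cartesian, a along x), its inverse,
#' and the reciprocal metric tensor used for d-spacings.
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a list with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `volume` (Angstrom^3), `orth` (3x3
#'   fractional-to-Cartesian matrix), `frac` (its inverse) and `gstar`
#'   (reciprocal metric tensor).
#' @examples
#' cell <- unit_cell(20, 20, 20)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("unit cell angles are degenerate (non-positive volume)")
  volume <- a * b * c * sqrt(vfac)
  # PDB convention: a along x, b in the xy plane
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, volume / (a * b * sg)
  ), nrow = 3, byrow = TRUE)
  gmat <- t(orth) %*% orth
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    volume = volume, orth = orth, frac = solve(orth), gstar = solve(gmat)
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("P1 unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Resolution (d-spacing) of Miller indices
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix with columns h, k, l (one row per reflection).
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "double"
  inv_d2 <- rowSums((hkl %*% cell$gstar) * hkl)
  1 / sqrt(inv_d2)
}

#' Convert fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac Matrix (n x 3) of fractional coordinates.
#' @return Matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- rbind(frac)
  t(cell$orth %*% t(frac))
}

#' Convert Cartesian to fractional coordinates
#'
#' @param cell A [unit_cell()].
#' @param cart Matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @return Matrix (n x 3) of fractional coordinates.
#' @export
cart_to_frac <- function(cell, cart) {
  cart <- rbind(cart)
  t(cell$frac %*% t(cart))
}

cells_equal <- function(a, b, tol = 1e-6) {
  all(abs(c(a$a - b$a, a$b - b$b, a$c - b$c,
            a$alpha - b$alpha, a$beta - b$beta, a$gamma - b$gamma)) < tol)
}
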