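#' Indexed structure-factor records
#'
#' A reflection set stores one record per Miller index in a fixed Friedel
#' half-sphere (h > 0, or h = 0 & k > 0, or h = k = 0 & l > 0; Friedel mates
#' are implied). Phases are stored internally in radians; the columnar text
#' format and all printed output use degrees.
#'
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param amplitude Numeric vector of structure-factor amplitudes (>= 0).
#' @param phase Numeric vector of phases in radians, or `NA` when unknown.
#' @param sigma Numeric vector of amplitude uncertainties, or `NA`.
#' @param cell A [unit_cell()].
#' @param d_min Resolution cutoff in Angstrom.
#' @param role One of "reference", "activated", "extrapolated", "calculated".
#' @param intensity Optional numeric vector of intensities.
#' @return An object of class `reflection_set`: a data frame with columns
#'   `h`, `k`, `l`, `F`, `phase`, `sigF`, `d` (and optionally `I`), plus
#'   attributes `cell`, `d_min`, `role`.
#' @export
reflection_set <- function(hkl, amplitude, phase = NA_real_, sigma = NA_real_,
                           cell = NULL, d_min = NA_real_, role = "calculated",
                           intensity = NULL) {
  hkl <- rbind(hkl)
  n <- nrow(hkl)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("duplicate Miller indices in reflection set")
  if (any(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0))
    stop("the (0,0,0) record is not allowed in a reflection set")
  if (any(amplitude < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  role <- match.arg(role, c("reference", "activated", "extrapolated", "calculated"))
  df <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                   l = as.integer(hkl[, 3]),
                   F = as.numeric(rep_len(amplitude, n)),
                   phase = as.numeric(rep_len(phase, n)),
                   sigF = as.numeric(rep_len(sigma, n)))
  if (!is.null(intensity)) df$I <- as.numeric(rep_len(intensity, n))
  if (!is.null(cell)) df$d <- d_spacing(cell, hkl)
  structure(df, cell = cell, d_min = d_min, role = role,
            class = c("reflection_set", "data.frame"))
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set (%s): %d reflections, d_min = %.2f A\n",
              attr(x, "role"), nrow(x), attr(x, "d_min")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

hkl_key <- function(rs) paste(rs$h, rs$k, rs$l)

#' Complex structure factors of a reflection set
#' @param rs A [reflection_set()] with phases present.
#' @return Complex vector `F * exp(i * phase)`.
#' @export
as_complex <- function(rs) {
  if (any(is.na(rs$phase))) stop("reflection set has missing phases")
  complex(modulus = rs$F, argument = rs$phase)
}

#' Phases in degrees, wrapped to \[-180, 180)
#' @param rs A [reflection_set()].
#' @return Numeric vector of phases in degrees.
#' @export
phase_deg <- function(rs) wrap_deg(rs$phase * 180 / pi)

wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Enumerate the Friedel half-sphere to a resolution cutoff
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution cutoff in Angstrom.
#' @return Integer matrix of Miller indices with d >= d_min, ordered by
#'   (h, k, l).
#' @export
hkl_half_sphere <- function(cell, d_min) {
  stopifnot(d_min > 0)
  lim <- ceiling(1 / (d_min * sqrt(diag(cell$gstar)))) + 1L
  g <- expand.grid(l = -lim[3]:lim[3], k = -lim[2]:lim[2], h = 0:lim[1])
  hkl <- as.matrix(g[, c("h", "k", "l")])
  keep <- hkl[, 1] > 0 |
    (hkl[, 1] == 0 & hkl[, 2] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0)
  hkl <- hkl[keep, , drop = FALSE]
  d <- d_spacing(cell, hkl)
  hkl <- hkl[d >= d_min, , drop = FALSE]
  if (nrow(hkl) == 0)
    stop(sprintf("zero reflections: d_min = %.2f A admits no Miller index in this cell", d_min))
  hkl[order(hkl[, 1], hkl[, 2], hkl[, 3]), , drop = FALSE]
}

# align rs_b's rows to rs_a's hkl order; error when sets differ
match_hkl <- function(rs_a, rs_b, context = "reflection sets") {
  ia <- hkl_key(rs_a); ib <- hkl_key(rs_b)
  idx <- match(ia, ib)
  if (anyNA(idx)) {
    miss <- ia[which(is.na(idx))[1]]
    stop(sprintf("%s differ: (%s) present in one set only", context, miss))
  }
  if (length(ib) != length(ia))
    stop(sprintf("%s differ: sizes %d vs %d", context, length(ia), length(ib)))
  idx
}

# inner join of two reflection sets on hkl; returns list(idx_a, idx_b)
common_hkl <- function(rs_a, rs_b) {
  ia <- hkl_key(rs_a); ib <- hkl_key(rs_b)
  common <- intersect(ia, ib)
  if (length(common) == 0) stop("reflection sets share no Miller indices")
  list(a = match(common, ia), b = match(common, ib))
}
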