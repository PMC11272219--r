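#' Stack difference maps into a voxels-by-maps matrix
#'
#' Arranges m resampled maps on a common grid as the columns of an n x m
#' matrix A (n voxels), ready for singular value decomposition A = U S V'.
#'
#' @param maps List of [density_map()]s (>= 2) on identical grids and cells.
#' @param provenance Optional column labels (replicate ids).
#' @return Object of class `map_stack`: list with matrix `A`, `dims`, `cell`,
#'   `provenance`.
#' @export
stack_maps <- function(maps, provenance = NULL) {
  if (length(maps) < 2) stop("need at least two maps to stack")
  dims <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!identical(dim(m$values), dims)) stop("maps are on different grids")
    if (!cells_equal(m$cell, maps[[1]]$cell)) stop("maps have different cells")
  }
  A <- vapply(maps, function(m) as.vector(m$values), numeric(prod(dims)))
  structure(list(A = A, dims = dims, cell = maps[[1]]$cell,
                 provenance = provenance %||% seq_along(maps)),
            class = "map_stack")
}

#' Unstack a column of a map stack back into a density map
#' @param stack A [stack_maps()] result.
#' @param j Column index.
#' @return A [density_map()].
#' @export
unstack_map <- function(stack, j) {
  density_map(array(stack$A[, j], dim = stack$dims), stack$cell,
              label = sprintf("replicate %s", stack$provenance[j]))
}

#' Singular value decomposition of a map stack
#'
#' Decomposes the voxels-by-maps matrix as A = U S V' with singular values in
#' decreasing order. The principal (first) component is the consensus
#' difference map of the replicate ensemble; noise uncorrelated between
#' replicates is pushed into the trailing components.
#'
#' @param stack A [stack_maps()] result.
#' @return Object of class `svd_result`: list with `u` (n x k), `d` (singular
#'   values), `v` (m x k), `m` (number of maps).
#' @export
svd_decompose <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  if (all(stack$A == 0)) stop("cannot decompose an all-zero map stack")
  s <- svd(stack$A)
  structure(list(u = s$u, d = s$d, v = s$v, m = ncol(stack$A)),
            class = "svd_result")
}

#' Principal-component consensus map
#'
#' Reshapes the first left singular vector onto the grid, scaled by
#' `S_1 / sqrt(m)` so its magnitude is comparable to an individual replicate
#' map. The sign of a singular vector is arbitrary; it is fixed so that the
#' component correlates positively with the voxel-wise mean of the stack.
#'
#' @param svd_res A [svd_decompose()] result.
#' @param stack The [stack_maps()] the decomposition came from.
#' @return A [density_map()].
#' @export
principal_map <- function(svd_res, stack) {
  pc1 <- svd_res$u[, 1] * svd_res$d[1] / sqrt(svd_res$m)
  mean_map <- rowMeans(stack$A)
  r <- stats::cor(pc1, mean_map)
  if (!is.finite(r) || abs(r) < 1e-6)
    stop("principal component sign is ambiguous (|cor with mean map| < 1e-6); fix the sign manually")
  if (r < 0) pc1 <- -pc1
  density_map(array(pc1, dim = stack$dims), stack$cell,
              label = "principal SVD component")
}

#' Integrate density within a sphere, above a pedestal
#'
#' Signed sum of the voxel values whose centers lie within `radius` of
#' `center` (minimum-image), after zeroing voxels with `|value| <
#' pedestal * sigma_map`, multiplied by the voxel volume. The pedestal is
#' applied with the map's own sigma. Used to quantify difference or omit
#' density associated with, e.g., a transient water site.
#'
#' @param map A [density_map()].
#' @param center Fractional coordinates of the sphere center.
#' @param radius Sphere radius in Angstrom (> 0); 0.8 A is the conventional
#'   water-site radius.
#' @param pedestal Sigma multiple below which voxels are zeroed (>= 0).
#' @return Integrated density (map units times Angstrom^3).
#' @export
integrate_sphere <- function(map, center, radius = 0.8, pedestal = 0) {
  stopifnot(inherits(map, "density_map"), radius > 0, pedestal >= 0)
  if (pedestal > 0 && map$sigma == 0)
    stop("pedestal masking needs a map with nonzero sigma")
  dims <- dim(map$values)
  inside <- voxels_within(map$cell, dims, matrix(center, 1), radius)
  if (!any(inside))
    stop("sphere contains no voxel center; use a finer grid")
  v <- map$values[inside]
  if (pedestal > 0) v[abs(v) < pedestal * map$sigma] <- 0
  sum(v) * map$cell$volume / prod(dims)
}

#' Quantify sphere-integrated density across time delays and replicates
#'
#' For each time delay and each named site, integrates every replicate map
#' with [integrate_sphere()] and reports the mean and standard deviation over
#' replicates — the resampling error bar on the feature amplitude.
#'
#' @param maps_by_delay Named list (one entry per delay) of lists of replicate
#'   [density_map()]s.
#' @param centers Named list of fractional coordinates, or a character vector
#'   of atom names resolved against `model`.
#' @param model Optional [atomic_model()] used to resolve atom names.
#' @param radius Sphere radius in Angstrom.
#' @param pedestal Sigma-multiple pedestal (2.0 for difference maps, 0.1 for
#'   omit maps by convention).
#' @return Object of class `quant_series`: data frame with columns `delay`,
#'   `atom`, `mean`, `sd`, `n`; attribute `values` holds per-replicate values.
#' @export
quantify_series <- function(maps_by_delay, centers, model = NULL,
                            radius = 0.8, pedestal = 2.0) {
  if (is.character(centers)) {
    if (is.null(model)) stop("resolving atom names requires a model")
    idx <- match(centers, model$atoms$name)
    if (anyNA(idx))
      stop("atom name(s) not found in model: ",
           paste(centers[is.na(idx)], collapse = ", "))
    centers <- stats::setNames(
      lapply(idx, function(i) as.numeric(model$atoms[i, c("fx", "fy", "fz")])),
      centers)
  }
  delays <- names(maps_by_delay) %||% as.character(seq_along(maps_by_delay))
  rows <- list()
  values <- list()
  for (d in seq_along(maps_by_delay)) {
    reps <- maps_by_delay[[d]]
    if (length(reps) < 1) stop("each delay needs at least one replicate map")
    for (a in names(centers)) {
      vals <- vapply(reps, integrate_sphere, 0, center = centers[[a]],
                     radius = radius, pedestal = pedestal)
      rows[[length(rows) + 1L]] <- data.frame(
        delay = delays[d], atom = a, mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0,
        n = length(vals))
      values[[paste(delays[d], a, sep = "|")]] <- vals
    }
  }
  out <- do.call(rbind, rows)
  structure(out, values = values, radius = radius, pedestal = pedestal,
            class = c("quant_series", "data.frame"))
}
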