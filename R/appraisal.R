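#' Occupancy scan with 1/f-law fit and Pearson-correlation selection
#'
#' Runs one partial-occupancy refinement per occupancy on a grid, records the
#' per-atom displacement profile of the refined activated conformer from the
#' fixed reference conformer, and derives the two appraisal products: (i) a
#' weighted least-squares line of mean displacement versus 1/f over a stated
#' domain (default f >= 0.25), quantifying the regime where the amplitude of
#' refined conformational changes is inversely proportional to the modeled
#' occupancy; and (ii) the per-occupancy Pearson correlation of the
#' displacement profile against the grid-mean profile, whose maximum is an
#' amplitude-independent occupancy estimate.
#'
#' @param F_obs Observed amplitudes.
#' @param model_dark Reference-state model (held fixed).
#' @param model_light_init Starting activated-state model.
#' @param f_grid Occupancy grid in (0, 1\] (default 5%..99% in 2% steps).
#' @param selection Atom-name selection for the displacement profile (`NULL` =
#'   all atoms).
#' @param fit_domain Occupancies (>= this value) entering the 1/f line fit.
#' @param opts Base [refine_options()]; its `f` is overridden per grid point.
#' @return Object of class `scan_result`: list with `f_grid`, `mean_disp`,
#'   `profiles` (atoms x f matrix), `correlation` (per f), `fit`
#'   (slope/intercept/r2 of mean_disp ~ 1/f), `f_best`, `f_best_range`,
#'   `models` (refined models).
#' @export
occupancy_scan <- function(F_obs, model_dark, model_light_init,
                           f_grid = seq(0.05, 0.99, by = 0.02),
                           selection = NULL, fit_domain = 0.25,
                           opts = refine_options()) {
  if (any(f_grid <= 0 | f_grid > 1)) stop("f_grid must lie in (0, 1]")
  f_grid <- sort(f_grid)
  profiles <- NULL
  models <- vector("list", length(f_grid))
  mean_disp <- numeric(length(f_grid))
  for (i in seq_along(f_grid)) {
    f <- f_grid[i]
    ts <- two_state_model(model_dark, model_light_init, f)
    o <- opts; o$f <- f; o$mode <- "partial_occupancy"
    rm_ <- tryCatch(refine(F_obs, ts, o),
                    error = function(e) stop(sprintf(
                      "occupancy scan failed at f = %.3f: %s", f,
                      conditionMessage(e))))
    models[[i]] <- rm_
    ref_b <- rm_$model$atoms[rm_$model$atoms$conformer == "B", , drop = FALSE]
    refined_light <- atomic_model(model_dark$cell, transform_occ(ref_b))
    prof <- rmsd_profile(model_dark, refined_light, selection)
    if (is.null(profiles))
      profiles <- matrix(NA_real_, nrow(prof), length(f_grid),
                         dimnames = list(prof$name, NULL))
    profiles[, i] <- prof$displacement
    mean_disp[i] <- attr(prof, "mean")
  }
  mean_profile <- rowMeans(profiles)
  correlation <- if (length(f_grid) == 1) {
    structure(1, flagged = "single-point grid: correlation 1 by convention")
  } else {
    apply(profiles, 2, function(x) {
      if (stats::sd(x) == 0 || stats::sd(mean_profile) == 0) return(NA_real_)
      stats::cor(x, mean_profile)
    })
  }
  dom <- f_grid >= fit_domain
  fit <- if (sum(dom) >= 2) {
    lf <- stats::lm(mean_disp[dom] ~ I(1 / f_grid[dom]))
    list(slope = unname(stats::coef(lf)[2]),
         intercept = unname(stats::coef(lf)[1]),
         r2 = summary(lf)$r.squared, domain = fit_domain)
  } else NULL
  cmax <- max(correlation, na.rm = TRUE)
  near <- which(correlation >= cmax - 1e-3)
  structure(list(f_grid = f_grid, mean_disp = mean_disp, profiles = profiles,
                 correlation = as.numeric(correlation), fit = fit,
                 f_best = f_grid[min(near)],
                 f_best_range = range(f_grid[near]), models = models),
            class = "scan_result")
}

# strip conformer bookkeeping so the activated conformer compares 1:1 with the
# reference model
transform_occ <- function(atoms) {
  atoms$occ <- 1
  atoms$conformer <- "A"
  atoms
}

#' Extract the refined activated conformer as a standalone model
#'
#' @param refined A [refine()] result.
#' @param conformer Conformer tag to extract (`"B"`); use `"A"` or `NULL` for
#'   single-conformer refinements.
#' @return An [atomic_model()] at occupancy 1.
#' @export
activated_model <- function(refined, conformer = "B") {
  at <- refined$model$atoms
  if (!is.null(conformer) && any(at$conformer == conformer))
    at <- at[at$conformer == conformer, , drop = FALSE]
  atomic_model(refined$model$cell, transform_occ(at),
               label = "activated conformer")
}

#' Coordinate spread over a set of refined replicate models
#'
#' Per-atom root mean square deviation of each atom's position from its mean
#' position over the replicates — the bootstrap estimate of coordinate error.
#'
#' @param models List (>= 2) of [refine()] results or [atomic_model()]s with
#'   common atom ordering.
#' @param selection Atom-name selection for the selection mean (`NULL` = all).
#' @return Object of class `error_estimate`: data frame with columns `name`,
#'   `spread` (Angstrom); attributes `mean_selection`, `mean_all`,
#'   `n_models`.
#' @export
coordinate_spread <- function(models, selection = NULL) {
  models <- lapply(models, function(m) if (inherits(m, "refined_model")) m$model else m)
  if (length(models) < 2) stop("need at least two models")
  ref <- models[[1]]
  for (m in models[-1]) {
    if (n_atoms(m) != n_atoms(ref) || any(m$atoms$name != ref$atoms$name))
      stop("models do not share atom ordering")
  }
  cart <- lapply(models, function(m)
    frac_to_cart(m$cell, as.matrix(m$atoms[, c("fx", "fy", "fz")])))
  arr <- simplify2array(cart)                       # atoms x 3 x models
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(x) rowSums((x - mean_pos)^2))
  spread <- sqrt(rowMeans(dev2))
  keep <- if (is.null(selection)) rep(TRUE, length(spread)) else
    ref$atoms$name %in% selection
  if (!any(keep)) stop("no atoms match the selection")
  out <- data.frame(name = ref$atoms$name, conformer = ref$atoms$conformer,
                    spread = spread)
  structure(out, mean_selection = mean(spread[keep]), mean_all = mean(spread),
            n_models = length(models),
            class = c("error_estimate", "data.frame"))
}

#' Closed-form coordinate-error estimate from refinement statistics
#'
#' Diffraction-precision-index style estimate
#' \deqn{\sigma_{free} = \sqrt{0.65\, (N_a/N_o)\, R_{free}^2\, d_{min}^2\, C^{e}},}
#' valid for full-occupancy refinement, where C is the completeness, N_a the
#' number of refined atoms and N_o the number of independent observations. The
#' completeness exponent is configurable (default -3/2): a lower completeness
#' must not shrink the estimate, and the simplified-formula literature uses the
#' negative exponent, but renderings of the formula are typographically
#' ambiguous on the sign, so it is exposed rather than silently resolved.
#'
#' @param N_a Number of atoms in refinement (> 0).
#' @param N_o Number of independent observations (> 0).
#' @param R_free Free R-factor as a fraction.
#' @param d_min Resolution in Angstrom.
#' @param C Completeness in (0, 1\].
#' @param completeness_exponent Exponent applied to C (default -1.5).
#' @return Coordinate error sigma_free in Angstrom.
#' @export
sigma_free <- function(N_a, N_o, R_free, d_min, C = 1,
                       completeness_exponent = -1.5) {
  if (N_o <= 0) stop("N_o must be positive")
  if (N_a <= 0 || R_free <= 0 || d_min <= 0) stop("all inputs must be positive")
  if (C <= 0 || C > 1) stop("completeness must lie in (0, 1]")
  sqrt(0.65 * (N_a / N_o) * R_free^2 * d_min^2 * C^completeness_exponent)
}

#' RMS displacement amplitude from an isotropic B-factor
#'
#' Inverts `B = 8 pi^2 <u^2>`: `u = sqrt(B / (8 pi^2))`. A mean B of 41 A^2
#' corresponds to u of about 0.7 A.
#'
#' @param B Isotropic B-factor in Angstrom^2 (>= 0).
#' @return RMS displacement u in Angstrom.
#' @export
b_to_u <- function(B) {
  if (any(B < 0)) stop("B must be non-negative")
  sqrt(B / (8 * pi^2))
}

#' Compare partial-occupancy and extrapolated-data refinements
#'
#' Computes, per atom, the separation of the mean coordinates recovered by the
#' two refinement approaches, their summed bootstrap error bars, and an
#' agreement flag (separation < summed bars). Also reports the Pearson
#' correlation of the two mean displacement profiles relative to a reference
#' model (or the pooled grand mean when none is given).
#'
#' @param models_partial List of partial-occupancy replicate models
#'   ([refine()] results or [atomic_model()]s).
#' @param models_extrapolated List of extrapolated-data replicate models.
#' @param selection Atom-name selection (`NULL` = all).
#' @param model_ref Optional reference model for the displacement profiles.
#' @return Object of class `approach_comparison`: data frame with columns
#'   `name`, `separation`, `bars`, `agree`; attributes `profile_correlation`,
#'   `fraction_agreeing`.
#' @export
compare_approaches <- function(models_partial, models_extrapolated,
                               selection = NULL, model_ref = NULL) {
  if (length(models_partial) == 0 || length(models_extrapolated) == 0)
    stop("both model sets must be non-empty")
  get_models <- function(ms) lapply(ms, function(m)
    if (inherits(m, "refined_model")) m$model else m)
  mp <- get_models(models_partial); me <- get_models(models_extrapolated)
  ref <- mp[[1]]
  for (m in c(mp, me))
    if (n_atoms(m) != n_atoms(ref) || any(m$atoms$name != ref$atoms$name))
      stop("models do not share atom ordering")
  keep <- if (is.null(selection)) rep(TRUE, n_atoms(ref)) else
    ref$atoms$name %in% selection
  if (!any(keep)) stop("no atoms match the selection")
  mean_cart <- function(ms) {
    arr <- simplify2array(lapply(ms, function(m)
      frac_to_cart(m$cell, as.matrix(m$atoms[, c("fx", "fy", "fz")]))))
    apply(arr, c(1, 2), mean)
  }
  cp <- mean_cart(mp); ce <- mean_cart(me)
  separation <- sqrt(rowSums((cp - ce)^2))
  spread_of <- function(ms) {
    if (length(ms) >= 2) coordinate_spread(ms)$spread else rep(0, n_atoms(ref))
  }
  bars <- spread_of(mp) + spread_of(me)
  ref_cart <- if (!is.null(model_ref))
    frac_to_cart(model_ref$cell, as.matrix(model_ref$atoms[, c("fx", "fy", "fz")]))
  else (cp + ce) / 2
  disp_p <- sqrt(rowSums((cp - ref_cart)^2))
  disp_e <- sqrt(rowSums((ce - ref_cart)^2))
  prof_cor <- if (sum(keep) > 1 && stats::sd(disp_p[keep]) > 0 &&
                  stats::sd(disp_e[keep]) > 0)
    stats::cor(disp_p[keep], disp_e[keep]) else 1
  out <- data.frame(name = ref$atoms$name[keep],
                    separation = separation[keep], bars = bars[keep],
                    agree = separation[keep] < bars[keep])
  structure(out, profile_correlation = prof_cor,
            fraction_agreeing = mean(out$agree),
            class = c("approach_comparison", "data.frame"))
}
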