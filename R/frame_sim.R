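#' Per-frame partial-intensity observations
#'
#' Container emulating the statistical structure of serial-crystallography
#' stream observations: each frame (one diffraction pattern, i.e. one
#' microcrystal) carries background-subtracted partial intensities for a
#' subset of reflections. Negative intensities are legal and preserved.
#'
#' @param obs Data frame with columns `frame` (0-based, dense ids), `h`, `k`,
#'   `l`, `I`, `sigma`.
#' @param n_frames Total number of frames (frames may have zero observations).
#' @param cell Optional [unit_cell()] of the underlying crystal.
#' @param params List of generator parameters (seed, noise levels, ...).
#' @param truth_label Label of the reflection set the frames were drawn from.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(obs, n_frames, cell = NULL, params = list(),
                      truth_label = "") {
  stopifnot(is.data.frame(obs))
  needed <- c("frame", "h", "k", "l", "I", "sigma")
  if (!all(needed %in% names(obs))) stop("observation table is missing columns")
  if (nrow(obs) > 0) {
    if (any(obs$frame < 0 | obs$frame >= n_frames))
      stop("frame ids must lie in [0, n_frames)")
    if (any(obs$sigma < 0)) stop("sigmas must be non-negative")
  }
  structure(list(obs = obs, n_frames = as.integer(n_frames), cell = cell,
                 params = params, truth_label = truth_label),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames, %d observations of %d unique reflections\n",
              x$n_frames, nrow(x$obs),
              nrow(unique(x$obs[, c("h", "k", "l")]))))
  invisible(x)
}

#' Simulate per-frame partial intensities from ground-truth structure factors
#'
#' Generates `n_frames` synthetic stream frames from a truth reflection set.
#' Each frame observes a Bernoulli(`obs_fraction`) subset of reflections with
#' \deqn{I_p = s\, p\, I_{true} + \epsilon,}
#' where the frame scale s ~ LogNormal(0, `scale_sigma`) models shot-to-shot
#' beam and crystal-size fluctuations, the partiality p ~ Uniform(
#' `partiality_min`, 1) models partially recorded reflections, and the additive
#' noise is Gaussian with sd `noise_frac * median(I_true)` (recorded as the
#' observation sigma). Frames are generated from per-frame seeds derived from
#' the master seed with [derive_seed()], so any subset reproduces identically.
#'
#' @param F_true Truth [reflection_set()]; intensities taken from column `I`
#'   when present, else `F^2`.
#' @param n_frames Number of frames (>= 1).
#' @param obs_fraction Probability that a frame observes a given reflection,
#'   in (0, 1\].
#' @param scale_sigma Lognormal sigma of the per-frame scale (0 disables).
#' @param partiality_min Lower bound of the uniform partiality, in (0, 1\].
#' @param noise_frac Additive Gaussian noise sd as a fraction of the median
#'   truth intensity (>= 0).
#' @param seed Master seed (required; no silent nondeterminism).
#' @return A [frame_set()].
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' m <- atomic_model(cell, atom_table("O", "O", c(0.1, 0.2, 0.3), b_iso = 5))
#' fs <- simulate_frames(structure_factors(m, 3), 10, seed = 1)
#' @export
simulate_frames <- function(F_true, n_frames, obs_fraction = 0.7,
                            scale_sigma = 0.3, partiality_min = 0.2,
                            noise_frac = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (!is.numeric(obs_fraction) || obs_fraction <= 0 || obs_fraction > 1)
    stop("obs_fraction must lie in (0, 1]")
  if (partiality_min <= 0 || partiality_min > 1)
    stop("partiality_min must lie in (0, 1]")
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  I_true <- if ("I" %in% names(F_true)) F_true$I else F_true$F^2
  nref <- length(I_true)
  noise_sd <- noise_frac * stats::median(I_true)
  sigma_rec <- max(noise_sd, .Machine$double.eps)
  hkl <- as.matrix(F_true[, c("h", "k", "l")])
  out <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    set.seed(derive_seed(seed, fr - 1L))
    sel <- if (obs_fraction >= 1) rep(TRUE, nref) else
      stats::runif(nref) < obs_fraction
    nsel <- sum(sel)
    if (nsel == 0) next
    s_frame <- if (scale_sigma > 0) stats::rlnorm(1, 0, scale_sigma) else 1
    p <- if (partiality_min < 1) stats::runif(nsel, partiality_min, 1) else rep(1, nsel)
    eps <- if (noise_sd > 0) stats::rnorm(nsel, 0, noise_sd) else 0
    out[[fr]] <- data.frame(frame = fr - 1L, h = hkl[sel, 1], k = hkl[sel, 2],
                            l = hkl[sel, 3],
                            I = s_frame * p * I_true[sel] + eps,
                            sigma = sigma_rec)
  }
  obs <- as.data.frame(data.table::rbindlist(Filter(Negate(is.null), out)))
  frame_set(obs, n_frames = n_frames, cell = attr(F_true, "cell"),
            params = list(obs_fraction = obs_fraction, scale_sigma = scale_sigma,
                          partiality_min = partiality_min,
                          noise_frac = noise_frac, seed = seed),
            truth_label = attr(F_true, "role") %||% "")
}

#' Simulate paired dark/light frame sets from a two-state ground truth
#'
#' The light frames are drawn from the intensities of the coherent mixture
#' `|(1 - f) F_dark + f F_light|^2` (see [mix_states()]), the dark frames from
#' `|F_dark|^2`. The two generators use disjoint seeds derived from the master
#' seed.
#'
#' @param model_dark,model_light [atomic_model()]s sharing atom correspondence.
#' @param f Activated-state occupancy in \[0, 1\].
#' @param d_min Resolution cutoff in Angstrom.
#' @param n_frames Frames per set.
#' @param seed Master seed.
#' @param ... Noise parameters passed to [simulate_frames()].
#' @return List with elements `dark` and `light` ([frame_set()]s), plus the
#'   truth reflection sets `F_dark`, `F_light`, `F_mix`.
#' @export
two_state_frameset <- function(model_dark, model_light, f, d_min, n_frames,
                               seed, ...) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  F_dark <- structure_factors(model_dark, d_min)
  F_light <- structure_factors(model_light, d_min)
  F_mix <- mix_states(F_dark, F_light, f)
  list(
    dark = simulate_frames(F_dark, n_frames, seed = derive_seed(seed, 101L), ...),
    light = simulate_frames(F_mix, n_frames, seed = derive_seed(seed, 202L), ...),
    F_dark = F_dark, F_light = F_light, F_mix = F_mix
  )
}
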