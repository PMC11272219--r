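#' Fixed-size bootstrap resampling plan
#'
#' Draws `n_resamples` multisets of exactly `sample_size` frame indices with
#' replacement from `[0, n_frames)`. This mirrors the fixed-size bootstrap used
#' to build quasi-independent serial-crystallography datasets: the resampling
#' unit is always the frame (diffraction pattern), never the individual
#' reflection observation. Each replicate uses its own seed derived from the
#' master seed, so replicates can be regenerated independently.
#'
#' @param n_frames Number of available frames (>= 1).
#' @param sample_size Frames per replicate (>= 1).
#' @param n_resamples Number of replicates (>= 1).
#' @param seed Master seed.
#' @return An object of class `resample_plan`: list with `indices` (list of
#'   0-based integer vectors), `n_frames`, `sample_size`, `n_resamples`,
#'   `seed`.
#' @examples
#' plan <- bootstrap_plan(1000, 100, 10, seed = 7)
#' lengths(plan$indices)
#' @export
bootstrap_plan <- function(n_frames, sample_size, n_resamples, seed) {
  if (n_frames < 1 || sample_size < 1 || n_resamples < 1)
    stop("n_frames, sample_size and n_resamples must all be >= 1")
  if (missing(seed)) stop("a seed is required")
  idx <- lapply(seq_len(n_resamples), function(r) {
    set.seed(derive_seed(seed, r))
    sample.int(n_frames, sample_size, replace = TRUE) - 1L
  })
  structure(list(indices = idx, n_frames = as.integer(n_frames),
                 sample_size = as.integer(sample_size),
                 n_resamples = as.integer(n_resamples), seed = seed),
            class = "resample_plan")
}

#' Expected number of selections per frame under a bootstrap plan
#'
#' With `n_resamples` replicates of `sample_size` draws from `n_frames`
#' frames, each frame is selected `n_resamples * sample_size / n_frames` times
#' on average; e.g. 100 replicates of 10 000 patterns from 250 000 select each
#' image four times on average.
#'
#' @param n_frames,sample_size,n_resamples Plan dimensions (>= 1).
#' @return Expected selections per frame.
#' @export
expected_multiplicity <- function(n_frames, sample_size, n_resamples) {
  if (n_frames < 1 || sample_size < 1 || n_resamples < 1)
    stop("all counts must be >= 1")
  n_resamples * sample_size / n_frames
}

#' Monte-Carlo merge of a frame multiset
#'
#' Merges the partial observations of the selected frames into per-reflection
#' mean intensities. Merging is a plain unweighted Monte-Carlo average (the
#' serial-crystallography baseline): partiality and scale fluctuations average
#' out over many frames. A frame drawn k times in the bootstrap multiset
#' contributes each of its observations k-fold, and the reported multiplicity
#' counts draws.
#'
#' @param frames A [frame_set()].
#' @param indices 0-based frame index multiset (one replicate of a
#'   [bootstrap_plan()]), or `NULL` to merge every frame once.
#' @param min_measurements Reflections with fewer contributing draws are
#'   dropped (and counted).
#' @return Object of class `merged_data`: data frame with columns `h`, `k`,
#'   `l`, `I` (mean), `sem` (standard error of the mean), `mult`
#'   (multiplicity); attributes `n_dropped`, `cell`.
#' @export
merge_frames <- function(frames, indices = NULL, min_measurements = 3) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(indices)) indices <- seq_len(frames$n_frames) - 1L
  if (length(indices) == 0) stop("empty frame selection")
  if (any(indices < 0 | indices >= frames$n_frames))
    stop("frame indices out of range")
  counts <- tabulate(indices + 1L, nbins = frames$n_frames)
  dt <- data.table::as.data.table(frames$obs)
  dt[, w := counts[frame + 1L]]
  dt <- dt[w > 0]
  if (nrow(dt) == 0) stop("selected frames carry no observations")
  m <- dt[, {
    sw <- sum(w)
    mu <- sum(w * I) / sw
    v <- if (sw > 1) sum(w * (I - mu)^2) / (sw - 1) else NA_real_
    list(I = mu, sem = if (sw > 1) sqrt(v / sw) else NA_real_, mult = sw)
  }, by = .(h, k, l)]
  dropped <- m[mult < min_measurements]
  m <- m[mult >= min_measurements]
  if (nrow(m) == 0) stop("no reflection reaches min_measurements")
  data.table::setorder(m, h, k, l)
  out <- as.data.frame(m)
  structure(out, n_dropped = nrow(dropped), cell = frames$cell,
            class = c("merged_data", "data.frame"))
}

#' Convert merged intensities to structure-factor amplitudes
#'
#' Clip-at-zero square-root policy: `F = sqrt(max(I, 0))`. Negative-intensity
#' records are clipped to zero amplitude, retained and flagged (column
#' `clipped`); the negative fraction is reported as an attribute. Sigma
#' propagation uses `sigF = sem / (2 F)` for positive amplitudes and
#' `sqrt(sem)` as the zero-amplitude fallback. A French-Wilson style treatment
#' is a documented future adapter.
#'
#' @param merged A [merge_frames()] result.
#' @param cell Optional [unit_cell()] (defaults to the one carried by
#'   `merged`).
#' @param d_min Resolution cutoff to record.
#' @param role Role tag for the returned set.
#' @return A [reflection_set()] with extra column `clipped`; attribute
#'   `negative_fraction` reports the clipped fraction.
#' @export
intensities_to_amplitudes <- function(merged, cell = NULL, d_min = NA_real_,
                                      role = "reference") {
  stopifnot(inherits(merged, "merged_data"), nrow(merged) > 0)
  cell <- cell %||% attr(merged, "cell")
  neg <- merged$I < 0
  Famp <- sqrt(pmax(merged$I, 0))
  sigF <- ifelse(Famp > 0, merged$sem / (2 * Famp), sqrt(pmax(merged$sem, 0)))
  rs <- reflection_set(as.matrix(merged[, c("h", "k", "l")]), amplitude = Famp,
                       phase = NA_real_, sigma = sigF, cell = cell,
                       d_min = d_min, role = role)
  rs$clipped <- neg
  attr(rs, "negative_fraction") <- mean(neg)
  rs
}

#' Random half-set R-split figure of merit
#'
#' Splits the frame multiset into two random halves, merges each, and computes
#' \deqn{R_{split} = 2^{-1/2} \sum |I_1 - I_2| / (\tfrac12 \sum (I_1 + I_2))}
#' over reflections present in both halves. Decreases as more frames are
#' merged.
#'
#' @param frames A [frame_set()].
#' @param indices Frame multiset (0-based); `NULL` uses every frame once.
#' @param seed Seed for the random half split.
#' @param min_measurements Per-half multiplicity cutoff.
#' @return R-split value (>= 0).
#' @export
half_set_rsplit <- function(frames, indices = NULL, seed = 1,
                            min_measurements = 1) {
  if (is.null(indices)) indices <- seq_len(frames$n_frames) - 1L
  if (length(indices) < 2) stop("need at least two frames for a half split")
  set.seed(derive_seed(seed, 0L))
  perm <- sample(length(indices))
  half <- length(indices) %/% 2
  m1 <- merge_frames(frames, indices[perm[seq_len(half)]], min_measurements)
  m2 <- merge_frames(frames, indices[perm[(half + 1):length(indices)]],
                     min_measurements)
  k1 <- paste(m1$h, m1$k, m1$l); k2 <- paste(m2$h, m2$k, m2$l)
  common <- intersect(k1, k2)
  if (length(common) == 0) stop("the two half-sets share no reflections")
  i1 <- m1$I[match(common, k1)]; i2 <- m2$I[match(common, k2)]
  (2^-0.5) * sum(abs(i1 - i2)) / (0.5 * sum(i1 + i2))
}
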