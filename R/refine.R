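#' Options for reciprocal-space two-state refinement
#'
#' @param mode `"partial_occupancy"`: F_calc is the coherent sum of the frozen
#'   conformer A (occupancy 1 - f) and the free conformer B (occupancy f);
#'   `"extrapolated"`: a single free conformer at occupancy 1 is refined
#'   against extrapolated (or plain) amplitudes.
#' @param f Activated-state occupancy in (0, 1\] (partial mode).
#' @param max_cycles Maximum refinement macro-cycles.
#' @param tol Convergence tolerance on the relative target decrease per cycle.
#' @param parameters Which parameter classes move: any of "coordinates",
#'   "b_factors".
#' @param frozen_conformer Conformer tag held fixed in partial mode.
#' @param free_frac Fraction of reflections held out for R-free, in (0, 0.5\].
#' @param free_seed Seed of the deterministic free-set split.
#' @param maxit_per_cycle Quasi-Newton iterations per macro-cycle.
#' @param origin_weight Weight (relative to the data target scale) of the
#'   soft restraint anchoring the free-atom centroid to its starting value.
#'   In P1 a joint translation of all scattering matter leaves every amplitude
#'   unchanged, so when the frozen conformer's occupancy is small this gauge
#'   mode must be pinned; the restraint has essentially zero curvature cost
#'   along genuine (data-determined) directions.
#' @return A list of class `refine_options`.
#' @export
refine_options <- function(mode = c("partial_occupancy", "extrapolated"),
                           f = 1, max_cycles = 5, tol = 1e-9,
                           parameters = c("coordinates", "b_factors"),
                           frozen_conformer = "A", free_frac = 0.05,
                           free_seed = 42, maxit_per_cycle = 60,
                           origin_weight = 0.01) {
  mode <- match.arg(mode)
  if (mode == "partial_occupancy" && (f <= 0 || f > 1))
    stop("partial-occupancy mode needs f in (0, 1]")
  if (free_frac <= 0 || free_frac > 0.5) stop("free_frac must lie in (0, 0.5]")
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  structure(list(mode = mode, f = f, max_cycles = max_cycles, tol = tol,
                 parameters = parameters, frozen_conformer = frozen_conformer,
                 free_frac = free_frac, free_seed = free_seed,
                 maxit_per_cycle = maxit_per_cycle,
                 origin_weight = origin_weight),
            class = "refine_options")
}

#' Reciprocal-space least-squares refinement of a (two-state) model
#'
#' Minimizes `sum_hkl (F_obs - k |F_calc|)^2` over the coordinates and
#' isotropic B-factors of the free atoms, with the overall scale k refit in
#' closed form (`k = sum(F_obs |F_calc|) / sum(|F_calc|^2)`) at every target
#' evaluation. In partial-occupancy mode the frozen conformer's contribution
#' is precomputed once and the free conformer scatters at occupancy f; in
#' extrapolated mode a single conformer at occupancy 1 is refined against the
#' supplied (typically extrapolated) amplitudes. No geometric restraints are
#' applied: the engine is an appraisal tool for sparse synthetic models, not a
#' macromolecular refinement program. A deterministic 5% reflection subset is
#' held out for R-free.
#'
#' @param F_obs Observed amplitudes ([reflection_set()]).
#' @param model An [atomic_model()]; in partial mode a two-conformer model
#'   (see [two_state_model()]) whose conformer B occupancies already encode f.
#' @param opts A [refine_options()].
#' @return Object of class `refined_model`: list with `model` (refined),
#'   `r_work`, `r_free`, `target_trace`, `scale_k`, `free_seed`, `n_work`,
#'   `n_free`.
#' @export
refine <- function(F_obs, model, opts = refine_options()) {
  stopifnot(inherits(model, "atomic_model"))
  at <- model$atoms
  if (opts$mode == "partial_occupancy") {
    free_sel <- at$conformer != opts$frozen_conformer
    if (!any(free_sel)) stop("no free atoms: every atom is in the frozen conformer")
  } else {
    free_sel <- rep(TRUE, nrow(at))
  }
  hkl <- as.matrix(F_obs[, c("h", "k", "l")])
  cell <- model$cell
  s2 <- 1 / d_spacing(cell, hkl)^2
  F_fix <- if (all(!free_sel)) 0 else if (any(!free_sel))
    calc_sf_complex(cell, at[!free_sel, , drop = FALSE], hkl) else
      complex(real = rep(0, nrow(hkl)))
  free_at <- at[free_sel, , drop = FALSE]
  nfree <- nrow(free_at)
  wz <- free_at$occ * free_at$z

  # deterministic R-free split
  set.seed(derive_seed(opts$free_seed, nrow(hkl)))
  n_free_refl <- max(1L, round(opts$free_frac * nrow(hkl)))
  free_refl <- sample.int(nrow(hkl), n_free_refl)
  work <- setdiff(seq_len(nrow(hkl)), free_refl)
  Fo <- F_obs$F

  move_xyz <- "coordinates" %in% opts$parameters
  move_b <- "b_factors" %in% opts$parameters
  pack <- function(a) c(if (move_xyz) as.vector(as.matrix(a[, c("fx", "fy", "fz")])),
                        if (move_b) a$b_iso)
  unpack <- function(p) {
    a <- free_at
    o <- 0
    if (move_xyz) {
      xyz <- matrix(p[1:(3 * nfree)], nfree, 3)
      a$fx <- xyz[, 1]; a$fy <- xyz[, 2]; a$fz <- xyz[, 3]
      o <- 3 * nfree
    }
    if (move_b) a$b_iso <- p[(o + 1):(o + nfree)]
    a
  }

  # soft origin anchor: the data cannot see a joint translation when the
  # frozen conformer's weight is small
  X0_centroid <- colMeans(as.matrix(free_at[, c("fx", "fy", "fz")]))
  w_origin <- (opts$origin_weight %||% 0.01) * sum(F_obs$F^2)

  eval_state <- function(p) {
    a <- unpack(p)
    X <- as.matrix(a[, c("fx", "fy", "fz")])
    P <- hkl %*% t(X)
    W <- exp(-outer(s2 / 4, a$b_iso)) *
      matrix(wz, length(s2), nfree, byrow = TRUE)
    C <- W * exp(2i * pi * P)
    Fc <- F_fix + as.vector(C %*% rep(1, nfree))
    A <- Mod(Fc)
    A[A < 1e-12] <- 1e-12
    k <- sum(Fo[work] * A[work]) / sum(A[work]^2)
    r <- Fo - k * A
    cc <- if (move_xyz) as.vector(cell$orth %*% (colMeans(X) - X0_centroid))
      else c(0, 0, 0)
    Tval <- sum(r[work]^2) + w_origin * sum(cc^2)
    if (!is.finite(Tval)) {
      bad <- which(!is.finite(r))[1] %||% 1L
      stop(sprintf("non-finite refinement target at reflection (%d %d %d)",
                   hkl[bad, 1], hkl[bad, 2], hkl[bad, 3]))
    }
    list(a = a, C = C, Fc = Fc, A = A, k = k, r = r, cc = cc, T = Tval)
  }

  grad_state <- function(st) {
    g <- numeric(length(Fo))
    g[work] <- -2 * st$k * st$r[work]     # dT/dA on the working set
    Z <- (Conj(st$Fc) / st$A) * st$C      # columns: per free atom
    gr <- numeric(0)
    if (move_xyz) {
      gx <- -2 * pi * as.vector(t(Im(Z)) %*% (g * hkl[, 1]))
      gy <- -2 * pi * as.vector(t(Im(Z)) %*% (g * hkl[, 2]))
      gz <- -2 * pi * as.vector(t(Im(Z)) %*% (g * hkl[, 3]))
      # origin-anchor gradient: each free atom contributes 1/n to the centroid
      go <- 2 * w_origin * as.vector(t(cell$orth) %*% st$cc) / nfree
      gr <- c(gx + go[1], gy + go[2], gz + go[3])
    }
    if (move_b) gr <- c(gr, as.vector(t(Re(Z)) %*% (g * (-s2 / 4))))
    gr
  }

  p <- pack(free_at)
  lower <- rep(-Inf, length(p))
  upper <- rep(Inf, length(p))
  if (move_b) {
    nb <- nfree
    lower[(length(p) - nb + 1):length(p)] <- 0.01
    upper[(length(p) - nb + 1):length(p)] <- 500
  }
  trace <- eval_state(p)$T
  for (cyc in seq_len(opts$max_cycles)) {
    fit <- stats::optim(p,
      fn = function(pp) eval_state(pp)$T,
      gr = function(pp) grad_state(eval_state(pp)),
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = opts$maxit_per_cycle, factr = 1e3))
    prev <- trace[length(trace)]
    p <- fit$par
    trace <- c(trace, fit$value)
    if (prev - fit$value <= opts$tol * max(1, prev)) break
  }

  st <- eval_state(p)
  at[free_sel, ] <- st$a
  r_work <- sum(abs(st$r[work])) / sum(Fo[work])
  r_free <- sum(abs(st$r[free_refl])) / sum(Fo[free_refl])
  structure(list(
    model = atomic_model(cell, at, label = paste(model$label, "(refined)")),
    r_work = r_work, r_free = r_free, target_trace = trace,
    scale_k = st$k, free_seed = opts$free_seed,
    n_work = length(work), n_free = length(free_refl), opts = opts),
    class = "refined_model")
}

#' @export
print.refined_model <- function(x, ...) {
  cat(sprintf("refined_model: R-work = %.2f%%, R-free = %.2f%% (%d work / %d free refl), %d cycles\n",
              100 * x$r_work, 100 * x$r_free, x$n_work, x$n_free,
              length(x$target_trace) - 1))
  invisible(x)
}
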