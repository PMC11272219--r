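# shared fixtures built in code

# strip phases so a calculated set plays the role of an observed amplitude set
as_obs <- function(rs, role = "activated") {
  reflection_set(as.matrix(rs[, c("h", "k", "l")]), rs$F,
                 sigma = rep(1, nrow(rs)),
                 cell = attr(rs, "cell"), d_min = attr(rs, "d_min"),
                 role = role)
}

# small two-state system shared across refinement tests
toy_system <- function(seed = 11, n_atoms = 8, displacement = 0.15,
                       move_fraction = 0.5, d_min = 2.0, f_true = 0.27) {
  sys <- toy_two_state(seed = seed, n_atoms = n_atoms,
                       displacement = displacement,
                       move_fraction = move_fraction)
  sys$f_true <- f_true
  sys$d_min <- d_min
  sys$F_dark <- structure_factors(sys$dark, d_min)
  sys$F_light <- structure_factors(sys$light, d_min)
  sys$F_mix <- mix_states(sys$F_dark, sys$F_light, f_true)
  sys
}

# independent brute-force direct summation (double loop), used as oracle
brute_force_sf <- function(model, hkl) {
  at <- model$atoms
  out <- complex(real = numeric(nrow(hkl)))
  for (i in seq_len(nrow(hkl))) {
    s2 <- 1 / d_spacing(model$cell, hkl[i, , drop = FALSE])^2
    for (j in seq_len(nrow(at))) {
      out[i] <- out[i] + at$occ[j] * at$z[j] * exp(-at$b_iso[j] * s2 / 4) *
        exp(2i * pi * sum(hkl[i, ] * unlist(at[j, c("fx", "fy", "fz")])))
    }
  }
  out
}
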