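test_that("single-coefficient synthesis matches the closed-form cosine", {
  cell <- unit_cell(10, 10, 10)
  A <- 2.5
  rs <- reflection_set(matrix(c(1, 0, 0), 1), amplitude = A, phase = 0,
                       cell = cell, d_min = 2.5)
  m <- synthesize_map(rs, grid = c(16, 16, 16))
  x <- (0:15) / 16
  expect_equal(m$values[, 1, 1], (2 * A / cell$volume) * cos(2 * pi * x),
               tolerance = 1e-12)
  # all y,z columns identical for an (h,0,0) coefficient
  expect_equal(m$values[, 5, 9], m$values[, 1, 1])
})

test_that("synthesized maps peak at atom sites", {
  sys <- toy_system(seed = 31, n_atoms = 4)
  m <- synthesize_map(sys$F_dark)
  dims <- dim(m$values)
  # each atom's nearest voxel should be a strong positive region
  for (j in seq_len(n_atoms(sys$dark))) {
    fr <- as.numeric(sys$dark$atoms[j, c("fx", "fy", "fz")])
    vox <- pmin(round(fr * dims) + 1, dims)
    expect_gt(m$values[vox[1], vox[2], vox[3]], 2 * m$sigma)
  }
})

test_that("difference maps are null, linear and antisymmetric", {
  sys <- toy_system(seed = 32, n_atoms = 6)
  Fd <- sys$F_dark; Fl <- sys$F_light
  null_map <- difference_map(as_obs(Fd), as_obs(Fd), phases_ref = Fd)
  expect_equal(max(abs(null_map$values)), 0)
  dm <- difference_map(as_obs(Fl), as_obs(Fd), phases_ref = Fd)
  # doubling the amplitude difference doubles every voxel
  Fl2 <- as_obs(Fl); Fl2$F <- Fd$F + 2 * (Fl$F - Fd$F)
  dm2 <- difference_map(Fl2, as_obs(Fd), phases_ref = Fd)
  expect_equal(dm2$values, 2 * dm$values, tolerance = 1e-9)
  # swapping activated and reference negates the map
  dms <- difference_map(as_obs(Fd), as_obs(Fl), phases_ref = Fd)
  expect_equal(dms$values, -dm$values, tolerance = 1e-12)
  expect_error(difference_map(as_obs(Fd)[1:3, ], as_obs(Fd)[4:6, ],
                              phases_ref = Fd), "common")
})

test_that("difference density has the right signs at moved atom sites", {
  # one atom moves by 1 A inside an anchoring scaffold; the difference
  # Fourier approximation needs the change to be a small part of the model
  cell <- unit_cell(12, 12, 12)
  set.seed(33)
  scaffold <- atom_table(sprintf("C%d", 1:6), "C",
                         matrix(runif(18, 0.05, 0.95), 6, 3), b_iso = 8)
  mover <- atom_table("OX", "O", c(0.25, 0.25, 0.25), b_iso = 4)
  dark <- atomic_model(cell, rbind(scaffold, mover))
  light_at <- dark$atoms
  light_at$fx[7] <- light_at$fx[7] + 1 / 12
  light <- atomic_model(cell, light_at)
  Fd <- structure_factors(dark, 1.5)
  Fl <- structure_factors(light, 1.5)
  dm <- difference_map(as_obs(Fl), as_obs(Fd), phases_ref = Fd)
  dims <- dim(dm$values)
  at_site <- function(fr) {
    vox <- (round(fr * dims) %% dims) + 1
    dm$values[vox[1], vox[2], vox[3]]
  }
  expect_lt(at_site(c(0.25, 0.25, 0.25)), -2 * dm$sigma)  # density lost
  expect_gt(at_site(c(0.25 + 1 / 12, 0.25, 0.25)), 2 * dm$sigma)  # gained
})

test_that("Parseval's identity holds on band-limited synthetic data", {
  sys <- toy_system(seed = 34, n_atoms = 5)
  Fd <- sys$F_dark; Fl <- sys$F_light
  dm <- difference_map(as_obs(Fl), as_obs(Fd), phases_ref = Fd)
  lhs <- mean(dm$values^2)
  rhs <- sum((Fl$F - Fd$F)^2) * 2 / attr(Fd, "cell")$volume^2
  expect_equal(lhs, rhs, tolerance = 0.01)
})

test_that("sigma scaling normalizes the rms and is idempotent", {
  cell <- unit_cell(10, 10, 10)
  m <- density_map(array(rnorm(8^3, 0, 3), dim = c(8, 8, 8)), cell)
  s <- sigma_scale(m)
  expect_equal(sqrt(mean(s$values^2)), 1, tolerance = 1e-9)
  expect_equal(sigma_scale(s)$values, s$values, tolerance = 1e-12)
  zero <- density_map(array(0, dim = c(4, 4, 4)), cell)
  expect_error(sigma_scale(zero), "all-zero")
})

test_that("map Pearson correlation behaves on identity, negation and shuffling", {
  cell <- unit_cell(10, 10, 10)
  set.seed(61)
  m <- density_map(array(rnorm(12^3), dim = c(12, 12, 12)), cell)
  expect_equal(map_pearson(m, m), 1)
  neg <- density_map(-m$values, cell)
  expect_equal(map_pearson(m, neg), -1)
  shuf <- density_map(array(sample(m$values), dim = dim(m$values)), cell)
  expect_lt(abs(map_pearson(m, shuf)), 3 / sqrt(length(m$values)))
  small <- density_map(array(0, dim = c(4, 4, 4)), cell)
  expect_error(map_pearson(m, small), "different grids")
})

test_that("omit maps reveal omitted atoms and stay silent at empty sites", {
  sys <- toy_two_state(seed = 35, n_atoms = 6, water = TRUE)
  truth <- sys$light          # includes the water
  F_obs <- as_obs(structure_factors(truth, 2.0), role = "reference")
  m_omit <- omit_map(F_obs, truth, omit = "WAT99")
  dims <- dim(m_omit$values)
  vox <- (round(sys$water_site * dims) %% dims) + 1
  expect_gt(m_omit$values[vox[1], vox[2], vox[3]], 3 * m_omit$sigma)
  # omitting an atom absent from the truth yields no peak above 3 sigma;
  # place the ghost at the grid point farthest from every real atom
  cand <- as.matrix(expand.grid(seq(0.05, 0.95, by = 0.1),
                                seq(0.05, 0.95, by = 0.1),
                                seq(0.05, 0.95, by = 0.1)))
  at_frac <- as.matrix(truth$atoms[, c("fx", "fy", "fz")])
  min_d <- apply(cand, 1, function(p) {
    d <- sweep(at_frac, 2, p)
    d <- d - round(d)
    min(sqrt(rowSums((d %*% t(truth$cell$orth))^2)))
  })
  ghost_site <- cand[which.max(min_d), ]
  ghost <- truth
  ghost$atoms <- rbind(ghost$atoms,
                       atom_table("GHOST", "O", ghost_site, b_iso = 12))
  ghost <- atomic_model(truth$cell, ghost$atoms)
  m_ghost <- omit_map(F_obs, ghost, omit = "GHOST")
  gvox <- (round(ghost_site * dims) %% dims) + 1
  # judged on the scale of a genuine omit map (the ghost map is near-null)
  expect_lt(abs(m_ghost$values[gvox[1], gvox[2], gvox[3]]), 3 * m_omit$sigma)
  expect_error(omit_map(F_obs, truth, omit = character(0)), "empty")
  expect_error(omit_map(F_obs, truth, omit = "NOPE"), "matches no atom")
})

test_that("the Polder exclusion radius is a no-op without a solvent model", {
  sys <- toy_two_state(seed = 36, n_atoms = 5, water = TRUE)
  F_obs <- as_obs(structure_factors(sys$light, 2.0), role = "reference")
  a <- omit_map(F_obs, sys$light, omit = "WAT99")
  b <- omit_map(F_obs, sys$light, omit = "WAT99",
                polder_exclusion_radius = 1.5)
  expect_identical(a$values, b$values)
  # with a flat solvent the exclusion changes the map
  solv <- list(k_sol = 0.35, r_probe = 1.2)
  c1 <- omit_map(F_obs, sys$light, omit = "WAT99", solvent = solv)
  c2 <- omit_map(F_obs, sys$light, omit = "WAT99", solvent = solv,
                 polder_exclusion_radius = 2.0)
  expect_false(identical(c1$values, c2$values))
})
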