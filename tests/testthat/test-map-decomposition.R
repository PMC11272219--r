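random_map <- function(cell, dims = c(8, 8, 8), sd = 1) {
  density_map(array(rnorm(prod(dims), 0, sd), dim = dims), cell)
}

test_that("map stacks validate grids and keep column order", {
  cell <- unit_cell(10, 10, 10)
  set.seed(71)
  m1 <- random_map(cell); m2 <- random_map(cell)
  stk <- stack_maps(list(m1, m2))
  expect_equal(ncol(stk$A), 2)
  expect_equal(stk$A[, 1], as.vector(m1$values))
  expect_equal(unstack_map(stk, 2)$values, m2$values)
  expect_error(stack_maps(list(m1)), "at least two")
  expect_error(stack_maps(list(m1, random_map(cell, dims = c(6, 6, 6)))),
               "different grids")
})

test_that("SVD of a rank-1 stack matches the closed form", {
  cell <- unit_cell(10, 10, 10)
  set.seed(72)
  m <- random_map(cell)
  reps <- 7
  stk <- stack_maps(rep(list(m), reps))
  sv <- svd_decompose(stk)
  expect_equal(sv$d[1], sqrt(reps) * sqrt(sum(m$values^2)), tolerance = 1e-8)
  expect_lt(max(sv$d[-1]), 1e-8 * sv$d[1])
  pc1 <- principal_map(sv, stk)
  expect_equal(map_pearson(pc1, m), 1, tolerance = 1e-10)
  # the scaled component reproduces the generating map itself
  expect_equal(pc1$values, m$values, tolerance = 1e-8)
})

test_that("SVD of orthogonal columns returns their norms as singular values", {
  cell <- unit_cell(10, 10, 10)
  dims <- c(4, 4, 4)
  v1 <- array(0, dims); v1[1, 1, 1] <- 3
  v2 <- array(0, dims); v2[2, 1, 1] <- 2
  v3 <- array(0, dims); v3[3, 1, 1] <- 1
  stk <- stack_maps(list(density_map(v1, cell), density_map(v2, cell),
                         density_map(v3, cell)))
  sv <- svd_decompose(stk)
  expect_equal(sv$d, c(3, 2, 1), tolerance = 1e-12)
})

test_that("SVD reconstructs the stack and matches a Gram-matrix oracle", {
  cell <- unit_cell(10, 10, 10)
  set.seed(73)
  stk <- stack_maps(lapply(1:20, function(i) random_map(cell, c(10, 10, 10))))
  sv <- svd_decompose(stk)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(norm(stk$A - recon, "F") / norm(stk$A, "F"), 1e-6)
  expect_true(all(diff(sv$d) <= 1e-12))
  # orthonormal factors
  expect_equal(crossprod(sv$u), diag(ncol(sv$u)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(sv$v), diag(ncol(sv$v)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # independent route: eigenvalues of A'A are the squared singular values
  ev <- eigen(crossprod(stk$A), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sv$d^2, ev, tolerance = 1e-6)
  zero <- density_map(array(0, dim = c(4, 4, 4)), cell)
  expect_error(svd_decompose(stack_maps(list(zero, zero))), "all-zero")
})

test_that("the principal map sign convention is stable under global flips", {
  cell <- unit_cell(10, 10, 10)
  set.seed(74)
  base <- random_map(cell)
  maps <- lapply(1:6, function(i)
    density_map(base$values + array(rnorm(length(base$values), 0, 0.2),
                                    dim = dim(base$values)), cell))
  stk <- stack_maps(maps)
  pc1 <- principal_map(svd_decompose(stk), stk)
  flipped <- stack_maps(lapply(maps, function(m) density_map(-m$values, cell)))
  pc1f <- principal_map(svd_decompose(flipped), flipped)
  # flipping every input flips the component (it follows the stack mean)
  expect_equal(pc1f$values, -pc1$values, tolerance = 1e-9)
  expect_gt(map_pearson(pc1, base), 0.9)
})

test_that("sphere integration matches analytic volumes and pedestal masking", {
  cell <- unit_cell(12, 12, 12)
  dims <- c(48, 48, 48)   # 0.25 A spacing
  rho0 <- 1.7
  uni <- density_map(array(rho0, dim = dims), cell)
  r <- 1.0
  # a generic (off-lattice) center, as for a real atom site
  got <- integrate_sphere(uni, c(0.48, 0.52, 0.505), radius = r, pedestal = 0)
  expect_equal(got, rho0 * 4 / 3 * pi * r^3, tolerance = 0.05)
  # zero map integrates to zero anywhere
  zero <- density_map(array(0, dim = c(8, 8, 8)), cell)
  expect_equal(integrate_sphere(zero, c(0.2, 0.7, 0.1), radius = 2), 0)
  # everything below the pedestal -> exactly zero
  set.seed(75)
  noisy <- density_map(array(rnorm(8^3, 0, 1), dim = c(8, 8, 8)), cell)
  expect_equal(integrate_sphere(noisy, c(0.5, 0.5, 0.5), radius = 3,
                                pedestal = 50), 0)
  # odd under map negation (no pedestal)
  v <- integrate_sphere(noisy, c(0.5, 0.5, 0.5), radius = 3)
  negm <- density_map(-noisy$values, cell)
  expect_equal(integrate_sphere(negm, c(0.5, 0.5, 0.5), radius = 3), -v)
  expect_error(integrate_sphere(noisy, c(0.52, 0.47, 0.51), radius = 0.01),
               "finer grid")
})

test_that("quantified series report replicate means, spreads and ground truth", {
  cell <- unit_cell(12, 12, 12)
  set.seed(76)
  base <- random_map(cell, c(12, 12, 12))
  # single replicate: sd is zero
  q1 <- quantify_series(list(d1 = list(base)),
                        centers = list(site = c(0.5, 0.5, 0.5)),
                        radius = 2, pedestal = 0)
  expect_equal(q1$sd, 0)
  expect_equal(q1$n, 1)
  # duplicated replicate maps: sd zero, mean equals the single value
  q2 <- quantify_series(list(d1 = list(base, base, base)),
                        centers = list(site = c(0.5, 0.5, 0.5)),
                        radius = 2, pedestal = 0)
  expect_equal(q2$sd, 0)
  expect_equal(q2$mean, q1$mean)
  # atom-name resolution against a model
  sys <- toy_two_state(seed = 77, n_atoms = 4)
  expect_error(quantify_series(list(d1 = list(base)), centers = "MISSING",
                               model = sys$dark), "not found")
})

test_that("a transiently ordered water shows up only at the delays that host it", {
  sys <- toy_two_state(seed = 78, n_atoms = 6, water = TRUE)
  f <- 0.4
  F_dark <- structure_factors(sys$dark, 2.0)
  light_nw <- atomic_model(sys$light$cell,
                           sys$light$atoms[!grepl("^WAT", sys$light$atoms$name), ])
  F_off <- mix_states(F_dark, structure_factors(light_nw, 2.0), f)
  F_on <- mix_states(F_dark, structure_factors(sys$light, 2.0), f)
  grid <- map_grid(F_dark, d_min = 2.0)
  noisy_diff <- function(F_state, r) {
    fr_l <- simulate_frames(F_state, 250, seed = derive_seed(500, r))
    fr_d <- simulate_frames(F_dark, 250, seed = derive_seed(600, r))
    dl <- intensities_to_amplitudes(merge_frames(fr_l), cell = sys$dark$cell, d_min = 2)
    dd <- intensities_to_amplitudes(merge_frames(fr_d), cell = sys$dark$cell, d_min = 2)
    difference_map(dl, dd, phases_ref = F_dark, grid = grid)
  }
  maps_by_delay <- list(
    early = lapply(1:4, function(r) noisy_diff(F_off, r)),
    middle = lapply(1:4, function(r) noisy_diff(F_on, 10 + r)),
    late = lapply(1:4, function(r) noisy_diff(F_off, 20 + r)))
  q <- quantify_series(maps_by_delay, centers = list(WAT99 = sys$water_site),
                       radius = 0.8, pedestal = 2)
  qm <- q$mean[match(c("early", "middle", "late"), q$delay)]
  expect_gt(qm[2], qm[1])
  expect_gt(qm[2], qm[3])
  mid <- q[q$delay == "middle", ]
  expect_gt(abs(mid$mean), 2 * mid$sd)
})
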