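make_toy_frameset <- function(n_frames = 3, seed = 1) {
  sys <- toy_system(seed = seed, n_atoms = 4)
  simulate_frames(sys$F_dark, n_frames, seed = seed)
}

test_that("stream write/read round-trips observations exactly", {
  fs <- make_toy_frameset(5)
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream(fs, path)
  back <- read_stream(path)
  expect_equal(back$n_frames, fs$n_frames)
  a <- fs$obs[order(fs$obs$frame, fs$obs$h, fs$obs$k, fs$obs$l), ]
  b <- back$obs[order(back$obs$frame, back$obs$h, back$obs$k, back$obs$l), ]
  expect_equal(b$h, a$h)
  expect_equal(b$I, a$I, tolerance = 1e-5)  # %.6g serialization
  expect_equal(attr(back, "counts")$chunks, 5L)
})

test_that("a file with three well-formed chunks yields three frames", {
  fs <- make_toy_frameset(3)
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream(fs, path)
  expect_equal(read_stream(path)$n_frames, 3L)
})

test_that("an empty frame set writes a valid zero-chunk file", {
  empty <- frame_set(data.frame(frame = integer(), h = integer(),
                                k = integer(), l = integer(), I = numeric(),
                                sigma = numeric()), n_frames = 0)
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream(empty, path)
  expect_equal(read_stream(path)$n_frames, 0L)
})

test_that("a realistic stream chunk with extra columns parses, extras dropped", {
  lines <- c(
    "----- Begin chunk -----",
    "Image filename: run0123.h5",
    "Event: //17",
    "Image serial number: 42",
    "hit = 1",
    "indexed_by = mosflm-nolatt-cell",
    "--- Begin crystal",
    "Cell parameters 6.22130 6.22130 11.017 nm, 90.0 90.0 120.0 deg",
    "Reflections measured after indexing",
    "   h    k    l          I   sigma(I)       peak background  fs/px  ss/px panel",
    "  -1    2    5      12.30       4.50      13.00       1.20  100.5  200.2 q0a0",
    "   3    0   -2     256.10      15.90     260.00       3.10  512.0  128.9 q1a2",
    "End of reflections",
    "--- End crystal",
    "----- End chunk -----")
  path <- withr::local_tempfile(fileext = ".stream")
  writeLines(lines, path)
  fs <- read_stream(path)
  expect_equal(fs$n_frames, 1L)
  expect_equal(fs$obs$h, c(-1, 3))
  expect_equal(fs$obs$I, c(12.30, 256.10))
  expect_equal(fs$obs$sigma, c(4.50, 15.90))
  # frames renumber densely from 0; the original serial is preserved
  expect_equal(fs$obs$frame, c(0L, 0L))
  expect_equal(fs$params$serials, 42L)
  expect_gt(attr(fs, "counts")$ignored_lines, 0)
})

test_that("malformed streams fail with a line number", {
  path <- withr::local_tempfile(fileext = ".stream")
  writeLines(c("----- Begin chunk -----",
               "Reflections measured after indexing",
               "1 0 0 10 1"), path)
  expect_error(read_stream(path), "unterminated")
  writeLines(c("----- Begin chunk -----",
               "Reflections measured after indexing",
               "1 0 0 ten 1",
               "End of reflections",
               "----- End chunk -----"), path)
  expect_error(read_stream(path), "line 3")
})

test_that("reflection tables round-trip and flag absent sigmas", {
  sys <- toy_system(seed = 8, n_atoms = 4)
  rs <- sys$F_dark
  rs$sigF <- runif(nrow(rs), 0.1, 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_reflections(rs, path)
  back <- read_reflections(path, cell = sys$dark$cell, d_min = 2)
  expect_equal(back$F, rs$F, tolerance = 1e-9)
  expect_equal(back$phase, rs$phase, tolerance = 1e-8)
  expect_equal(back$sigF, rs$sigF, tolerance = 1e-9)
  expect_false(attr(back, "sigmas_absent"))
  # sigF column absent -> flagged, sigmas NA
  writeLines(c("h k l F phase", "1 0 0 10 45"), path)
  nos <- read_reflections(path)
  expect_true(attr(nos, "sigmas_absent"))
  expect_true(is.na(nos$sigF))
  # duplicate Miller indices refused
  writeLines(c("h k l F phase sigF", "1 0 0 10 45 1", "1 0 0 11 45 1"), path)
  expect_error(read_reflections(path), "duplicate")
})

test_that("large random reflection tables survive a round-trip", {
  set.seed(99)
  cell <- unit_cell(20, 20, 20)
  hkl <- unique(matrix(sample(-8:8, 3 * 500, replace = TRUE), ncol = 3))
  hkl <- hkl[!(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0), ]
  rs <- reflection_set(hkl, amplitude = runif(nrow(hkl), 0, 1e4),
                       phase = runif(nrow(hkl), -pi, pi),
                       sigma = runif(nrow(hkl)), cell = cell, d_min = 2)
  path <- withr::local_tempfile()
  write_reflections(rs, path)
  back <- read_reflections(path, cell = cell)
  expect_equal(back$F, rs$F, tolerance = 1e-9)
  expect_equal(back$phase, rs$phase, tolerance = 1e-8)
})

test_that("density maps round-trip through the text container", {
  cell <- unit_cell(11, 12, 13, 85, 92, 103)
  vals <- array(rnorm(6 * 8 * 10), dim = c(6, 8, 10))
  m <- density_map(vals, cell, label = "test")
  path <- withr::local_tempfile(fileext = ".map")
  write_map(m, path)
  back <- read_map(path)
  expect_equal(back$values, m$values, tolerance = 1e-6)
  expect_equal(back$cell$a, cell$a)
  expect_equal(back$cell$gamma, cell$gamma)
  expect_equal(back$sigma, m$sigma, tolerance = 1e-6)
})

test_that("PDB files round-trip conformers, occupancies and B-factors", {
  sys <- toy_system(seed = 13, n_atoms = 5)
  two <- two_state_model(sys$dark, sys$light, 0.3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(two, path)
  back <- read_pdb(path)
  expect_equal(back$atoms$name, two$atoms$name)
  expect_equal(back$atoms$conformer, two$atoms$conformer)
  expect_equal(back$atoms$occ, two$atoms$occ, tolerance = 0.005)
  expect_equal(back$atoms$b_iso, two$atoms$b_iso, tolerance = 0.005)
  expect_equal(as.matrix(back$atoms[, c("fx", "fy", "fz")]),
               as.matrix(two$atoms[, c("fx", "fy", "fz")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$cell$a, two$cell$a, tolerance = 1e-3)
})

test_that("written PDB fixed columns parse identically with bio3d", {
  skip_if_not_installed("bio3d")
  sys <- toy_system(seed = 13, n_atoms = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$dark, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  cart <- frac_to_cart(ours$cell, as.matrix(ours$atoms[, c("fx", "fy", "fz")]))
  expect_equal(unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               unname(cart), tolerance = 1e-3)
  expect_equal(ref$atom$b, ours$atoms$b_iso, tolerance = 0.005)
  expect_equal(ref$atom$o, ours$atoms$occ, tolerance = 0.005)
  expect_equal(trimws(ref$atom$elety), ours$atoms$name)
})
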