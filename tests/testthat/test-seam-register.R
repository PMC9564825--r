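test_that("ZYZ Euler conversion round-trips and composes as a group", {
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
  set.seed(13)
  for (i in seq_len(200)) {
    e <- c(runif(1, -180, 180), runif(1, 0, 180), runif(1, -180, 180))
    R <- euler_to_matrix(e[1], e[2], e[3])
    expect_equal(det(R), 1, tolerance = 1e-12)
    e2 <- matrix_to_euler(R)
    expect_lt(max(abs(euler_to_matrix(e2[1], e2[2], e2[3]) - R)), 1e-9)
  }
  # gimbal case: all in-plane rotation lands in psi
  eg <- matrix_to_euler(euler_to_matrix(25, 0, 40))
  expect_equal(unname(eg["rot"]), 0)
  expect_equal(unname(eg["psi"]), 65, tolerance = 1e-9)
  # products of orientation matrices stay inside the parameterization
  A <- euler_to_matrix(33, 71, -120); B <- euler_to_matrix(-15, 140, 8)
  eAB <- matrix_to_euler(A %*% B)
  expect_lt(max(abs(euler_to_matrix(eAB[1], eAB[2], eAB[3]) - A %*% B)), 1e-9)
})

star_fixture <- function(path, psi = TRUE) {
  cols <- c("_rlnImageName #1", "_rlnAngleRot #2", "_rlnAngleTilt #3",
            if (psi) "_rlnAnglePsi #4",
            "_rlnOriginXAngst #5", "_rlnOriginYAngst #6",
            "_rlnClassNumber #7", "_rlnMicrographName #8")
  rows <- c(paste("img_001.mrc 10.500000 85.000000",
                  if (psi) "-40.250000", "1.200000 -3.400000 1 mic_a.mrc"),
            paste("img_002.mrc -170.000000 12.000000",
                  if (psi) "3.000000", "0.000000 5.000000 2 mic_b.mrc"))
  writeLines(c("", "data_particles", "", "loop_", cols, rows, ""), path)
  path
}

test_that("STAR orientation tables read exactly and round-trip losslessly", {
  f <- withr::local_tempfile(fileext = ".star")
  star_fixture(f)
  tab <- read_orientation_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$particle_id, c("img_001.mrc", "img_002.mrc"))
  expect_equal(tab$rot, c(10.5, -170))
  expect_equal(tab$tilt, c(85, 12))
  expect_equal(tab$psi, c(-40.25, 3))
  expect_equal(tab$origin_x, c(1.2, 0))
  expect_equal(tab$class_id, c(1L, 2L))
  expect_equal(tab$origin_z, c(0, 0))      # absent column defaults to zero
  # write(read(f)) then read again: handled columns identical, unhandled
  # (micrograph name) preserved verbatim
  f2 <- withr::local_tempfile(fileext = ".star")
  write_orientation_table(tab, f2)
  tab2 <- read_orientation_table(f2)
  expect_equal(tab2[names(tab2)], tab[names(tab)])
  expect_equal(attr(tab2, "star_extra")[, "_rlnMicrographName"],
               attr(tab, "star_extra")[, "_rlnMicrographName"])
  f3 <- withr::local_tempfile(fileext = ".star")
  write_orientation_table(tab2, f3)
  expect_identical(readLines(f3), readLines(f2))
  # a table without the psi column is rejected by name
  f4 <- withr::local_tempfile(fileext = ".star")
  star_fixture(f4, psi = FALSE)
  expect_error(read_orientation_table(f4), "_rlnAnglePsi")
})

uniform_table <- function(n_per_class = 10, classes = 1:4) {
  n <- n_per_class * length(classes)
  structure(data.frame(
    particle_id = sprintf("p%04d", seq_len(n)),
    rot = 12, tilt = 84, psi = -31,
    origin_x = 1.5, origin_y = -2, origin_z = 0.5,
    class_id = rep(classes, each = n_per_class),
    stringsAsFactors = FALSE), class = c("orientation_table", "data.frame"))
}

test_that("identity corrections leave the table unchanged", {
  tab <- uniform_table()
  out <- apply_register_correction(tab, register_corrections(1:4))
  for (col in c("rot", "tilt", "psi", "origin_x", "origin_y", "origin_z"))
    expect_equal(out[[col]], tab[[col]], tolerance = 1e-9)
})

test_that("a correction followed by its inverse is the identity", {
  tab <- uniform_table(n_per_class = 5, classes = 1)
  fwd <- data.frame(class_id = 1, delta_phi = 27.692, delta_shift = 40)
  bwd <- data.frame(class_id = 1, delta_phi = -27.692, delta_shift = -40)
  out <- apply_register_correction(apply_register_correction(tab, fwd), bwd)
  for (col in c("rot", "tilt", "psi", "origin_x", "origin_y", "origin_z"))
    expect_equal(out[[col]], tab[[col]], tolerance = 1e-6)
})

test_that("corrections compose additively (mod the lattice repeat)", {
  tab <- uniform_table(n_per_class = 3, classes = 1:2)
  c1 <- register_corrections(1:2, k = c(1, -2), m = c(0, 1))
  c2 <- register_corrections(1:2, k = c(2, 5), m = c(1, -2))
  c12 <- register_corrections(1:2, k = c(3, 3), m = c(1, -1))
  a <- apply_register_correction(apply_register_correction(tab, c1), c2)
  b <- apply_register_correction(tab, c12)
  for (i in seq_len(nrow(tab))) {
    Ra <- euler_to_matrix(a$rot[i], a$tilt[i], a$psi[i])
    Rb <- euler_to_matrix(b$rot[i], b$tilt[i], b$psi[i])
    expect_lt(max(abs(Ra - Rb)), 1e-9)
  }
  expect_equal(a$origin_x, b$origin_x, tolerance = 1e-9)
  expect_equal(a$origin_z, b$origin_z, tolerance = 1e-9)
})

test_that("known per-class register offsets are fully removed", {
  # scramble a uniform table with per-class pseudo-helical offsets
  # (k * 360/13 rotations, m * 40 A monomer shifts), then realign
  tab <- uniform_table(n_per_class = 25, classes = 1:4)
  k <- c(0, 3, -5, 9); m <- c(0, 1, -1, 2)
  scrambled <- apply_register_correction(tab, register_corrections(1:4, k, m))
  R0 <- euler_to_matrix(12, 84, -31)
  worst <- max(vapply(seq_len(nrow(scrambled)), function(i) {
    R <- euler_to_matrix(scrambled$rot[i], scrambled$tilt[i], scrambled$psi[i])
    mtlattice:::rotation_angle_deg(R %*% t(R0))
  }, 1))
  expect_gt(worst, 1)                                # genuinely scrambled
  fixed <- apply_register_correction(scrambled,
                                     register_corrections(1:4, -k, -m))
  R_ref <- euler_to_matrix(12, 84, -31)
  res <- vapply(seq_len(nrow(fixed)), function(i) {
    R <- euler_to_matrix(fixed$rot[i], fixed$tilt[i], fixed$psi[i])
    mtlattice:::rotation_angle_deg(R %*% t(R_ref))
  }, 1)
  expect_lt(max(res), 1e-4)
  expect_lt(max(abs(fixed$origin_x - tab$origin_x)), 1e-6)
  expect_lt(max(abs(fixed$origin_z - tab$origin_z)), 1e-6)
})

test_that("a class without a correction is reported by id", {
  tab <- uniform_table(classes = 1:3)
  expect_error(apply_register_correction(tab, register_corrections(1:2)),
               "class\\(es\\) 3")
})
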