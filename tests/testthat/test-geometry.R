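atoms_row <- function(i, el, x, y, z, chain = "A") {
  data.frame(serial = i, name = el, element = el, res_name = "LIG",
             res_seq = i, chain_id = chain, x = x, y = y, z = z,
             occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
}

test_that("mass centers follow standard atomic masses", {
  two_c <- rbind(atoms_row(1, "C", -1, 0, 0), atoms_row(2, "C", 1, 0, 0))
  expect_equal(mass_center(two_c), c(0, 0, 0))
  co <- rbind(atoms_row(1, "C", 0, 0, 0), atoms_row(2, "O", 1, 0, 0))
  expect_equal(mass_center(co)[1], 15.999 / (12.011 + 15.999), tolerance = 1e-9)
  expect_equal(mass_center(co, "geometric")[1], 0.5)
  # all-carbon clouds: mass and geometric weighting coincide
  tub <- FIX$lat$model$atoms[FIX$lat$model$atoms$chain_id == "S01.0a", ]
  expect_equal(mass_center(tub), mass_center(tub, "geometric"))
  expect_error(mass_center(tub[0, ]), "empty")
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(21)
  cl <- matrix(rnorm(900), ncol = 3)
  fit0 <- kabsch_superpose(cl, cl)
  expect_lt(fit0$rmsd, 1e-12)
  expect_lt(fit0$rotation_angle, 1e-9)
  # a known rotation is recovered to microdegrees
  R <- mtlattice:::rot_z(27.692)
  fit <- kabsch_superpose(cl, sweep(cl %*% t(R), 2, c(3, -7, 11), "+"))
  expect_lt(abs(fit$rotation_angle - 27.692), 1e-6)
  expect_lt(max(abs(fit$R - R)), 1e-9)
  # Monte-Carlo noise oracle: both copies carry independent noise with rms
  # atomic displacement sigma, so the expected RMSD is sigma * sqrt(2)
  n <- 1e4; sigma <- 0.8
  big <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
  noise <- function() matrix(rnorm(3 * n, sd = sigma / sqrt(3)), ncol = 3)
  fitn <- kabsch_superpose(big + noise(), big + noise())
  expect_lt(abs(fitn$rmsd - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.1)
  # degenerate input
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(cl[1:2, ], cl[1:2, ]), "3 paired")
})

test_that("dimer spacings count n-1 per protofilament and track the rise", {
  lat <- build_singlet(lattice_params(n_repeats = 6), TPL)
  ann <- annotate_lattice(lat$model, min_tubulin_res = 50)
  d <- dimer_spacings(ann, lat$model, 3)
  expect_length(d, 5)                      # 6 dimers -> 5 measurements
  expect_equal(d, rep(80, 5), tolerance = 1e-9)
  # jittered lattice: mean spacing stays within 0.2 A of the rise
  set.seed(5)
  latj <- build_singlet(lattice_params(n_repeats = 6), TPL, jitter_sd = 0.3)
  annj <- annotate_lattice(latj$model, min_tubulin_res = 50)
  dj <- unlist(lapply(0:12, function(p) dimer_spacings(annj, latj$model, p)))
  expect_lt(abs(mean(dj) - 80), 0.2)
  one <- build_singlet(lattice_params(n_repeats = 1), TPL)
  ann1 <- suppressWarnings(annotate_lattice(one$model, min_tubulin_res = 50))
  expect_error(dimer_spacings(ann1, one$model, 0), "fewer than 2")
})

test_that("interprotofilament angles equal 360/n_pf on regular tubes", {
  ann <- FIX$ann; m <- FIX$lat$model
  for (i in c(0, 6, 12))                   # including the seam interface
    expect_lt(abs(interprotofilament_angle(ann, m, i) - 360 / 13), 0.05)
  # a dimer against itself rotates by nothing
  da <- mtlattice:::.dimer_atoms(ann, m, "S", 2, 1)
  expect_lt(kabsch_superpose(da, da)$rotation_angle, 1e-9)
  lat12 <- build_singlet(lattice_params(n_pf = 12, n_repeats = 3), TPL)
  ann12 <- annotate_lattice(lat12$model, min_tubulin_res = 50)
  expect_lt(abs(interprotofilament_angle(ann12, lat12$model, 4) - 30), 0.05)
})

test_that("tilt angles fold correctly between plane and normal", {
  dimer_a <- FIX$lat$model$atoms[FIX$lat$model$atoms$chain_id %in%
                                   c("S03.1a", "S03.1b"), ]
  dimer_b <- FIX$lat$model$atoms[FIX$lat$model$atoms$chain_id %in%
                                   c("S04.1a", "S04.1b"), ]
  both <- rbind(atom_xyz(dimer_a), atom_xyz(dimer_b))
  pc <- mtlattice:::principal_axes(both)
  nrm <- pc$vectors[, 3]; in_plane <- pc$vectors[, 1]
  rod <- function(v) {
    p <- sweep(outer(seq(-20, 20, length.out = 9), v), 2, pc$center, "+")
    p <- rbind(p, sweep(rbind(pc$vectors[, 2], -pc$vectors[, 2]), 2, pc$center, "+"))
    data.frame(serial = seq_len(nrow(p)), name = "CA", element = "C",
               res_name = "MIP", res_seq = seq_len(nrow(p)), chain_id = "m",
               x = p[, 1], y = p[, 2], z = p[, 3], occupancy = 1, b_factor = 0)
  }
  expect_lt(tilt_angle(rod(in_plane), dimer_a, dimer_b), 0.01)
  expect_gt(tilt_angle(rod(nrm), dimer_a, dimer_b), 89.9)
  # generated decorations recover their tilt parameter
  tt <- mtlattice:::.mip_tilt_table(FIX$ann, FIX$lat$model, "SPACA9")
  expect_lt(max(abs(tt$tilt - 51.5)), 0.5)
  expect_error(tilt_angle(rod(nrm)[1:2, ], dimer_a, dimer_b), "3 atoms")
})

test_that("Shrake-Rupley areas match closed forms", {
  one <- atoms_row(1, "C", 0, 0, 0)
  expect_lt(abs(shrake_rupley_sasa(one) - 4 * pi * 3.1^2) / (4 * pi * 3.1^2),
            0.01)
  # far-separated atoms are additive
  far <- rbind(atoms_row(1, "C", 0, 0, 0), atoms_row(2, "O", 50, 0, 0))
  expect_equal(sum(shrake_rupley_sasa(far)),
               shrake_rupley_sasa(far[1, ]) + shrake_rupley_sasa(far[2, ]),
               tolerance = 1e-9)
  # an atom enclosed by a dense shell is buried
  shell <- mtlattice:::fibonacci_sphere(42) * 2.8
  enc <- rbind(atoms_row(1, "C", 0, 0, 0),
               do.call(rbind, lapply(seq_len(42), function(i)
                 atoms_row(i + 1, "C", shell[i, 1], shell[i, 2], shell[i, 3]))))
  expect_lt(shrake_rupley_sasa(enc)[1], 1)
  expect_warning(shrake_rupley_sasa(atoms_row(1, "XX", 0, 0, 0)), "default")
})

test_that("buried interface area follows the spherical-cap closed form", {
  d <- 3
  pair <- rbind(atoms_row(1, "C", 0, 0, 0, "A"),
                atoms_row(2, "C", d, 0, 0, "B"))
  ai <- interface_area(pair[1, ], pair[2, ])
  R <- 1.70 + 1.4
  cap <- 2 * pi * R * (R - d / 2)          # delta-SASA/2 of two equal spheres
  expect_lt(abs(ai - cap) / cap, 0.02)
  expect_equal(interface_area(pair[2, ], pair[1, ]), ai, tolerance = 1e-9)
  pair$x[2] <- 60
  expect_equal(interface_area(pair[1, ], pair[2, ]), 0)
})

test_that("periodicity, handedness and copy counts describe the decoration", {
  ann <- FIX$ann; m <- FIX$lat$model
  expect_equal(axial_periodicity(ann, m, "SPACA9"), 8.0, tolerance = 1e-9)
  expect_equal(spiral_handedness(ann, m, "SPACA9"), "left")
  expect_equal(copies_per_repeat(ann, m, "SPACA9"), 12L)
  expect_equal(copies_per_repeat(ann, m, "ABSENT"), 0L)
  # decoration every second dimer doubles the periodicity
  lat2 <- decorate_mips(build_singlet(lattice_params(n_repeats = 5), TPL),
                        mip_decoration("SPARSE", periodicity = 160))
  ann2 <- annotate_lattice(lat2$model, min_tubulin_res = 50)
  expect_equal(axial_periodicity(ann2, lat2$model, "SPARSE"), 16.0,
               tolerance = 1e-9)
  # mirrored lattice spirals the other way
  lat_r <- decorate_mips(
    build_singlet(lattice_params(n_repeats = 3, handedness_sign = 1), TPL),
    mip_decoration("SPACA9"))
  ann_r <- annotate_lattice(lat_r$model, min_tubulin_res = 50)
  expect_equal(spiral_handedness(ann_r, lat_r$model, "SPACA9"), "right")
  # flat rings (zero stagger) have no handedness
  suppressWarnings({
    flat <- decorate_mips(
      build_singlet(lattice_params(n_repeats = 3, stagger = 0), TPL),
      mip_decoration("RING"))
    ann_f <- annotate_lattice(flat$model, min_tubulin_res = 50)
  })
  expect_equal(spiral_handedness(ann_f, flat$model, "RING"), "none")
  # a single copy has no defined periodicity
  lone <- decorate_mips(build_singlet(lattice_params(n_repeats = 3), TPL),
                        mip_decoration("LONE", pf_span = 4, periodicity = 240))
  ann_l <- annotate_lattice(lone$model, min_tubulin_res = 50)
  expect_error(axial_periodicity(ann_l, lone$model, "LONE"), "undefined")
})

test_that("pairwise MIP RMSD is zero for exact copies and tracks atom noise", {
  rm0 <- mip_pairwise_rmsd(FIX$ann, FIX$lat$model, "SPACA9")
  expect_equal(dim(rm0), c(36, 36))
  expect_lt(max(rm0[upper.tri(rm0)]), 1e-6)
  expect_lt(max(abs(rm0 - t(rm0))), 1e-3)
  # per-atom noise with rms displacement sigma on every copy: expected
  # pairwise RMSD is sigma * sqrt(2)
  set.seed(8)
  sigma <- 1
  tpl_dense <- build_dimer_template(240, seed = 4)
  lat <- decorate_mips(
    build_doublet(lattice_params(n_repeats = 2), template = tpl_dense),
    mip_decoration("BIG", pf_span = c("B02", "B05"),
                   tubule = "B", n_atoms = 200, length = 45))
  m <- lat$model
  mip_sel <- m$atoms$res_name == "BIG"
  m$atoms$x[mip_sel] <- m$atoms$x[mip_sel] + rnorm(sum(mip_sel), sd = sigma / sqrt(3))
  m$atoms$y[mip_sel] <- m$atoms$y[mip_sel] + rnorm(sum(mip_sel), sd = sigma / sqrt(3))
  m$atoms$z[mip_sel] <- m$atoms$z[mip_sel] + rnorm(sum(mip_sel), sd = sigma / sqrt(3))
  ann <- annotate_lattice(m, min_tubulin_res = 220)
  rmn <- mip_pairwise_rmsd(ann, m, "BIG")
  off <- rmn[upper.tri(rmn)]
  expect_lt(abs(mean(off) - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.15)
})

test_that("every descriptor is invariant to rigid-body transforms", {
  m <- FIX$lat$model; ann <- FIX$ann
  R <- mtlattice:::rot_about_axis(c(3, -1, 2), 73)
  m2 <- transform_model(m, R, c(-40, 15, 90))
  ann2 <- annotate_lattice(m2, min_tubulin_res = 50)
  expect_equal(dimer_spacings(ann2, m2, 7), dimer_spacings(ann, m, 7),
               tolerance = 1e-3)
  expect_equal(interprotofilament_angle(ann2, m2, 4),
               interprotofilament_angle(ann, m, 4), tolerance = 1e-3)
  expect_equal(axial_periodicity(ann2, m2, "SPACA9"),
               axial_periodicity(ann, m, "SPACA9"), tolerance = 1e-4)
  expect_equal(spiral_handedness(ann2, m2, "SPACA9"),
               spiral_handedness(ann, m, "SPACA9"))
  expect_equal(copies_per_repeat(ann2, m2, "SPACA9"),
               copies_per_repeat(ann, m, "SPACA9"))
  t1 <- mtlattice:::.mip_tilt_table(ann, m, "SPACA9")
  t2 <- mtlattice:::.mip_tilt_table(ann2, m2, "SPACA9")
  expect_equal(t2$tilt, t1$tilt, tolerance = 1e-3)
})
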