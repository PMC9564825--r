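test_that("dimer template is centered, axis-aligned and deterministic", {
  tpl <- build_dimer_template(50, seed = 9)
  expect_lt(max(abs(mass_center(tpl$atoms))), 1e-6)
  # longest principal axis along z (up to sign)
  pc <- eigen(cov(atom_xyz(tpl$atoms)), symmetric = TRUE)
  expect_lt(acos(min(1, abs(pc$vectors[3, 1]))) * 180 / pi, 1e-3)
  tpl2 <- build_dimer_template(50, seed = 9)
  expect_identical(tpl$atoms, tpl2$atoms)
  tpl3 <- build_dimer_template(50, seed = 10)
  expect_false(identical(tpl$atoms, tpl3$atoms))
  expect_error(build_dimer_template(3), ">= 4")
  # alpha sits below beta along +z
  expect_lt(mean(tpl$atoms$z[tpl$atoms$res_name == "TBA"]),
            mean(tpl$atoms$z[tpl$atoms$res_name == "TBB"]))
})

test_that("a default singlet has 13 pf, exact rise, and exactly one seam", {
  lat <- build_singlet(lattice_params(n_repeats = 6), TPL)
  labs <- lat$truth$chain_labels
  expect_equal(length(unique(labs$pf_index)), 13)
  expect_equal(nrow(labs) / 2, 13 * 6)           # 78 dimers
  het <- brute_force_heterotypic(lat$model, lat$truth)
  expect_equal(sum(het > 0.5), 1)
  expect_equal(which(het > 0.5) - 1L, lat$truth$lattice$seam_index)
  # consecutive dimer mass-center spacing is the rise, by construction
  ann <- annotate_lattice(lat$model, min_tubulin_res = 50)
  expect_equal(dimer_spacings(ann, lat$model, 0), rep(80, 5), tolerance = 1e-9)
  lat82 <- build_singlet(lattice_params(dimer_rise = 82, n_repeats = 3), TPL)
  ann82 <- annotate_lattice(lat82$model, min_tubulin_res = 50)
  expect_equal(dimer_spacings(ann82, lat82$model, 5), rep(82, 2), tolerance = 1e-9)
})

test_that("a 14-pf tube with 3-start closure still has exactly one seam", {
  p <- lattice_params(n_pf = 14, n_repeats = 4)
  expect_equal(p$stagger, 3 * 40 / 14)
  lat <- build_singlet(p, TPL)
  het <- brute_force_heterotypic(lat$model, lat$truth)
  expect_equal(sum(het > 0.5), 1)
})

test_that("doublet carries A01-A13 and B01-B10 with an open B arc", {
  dbl <- build_doublet(lattice_params(n_repeats = 3), template = TPL)
  ids <- chain_ids(dbl$model)
  expect_true(all(sprintf("A%02d.0a", 1:13) %in% ids))
  expect_true(all(sprintf("B%02d.0a", 1:10) %in% ids))
  ann <- annotate_lattice(dbl$model, min_tubulin_res = 50)
  expect_equal(nrow(ann$tubules$B$interfaces), 9)   # open arc: n_pf_B - 1
  expect_false(ann$tubules$B$closed)
  # the A tubule of the doublet measures identically to a standalone singlet
  sgl <- build_singlet(lattice_params(n_repeats = 3), TPL, prefix = "A")
  ann_s <- annotate_lattice(sgl$model, min_tubulin_res = 50)
  expect_equal(interprotofilament_angle(ann, dbl$model, 2, tubule = "A"),
               interprotofilament_angle(ann_s, sgl$model, 2, tubule = "A"),
               tolerance = 1e-9)
  expect_equal(dimer_spacings(ann, dbl$model, 4, tubule = "A"),
               dimer_spacings(ann_s, sgl$model, 4, tubule = "A"),
               tolerance = 1e-9)
})

test_that("lateral decoration honors counts, the seam exclusion, and tilt", {
  # full non-seam decoration of a 13-pf singlet: 12 copies per repeat
  dec <- FIX$lat$truth$decorations$SPACA9
  expect_equal(length(dec$placements), 12 * 3)
  expect_false(any(vapply(dec$placements, `[[`, 1, "interface") ==
                     FIX$lat$truth$lattice$seam_index))
  # an arc over B02-B05 carries three copies per repeat
  dbl <- build_doublet(lattice_params(n_repeats = 3), template = TPL)
  dbl <- decorate_mips(dbl, mip_decoration("SPACA9",
                                           pf_span = c("B02", "B05"),
                                           tubule = "B"))
  pl <- dbl$truth$decorations$SPACA9$placements
  expect_equal(sort(unique(vapply(pl, `[[`, 1, "interface"))), c(1, 2, 3))
  expect_equal(length(pl), 3 * 3)
  # explicit request to decorate the seam is refused
  expect_error(
    decorate_mips(build_singlet(lattice_params(n_repeats = 3), TPL),
                  mip_decoration("X", pf_span = 12)),
    "seam")
  # in-plane decoration measures 0 tilt
  flat <- decorate_mips(build_singlet(lattice_params(n_repeats = 3), TPL),
                        mip_decoration("FLAT", tilt = 0))
  ann <- annotate_lattice(flat$model, min_tubulin_res = 50)
  tt <- mtlattice:::.mip_tilt_table(ann, flat$model, "FLAT")
  expect_lt(max(abs(tt$tilt)), 0.5)
  # periodicity must be an integer multiple of the rise
  expect_error(
    decorate_mips(build_singlet(lattice_params(n_repeats = 3), TPL),
                  mip_decoration("X", periodicity = 100)),
    "integer multiple")
})

test_that("ground truth serializes to JSON and back", {
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(FIX$lat$truth, f)
  tr <- read_ground_truth(f)
  expect_equal(tr$lattice$n_pf, 13L)
  expect_equal(tr$lattice$stagger, FIX$lat$truth$lattice$stagger)
  expect_equal(tr$chain_labels, FIX$lat$truth$chain_labels)
  expect_equal(length(tr$decorations$SPACA9$placements),
               length(FIX$lat$truth$decorations$SPACA9$placements))
  expect_equal(tr$decorations$SPACA9$placements[[5]]$anchor,
               FIX$lat$truth$decorations$SPACA9$placements[[5]]$anchor,
               tolerance = 1e-9)
})
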