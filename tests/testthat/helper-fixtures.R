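# Shared fixtures, built once per test run. The reduced template density
# (60 pseudo-atoms per monomer) keeps the suite fast; tests that exercise the
# tubulin/MIP size classifier pass min_tubulin_res accordingly.

TPL <- build_dimer_template(n_atoms_per_monomer = 60, seed = 2)

FIX <- local({
  lat <- build_singlet(lattice_params(n_repeats = 3), TPL)
  lat <- decorate_mips(lat, mip_decoration("SPACA9"))
  ann <- annotate_lattice(lat$model, min_tubulin_res = 50)
  list(lat = lat, ann = ann)
})

# Random atom table helper for I/O round trips.
random_atoms <- function(n = 100, chains = c("A", "B"), seed = 11) {
  set.seed(seed)
  data.frame(
    serial = seq_len(n),
    name = sample(c("CA", "CB", "N", "O"), n, replace = TRUE),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    res_name = sample(c("GLY", "ALA", "LYS"), n, replace = TRUE),
    res_seq = sort(sample.int(400, n, replace = TRUE)),
    chain_id = sort(sample(chains, n, replace = TRUE)),
    x = round(runif(n, -90, 90), 3), y = round(runif(n, -90, 90), 3),
    z = round(runif(n, -90, 90), 3),
    occupancy = 1, b_factor = round(runif(n, 0, 50), 2),
    stringsAsFactors = FALSE)
}

# Independent brute-force seam census: for every adjacent-pf interface of the
# generated tubule, classify each monomer's nearest lateral neighbor as
# homotypic or heterotypic using only the generator's ground-truth labels and
# raw coordinates. Returns the per-interface heterotypic fractions.
brute_force_heterotypic <- function(model, truth, tubule = NULL) {
  labs <- truth$chain_labels
  labs <- labs[labs$role %in% c("alpha", "beta"), ]
  if (!is.null(tubule)) labs <- labs[labs$tubule == tubule, ]
  tb <- if (is.null(tubule)) labs$tubule[1] else tubule
  labs <- labs[labs$tubule == tb, ]
  a <- model$atoms
  cen <- t(vapply(labs$chain_id, function(id) {
    r <- a[a$chain_id == id, ]
    c(mean(r$x), mean(r$y), mean(r$z))
  }, numeric(3)))
  n_pf <- truth$tubules[[tb]]$n_pf
  closed <- truth$tubules[[tb]]$closed
  n_int <- if (closed) n_pf else n_pf - 1
  het <- numeric(n_int)
  for (i in seq_len(n_int)) {
    pa <- i - 1; pb <- i %% n_pf
    A <- which(labs$pf_index == pa); B <- which(labs$pf_index == pb)
    frac <- vapply(A, function(r) {
      d2 <- rowSums((cen[B, , drop = FALSE] -
                       matrix(cen[r, ], length(B), 3, byrow = TRUE))^2)
      labs$role[r] != labs$role[B[which.min(d2)]]
    }, TRUE)
    het[i] <- mean(frac)
  }
  het
}

expect_angle_equal <- function(a, b, tol) {
  d <- abs(a - b) %% 360
  expect_lt(min(d, 360 - d), tol)
}
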