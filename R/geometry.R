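#' Mass or geometric center of an atom selection
#'
#' @param atoms atom table (rows of a \code{structure_model})
#' @param weighting \code{"mass"} (standard atomic masses by element) or
#'   \code{"geometric"} (equal weights)
#' @return 3-vector, Angstrom
#' @export
mass_center <- function(atoms, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (is.null(atoms) || nrow(atoms) == 0) stop("mass_center: empty selection")
  w <- if (weighting == "mass") element_mass(atoms$element) else rep(1, nrow(atoms))
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z)) / sum(w)
}

# Pair two atom tables by (chain-position, res_seq, name); falls back to row
# order for bare matrices or equal-length tables without usable keys.
# When `calpha_only`, restrict to CA atoms if both sides have them.
.pair_xyz <- function(mobile, ref, calpha_only = TRUE) {
  if (is.matrix(mobile) && is.matrix(ref)) {
    if (nrow(mobile) != nrow(ref)) stop("superposition: unequal point counts")
    return(list(mob = mobile, ref = ref))
  }
  m <- mobile; r <- ref
  if (calpha_only && any(m$name == "CA") && any(r$name == "CA")) {
    m <- m[m$name == "CA", ]; r <- r[r$name == "CA", ]
  }
  mk <- function(a) {
    ch <- match(a$chain_id, unique(a$chain_id))     # chain position, not id
    paste(ch, a$res_seq, a$name)
  }
  km <- mk(m); kr <- mk(r)
  common <- intersect(km, kr)
  if (length(common) < 3) {
    if (nrow(m) == nrow(r)) return(list(mob = atom_xyz(m), ref = atom_xyz(r)))
    stop("superposition: no residue correspondence between selections")
  }
  list(mob = atom_xyz(m[match(common, km), ]),
       ref = atom_xyz(r[match(common, kr), ]))
}

#' Least-squares rigid superposition (Kabsch) with rotation angle
#'
#' Finds the proper rotation R (det +1) and translation t minimizing the RMSD
#' of \code{R x + t} against the reference, and reports the rotation angle
#' \code{acos((tr(R) - 1) / 2)} in degrees — the quantity used for
#' interprotofilament angles.
#'
#' @param mobile,ref atom tables or n x 3 coordinate matrices; atom tables
#'   are paired by chain position, residue number and atom name (CA atoms
#'   when both sides have them)
#' @param calpha_only restrict atom-table pairing to CA atoms (default TRUE)
#' @return list(R, t, rmsd, rotation_angle, n)
#' @export
kabsch_superpose <- function(mobile, ref, calpha_only = TRUE) {
  p <- .pair_xyz(mobile, ref, calpha_only)
  X <- p$mob; Y <- p$ref
  if (nrow(X) < 3) stop("kabsch_superpose: need at least 3 paired atoms")
  xb <- colMeans(X); yb <- colMeans(Y)
  Xc <- sweep(X, 2, xb); Yc <- sweep(Y, 2, yb)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("kabsch_superpose: collinear atoms; rotation undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- yb - as.numeric(R %*% xb)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  list(R = R, t = t, rmsd = rmsd, rotation_angle = rotation_angle_deg(R),
       n = nrow(X))
}

# --- lattice-addressed selections -------------------------------------------

# Atom rows of the dimer (tubule, pf, axial) using the annotation.
.dimer_atoms <- function(annotation, model, tubule, pf, axial) {
  ch <- annotation$chains
  ids <- ch$chain_id[ch$tubule == tubule & !is.na(ch$pf_index) &
                       ch$pf_index == pf & ch$axial_index == axial &
                       ch$role %in% c("alpha", "beta")]
  model$atoms[model$atoms$chain_id %in% ids, , drop = FALSE]
}

.first_tubule <- function(annotation) names(annotation$tubules)[1]

# Mass centers of all dimers of one tubule: data.frame(pf, axial, x, y, z).
.dimer_center_table <- function(annotation, model, tubule) {
  ch <- annotation$chains
  ch <- ch[ch$tubule == tubule & ch$role %in% c("alpha", "beta") &
             !is.na(ch$pf_index), ]
  a <- model$atoms[model$atoms$chain_id %in% ch$chain_id, , drop = FALSE]
  if (!nrow(a)) return(data.frame(pf = integer(), axial = integer(),
                                  x = numeric(), y = numeric(), z = numeric()))
  key_of_chain <- stats::setNames(paste(ch$pf_index, ch$axial_index),
                                  ch$chain_id)
  key <- key_of_chain[a$chain_id]
  w <- element_mass(a$element)
  sums <- rowsum(cbind(w * a$x, w * a$y, w * a$z, w), key)
  k <- do.call(rbind, strsplit(rownames(sums), " "))
  data.frame(pf = as.integer(k[, 1]), axial = as.integer(k[, 2]),
             x = sums[, 1] / sums[, 4], y = sums[, 2] / sums[, 4],
             z = sums[, 3] / sums[, 4])
}

#' Longitudinal dimer spacings along one protofilament
#'
#' Euclidean distances between mass centers of consecutive tubulin dimers:
#' a protofilament of n dimers yields n - 1 spacings.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param pf_index 0-based protofilament index
#' @param tubule tubule name (default: first)
#' @return numeric vector of spacings, Angstrom
#' @export
dimer_spacings <- function(annotation, model, pf_index, tubule = NULL) {
  if (is.null(tubule)) tubule <- .first_tubule(annotation)
  centers <- .dimer_center_table(annotation, model, tubule)
  centers <- centers[centers$pf == pf_index, ]
  if (nrow(centers) < 2)
    stop("dimer_spacings: protofilament ", pf_index, " has fewer than 2 dimers")
  centers <- centers[order(centers$axial), ]
  unname(sqrt(rowSums(diff(as.matrix(centers[, c("x", "y", "z")]))^2)))
}

#' Interprotofilament rotation angle at a lateral interface
#'
#' The rotation angle of the rigid superposition mapping a tubulin dimer
#' onto its lateral neighbor at the matched axial level, with atoms paired
#' by residue correspondence. For an ideal closed N-protofilament tube this
#' is 360/N degrees at every interface.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param interface 0-based interface index (interface i joins pf i and
#'   pf i+1 modulo n_pf)
#' @param tubule tubule name (default: first)
#' @param axial axial dimer level (default: the middle level present in both)
#' @return angle in degrees
#' @export
interprotofilament_angle <- function(annotation, model, interface,
                                     tubule = NULL, axial = NULL) {
  if (is.null(tubule)) tubule <- .first_tubule(annotation)
  tub <- annotation$tubules[[tubule]]
  r <- which(tub$interfaces$index == interface)
  if (!length(r)) stop("interprotofilament_angle: no interface ", interface)
  pa <- tub$interfaces$pf_a[r]; pb <- tub$interfaces$pf_b[r]
  centers <- .dimer_center_table(annotation, model, tubule)
  ka <- sort(centers$axial[centers$pf == pa])
  kb <- sort(centers$axial[centers$pf == pb])
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("interprotofilament_angle: no shared axial level")
  if (is.null(axial)) axial <- shared[ceiling(length(shared) / 2)]
  da <- .dimer_atoms(annotation, model, tubule, pa, axial)
  db <- .dimer_atoms(annotation, model, tubule, pb, axial)
  if (!nrow(da) || !nrow(db))
    stop("interprotofilament_angle: missing dimer at axial level ", axial)
  kabsch_superpose(da, db)$rotation_angle
}

#' Tilt angle of a MIP rod relative to its tubulin-dimer plane
#'
#' The plane is the least-squares plane over all atoms of both flanking
#' dimers (normal = smallest-variance principal direction); the MIP long
#' axis is its largest-variance principal direction. The tilt is 90 degrees
#' minus the axis/normal angle, folded into [0, 90].
#'
#' @param mip_atoms atom table of the MIP copy (>= 3 non-collinear atoms)
#' @param dimer_a_atoms,dimer_b_atoms atom tables of the two dimers
#' @return tilt angle, degrees in [0, 90]
#' @export
tilt_angle <- function(mip_atoms, dimer_a_atoms, dimer_b_atoms) {
  if (nrow(mip_atoms) < 3) stop("tilt_angle: MIP has fewer than 3 atoms")
  mp <- principal_axes(atom_xyz(mip_atoms))
  if (mp$values[2] < 1e-12 * max(mp$values[1], 1))
    warning("tilt_angle: MIP atoms nearly collinear; long axis still defined")
  axis <- mp$vectors[, 1]
  both <- rbind(atom_xyz(dimer_a_atoms), atom_xyz(dimer_b_atoms))
  pp <- principal_axes(both)
  if (pp$values[2] < 1e-12 * max(pp$values[1], 1))
    stop("tilt_angle: degenerate dimer geometry; plane undefined")
  normal <- pp$vectors[, 3]
  tau <- 90 - angle_between_deg(axis, normal)
  abs(tau)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Standard Shrake-Rupley: for each atom, the fraction of quasi-uniform
#' sphere points at radius r_vdw + probe not inside any neighbor's expanded
#' sphere, times the sphere area. Van der Waals radii: C 1.70, N 1.55,
#' O 1.52, S 1.80, P 1.80, H 1.20; unknown elements fall back to 1.70 with a
#' warning.
#'
#' @param atoms atom table
#' @param probe_radius probe radius, Angstrom (default 1.4, water)
#' @param n_points sphere test points per atom (default 960)
#' @return numeric vector of per-atom areas, Angstrom^2
#' @export
shrake_rupley_sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  if (nrow(atoms) == 0) stop("shrake_rupley_sasa: empty selection")
  radii <- element_vdw_radius(atoms$element)
  .sasa_kernel(atom_xyz(atoms), radii, probe_radius, fibonacci_sphere(n_points))
}

#' Buried interface area between two atom sets (PISA convention)
#'
#' \code{A_int = (SASA(A) + SASA(B) - SASA(A and B)) / 2}: half the solvent-
#' accessible surface lost on complex formation.
#'
#' @param part_a_atoms,part_b_atoms atom tables of the two parts
#' @param probe_radius,n_points passed to \code{\link{shrake_rupley_sasa}}
#' @return interface area, Angstrom^2 (clamped at 0)
#' @export
interface_area <- function(part_a_atoms, part_b_atoms, probe_radius = 1.4,
                           n_points = 960) {
  sa <- sum(shrake_rupley_sasa(part_a_atoms, probe_radius, n_points))
  sb <- sum(shrake_rupley_sasa(part_b_atoms, probe_radius, n_points))
  sab <- sum(shrake_rupley_sasa(rbind(part_a_atoms, part_b_atoms),
                                probe_radius, n_points))
  max(0, (sa + sb - sab) / 2)
}

# --- decoration-level descriptors -------------------------------------------

# MIP copies of one class: list of (chain_id, center, phi, z) in the frame of
# the tubule the copies decorate (azimuth about the tubule's own center).
.mip_copies <- function(annotation, model, class_name) {
  ch <- annotation$chains
  sel <- ch[ch$role == paste0("mip:", class_name), ]
  if (!nrow(sel)) return(NULL)
  # use the tubule whose tubulin centroid is nearest the copies' centroid
  b <- .axis_basis(annotation$axis$direction)
  tub_names <- names(annotation$tubules)
  cen <- vapply(tub_names, function(tb) annotation$tubules[[tb]]$center, numeric(3))
  mid <- colMeans(sel[, c("cx", "cy", "cz")])
  tb <- tub_names[which.min(colSums((cen - mid)^2))]
  ctr <- annotation$tubules[[tb]]$center
  rel <- sweep(as.matrix(sel[, c("cx", "cy", "cz")]), 2, ctr)
  u <- rel %*% b$perp
  data.frame(chain_id = sel$chain_id,
             phi = (atan2(u[, 2], u[, 1]) * 180 / pi) %% 360,
             z = as.numeric(rel %*% annotation$axis$direction),
             stringsAsFactors = FALSE)
}

# Group copies into azimuthal columns (one column per decorated interface).
.mip_columns <- function(copies) {
  if (nrow(copies) == 1) return(rep(1L, 1))
  .cluster_azimuths(copies$phi)
}

#' Axial periodicity of a MIP decoration class
#'
#' Per azimuthal column of copies, consecutive axial spacings of copy mass
#' centers are collected; the median over all columns is returned in nm.
#' The median resists a missing copy.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param class_name decoration class (e.g. \code{"SPACA9"})
#' @return periodicity in nm
#' @export
axial_periodicity <- function(annotation, model, class_name) {
  copies <- .mip_copies(annotation, model, class_name)
  if (is.null(copies) || nrow(copies) < 2)
    stop("axial_periodicity: periodicity undefined (fewer than 2 copies of ",
         class_name, ")")
  col <- .mip_columns(copies)
  diffs <- unlist(lapply(split(copies$z, col), function(z)
    if (length(z) >= 2) diff(sort(z)) else numeric(0)))
  if (!length(diffs))
    stop("axial_periodicity: periodicity undefined (no column has 2 copies)")
  stats::median(diffs) / 10
}

#' Handedness of a MIP spiral decoration
#'
#' For each pair of azimuthally adjacent copy columns, the closest-in-z copy
#' pair gives a local slope dz/dphi along the decoration path. Viewed from
#' the plus end (+axis), a negative median slope (rising clockwise) is a
#' left-handed spiral; positive is right-handed; axial spread below
#' tolerance is \code{"none"} (a flat ring).
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param class_name decoration class
#' @param z_tol axial spread (Angstrom) below which the decoration is flat
#' @return \code{"left"}, \code{"right"} or \code{"none"}
#' @export
spiral_handedness <- function(annotation, model, class_name, z_tol = 0.5) {
  copies <- .mip_copies(annotation, model, class_name)
  if (is.null(copies) || nrow(copies) < 3)
    stop("spiral_handedness: need at least 3 copies")
  col <- .mip_columns(copies)
  if (max(col) < 3) stop("spiral_handedness: copies on fewer than 3 interfaces")
  mean_phi <- vapply(split(copies$phi, col), function(p) {
    pr <- p * pi / 180; (atan2(mean(sin(pr)), mean(cos(pr))) * 180 / pi) %% 360
  }, 1)
  ord <- order(mean_phi)
  slopes <- numeric(0)
  for (j in seq_along(ord)) {
    a <- ord[j]; b <- ord[if (j == length(ord)) 1L else j + 1L]
    dphi <- (mean_phi[b] - mean_phi[a]) %% 360
    if (dphi > 180 || dphi < 1e-9) next
    za <- copies$z[col == as.integer(names(mean_phi)[a])]
    zb <- copies$z[col == as.integer(names(mean_phi)[b])]
    dz <- as.vector(outer(zb, za, "-"))
    slopes <- c(slopes, dz[which.min(abs(dz))] / dphi)
  }
  if (!length(slopes)) stop("spiral_handedness: no adjacent column pairs")
  dz_med <- stats::median(slopes) * stats::median(abs(diff(sort(mean_phi))))
  if (abs(dz_med) < z_tol) return("none")
  if (stats::median(slopes) < 0) "left" else "right"
}

#' MIP copies per axial repeat
#'
#' Copies are grouped into azimuthal columns and, within each column,
#' indexed by axial repeat; the best-covered repeat's copy count is
#' returned — the number of copies forming one spiral/striation unit.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param class_name decoration class
#' @return integer copy count (0 when the class is absent)
#' @export
copies_per_repeat <- function(annotation, model, class_name) {
  copies <- .mip_copies(annotation, model, class_name)
  if (is.null(copies)) return(0L)
  if (nrow(copies) == 1) return(1L)
  col <- .mip_columns(copies)
  per_col <- split(copies$z, col)
  steps <- unlist(lapply(per_col, function(z) diff(sort(z))))
  period <- if (length(steps)) stats::median(steps) else NA_real_
  if (!is.finite(period) || period <= 0) return(length(per_col))
  # repeat index within each column (columns share the same axial repeat
  # set, so the window follows the spiral); count per repeat and report the
  # best-covered one (edge repeats may be truncated)
  k_all <- unlist(lapply(per_col, function(z) round((z - min(z)) / period)))
  max(tabulate(k_all + 1L))
}

#' Pairwise RMSD of MIP copies after superposing their anchor tubulins
#'
#' Each copy's associated alpha-tubulin is the alpha monomer sharing the
#' largest buried interface area with the copy (ties broken toward the lower
#' protofilament, then lower axial index). For each pair (i, j), copy j's
#' alpha is superposed onto copy i's alpha, the transform applied to copy j,
#' and the RMSD against copy i computed over residue-paired atoms.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated model
#' @param class_name decoration class
#' @param contact_cutoff candidate alphas must approach the copy within this
#'   distance (Angstrom, default 12)
#' @param n_points SASA quadrature used to rank candidate alphas
#' @return symmetric RMSD matrix (Angstrom) with copy chain ids as dimnames
#' @export
mip_pairwise_rmsd <- function(annotation, model, class_name,
                              contact_cutoff = 12, n_points = 240) {
  ch <- annotation$chains
  mips <- ch[ch$role == paste0("mip:", class_name), ]
  if (nrow(mips) < 2) stop("mip_pairwise_rmsd: need at least 2 copies")
  alphas <- ch[ch$role == "alpha", ]
  a <- model$atoms
  anchor <- character(nrow(mips))
  for (i in seq_len(nrow(mips))) {
    m_at <- a[a$chain_id == mips$chain_id[i], ]
    d <- sqrt((alphas$cx - mean(m_at$x))^2 + (alphas$cy - mean(m_at$y))^2 +
                (alphas$cz - mean(m_at$z))^2)
    cand <- alphas[d < contact_cutoff + 60, ]
    cand <- cand[order(d[d < contact_cutoff + 60])[seq_len(min(4, nrow(cand)))], ]
    if (!nrow(cand)) stop("mip_pairwise_rmsd: copy ", mips$chain_id[i],
                          " has no alpha-tubulin nearby")
    areas <- vapply(cand$chain_id, function(cid)
      interface_area(m_at, a[a$chain_id == cid, ], n_points = n_points), 1)
    if (max(areas) >= 5) {
      # real contact: largest buried area; ties (within 5%) resolve to the
      # lower pf index, then lower axial index
      tied <- which(areas >= max(areas) * 0.95)
      tied <- tied[order(cand$pf_index[tied], cand$axial_index[tied])]
      anchor[i] <- cand$chain_id[tied[1]]
    } else {
      # no burial anywhere (idealized rods): nearest alpha center, which is
      # the same lattice-relative choice for every copy
      anchor[i] <- cand$chain_id[1]
    }
  }
  n <- nrow(mips)
  out <- matrix(0, n, n, dimnames = list(mips$chain_id, mips$chain_id))
  mip_at <- lapply(mips$chain_id, function(cid) a[a$chain_id == cid, ])
  alpha_at <- lapply(anchor, function(cid) a[a$chain_id == cid, ])
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    fit <- kabsch_superpose(alpha_at[[j]], alpha_at[[i]])
    moved <- atom_xyz(mip_at[[j]]) %*% t(fit$R)
    moved <- sweep(moved, 2, fit$t, "+")
    ref <- atom_xyz(mip_at[[i]])
    if (nrow(moved) != nrow(ref)) {
      keyj <- paste(mip_at[[j]]$res_seq, mip_at[[j]]$name)
      keyi <- paste(mip_at[[i]]$res_seq, mip_at[[i]]$name)
      common <- intersect(keyj, keyi)
      if (length(common) < 3)
        stop("mip_pairwise_rmsd: copies ", mips$chain_id[i], " and ",
             mips$chain_id[j], " share no residue correspondence")
      moved <- moved[match(common, keyj), , drop = FALSE]
      ref <- ref[match(common, keyi), , drop = FALSE]
    }
    out[i, j] <- out[j, i] <- sqrt(mean(rowSums((moved - ref)^2)))
  }
  out
}
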