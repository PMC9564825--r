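#' Lattice parameters for synthetic microtubule generation
#'
#' Bundles the helical bookkeeping of an idealized microtubule: protofilament
#' count, longitudinal dimer rise, lateral stagger, radius, seam position and
#' polarity. Defaults describe the canonical 13-protofilament, 3-start
#' B-lattice with an 8-nm dimer repeat.
#'
#' @param n_pf protofilament count (>= 3), default 13
#' @param dimer_rise longitudinal rise per tubulin dimer, Angstrom (default 80)
#' @param monomer_len monomer length along the axis, Angstrom
#'   (default \code{dimer_rise / 2})
#' @param stagger axial offset per lateral interface, Angstrom. Default
#'   \code{3 * monomer_len / n_pf}, the 3-start lattice; with seam closure the
#'   total stagger around the tube must be an odd integer number of monomer
#'   lengths so that exactly one heterotypic (seam) interface results.
#' @param radius protofilament circle radius, Angstrom (default 105)
#' @param n_repeats dimers per protofilament (default 6, a 48-nm column)
#' @param seam_index lateral interface index in \code{[0, n_pf)} carrying the
#'   seam (default \code{n_pf - 1})
#' @param polarity \code{"plus_up"} (alpha below beta along +z) or
#'   \code{"plus_down"}
#' @param handedness_sign +1 or -1; the sign of the azimuthal step per
#'   protofilament. The default -1 makes the decoration path rise clockwise
#'   when viewed from the plus end, i.e. a left-handed spiral.
#' @param start_number number of monomer lengths of stagger accumulated per
#'   turn (default 3). Used to re-derive \code{stagger} when only
#'   \code{n_pf} changes.
#' @return object of class \code{lattice_params}
#' @export
lattice_params <- function(n_pf = 13, dimer_rise = 80, monomer_len = dimer_rise / 2,
                           stagger = NULL, radius = 105, n_repeats = 6,
                           seam_index = n_pf - 1,
                           polarity = c("plus_up", "plus_down"),
                           handedness_sign = -1, start_number = 3) {
  polarity <- match.arg(polarity)
  if (n_pf < 3) stop("lattice_params: n_pf must be >= 3")
  if (dimer_rise <= 0) stop("lattice_params: dimer_rise must be positive")
  if (is.null(stagger)) stagger <- start_number * monomer_len / n_pf
  # seam closure needs n_pf * stagger to be an integer number of monomers
  turns <- n_pf * stagger / monomer_len
  if (abs(turns - round(turns)) > 1e-6) {
    stagger <- round(turns) * monomer_len / n_pf
    warning("lattice_params: stagger adjusted to ", signif(stagger, 6),
            " A so the tube closes on an integer monomer offset")
  }
  if (seam_index < 0 || seam_index >= n_pf)
    stop("lattice_params: seam_index must lie in [0, n_pf)")
  if (!handedness_sign %in% c(-1, 1))
    stop("lattice_params: handedness_sign must be +1 or -1")
  structure(list(n_pf = as.integer(n_pf), dimer_rise = dimer_rise,
                 monomer_len = monomer_len, stagger = stagger, radius = radius,
                 n_repeats = as.integer(n_repeats),
                 seam_index = as.integer(seam_index), polarity = polarity,
                 handedness_sign = handedness_sign),
            class = "lattice_params")
}

#' Build a pseudo-atomic tubulin dimer template
#'
#' Generates two anisotropic ellipsoidal clouds of carbon pseudo-atoms
#' standing in for the alpha- and beta-tubulin monomers (alpha below beta
#' along +z). The combined cloud is centered at the origin and rotated into
#' its principal frame so the longest principal axis lies exactly along z.
#' Each pseudo-atom is its own residue, so residue counts track atom counts.
#'
#' @param n_atoms_per_monomer atoms per monomer cloud (>= 4)
#' @param seed RNG seed; the same seed always yields the same template
#' @param monomer_len axial monomer length, Angstrom (default 40)
#' @return a \code{structure_model} with chains \code{"a"} (res_name
#'   \code{TBA}) and \code{"b"} (res_name \code{TBB})
#' @export
build_dimer_template <- function(n_atoms_per_monomer = 440, seed = 1,
                                 monomer_len = 40) {
  if (n_atoms_per_monomer < 4)
    stop("build_dimer_template: need n_atoms_per_monomer >= 4 for axis/plane fits")
  n <- n_atoms_per_monomer
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # sds chosen distinct so all three principal directions are well separated:
  # x ~ radial, y ~ tangential, z ~ longitudinal after lattice placement
  cloud <- function(zc) cbind(stats::rnorm(n, 0, 9), stats::rnorm(n, 0, 6),
                              stats::rnorm(n, zc, monomer_len * 0.28))
  xyz <- rbind(cloud(-monomer_len / 2), cloud(monomer_len / 2))
  # rotate into the principal frame: largest-variance axis -> z, then x, y
  pc <- principal_axes(xyz)
  V <- pc$vectors[, c(2, 3, 1)]            # new x, y, z
  for (k in 1:3) if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  if (det(V) < 0) V[, 2] <- -V[, 2]
  xyz <- sweep(xyz, 2, pc$center) %*% V
  # enforce alpha-below-beta in the principal frame
  if (mean(xyz[seq_len(n), 3]) > mean(xyz[-seq_len(n), 3]))
    xyz[, c(1, 3)] <- -xyz[, c(1, 3)]
  xyz <- sweep(xyz, 2, colMeans(xyz))      # exact geometric/mass center at origin
  atoms <- data.frame(
    serial = seq_len(2L * n), name = "CA", element = "C",
    res_name = rep(c("TBA", "TBB"), each = n),
    res_seq = rep(seq_len(n), 2),
    chain_id = rep(c("a", "b"), each = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  structure_model(atoms, metadata = list(
    title = "synthetic tubulin dimer template", template_seed = seed,
    n_atoms_per_monomer = n, monomer_len = monomer_len))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Place one template copy: rotate about z by phi (deg) after shifting to
# radius, then translate along z. Returns the transformed coordinate matrix.
.place_dimer <- function(txyz, radius, phi, z, center = c(0, 0)) {
  p <- txyz
  p[, 1] <- p[, 1] + radius
  p <- p %*% t(rot_z(phi))
  p[, 1] <- p[, 1] + center[1]
  p[, 2] <- p[, 2] + center[2]
  p[, 3] <- p[, 3] + z
  p
}

.tubule_atoms <- function(template, params, prefix, center = c(0, 0),
                          pf_azimuths = NULL, pf_z0 = NULL, jitter_sd = 0,
                          serial_from = 1L) {
  p <- params
  n_pf_here <- if (is.null(pf_azimuths)) p$n_pf else length(pf_azimuths)
  if (is.null(pf_azimuths))
    pf_azimuths <- p$handedness_sign * 360 * (seq_len(p$n_pf) - 1) / p$n_pf
  if (is.null(pf_z0)) {
    # accumulate stagger so the closure break falls at interface seam_index
    ord <- (seq_len(p$n_pf) - 1 - (p$seam_index + 1)) %% p$n_pf
    pf_z0 <- ord * p$stagger
  }
  txyz <- atom_xyz(template$atoms)
  if (p$polarity == "plus_down") txyz <- txyz %*% t(rot_y(180))
  n_t <- nrow(txyz)
  n_mono <- n_t / 2
  blocks <- vector("list", n_pf_here * p$n_repeats)
  labels <- vector("list", n_pf_here * p$n_repeats)
  idx <- 0L
  for (i in seq_len(n_pf_here)) {
    for (k in seq_len(p$n_repeats)) {
      idx <- idx + 1L
      z <- pf_z0[i] + (k - 1) * p$dimer_rise
      xyz <- .place_dimer(txyz, p$radius, pf_azimuths[i], z, center)
      if (jitter_sd > 0) xyz <- sweep(xyz, 2, stats::rnorm(3, 0, jitter_sd), "+")
      chains <- sprintf("%s%02d.%d%s", prefix, i, k - 1, c("a", "b"))
      a <- template$atoms
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      a$chain_id <- rep(chains, each = n_mono)
      blocks[[idx]] <- a
      labels[[idx]] <- data.frame(
        chain_id = chains, role = c("alpha", "beta"), tubule = prefix,
        pf_index = i - 1L, axial_index = k - 1L, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, blocks)
  atoms$serial <- seq.int(serial_from, length.out = nrow(atoms))
  list(atoms = atoms, labels = do.call(rbind, labels))
}

#' Build a closed singlet microtubule lattice
#'
#' Protofilament i sits at azimuth \code{handedness_sign * 360 * i / n_pf} on
#' a cylinder of the given radius, shifted axially by the accumulated lateral
#' stagger; \code{n_repeats} dimers are stacked at \code{dimer_rise} along z.
#' The 3-start stagger leaves a residual offset of three monomer lengths at
#' the closure interface, making its nearest lateral contacts heterotypic
#' (alpha against beta): the seam.
#'
#' @param params a \code{\link{lattice_params}}
#' @param template dimer template from \code{\link{build_dimer_template}}
#' @param jitter_sd per-dimer rigid displacement noise, Angstrom (default 0)
#' @param prefix chain-label prefix, default \code{"S"} (singlet)
#' @return list with elements \code{model} (\code{structure_model}) and
#'   \code{truth} (ground-truth annotation, see \code{\link{write_ground_truth}})
#' @export
build_singlet <- function(params, template = build_dimer_template(),
                          jitter_sd = 0, prefix = "S") {
  stopifnot(inherits(params, "lattice_params"))
  tub <- .tubule_atoms(template, params, prefix, jitter_sd = jitter_sd)
  model <- structure_model(tub$atoms, metadata = list(
    title = sprintf("synthetic %d-pf singlet", params$n_pf)))
  truth <- list(
    lattice = params, decorations = list(),
    tubules = stats::setNames(list(list(closed = TRUE, n_pf = params$n_pf,
                                        seam_index = params$seam_index,
                                        center = c(0, 0))), prefix),
    chain_labels = tub$labels)
  class(truth) <- "lattice_ground_truth"
  list(model = model, truth = truth)
}

#' Build a doublet microtubule lattice (A tubule plus partial B tubule)
#'
#' The A tubule is a closed singlet (chains A01...). The B tubule is a
#' geometric stand-in: an open arc of \code{n_pf_B} protofilaments on a
#' second, tangent cylinder of the same radius, sharing the A tubule's rise
#' and stagger, labeled B01...B\code{n_pf_B}. The inner/outer junction
#' architecture is intentionally not modeled; only labels, rise and stagger
#' matter to the analyses exercised here.
#'
#' @param params_A \code{\link{lattice_params}} for the A tubule
#' @param n_pf_B number of B-tubule protofilaments (>= 4, default 10)
#' @param template dimer template
#' @param jitter_sd per-dimer rigid noise, Angstrom
#' @return list(model, truth) as in \code{\link{build_singlet}}
#' @export
build_doublet <- function(params_A, n_pf_B = 10, template = build_dimer_template(),
                          jitter_sd = 0) {
  stopifnot(inherits(params_A, "lattice_params"))
  if (n_pf_B < 4) stop("build_doublet: n_pf_B must be >= 4")
  A <- .tubule_atoms(template, params_A, "A", jitter_sd = jitter_sd)
  p <- params_A
  centerB <- c(2 * p$radius, 0)
  # open arc on the far side of the B cylinder from the A tubule
  step <- p$handedness_sign * 360 / 13
  phiB <- 180 + step * (seq_len(n_pf_B) + 0.5)
  zB <- (seq_len(n_pf_B) - 1) * p$stagger
  B <- .tubule_atoms(template, p, "B", center = centerB, pf_azimuths = phiB,
                     pf_z0 = zB, jitter_sd = jitter_sd,
                     serial_from = nrow(A$atoms) + 1L)
  # B is built with params_A counts; keep only its own pf count
  keepB <- B$labels$pf_index < n_pf_B
  atoms <- rbind(A$atoms, B$atoms)
  dmin <- .min_intertubule_gap(A$atoms, B$atoms)
  if (dmin < 2) warning(sprintf(
    "build_doublet: tubules overlap (closest pseudo-atoms %.2f A apart)", dmin))
  model <- structure_model(atoms, metadata = list(
    title = sprintf("synthetic doublet A%d/B%d", p$n_pf, n_pf_B)))
  truth <- list(
    lattice = p, decorations = list(),
    tubules = list(A = list(closed = TRUE, n_pf = p$n_pf,
                            seam_index = p$seam_index, center = c(0, 0)),
                   B = list(closed = FALSE, n_pf = as.integer(n_pf_B),
                            seam_index = NA_integer_, center = centerB)),
    chain_labels = rbind(A$labels, B$labels))
  class(truth) <- "lattice_ground_truth"
  list(model = model, truth = truth)
}

.min_intertubule_gap <- function(a, b) {
  # coarse: nearest chain-center pair, then exact over those two chains
  ca <- vapply(split(seq_len(nrow(a)), a$chain_id), function(i)
    colMeans(cbind(a$x[i], a$y[i], a$z[i])), numeric(3))
  cb <- vapply(split(seq_len(nrow(b)), b$chain_id), function(i)
    colMeans(cbind(b$x[i], b$y[i], b$z[i])), numeric(3))
  d2 <- outer(colSums(ca^2), colSums(cb^2), "+") - 2 * t(ca) %*% cb
  ij <- arrayInd(which.min(d2), dim(d2))
  ai <- a[a$chain_id == rownames(d2)[ij[1]], ]
  bi <- b[b$chain_id == colnames(d2)[ij[2]], ]
  pa <- atom_xyz(ai); pb <- atom_xyz(bi)
  sqrt(min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)))
}

#' Describe a MIP decoration class
#'
#' A decoration is a class of microtubule inner proteins placed on the
#' lumenal wall: either rods bridging lateral interprotofilament interfaces
#' (the striation/spiral mode) or rods running longitudinally along single
#' protofilaments (the filament mode).
#'
#' @param class_name decoration class label, e.g. \code{"SPACA9"}
#' @param mode \code{"lateral_interface"} or \code{"longitudinal_filament"}
#' @param pf_span \code{"all_non_seam"}, an integer vector of 0-based
#'   interface indices (lateral mode) or protofilament indices (longitudinal
#'   mode), or a character vector of protofilament labels such as
#'   \code{c("B02","B05")} denoting the interfaces among the inclusive range
#' @param periodicity axial repeat of the decoration, Angstrom; must be a
#'   positive integer multiple of the dimer rise used at placement time
#' @param tilt rod tilt relative to the local protofilament-pair plane,
#'   degrees (default 51.5)
#' @param length rod length, Angstrom (default 45)
#' @param n_atoms pseudo-atoms per rod (default 24; 8 of them form a thin
#'   symmetric sheath so the rod is non-collinear without moving its
#'   principal axis)
#' @param inset radial inward displacement of the rod anchor from the
#'   flanking-dimer midpoint, Angstrom (default 15, which leaves the rod
#'   nestled against the lumenal wall)
#' @param tubule tubule whose interfaces are decorated (default the first)
#' @return object of class \code{mip_decoration}
#' @export
mip_decoration <- function(class_name, mode = c("lateral_interface",
                                                "longitudinal_filament"),
                           pf_span = "all_non_seam", periodicity = NULL,
                           tilt = 51.5, length = 45, n_atoms = 24, inset = 15,
                           tubule = NULL) {
  mode <- match.arg(mode)
  if (n_atoms < 11) stop("mip_decoration: need n_atoms >= 11")
  structure(list(class_name = class_name, mode = mode, pf_span = pf_span,
                 periodicity = periodicity, tilt = tilt, length = length,
                 n_atoms = as.integer(n_atoms), inset = inset, tubule = tubule,
                 placements = NULL),
            class = "mip_decoration")
}

# Resolve a pf_span to 0-based interface indices of a tubule.
.resolve_interfaces <- function(span, tub, tubule_name) {
  n_pf <- tub$n_pf
  n_int <- if (tub$closed) n_pf else n_pf - 1L
  if (identical(span, "all_non_seam")) {
    if (!tub$closed) return(seq_len(n_int) - 1L)
    return(setdiff(seq_len(n_int) - 1L, tub$seam_index))
  }
  if (is.character(span)) {
    pf <- as.integer(sub("^[A-Za-z]+", "", span)) - 1L
    pf <- seq(min(pf), max(pf))
    ifc <- pf[-length(pf)]
  } else ifc <- as.integer(span)
  if (any(ifc < 0 | ifc >= n_int))
    stop("decorate_mips: interface indices out of range for tubule ", tubule_name)
  if (tub$closed && tub$seam_index %in% ifc)
    stop("decorate_mips: interface ", tub$seam_index, " of tubule ", tubule_name,
         " is the seam; lateral-interface MIPs cannot occupy the seam")
  ifc
}

# Symmetric rod of pseudo-atoms: axis through `anchor` along unit vector v.
# n_atoms - 8 atoms lie on the axis; 8 form a thin symmetric sheath so the
# rod is non-collinear while its centroid and principal axis stay exact.
.rod_atoms <- function(anchor, v, length, n_atoms, ref = c(0, 0, 1)) {
  n_ax <- n_atoms - 8L
  t_ax <- seq(-length / 2, length / 2, length.out = n_ax)
  if (abs(sum(ref * v)) > 0.99 * sqrt(sum(ref^2)))
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- .unit(ref - sum(ref * v) * v)
  p2 <- .cross(v, p1)
  w <- 1.5
  offs <- rbind(w * p1, -w * p1, w * p2, -w * p2)
  pts <- rbind(outer(t_ax, v),
               sweep(offs, 2, (length / 4) * v, "+"),
               sweep(offs, 2, (-length / 4) * v, "+"))
  sweep(pts, 2, anchor, "+")
}

#' Decorate a synthetic lattice with a MIP class
#'
#' For every decorated interface and every axial repeat at the stated
#' periodicity, a rod of pseudo-atoms is placed: anchored at the midpoint of
#' the two flanking dimers' mass centers displaced radially inward, with its
#' axis making the stated tilt angle with the local protofilament-pair plane
#' (the least-squares plane over all atoms of both flanking dimers). Lateral
#' decorations never occupy the seam. In longitudinal mode one rod runs
#' along each listed protofilament per repeat.
#'
#' @param lattice list(model, truth) from a builder
#' @param decoration a \code{\link{mip_decoration}}
#' @return list(model, truth) with the decoration added and ground-truth
#'   placements recorded
#' @export
decorate_mips <- function(lattice, decoration) {
  model <- lattice$model; truth <- lattice$truth
  dec <- decoration
  p <- truth$lattice
  if (is.null(dec$tubule)) dec$tubule <- names(truth$tubules)[1]
  tub <- truth$tubules[[dec$tubule]]
  if (is.null(tub)) stop("decorate_mips: no tubule '", dec$tubule, "' in model")
  if (is.null(dec$periodicity)) dec$periodicity <- p$dimer_rise
  step <- dec$periodicity / p$dimer_rise
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop("decorate_mips: periodicity must be a positive integer multiple of the dimer rise")
  step <- as.integer(round(step))

  labels <- truth$chain_labels
  atoms <- model$atoms
  centers <- .dimer_centers_from_truth(atoms, labels, dec$tubule)

  new_blocks <- list(); new_labels <- list(); placements <- list()
  serial0 <- max(atoms$serial)
  axial_set <- seq(0L, p$n_repeats - 1L, by = step)

  if (dec$mode == "lateral_interface") {
    ifcs <- .resolve_interfaces(dec$pf_span, tub, dec$tubule)
    for (i in ifcs) {
      a <- i; b <- (i + 1L) %% tub$n_pf
      for (k in axial_set) {
        da <- .dimer_atom_rows(atoms, labels, dec$tubule, a, k)
        db <- .dimer_atom_rows(atoms, labels, dec$tubule, b, k)
        if (!nrow(da) || !nrow(db)) next
        ca <- centers[centers$pf == a & centers$axial == k, c("x", "y", "z")]
        cb <- centers[centers$pf == b & centers$axial == k, c("x", "y", "z")]
        mid <- as.numeric((ca + cb) / 2)
        inward <- -.unit(c(mid[1] - tub$center[1], mid[2] - tub$center[2], 0))
        anchor <- mid + dec$inset * inward
        both <- rbind(atom_xyz(da), atom_xyz(db))
        pc <- principal_axes(both)
        nrm <- pc$vectors[, 3]                      # plane normal
        if (sum(nrm * inward) < 0) nrm <- -nrm      # orient into the lumen
        lat <- as.numeric(cb - ca); lat <- .unit(lat - sum(lat * nrm) * nrm)
        v <- cos(.deg2rad(dec$tilt)) * lat + sin(.deg2rad(dec$tilt)) * nrm
        res <- .append_rod(anchor, v, dec, i, k, serial0 + length(new_blocks) * dec$n_atoms)
        new_blocks[[length(new_blocks) + 1L]] <- res$atoms
        new_labels[[length(new_labels) + 1L]] <- res$label
        placements[[length(placements) + 1L]] <- list(interface = i, axial = k,
                                                      anchor = anchor, axis = v)
      }
    }
  } else {
    pfs <- if (identical(dec$pf_span, "all_non_seam")) seq_len(tub$n_pf) - 1L
           else if (is.character(dec$pf_span)) as.integer(sub("^[A-Za-z]+", "", dec$pf_span)) - 1L
           else as.integer(dec$pf_span)
    for (i in pfs) {
      for (k in axial_set) {
        ci <- centers[centers$pf == i & centers$axial == k, c("x", "y", "z")]
        if (!nrow(ci)) next
        ci <- as.numeric(ci)
        inward <- -.unit(c(ci[1] - tub$center[1], ci[2] - tub$center[2], 0))
        anchor <- ci + dec$inset * inward
        v <- c(0, 0, 1)
        res <- .append_rod(anchor, v, dec, i, k,
                           serial0 + length(new_blocks) * dec$n_atoms,
                           ref = inward)
        new_blocks[[length(new_blocks) + 1L]] <- res$atoms
        new_labels[[length(new_labels) + 1L]] <- res$label
        placements[[length(placements) + 1L]] <- list(interface = i, axial = k,
                                                      anchor = anchor, axis = v)
      }
    }
  }
  if (!length(new_blocks)) stop("decorate_mips: no placements generated")
  dec$placements <- placements
  model <- structure_model(rbind(atoms, do.call(rbind, new_blocks)),
                           metadata = model$metadata)
  truth$decorations[[dec$class_name]] <- dec
  truth$chain_labels <- rbind(labels, do.call(rbind, new_labels))
  list(model = model, truth = truth)
}

.append_rod <- function(anchor, v, dec, interface, k, serial0, ref = c(0, 0, 1)) {
  xyz <- .rod_atoms(anchor, v, dec$length, dec$n_atoms, ref)
  chain <- sprintf("%s_%02d_%02d", dec$class_name, interface, k)
  atoms <- data.frame(
    serial = seq.int(serial0 + 1L, length.out = nrow(xyz)),
    name = "CA", element = "C", res_name = dec$class_name,
    res_seq = seq_len(nrow(xyz)), chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  label <- data.frame(chain_id = chain, role = paste0("mip:", dec$class_name),
                      tubule = dec$tubule, pf_index = interface,
                      axial_index = k, stringsAsFactors = FALSE)
  list(atoms = atoms, label = label)
}

.dimer_atom_rows <- function(atoms, labels, tubule, pf, axial) {
  ch <- labels$chain_id[labels$tubule == tubule & labels$pf_index == pf &
                          labels$axial_index == axial &
                          labels$role %in% c("alpha", "beta")]
  atoms[atoms$chain_id %in% ch, , drop = FALSE]
}

.dimer_centers_from_truth <- function(atoms, labels, tubule) {
  tl <- labels[labels$tubule == tubule & labels$role %in% c("alpha", "beta"), ]
  key <- paste(tl$pf_index, tl$axial_index)
  out <- lapply(split(tl$chain_id, key), function(ch) {
    a <- atoms[atoms$chain_id %in% ch, ]
    colMeans(cbind(a$x, a$y, a$z))
  })
  k <- do.call(rbind, strsplit(names(out), " "))
  data.frame(pf = as.integer(k[, 1]), axial = as.integer(k[, 2]),
             do.call(rbind, out) |> `colnames<-`(c("x", "y", "z")))
}

#' Serialize / read generator ground truth as a JSON side-car
#' @param truth a \code{lattice_ground_truth}
#' @param path JSON file path
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    lattice = unclass(truth$lattice),
    tubules = truth$tubules,
    chain_labels = truth$chain_labels,
    decorations = lapply(truth$decorations, function(d) {
      d <- unclass(d)
      d$placements <- lapply(d$placements, function(pl)
        list(interface = pl$interface, axial = pl$axial,
             anchor = as.numeric(pl$anchor), axis = as.numeric(pl$axis)))
      d
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(
    lattice = do.call(lattice_params, raw$lattice[
      c("n_pf", "dimer_rise", "monomer_len", "stagger", "radius", "n_repeats",
        "seam_index", "polarity", "handedness_sign")]),
    tubules = lapply(raw$tubules, function(t) {
      t$center <- as.numeric(t$center); t }),
    chain_labels = as.data.frame(raw$chain_labels),
    decorations = lapply(raw$decorations, function(d) {
      dec <- mip_decoration(d$class_name, d$mode,
                            pf_span = unlist(d$pf_span),
                            periodicity = d$periodicity, tilt = d$tilt,
                            length = d$length, n_atoms = d$n_atoms,
                            inset = d$inset, tubule = d$tubule)
      if (!is.null(d$placements) && length(d$placements$interface)) {
        pick <- function(col, i)
          if (is.matrix(col)) as.numeric(col[i, ]) else as.numeric(col[[i]])
        dec$placements <- lapply(seq_along(d$placements$interface), function(i)
          list(interface = d$placements$interface[i],
               axial = d$placements$axial[i],
               anchor = pick(d$placements$anchor, i),
               axis = pick(d$placements$axis, i)))
      }
      dec
    }))
  class(truth) <- "lattice_ground_truth"
  truth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
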