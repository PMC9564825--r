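#' Full geometry report for a microtubule model
#'
#' Runs every lattice descriptor on an annotated model: per-protofilament
#' dimer spacings and means, interprotofilament angles per interface, and —
#' per MIP decoration class — tilt angles, buried interface areas, axial
#' periodicity, handedness, copies per repeat and the pairwise RMSD matrix
#' after anchor-tubulin superposition. Deterministic for a fixed model.
#'
#' @param model a \code{structure_model} or path readable by
#'   \code{\link{read_structure}}
#' @param annotation optional precomputed \code{lattice_annotation}
#' @param n_pf_hint,chain_map,min_tubulin_res passed to
#'   \code{\link{annotate_lattice}}
#' @param sasa_points SASA quadrature for interface areas (default 960)
#' @param with_interface_areas compute per-copy buried areas (default TRUE;
#'   the slowest descriptor)
#' @param with_rmsd compute the pairwise RMSD matrix (default TRUE)
#' @return object of class \code{geometry_report}: list of data.frames and
#'   per-class summaries
#' @export
analyze_model <- function(model, annotation = NULL, n_pf_hint = NULL,
                          chain_map = NULL, min_tubulin_res = 300,
                          sasa_points = 960, with_interface_areas = TRUE,
                          with_rmsd = TRUE) {
  if (is.character(model)) model <- read_structure(model)
  if (is.null(annotation))
    annotation <- annotate_lattice(model, n_pf_hint = n_pf_hint,
                                   chain_map = chain_map,
                                   min_tubulin_res = min_tubulin_res)
  ann <- annotation
  ch <- ann$chains

  spac <- list(); ipf <- list()
  for (tb in names(ann$tubules)) {
    tub <- ann$tubules[[tb]]
    for (p in seq_len(tub$n_pf) - 1L) {
      d <- tryCatch(dimer_spacings(ann, model, p, tubule = tb),
                    error = function(e) numeric(0))
      if (length(d))
        spac[[length(spac) + 1L]] <- data.frame(
          tubule = tb, pf_index = p, measurement = seq_along(d) - 1L,
          spacing = d)
    }
    for (r in seq_len(nrow(tub$interfaces))) {
      th <- tryCatch(interprotofilament_angle(ann, model,
                                              tub$interfaces$index[r],
                                              tubule = tb),
                     error = function(e) NA_real_)
      ipf[[length(ipf) + 1L]] <- data.frame(
        tubule = tb, interface = tub$interfaces$index[r],
        pf_a = tub$interfaces$pf_a[r], pf_b = tub$interfaces$pf_b[r],
        is_seam = identical(tub$interfaces$index[r], tub$seam_index),
        theta = th)
    }
  }
  spacings <- if (length(spac)) do.call(rbind, spac) else
    data.frame(tubule = character(), pf_index = integer(),
               measurement = integer(), spacing = numeric())
  angles <- if (length(ipf)) do.call(rbind, ipf) else
    data.frame(tubule = character(), interface = integer(), pf_a = integer(),
               pf_b = integer(), is_seam = logical(), theta = numeric())

  classes <- unique(sub("^mip:", "", ch$role[startsWith(ch$role, "mip:")]))
  mip <- list()
  for (cls in classes) {
    copies <- ch[ch$role == paste0("mip:", cls), ]
    tilt_tab <- .mip_tilt_table(ann, model, cls)
    areas <- if (with_interface_areas)
      .mip_area_table(ann, model, cls, sasa_points) else NULL
    per <- tryCatch(axial_periodicity(ann, model, cls),
                    error = function(e) NA_real_)
    hand <- tryCatch(spiral_handedness(ann, model, cls),
                     error = function(e) NA_character_)
    rmsd <- if (with_rmsd && nrow(copies) >= 2)
      tryCatch(mip_pairwise_rmsd(ann, model, cls), error = function(e) NULL)
    else NULL
    mip[[cls]] <- list(
      class_name = cls, n_copies = nrow(copies),
      copies_per_repeat = copies_per_repeat(ann, model, cls),
      periodicity_nm = per, handedness = hand,
      tilt = tilt_tab, interface_areas = areas, rmsd_matrix = rmsd)
  }

  structure(list(
    annotation = ann, spacings = spacings, angles = angles, mips = mip,
    summary = list(
      n_chains = nrow(ch),
      tubules = lapply(ann$tubules, function(t)
        list(n_pf = t$n_pf, closed = t$closed, seam_index = t$seam_index)),
      mean_spacing = if (nrow(spacings)) mean(spacings$spacing) else NA_real_,
      mean_theta_nonseam = if (nrow(angles))
        mean(angles$theta[!angles$is_seam], na.rm = TRUE) else NA_real_)),
    class = "geometry_report")
}

# Tilt of each MIP copy against the plane of the two tubulin dimers it
# bridges (the two nearest dimer mass centers on distinct protofilaments).
.mip_tilt_table <- function(ann, model, cls) {
  ch <- ann$chains
  copies <- ch[ch$role == paste0("mip:", cls), ]
  if (!nrow(copies)) return(NULL)
  a <- model$atoms
  tb <- copies$tubule[1]
  if (!tb %in% names(ann$tubules)) tb <- .first_tubule(ann)
  center_tabs <- lapply(names(ann$tubules), function(tbn) {
    d <- .dimer_center_table(ann, model, tbn)
    if (nrow(d)) d$tubule <- tbn
    d
  })
  center_tab <- do.call(rbind, center_tabs[vapply(center_tabs, nrow, 1L) > 0])
  atoms_by_chain <- split(seq_len(nrow(a)), a$chain_id)
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    m_at <- a[atoms_by_chain[[copies$chain_id[i]]], ]
    mc <- mass_center(m_at)
    dimers <- .nearest_dimers(ann, model, mc, n = 2, center_tab = center_tab)
    if (is.null(dimers)) return(NULL)
    tau <- tilt_angle(m_at,
                      .dimer_atoms(ann, model, dimers$tubule[1],
                                   dimers$pf[1], dimers$axial[1]),
                      .dimer_atoms(ann, model, dimers$tubule[2],
                                   dimers$pf[2], dimers$axial[2]))
    data.frame(chain_id = copies$chain_id[i],
               pf_a = dimers$pf[1], pf_b = dimers$pf[2],
               axial = dimers$axial[1], tilt = tau)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows)) do.call(rbind, rows) else NULL
}

# The n nearest dimers (on distinct protofilaments) to a point.
.nearest_dimers <- function(ann, model, point, n = 2, center_tab = NULL) {
  if (is.null(center_tab)) {
    tabs <- lapply(names(ann$tubules), function(tb) {
      d <- .dimer_center_table(ann, model, tb)
      if (!nrow(d)) return(NULL)
      d$tubule <- tb
      d
    })
    center_tab <- do.call(rbind, tabs[!vapply(tabs, is.null, TRUE)])
  }
  tab <- center_tab
  if (is.null(tab) || !nrow(tab)) return(NULL)
  tab$dist <- sqrt((tab$x - point[1])^2 + (tab$y - point[2])^2 +
                     (tab$z - point[3])^2)
  tab <- tab[order(tab$dist), ]
  picked <- tab[1, ]
  for (r in seq(2, nrow(tab))) {
    if (nrow(picked) >= n) break
    if (!any(picked$pf == tab$pf[r] & picked$tubule == tab$tubule[r]))
      picked <- rbind(picked, tab[r, ])
  }
  if (nrow(picked) < n) NULL else picked
}

# Buried interface area of each copy against its contacting tubulin chains
# (chains contributing at least `min_chain_area` individually).
.mip_area_table <- function(ann, model, cls, sasa_points = 960,
                            min_chain_area = 50, contact_dist = 6) {
  ch <- ann$chains
  copies <- ch[ch$role == paste0("mip:", cls), ]
  if (!nrow(copies)) return(NULL)
  a <- model$atoms
  tub_rows <- ch[ch$role %in% c("alpha", "beta"), ]
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    m_at <- a[a$chain_id == copies$chain_id[i], ]
    mc <- colMeans(atom_xyz(m_at))
    d <- sqrt((tub_rows$cx - mc[1])^2 + (tub_rows$cy - mc[2])^2 +
                (tub_rows$cz - mc[3])^2)
    cand <- tub_rows$chain_id[d < 90]
    near <- vapply(cand, function(cid) {
      t_at <- a[a$chain_id == cid, ]
      min(outer(m_at$x, t_at$x, "-")^2 + outer(m_at$y, t_at$y, "-")^2 +
            outer(m_at$z, t_at$z, "-")^2) < contact_dist^2
    }, TRUE)
    contacts <- cand[near]
    if (!length(contacts))
      return(data.frame(chain_id = copies$chain_id[i], area = 0,
                        n_contact_chains = 0L))
    per_chain <- vapply(contacts, function(cid)
      interface_area(m_at, a[a$chain_id == cid, ], n_points = sasa_points), 1)
    keep <- contacts[per_chain >= min_chain_area]
    if (!length(keep)) keep <- contacts[which.max(per_chain)]
    total <- interface_area(m_at, a[a$chain_id %in% keep, ],
                            n_points = sasa_points)
    data.frame(chain_id = copies$chain_id[i], area = total,
               n_contact_chains = length(keep))
  })
  do.call(rbind, rows)
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("geometry_report\n")
  for (tb in names(x$summary$tubules)) {
    t <- x$summary$tubules[[tb]]
    cat(sprintf("  tubule %s: %d pf (%s), seam interface %s\n", tb, t$n_pf,
                if (t$closed) "closed" else "open",
                if (is.na(t$seam_index)) "none" else t$seam_index))
  }
  if (nrow(x$spacings))
    cat(sprintf("  dimer spacing: mean %.3f A over %d measurements\n",
                x$summary$mean_spacing, nrow(x$spacings)))
  ok <- !x$angles$is_seam & !is.na(x$angles$theta)
  if (any(ok))
    cat(sprintf("  interprotofilament angle (non-seam): mean %.3f deg\n",
                mean(x$angles$theta[ok])))
  for (cls in names(x$mips)) {
    m <- x$mips[[cls]]
    cat(sprintf("  MIP %s: %d copies, %d per repeat, periodicity %s nm, %s\n",
                cls, m$n_copies, m$copies_per_repeat,
                if (is.na(m$periodicity_nm)) "NA"
                else sprintf("%.1f", m$periodicity_nm),
                if (is.na(m$handedness)) "handedness NA"
                else paste0(m$handedness, "-handed")))
    if (!is.null(m$tilt))
      cat(sprintf("    tilt: %.1f-%.1f deg (mean %.1f)\n",
                  min(m$tilt$tilt), max(m$tilt$tilt), mean(m$tilt$tilt)))
    if (!is.null(m$interface_areas))
      cat(sprintf("    interface area: mean %.0f A^2\n",
                  mean(m$interface_areas$area)))
    if (!is.null(m$rmsd_matrix)) {
      off <- m$rmsd_matrix[upper.tri(m$rmsd_matrix)]
      cat(sprintf("    pairwise RMSD: %.2f-%.2f A\n", min(off), max(off)))
    }
  }
  invisible(x)
}

#' Write a geometry report as JSON plus flat TSV tables
#'
#' @param report a \code{geometry_report}
#' @param out_dir output directory (created if needed)
#' @param seed seed to record in the report header
#' @param config configuration list echoed (hashed) into the header
#' @return invisibly, the paths written
#' @export
write_report <- function(report, out_dir, seed = NA_integer_, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    package = "mtlattice",
    version = as.character(utils::packageVersion("mtlattice")),
    seed = seed, config_hash = .fnv1a(config),
    numbering = "chain labels when present, seam/azimuth order otherwise")
  js <- list(
    header = header,
    summary = report$summary,
    mips = lapply(report$mips, function(m) {
      m$rmsd_matrix <- if (!is.null(m$rmsd_matrix))
        list(chains = rownames(m$rmsd_matrix),
             rmsd = unname(as.matrix(m$rmsd_matrix)))
      else NULL
      m
    }))
  paths <- c(file.path(out_dir, "report.json"),
             file.path(out_dir, "spacings.tsv"),
             file.path(out_dir, "angles.tsv"))
  jsonlite::write_json(js, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.table(report$spacings, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$angles, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (cls in names(report$mips)) {
    m <- report$mips[[cls]]
    if (!is.null(m$tilt)) {
      p <- file.path(out_dir, sprintf("tilt_%s.tsv", cls))
      utils::write.table(m$tilt, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

# Tiny polynomial rolling hash over the deparsed config; fingerprints a run
# configuration in report headers.
.fnv1a <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Compare lattice geometry of two models
#'
#' Pairs protofilaments by label (or an explicit mapping), then reports
#' per-protofilament differences of mean dimer spacing and per-interface
#' differences of interprotofilament angle, with summary extrema.
#'
#' @param model_a,model_b models or paths
#' @param pf_map optional data.frame(pf_a, pf_b) of 0-based protofilament
#'   indices pairing model A to model B; default: identical indices
#' @param tubule_a,tubule_b tubule names (default: first in each)
#' @param ... passed to \code{\link{annotate_lattice}}
#' @return list(spacing = data.frame, angle = data.frame, extrema = list)
#' @export
compare_models <- function(model_a, model_b, pf_map = NULL,
                           tubule_a = NULL, tubule_b = NULL, ...) {
  if (is.character(model_a)) model_a <- read_structure(model_a)
  if (is.character(model_b)) model_b <- read_structure(model_b)
  ann_a <- annotate_lattice(model_a, ...)
  ann_b <- annotate_lattice(model_b, ...)
  if (is.null(tubule_a)) tubule_a <- .first_tubule(ann_a)
  if (is.null(tubule_b)) tubule_b <- .first_tubule(ann_b)
  na <- ann_a$tubules[[tubule_a]]$n_pf
  nb <- ann_b$tubules[[tubule_b]]$n_pf
  if (is.null(pf_map)) {
    if (na != nb)
      stop("compare_models: models have ", na, " and ", nb,
           " protofilaments and no pf_map was given")
    pf_map <- data.frame(pf_a = seq_len(na) - 1L, pf_b = seq_len(na) - 1L)
  }
  sp <- lapply(seq_len(nrow(pf_map)), function(r) {
    da <- mean(dimer_spacings(ann_a, model_a, pf_map$pf_a[r], tubule_a))
    db <- mean(dimer_spacings(ann_b, model_b, pf_map$pf_b[r], tubule_b))
    data.frame(pf_a = pf_map$pf_a[r], pf_b = pf_map$pf_b[r],
               mean_spacing_a = da, mean_spacing_b = db, diff = da - db)
  })
  spacing <- do.call(rbind, sp)
  ia <- ann_a$tubules[[tubule_a]]$interfaces
  ib <- ann_b$tubules[[tubule_b]]$interfaces
  common <- intersect(ia$index, ib$index)
  th <- lapply(common, function(i) {
    ta <- interprotofilament_angle(ann_a, model_a, i, tubule_a)
    tb2 <- interprotofilament_angle(ann_b, model_b, i, tubule_b)
    data.frame(interface = i, theta_a = ta, theta_b = tb2, diff = ta - tb2)
  })
  angle <- do.call(rbind, th)
  list(spacing = spacing, angle = angle,
       extrema = list(
         max_abs_spacing_diff = max(abs(spacing$diff)),
         max_abs_angle_diff = if (!is.null(angle)) max(abs(angle$diff)) else NA))
}

#' Generate a synthetic lattice from a configuration
#'
#' Configuration is a list (or YAML/JSON file) with optional blocks
#' \code{lattice} (arguments of \code{\link{lattice_params}}),
#' \code{template} (\code{n_atoms_per_monomer}, \code{seed}),
#' \code{doublet} (\code{n_pf_B}), and \code{decorations} (list of
#' \code{\link{mip_decoration}} argument lists).
#'
#' @param config list, or path to a YAML/JSON config file
#' @param out_dir optional directory: writes \code{model.cif} and
#'   \code{ground_truth.json}
#' @param seed overrides the template seed
#' @return list(model, truth)
#' @export
simulate_lattice <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  params <- do.call(lattice_params, config$lattice %||% list())
  t_args <- config$template %||% list()
  if (!is.null(seed)) t_args$seed <- seed
  t_args$monomer_len <- params$monomer_len
  template <- do.call(build_dimer_template, t_args)
  lattice <- if (!is.null(config$doublet))
    build_doublet(params, n_pf_B = config$doublet$n_pf_B %||% 10,
                  template = template)
  else build_singlet(params, template = template)
  for (d in config$decorations %||% list())
    lattice <- decorate_mips(lattice, do.call(mip_decoration, d))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure(lattice$model, file.path(out_dir, "model.cif"))
    write_ground_truth(lattice$truth, file.path(out_dir, "ground_truth.json"))
  }
  lattice
}
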