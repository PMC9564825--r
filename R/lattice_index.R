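#' Fit the helical axis of a microtubule model
#'
#' The axis is the largest-variance principal direction of the tubulin chain
#' mass centers, anchored at their centroid. The direction sign is
#' canonicalized (largest-magnitude component positive), so callers comparing
#' axes should do so up to sign.
#'
#' @param model a \code{structure_model}
#' @param chains optional chain ids to use (default: all chains)
#' @return list(direction = unit 3-vector, point = 3-vector)
#' @export
fit_axis <- function(model, chains = NULL) {
  a <- model$atoms
  if (!is.null(chains)) a <- a[a$chain_id %in% chains, ]
  ids <- unique(a$chain_id)
  centers <- t(vapply(split(seq_len(nrow(a)), a$chain_id)[ids],
                      function(i) colMeans(cbind(a$x[i], a$y[i], a$z[i])),
                      numeric(3)))
  if (nrow(centers) < 3) stop("fit_axis: need at least 3 chains")
  pc <- principal_axes(centers)
  if (pc$values[2] < 1e-9 * max(pc$values, 1))
    stop("fit_axis: degenerate (collinear) chain geometry")
  v <- pc$vectors[, 1]
  # The raw principal direction is biased by the seam's stagger sawtooth
  # (axial offsets correlate with azimuth around the tube). Refine with
  # nearest-neighbor bond directions: on a lattice the nearest chain center
  # is the longitudinal neighbor, so these bonds point along the axis.
  if (nrow(centers) >= 6) {
    D2 <- as.matrix(stats::dist(centers))^2
    diag(D2) <- Inf
    nb <- apply(D2, 1, which.min)
    d <- centers[nb, , drop = FALSE] - centers
    len <- sqrt(rowSums(d^2))
    keep <- len < 1.2 * stats::median(len)            # drop oddball bonds
    if (sum(keep) >= 3) {
      e <- eigen(crossprod(d[keep, , drop = FALSE]), symmetric = TRUE)
      if (e$values[1] > 4 * e$values[2]) v <- e$vectors[, 1]
    }
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  list(direction = v, point = pc$center)
}

# Cluster circular azimuths (degrees) by the largest-gap statistic: the
# cluster count is where the sorted circular gaps drop fastest (or `k` when
# given). Returns integer membership, clusters numbered in traversal order.
.cluster_azimuths <- function(phi, k = NULL) {
  n <- length(phi)
  ord <- order(phi)
  sp <- phi[ord]
  gaps <- c(diff(sp), sp[1] + 360 - sp[n])    # gap i follows sorted point i
  if (is.null(k)) {
    gs <- sort(gaps, decreasing = TRUE)
    # first large drop in the sorted circular gaps separates between-pf gaps
    # from within-pf spread (e.g. the small alpha/beta azimuth offset);
    # sentinel: if all gaps are comparable, every point is its own cluster
    ratios <- c(gs[-n] / pmax(gs[-1], 1e-12), gs[n] / 1e-12)
    ratios[1] <- 0                            # a tubule has at least 2 pfs
    cand <- which(ratios > 8)
    k <- if (length(cand)) cand[1] else which.max(ratios)
  }
  k <- min(k, n)
  boundary <- sort(sort.list(gaps, decreasing = TRUE)[seq_len(k)])
  cl_sorted <- integer(n)
  cl <- 1L
  j <- (boundary[k] %% n) + 1L               # first point past the last boundary
  for (step in seq_len(n)) {
    cl_sorted[j] <- cl
    if (j %in% boundary) cl <- cl + 1L
    j <- (j %% n) + 1L
  }
  membership <- integer(n)
  membership[ord] <- cl_sorted
  membership
}

.axis_basis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * v) * v)
  e2 <- .cross(v, e1)
  list(perp = cbind(e1, e2), e1 = e1, e2 = e2)
}

#' Annotate a model with lattice assignments
#'
#' Classifies chains into tubulin and MIP, splits tubules, clusters tubulin
#' chains into protofilaments by azimuth about the fitted axis, assigns
#' axial (dimer) indices and monomer classes, enumerates adjacent-pf
#' interfaces and detects the seam of each closed tubule. The annotation is
#' invariant to rigid-body transforms of the model and to chain order in the
#' file.
#'
#' Protofilament numbering follows chain labels when they encode it (e.g.
#' generator labels \code{S03.1a} or author labels \code{B02}); otherwise
#' numbering starts just after the seam and increases with azimuth, and the
#' printed report states which origin was used.
#'
#' @param model a \code{structure_model}
#' @param n_pf_hint optional protofilament count; estimated from the largest
#'   gap statistic over circular azimuth spacing when absent
#' @param chain_map optional named list (or JSON file path) mapping chain_id
#'   to a list with entries \code{role} ("alpha", "beta", "mip:CLASS",
#'   "other") and optionally \code{tubule}
#' @param min_tubulin_res chains with at least this many residues are
#'   tubulin candidates (default 300; deposited tubulins have ~440 residues)
#' @return object of class \code{lattice_annotation}
#' @export
annotate_lattice <- function(model, n_pf_hint = NULL, chain_map = NULL,
                             min_tubulin_res = 300) {
  if (is.character(chain_map) && length(chain_map) == 1 && file.exists(chain_map))
    chain_map <- jsonlite::read_json(chain_map)
  a <- model$atoms
  ids <- unique(a$chain_id)
  rows_by_chain <- split(seq_len(nrow(a)), a$chain_id)[ids]
  n_res <- vapply(rows_by_chain, function(i) length(unique(a$res_seq[i])), 1L)
  res_name1 <- vapply(rows_by_chain, function(i) a$res_name[i][1], "")
  w <- element_mass(a$element)
  sums <- rowsum(cbind(w * a$x, w * a$y, w * a$z, w), a$chain_id)[ids, , drop = FALSE]
  centers <- sums[, 1:3, drop = FALSE] / sums[, 4]

  role <- stats::setNames(rep(NA_character_, length(ids)), ids)
  tubule <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(chain_map)) {
    for (id in intersect(ids, names(chain_map))) {
      role[id] <- chain_map[[id]]$role
      tubule[id] <- chain_map[[id]]$tubule %||% NA_character_
    }
  }
  un <- is.na(role)
  role[un] <- ifelse(n_res[un] >= min_tubulin_res,
                     unname(c(TBA = "alpha", TBB = "beta")[res_name1[un]]),
                     paste0("mip:", res_name1[un]))
  role[is.na(role)] <- "tubulin"   # large chain, monomer class resolved below

  is_tub <- role %in% c("alpha", "beta", "tubulin")
  if (sum(is_tub) < 3) stop("annotate_lattice: fewer than 3 tubulin chains")
  axis <- fit_axis(model, chains = ids[is_tub])

  # tubule split: label prefixes (A/B/S + pf number) first, geometry otherwise
  has_pref <- grepl("^[ABS][0-9]", ids)
  need <- is.na(tubule) & has_pref & is_tub
  tubule[need] <- substr(ids[need], 1, 1)
  if (anyNA(tubule[is_tub])) {
    b <- .axis_basis(axis$direction)
    proj <- sweep(centers[is_tub, , drop = FALSE], 2, axis$point) %*% b$perp
    km2 <- stats::kmeans(proj, 2, nstart = 5)
    sep <- sqrt(sum((km2$centers[1, ] - km2$centers[2, ])^2))
    spread <- sqrt(mean(km2$withinss / pmax(km2$size, 1)))
    lab <- if (sep > 1.2 * spread)
      ifelse(km2$cluster == which.max(km2$size), "A", "B")
    else rep("S", sum(is_tub))
    miss <- is.na(tubule[is_tub])
    tubule[is_tub][miss] <- lab[miss]
  }
  tubule[is.na(tubule)] <- "S"

  chains <- data.frame(chain_id = ids, role = unname(role),
                       tubule = unname(tubule),
                       pf_index = NA_integer_, axial_index = NA_integer_,
                       n_res = unname(n_res),
                       cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                       stringsAsFactors = FALSE)

  tubules <- list()
  for (tb in unique(chains$tubule[is_tub])) {
    sel <- which(is_tub & chains$tubule == tb)
    tres <- .annotate_tubule(chains[sel, ], axis, n_pf_hint)
    chains$pf_index[sel] <- unname(tres$pf_index_of[chains$chain_id[sel]])
    chains$axial_index[sel] <- unname(tres$axial_index_of[chains$chain_id[sel]])
    chains$role[sel] <- unname(tres$role_of[chains$chain_id[sel]])
    tres$pf_index_of <- tres$axial_index_of <- tres$role_of <- NULL
    tubules[[tb]] <- tres
  }

  # MIP chains belong to the tubule whose wall centroid is nearest
  mip_rows <- which(startsWith(chains$role, "mip:"))
  if (length(mip_rows) && length(tubules)) {
    cen <- vapply(tubules, `[[`, numeric(3), "center")
    for (i in mip_rows) {
      d2 <- colSums((cen - c(chains$cx[i], chains$cy[i], chains$cz[i]))^2)
      chains$tubule[i] <- names(tubules)[which.min(d2)]
    }
  }

  ann <- structure(list(axis = axis, chains = chains, tubules = tubules),
                   class = "lattice_annotation")
  for (tb in names(tubules)) {
    t <- tubules[[tb]]
    if (!t$closed) { ann$tubules[[tb]]$seam_index <- NA_integer_; next }
    seam <- tryCatch(detect_seam(ann, model, tubule = tb), error = function(e) {
      warning("annotate_lattice: ", conditionMessage(e), call. = FALSE)
      NA_integer_
    })
    if (is.na(seam)) { ann$tubules[[tb]]$seam_index <- NA_integer_; next }
    if (!t$labels_used) {
      # renumber so pf 0 sits just after the seam (seam = last interface)
      sel <- ann$chains$tubule == tb & ann$chains$role %in% c("alpha", "beta")
      ann$chains$pf_index[sel] <-
        (ann$chains$pf_index[sel] - (seam + 1L)) %% t$n_pf
      seam <- t$n_pf - 1L
    }
    ann$tubules[[tb]]$seam_index <- seam
  }
  ann
}

# Annotate one tubule's chains (data.frame rows with precomputed centers).
.annotate_tubule <- function(sub, axis, n_pf_hint) {
  ctr <- colMeans(sub[, c("cx", "cy", "cz")])
  b <- .axis_basis(axis$direction)
  rel <- sweep(as.matrix(sub[, c("cx", "cy", "cz")]), 2, ctr)
  u <- rel %*% b$perp
  zc <- as.numeric(rel %*% axis$direction)
  phi <- (atan2(u[, 2], u[, 1]) * 180 / pi) %% 360
  cl <- .cluster_azimuths(phi, k = n_pf_hint)
  n_pf <- max(cl)
  sizes <- tabulate(cl)
  if (max(sizes) - min(sizes) > 2)
    stop("annotate_lattice: irreconcilable protofilament clustering ",
         "(cluster populations ", paste(sizes, collapse = "/"), ")")

  mean_phi <- vapply(seq_len(n_pf), function(c_i) {
    p <- phi[cl == c_i] * pi / 180
    (atan2(mean(sin(p)), mean(cos(p))) * 180 / pi) %% 360
  }, 1)

  # numbering: label-encoded when consistent, azimuth order otherwise
  lab_pf <- suppressWarnings(as.integer(sub("^[ABS]([0-9]+).*$", "\\1",
                                            sub$chain_id))) - 1L
  pf_of_cluster <- rep(NA_integer_, n_pf)
  labels_used <- FALSE
  if (!anyNA(lab_pf) && length(unique(lab_pf)) == n_pf) {
    for (c_i in seq_len(n_pf)) {
      votes <- table(lab_pf[cl == c_i])
      pf_of_cluster[c_i] <- as.integer(names(votes)[which.max(votes)])
    }
    labels_used <- !anyDuplicated(pf_of_cluster) &&
      all(sort(pf_of_cluster) == seq_len(n_pf) - 1L)
    if (!labels_used) pf_of_cluster <- rep(NA_integer_, n_pf)
  }
  if (anyNA(pf_of_cluster))
    pf_of_cluster[order(mean_phi)] <- seq_len(n_pf) - 1L
  pf <- pf_of_cluster[cl]

  # closed tube iff no anomalous azimuthal gap between adjacent pfs
  sg <- sort(mean_phi)
  gaps <- c(diff(sg), sg[1] + 360 - sg[length(sg)])
  closed <- max(gaps) < 1.6 * stats::median(gaps)
  n_int <- if (closed) n_pf else n_pf - 1L
  interfaces <- data.frame(index = seq_len(n_int) - 1L,
                           pf_a = seq_len(n_int) - 1L,
                           pf_b = seq_len(n_int) %% n_pf)

  role_of <- stats::setNames(sub$role, sub$chain_id)
  axial_of <- stats::setNames(rep(NA_integer_, nrow(sub)), sub$chain_id)
  for (p_i in seq_len(n_pf) - 1L) {
    rows <- which(pf == p_i)
    rows <- rows[order(zc[rows])]
    rl <- role_of[sub$chain_id[rows]]
    if (any(rl == "tubulin")) {
      rl <- rep(c("alpha", "beta"), length.out = length(rows))
      role_of[sub$chain_id[rows]] <- rl
    }
    # dimer pairing: a new dimer starts at each monomer of the leading class
    d_idx <- -1L
    for (r in seq_along(rows)) {
      if (rl[r] == rl[1]) d_idx <- d_idx + 1L
      axial_of[sub$chain_id[rows[r]]] <- d_idx
    }
  }
  list(closed = closed, n_pf = n_pf, interfaces = interfaces, center = ctr,
       labels_used = labels_used,
       pf_index_of = stats::setNames(pf, sub$chain_id),
       axial_index_of = axial_of, role_of = role_of)
}

#' Detect the seam of a closed tubule
#'
#' For each adjacent-protofilament interface, each monomer's nearest lateral
#' neighbor in the partner protofilament is classified homotypic
#' (alpha-alpha / beta-beta) or heterotypic (alpha-beta). The unique
#' interface whose nearest contacts are predominantly heterotypic is the
#' seam.
#'
#' @param annotation a \code{lattice_annotation}
#' @param model the annotated \code{structure_model}
#' @param tubule tubule name (default: first closed tubule)
#' @return 0-based seam interface index
#' @export
detect_seam <- function(annotation, model, tubule = NULL) {
  ann <- annotation
  if (is.null(tubule)) {
    cand <- names(ann$tubules)[vapply(ann$tubules, `[[`, TRUE, "closed")]
    if (!length(cand)) stop("detect_seam: no closed tubule; no seam exists")
    tubule <- cand[1]
  }
  tub <- ann$tubules[[tubule]]
  if (is.null(tub) || !tub$closed)
    stop("detect_seam: tubule is not closed; no seam exists")
  ch <- ann$chains
  ch <- ch[ch$tubule == tubule & ch$role %in% c("alpha", "beta"), ]
  het <- numeric(nrow(tub$interfaces))
  for (r in seq_len(nrow(tub$interfaces))) {
    A <- ch[ch$pf_index == tub$interfaces$pf_a[r], ]
    B <- ch[ch$pf_index == tub$interfaces$pf_b[r], ]
    d2 <- outer(A$cx, B$cx, "-")^2 + outer(A$cy, B$cy, "-")^2 +
      outer(A$cz, B$cz, "-")^2
    nb <- apply(d2, 1, which.min)
    het[r] <- mean(A$role != B$role[nb])
  }
  # inclusive threshold: end monomers of short lattices lack a lateral
  # partner toward the plus end, which halves the heterotypic census
  hits <- which(het >= 0.5)
  if (length(hits) != 1)
    stop("detect_seam: expected exactly one heterotypic interface, found ",
         length(hits), " (heterotypic fractions: ",
         paste(sprintf("%d:%.2f", tub$interfaces$index, het), collapse = ", "),
         ")")
  tub$interfaces$index[hits]
}

#' @export
print.lattice_annotation <- function(x, ...) {
  cat("lattice_annotation:", nrow(x$chains), "chains;",
      "axis ~ (", paste(sprintf("%.3f", x$axis$direction), collapse = ", "), ")\n")
  for (tb in names(x$tubules)) {
    t <- x$tubules[[tb]]
    cat(sprintf("  tubule %s: %d pf, %s, seam interface %s, numbering from %s\n",
                tb, t$n_pf, if (t$closed) "closed" else "open arc",
                if (is.na(t$seam_index)) "none" else t$seam_index,
                if (t$labels_used) "chain labels" else "seam/azimuth order"))
  }
  invisible(x)
}
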