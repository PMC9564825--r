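#' Euler triplet (ZYZ) to rotation matrix and back
#'
#' Convention: intrinsic Z-Y-Z, rotations applied rot about z, then tilt
#' about the new y, then psi about the new z, i.e.
#' \code{R = Rz(rot) Ry(tilt) Rz(psi)} — the parameterization used by
#' cryo-EM particle tables. The gimbal case tilt = 0 is resolved by placing
#' all in-plane rotation into psi.
#'
#' @param rot,tilt,psi Euler angles, degrees
#' @return \code{euler_to_matrix}: 3x3 proper rotation matrix.
#'   \code{matrix_to_euler}: numeric c(rot, tilt, psi) with
#'   tilt in [0, 180] and rot, psi in (-180, 180].
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
}

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' @rdname euler_to_matrix
#' @param R 3x3 rotation matrix
#' @export
matrix_to_euler <- function(R) {
  ct <- min(1, max(-1, R[3, 3]))
  tilt <- .rad2deg(acos(ct))
  if (abs(ct) > 1 - 1e-12) {
    # gimbal: rot and psi share an axis; put everything into psi
    rot <- 0
    psi <- if (ct > 0) .rad2deg(atan2(R[2, 1], R[1, 1]))
           else .rad2deg(atan2(R[2, 1], R[2, 2]))
  } else {
    rot <- .rad2deg(atan2(R[2, 3], R[1, 3]))
    psi <- .rad2deg(atan2(R[3, 2], -R[3, 1]))
  }
  c(rot = .wrap180(rot), tilt = tilt, psi = .wrap180(psi))
}

# --- STAR-format orientation tables -----------------------------------------

.STAR_MAP <- c(rot = "_rlnAngleRot", tilt = "_rlnAngleTilt",
               psi = "_rlnAnglePsi",
               origin_x = "_rlnOriginXAngst", origin_y = "_rlnOriginYAngst",
               origin_z = "_rlnOriginZAngst",
               class_id = "_rlnClassNumber", particle_id = "_rlnImageName")

#' Read a STAR-format particle orientation table
#'
#' Parses the first loop block containing the angle columns. Handled columns
#' (\code{_rlnAngleRot/Tilt/Psi}, \code{_rlnOriginX/Y/ZAngst},
#' \code{_rlnClassNumber}, \code{_rlnImageName}) are mapped onto an
#' orientation table; all other columns are preserved verbatim and written
#' back unchanged by \code{\link{write_orientation_table}}.
#'
#' @param path STAR file path
#' @return data.frame of class \code{orientation_table} with columns
#'   particle_id, rot, tilt, psi, origin_x, origin_y, origin_z, class_id
#' @export
read_orientation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, sub("\\s+#.*$", "", trimws(lines[j]))); j <- j + 1L
      }
      tags <- sub("\\s.*$", "", tags)
      if (any(.STAR_MAP[c("rot", "tilt", "psi")] %in% tags)) {
        missing <- setdiff(.STAR_MAP[c("rot", "tilt", "psi")], tags)
        if (length(missing))
          stop("read_orientation_table: missing required column(s): ",
               paste(missing, collapse = ", "))
        rows <- character()
        while (j <= n && nzchar(trimws(lines[j])) &&
               !grepl("^\\s*(loop_|data_|#)", lines[j])) {
          rows <- c(rows, trimws(lines[j])); j <- j + 1L
        }
        return(.star_table(tags, rows))
      }
      i <- j
    } else i <- i + 1L
  }
  stop("read_orientation_table: no particle loop with angle columns found in ",
       path)
}

.star_table <- function(tags, rows) {
  cells <- strsplit(rows, "\\s+")
  bad <- which(vapply(cells, length, 1L) != length(tags))
  if (length(bad))
    stop("read_orientation_table: row ", bad[1], " has ",
         length(cells[[bad[1]]]), " fields, expected ", length(tags))
  m <- do.call(rbind, cells)
  colnames(m) <- tags
  get_num <- function(tag, default) {
    if (tag %in% tags) as.numeric(m[, tag]) else rep(default, nrow(m))
  }
  out <- data.frame(
    particle_id = if (.STAR_MAP["particle_id"] %in% tags)
      m[, .STAR_MAP["particle_id"]] else sprintf("particle_%06d", seq_len(nrow(m))),
    rot = .wrap180(get_num(.STAR_MAP["rot"], 0)),
    tilt = get_num(.STAR_MAP["tilt"], 0),
    psi = .wrap180(get_num(.STAR_MAP["psi"], 0)),
    origin_x = get_num(.STAR_MAP["origin_x"], 0),
    origin_y = get_num(.STAR_MAP["origin_y"], 0),
    origin_z = get_num(.STAR_MAP["origin_z"], 0),
    class_id = as.integer(get_num(.STAR_MAP["class_id"], 1)),
    stringsAsFactors = FALSE)
  extra <- setdiff(tags, .STAR_MAP)
  attr(out, "star_tags") <- tags
  attr(out, "star_extra") <- if (length(extra)) m[, extra, drop = FALSE] else NULL
  class(out) <- c("orientation_table", "data.frame")
  out
}

#' Write a STAR-format particle orientation table
#'
#' Writes the handled columns from the table and any preserved unhandled
#' columns verbatim, in the original column order when the table came from
#' \code{\link{read_orientation_table}}.
#'
#' @param records an \code{orientation_table}
#' @param path output STAR file path
#' @export
write_orientation_table <- function(records, path) {
  tags <- attr(records, "star_tags")
  if (is.null(tags)) tags <- unname(.STAR_MAP[c("particle_id", "rot", "tilt",
                                                "psi", "origin_x", "origin_y",
                                                "origin_z", "class_id")])
  extra <- attr(records, "star_extra")
  fmt_num <- function(x) formatC(x, format = "f", digits = 6)
  cols <- lapply(tags, function(tag) {
    key <- names(.STAR_MAP)[match(tag, .STAR_MAP)]
    if (!is.na(key)) {
      v <- records[[key]]
      if (key %in% c("particle_id")) as.character(v)
      else if (key == "class_id") as.character(as.integer(v))
      else fmt_num(v)
    } else extra[, tag]
  })
  body <- do.call(paste, cols)
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("%s #%d", tags, seq_along(tags)), body, ""), path)
  invisible(path)
}

#' Apply per-class seam-register corrections to particle orientations
#'
#' Microtubule particle classes refined independently end up offset from a
#' common seam register by the pseudo-helical ambiguities: rotations by
#' multiples of 360/n_pf about the helical axis and axial shifts by
#' multiples of one tubulin monomer (4 nm). Each particle's orientation
#' matrix is post-composed with the rotation by \code{delta_phi} about the
#' reference helical axis, and its origin shifted by \code{delta_shift}
#' along the particle's helical axis as expressed in the particle frame.
#'
#' @param records an \code{orientation_table}
#' @param corrections data.frame with columns class_id, delta_phi (degrees),
#'   delta_shift (Angstrom); every class present in \code{records} must have
#'   a row (identity corrections allowed)
#' @param axis helical axis in the reference frame (default z)
#' @return corrected \code{orientation_table}
#' @export
apply_register_correction <- function(records, corrections,
                                      axis = c(0, 0, 1)) {
  stopifnot(all(c("class_id", "delta_phi", "delta_shift") %in% names(corrections)))
  missing <- setdiff(unique(records$class_id), corrections$class_id)
  if (length(missing))
    stop("apply_register_correction: no correction for class(es) ",
         paste(sort(missing), collapse = ", "))
  axis <- .unit(axis)
  idx <- match(records$class_id, corrections$class_id)
  out <- records
  for (i in seq_len(nrow(records))) {
    dphi <- corrections$delta_phi[idx[i]]
    dshift <- corrections$delta_shift[idx[i]]
    R <- euler_to_matrix(records$rot[i], records$tilt[i], records$psi[i])
    R2 <- R %*% rot_about_axis(axis, dphi)
    eul <- matrix_to_euler(R2)
    shift_vec <- dshift * as.numeric(R %*% axis)
    out$rot[i] <- eul["rot"]; out$tilt[i] <- eul["tilt"]; out$psi[i] <- eul["psi"]
    out$origin_x[i] <- records$origin_x[i] + shift_vec[1]
    out$origin_y[i] <- records$origin_y[i] + shift_vec[2]
    out$origin_z[i] <- records$origin_z[i] + shift_vec[3]
  }
  out
}

#' Build pseudo-helical register corrections from lattice quanta
#'
#' Convenience constructor: \code{delta_phi = k * 360 / n_pf} and
#' \code{delta_shift = m * monomer_len} per class.
#'
#' @param class_id integer vector of class ids
#' @param k integer protofilament steps (rotation quanta)
#' @param m integer monomer steps (4-nm shift quanta at the default)
#' @param n_pf protofilament count (default 13)
#' @param monomer_len monomer length, Angstrom (default 40)
#' @return corrections data.frame for
#'   \code{\link{apply_register_correction}}
#' @export
register_corrections <- function(class_id, k = 0, m = 0, n_pf = 13,
                                 monomer_len = 40) {
  data.frame(class_id = as.integer(class_id),
             delta_phi = .wrap180(k * 360 / n_pf),
             delta_shift = m * monomer_len)
}
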