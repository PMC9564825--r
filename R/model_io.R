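#' Construct a structure model from an atom table
#'
#' A \code{structure_model} is the atom container shared by every analysis in
#' the package: a flat table of atoms (one row per atom, author chain and
#' residue numbering) plus free-form metadata. Chains are ordered by first
#' appearance in the table.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{res_name}, \code{res_seq}, \code{chain_id},
#'   \code{x}, \code{y}, \code{z}, \code{occupancy}, \code{b_factor}.
#'   Coordinates are in Angstrom.
#' @param metadata named list of free-form metadata (title, generator ground
#'   truth for synthetic models, ...).
#' @return object of class \code{structure_model}
#' @export
structure_model <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "element", "res_name", "res_seq",
                "chain_id", "x", "y", "z", "occupancy", "b_factor")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("structure_model: atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  if (nrow(atoms) == 0) stop("structure_model: empty atom table")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("structure_model: non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("structure_model: empty element symbol")
  if (anyDuplicated(atoms$serial)) stop("structure_model: duplicated atom serials")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(chain_ids(x)), "chains\n")
  if (!is.null(x$metadata$title)) cat("  title:", x$metadata$title, "\n")
  invisible(x)
}

#' Chain identifiers of a model, in order of first appearance
#' @param model a \code{structure_model}
#' @export
chain_ids <- function(model) unique(model$atoms$chain_id)

#' Extract the atom table of one or more chains
#' @param model a \code{structure_model}
#' @param chains character vector of chain ids
#' @export
chain_atoms <- function(model, chains) {
  model$atoms[model$atoms$chain_id %in% chains, , drop = FALSE]
}

#' Coordinates of an atom table as an n x 3 matrix
#' @param atoms atom table (rows of a \code{structure_model})
#' @export
atom_xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

#' Apply a rigid-body transform to a model
#' @param model a \code{structure_model}
#' @param R 3x3 rotation matrix
#' @param t translation 3-vector (Angstrom)
#' @return transformed \code{structure_model}
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atom_xyz(model$atoms) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb"
  else stop("cannot guess structure format from extension '", ext,
            "'; pass format explicitly")
}

#' Read an atomic structure model (PDB or mmCIF)
#'
#' All ATOM/HETATM records are retained; chain order and author (auth)
#' chain/residue numbering are preserved. PDB files are parsed with
#' \pkg{bio3d}; mmCIF files with the package's atom_site reader.
#'
#' @param path file path
#' @param format one of \code{"auto"}, \code{"pdb"}, \code{"mmcif"}
#' @return a \code{structure_model}
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (file.size(path) == 0) stop("parse error: '", path, "' is empty")
  switch(format,
         pdb = .read_pdb(path),
         mmcif = .read_mmcif(path))
}

.read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("parse error reading PDB '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("parse error: no ATOM/HETATM records in ", path)
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) elem[blank] <- substr(trimws(a$elety[blank]), 1, 1)
  structure_model(data.frame(
    serial = a$eleno, name = trimws(a$elety), element = trimws(elem),
    res_name = trimws(a$resid), res_seq = a$resno,
    chain_id = ifelse(is.na(a$chain), " ", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE
  ), metadata = list(source = path, format = "pdb"))
}

# Minimal mmCIF atom_site loop reader. Handles whitespace-delimited loop rows
# with optional single/double-quoted tokens; auth_* numbering preferred,
# label_* used as fallback.
.read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  cols <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_atom_site."))) {
        cols <- sub("^_atom_site\\.", "", tags)
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- .cif_tokens(lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("parse error: no _atom_site loop found in ", path)
  bad <- which(vapply(rows, length, 1L) != length(cols))
  if (length(bad))
    stop("parse error in ", path, ": atom_site row ", bad[1],
         " has ", length(rows[[bad[1]]]), " fields, expected ", length(cols))
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  pick <- function(a, b) if (a %in% cols) m[, a] else if (b %in% cols) m[, b]
    else stop("parse error: mmCIF lacks both ", a, " and ", b)
  num <- function(x) as.numeric(x)
  structure_model(data.frame(
    serial = as.integer(m[, "id"]),
    name = pick("auth_atom_id", "label_atom_id"),
    element = pick("type_symbol", "type_symbol"),
    res_name = pick("auth_comp_id", "label_comp_id"),
    res_seq = as.integer(pick("auth_seq_id", "label_seq_id")),
    chain_id = pick("auth_asym_id", "label_asym_id"),
    x = num(m[, "Cartn_x"]), y = num(m[, "Cartn_y"]), z = num(m[, "Cartn_z"]),
    occupancy = if ("occupancy" %in% cols) num(m[, "occupancy"]) else 1,
    b_factor = if ("B_iso_or_equiv" %in% cols) num(m[, "B_iso_or_equiv"]) else 0,
    stringsAsFactors = FALSE
  ), metadata = list(source = path, format = "mmcif"))
}

.cif_tokens <- function(line) {
  out <- character(); s <- trimws(line)
  while (nzchar(s)) {
    ch <- substr(s, 1, 1)
    if (ch %in% c("'", '"')) {
      end <- regexpr(paste0(ch, "(\\s|$)"), substr(s, 2, nchar(s)))
      if (end < 0) stop("parse error: unterminated quote in mmCIF row")
      out <- c(out, substr(s, 2, end))
      s <- trimws(substr(s, end + 2, nchar(s)))
    } else {
      sp <- regexpr("\\s", s)
      if (sp < 0) { out <- c(out, s); s <- "" }
      else { out <- c(out, substr(s, 1, sp - 1)); s <- trimws(substr(s, sp, nchar(s)))}
    }
  }
  out
}

#' Write an atomic structure model (PDB or mmCIF)
#'
#' The written file round-trips through \code{\link{read_structure}} with
#' coordinates preserved to 0.001 Angstrom and chain order intact. PDB output
#' enforces the fixed-column limits of the format (single-character chain
#' ids, coordinates within the 8.3 field); models that exceed them must be
#' written as mmCIF.
#'
#' @param model a \code{structure_model}
#' @param path output file path
#' @param format \code{"pdb"} or \code{"mmcif"} (default: from extension)
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  a <- model$atoms
  if (nrow(a) == 0) stop("write_structure: empty model")
  if (format == "pdb") {
    if (any(nchar(a$chain_id) > 1))
      stop("write_structure: chain ids longer than one character cannot be ",
           "written as PDB; use format = 'mmcif'")
    if (any(abs(c(a$x, a$y, a$z)) >= 10000) || any(c(a$x, a$y, a$z) <= -1000))
      stop("write_structure: coordinates overflow PDB fixed columns; ",
           "use format = 'mmcif'")
    bio3d::write.pdb(pdb = NULL, file = path, xyz = as.vector(t(atom_xyz(a))),
                     resno = a$res_seq, resid = a$res_name, eleno = a$serial,
                     elety = a$name, chain = a$chain_id, o = a$occupancy,
                     b = a$b_factor, elesy = a$element)
  } else {
    .write_mmcif(model, path)
  }
  invisible(path)
}

.write_mmcif <- function(model, path) {
  a <- model$atoms
  q <- function(x) ifelse(grepl("\\s|^$", x), paste0("'", x, "'"), x)
  rows <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f %s %d %s",
                  a$serial, q(a$element), q(a$name), q(a$res_name), q(a$chain_id),
                  a$res_seq, a$x, a$y, a$z, a$occupancy, a$b_factor,
                  q(a$chain_id), a$res_seq, q(a$name))
  title <- if (!is.null(model$metadata$title)) model$metadata$title else "mtlattice model"
  writeLines(c(
    "data_mtlattice",
    paste0("_struct.title '", title, "'"),
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_comp_id", "label_asym_id", "label_seq_id",
                            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                            "B_iso_or_equiv", "auth_asym_id", "auth_seq_id",
                            "auth_atom_id")),
    rows,
    "#"), path)
  invisible(path)
}
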