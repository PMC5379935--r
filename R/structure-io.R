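#' @keywords internal
"_PACKAGE"

# ---- structure_model container ------------------------------------------

#' Construct a structure model
#'
#' A `structure_model` is the coordinate container used throughout the
#' package: a flat atom table (one row per atom) plus an optional unit cell
#' and a title. Atoms are ordered by chain, then residue number, mirroring
#' the record order of a PDB file.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elt`, `alt`,
#'   `resn`, `chain`, `resi`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `u11`,`u22`,`u33`,`u12`,`u13`,`u23` (NA when no anisotropic ADPs) and
#'   logical `het`.
#' @param cell optional unit cell from [unit_cell()].
#' @param title character title.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, title = "") {
  req <- c("serial", "name", "elt", "alt", "resn", "chain", "resi", "icode",
           "x", "y", "z", "occ", "b",
           "u11", "u22", "u33", "u12", "u13", "u23", "het")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stop("atoms table missing columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
      stop("occupancies must lie in [0, 1]")
    key <- paste(atoms$chain, atoms$resi, atoms$icode, atoms$name, atoms$alt)
    if (anyDuplicated(key))
      stop("duplicate atom identifier: ", key[which(duplicated(key))[1]])
    has_u <- !is.na(atoms$u11)
    if (any(has_u) &&
        any(atoms$u11[has_u] <= 0 | atoms$u22[has_u] <= 0 |
            atoms$u33[has_u] <= 0))
      stop("anisotropic U diagonal elements must be positive")
  }
  structure(list(atoms = atoms, cell = cell, title = title),
            class = "structure_model")
}

#' Unit cell parameters
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @param space_group space-group symbol string.
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      space_group = "P 1") {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) stop("cell angles must lie in (0, 180)")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, space_group = space_group),
            class = "unit_cell")
}

empty_atoms <- function(n = 0) {
  data.frame(serial = integer(n), name = character(n), elt = character(n),
             alt = character(n), resn = character(n), chain = character(n),
             resi = integer(n), icode = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             occ = numeric(n), b = numeric(n),
             u11 = rep(NA_real_, n), u22 = rep(NA_real_, n),
             u33 = rep(NA_real_, n), u12 = rep(NA_real_, n),
             u13 = rep(NA_real_, n), u23 = rep(NA_real_, n),
             het = logical(n), stringsAsFactors = FALSE)
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  cat("structure_model: ", nrow(at), " atoms, ",
      length(unique(at$chain)), " chain(s)",
      if (!is.null(x$cell)) " [unit cell present]" else "", "\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#' @param model a `structure_model`.
#' @return numeric n x 3 matrix of orthogonal coordinates (Angstrom).
#' @export
xyz_matrix <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

set_xyz <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# ---- reading -------------------------------------------------------------

num_field <- function(lines, from, to, what, lineno) {
  s <- trimws(substr(lines, from, to))
  v <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(v) & nzchar(s) | !nzchar(s))
  if (length(bad) > 0)
    stop("cannot parse ", what, " on line ", lineno[bad[1]])
  v
}

parse_cryst1 <- function(line) {
  unit_cell(a = as.numeric(substr(line, 7, 15)),
            b = as.numeric(substr(line, 16, 24)),
            c = as.numeric(substr(line, 25, 33)),
            alpha = as.numeric(substr(line, 34, 40)),
            beta  = as.numeric(substr(line, 41, 47)),
            gamma = as.numeric(substr(line, 48, 54)),
            space_group = trimws(substr(line, 56, 66)))
}

#' Read a macromolecular structure in PDB format
#'
#' Parses ATOM/HETATM records (via the bio3d reader), merges ANISOU records
#' onto their atoms using the standard 1e-4 Angstrom^2 integer scale, and maps
#' a CRYST1 record to a [unit_cell()]. For multi-model files a single model is
#' returned (`model_index`, default 1).
#'
#' Alternate-location handling: by default only the highest-occupancy
#' conformer of each alternate group is kept (ties broken by alt-loc
#' identifier); `keep_alt = TRUE` retains all conformers.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number to extract.
#' @param keep_alt keep all alternate-location conformers?
#' @return a [structure_model()].
#' @export
read_structure <- function(path, model_index = 1, keep_alt = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_at <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_at)) stop("no ATOM/HETATM records in ", path)
  lineno <- which(is_at)
  al <- lines[is_at]
  short <- which(nchar(al) < 54)
  if (length(short) > 0)
    stop("malformed fixed-width ATOM/HETATM record (line ",
         lineno[short[1]], "): too short")
  # validate the numeric fields up front so errors carry line numbers
  num_field(al, 31, 38, "x coordinate", lineno)
  num_field(al, 39, 46, "y coordinate", lineno)
  num_field(al, 47, 54, "z coordinate", lineno)

  n_models <- max(1L, sum(rec == "MODEL "))
  if (model_index < 1 || model_index > n_models)
    stop("model ", model_index, " not found (file has ", n_models, " model",
         if (n_models > 1) "s", ")")

  pdb <- bio3d::read.pdb(path, multi = n_models > 1, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  xyz <- if (n_models > 1) {
    matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  } else {
    cbind(at$x, at$y, at$z)
  }

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    elt = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                 guess_element(at$elety), trimws(at$elesy)),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    resn = as.character(at$resid),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resi = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)

  # ANISOU records: integer U_ij * 1e4, matched to atoms by serial number
  ani <- lines[rec == "ANISOU"]
  if (length(ani) > 0) {
    aserial <- as.integer(substr(ani, 7, 11))
    u <- sapply(0:5, function(k)
      as.numeric(substr(ani, 29 + 7 * k, 35 + 7 * k))) * 1e-4
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    idx <- match(aserial, atoms$serial)
    ok <- !is.na(idx)
    atoms[idx[ok], c("u11", "u22", "u33", "u12", "u13", "u23")] <-
      u[ok, , drop = FALSE]
  }

  if (!keep_alt && any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resi, atoms$icode, atoms$name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                          function(i) {
                            if (length(i) == 1) return(i)
                            i[order(-atoms$occ[i], atoms$alt[i])][1]
                          }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    atoms$alt <- ""
    rownames(atoms) <- NULL
  }

  cell <- NULL
  ic <- which(rec == "CRYST1")
  if (length(ic) > 0) cell <- parse_cryst1(lines[ic[1]])
  title <- trimws(paste(substr(lines[rec == "TITLE "], 11, 80),
                        collapse = " "))
  structure_model(atoms, cell = cell, title = title)
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(nm) == 2, two, substr(nm, 1, 1))
}

# ---- writing -------------------------------------------------------------

#' Write a structure model in PDB format
#'
#' Emits CRYST1 (when a cell is present), ATOM/HETATM records, and an ANISOU
#' record after every atom carrying an anisotropic ADP tensor (integer values
#' `round(U * 1e4)`). Coordinates are written to 3 decimals and
#' occupancy/B-factor to 2 decimals, so `read_structure(write_structure(m))`
#' reproduces those fields to that precision.
#'
#' @param model a [structure_model()]; must contain at least one atom.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (any(nchar(at$chain) > 1))
    stop("chain identifiers longer than one character cannot be encoded")
  if (any(nchar(at$resn) > 3))
    stop("residue names longer than three characters cannot be encoded")
  if (any(at$resi < -999 | at$resi > 9999))
    stop("residue numbers outside [-999, 9999] cannot be encoded")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$cell)) {
    cl <- model$cell
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                       cl$space_group), con)
  }
  pad_name <- function(nm, elt) {
    # element symbol occupies columns 13-14; 1-letter elements start col 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           ifelse(nchar(elt) == 2, sprintf("%-4s", nm),
                  sprintf(" %-3s", nm)))
  }
  rectype <- ifelse(at$het, "HETATM", "ATOM  ")
  alt <- ifelse(nzchar(at$alt), at$alt, " ")
  ico <- ifelse(nzchar(at$icode), at$icode, " ")
  main <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  rectype, at$serial %% 100000L, pad_name(at$name, at$elt),
                  alt, at$resn, at$chain, at$resi, ico,
                  at$x, at$y, at$z, at$occ, at$b,
                  formatC(at$elt, width = 2, flag = " "))
  has_u <- !is.na(at$u11)
  if (any(has_u)) {
    au <- at[has_u, , drop = FALSE]
    ui <- round(as.matrix(au[, c("u11", "u22", "u33",
                                 "u12", "u13", "u23")]) * 1e4)
    alines <- sprintf("ANISOU%5d %s%1s%3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
                      au$serial %% 100000L, pad_name(au$name, au$elt),
                      alt[has_u], au$resn, au$chain, au$resi, ico[has_u],
                      ui[, 1], ui[, 2], ui[, 3], ui[, 4], ui[, 5], ui[, 6],
                      formatC(au$elt, width = 2, flag = " "))
    # interleave: each ANISOU directly follows its atom record
    out <- character(nrow(at) + nrow(au))
    pos <- seq_len(nrow(at)) + cumsum(has_u) - has_u
    out[pos] <- main
    out[pos[has_u] + 1] <- alines
    writeLines(out, con)
  } else {
    writeLines(main, con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- symmetry expansion --------------------------------------------------

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

chain_label_pool <- c(LETTERS, letters, as.character(0:9))

#' Expand a model by pure rotational (cyclic) symmetry
#'
#' Places `fold` copies of the input, rotated by k*360/fold degrees
#' (k = 0..fold-1) about the given axis through `origin`. Chains of the
#' rotated copies are relabelled with the next unused single-character
#' labels; atom serial numbers are renumbered sequentially.
#'
#' @param model a [structure_model()].
#' @param fold integer symmetry order (>= 1).
#' @param axis rotation axis 3-vector (default z).
#' @param origin point on the axis (default origin).
#' @return a [structure_model()] with `fold` times the input atom count.
#' @export
expand_rotational_symmetry <- function(model, fold, axis = c(0, 0, 1),
                                       origin = c(0, 0, 0)) {
  stopifnot(fold >= 1)
  if (sum(axis^2) == 0) stop("rotation axis must be nonzero")
  if (fold == 1) return(model)
  ch0 <- unique(model$atoms$chain)
  needed <- length(ch0) * fold
  if (needed > length(chain_label_pool))
    stop("chain-label exhaustion: need ", needed, " labels")
  avail <- setdiff(chain_label_pool, ch0)
  xyz <- xyz_matrix(model)
  out <- vector("list", fold)
  out[[1]] <- model$atoms
  used <- 0
  for (k in seq_len(fold - 1)) {
    R <- rotation_about_axis(axis, 360 * k / fold)
    new_xyz <- sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
    ak <- model$atoms
    ak$x <- new_xyz[, 1]; ak$y <- new_xyz[, 2]; ak$z <- new_xyz[, 3]
    relab <- avail[used + seq_along(ch0)]
    used <- used + length(ch0)
    ak$chain <- relab[match(ak$chain, ch0)]
    out[[k + 1]] <- ak
  }
  atoms <- do.call(rbind, out)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure_model(atoms, cell = model$cell, title = model$title)
}

# ---- selection -----------------------------------------------------------

#' Atom selection descriptor
#'
#' Bundles the selection criteria understood by [select_atoms()]:
#' a chain list, an inclusive residue-number range, an atom-name set,
#' a het/polymer class, and the named presets `"main-chain"`
#' (atoms N, CA, C, O of polymer residues) and `"CA"`.
#'
#' @param chains character vector of chain identifiers, or NULL for all.
#' @param resi_range length-2 numeric `c(first, last)` residue range, or NULL.
#' @param names atom-name set, or NULL.
#' @param resn residue-name set, or NULL.
#' @param class one of `"all"`, `"polymer"`, `"het"`.
#' @param preset NULL, `"main-chain"` or `"CA"`.
#' @return an `atom_selection` object.
#' @export
atom_selection <- function(chains = NULL, resi_range = NULL, names = NULL,
                           resn = NULL, class = c("all", "polymer", "het"),
                           preset = NULL) {
  class <- match.arg(class)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("main-chain", "CA"))
    names <- if (preset == "CA") "CA" else c("N", "CA", "C", "O")
    if (class == "all") class <- "polymer"
  }
  structure(list(chains = chains, resi_range = resi_range, names = names,
                 resn = resn, class = class), class = "atom_selection")
}

#' Select a subset of atoms
#'
#' Applies an [atom_selection()] (or criteria given directly through `...`)
#' to a model, preserving atom order and all parent identifiers. Selection is
#' idempotent. An empty result is returned as an empty model carrying an
#' `empty_selection` attribute, with a warning.
#'
#' @param model a [structure_model()].
#' @param sel an [atom_selection()], or NULL to build one from `...`.
#' @param ... passed to [atom_selection()] when `sel` is NULL.
#' @return a [structure_model()] subset.
#' @export
select_atoms <- function(model, sel = NULL, ...) {
  if (is.null(sel)) sel <- atom_selection(...)
  stopifnot(inherits(sel, "atom_selection"))
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chains)) keep <- keep & at$chain %in% sel$chains
  if (!is.null(sel$resi_range))
    keep <- keep & at$resi >= sel$resi_range[1] & at$resi <= sel$resi_range[2]
  if (!is.null(sel$names)) keep <- keep & at$name %in% sel$names
  if (!is.null(sel$resn)) keep <- keep & at$resn %in% sel$resn
  if (sel$class == "polymer") keep <- keep & !at$het
  if (sel$class == "het") keep <- keep & at$het
  sub <- at[keep, , drop = FALSE]
  rownames(sub) <- NULL
  out <- structure_model(sub, cell = model$cell, title = model$title)
  if (nrow(sub) == 0) {
    warning("selection matched no atoms")
    attr(out, "empty_selection") <- TRUE
  }
  out
}
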