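# Structure containers and multi-model PDB/mmCIF input/output.
#
# A StructureModel is one conformer: an ordered atom table plus free-form
# metadata. Parsing of the standard formats is delegated to bio3d; this layer
# adds the per-model bookkeeping and the strict validity checks the ensemble
# pipeline relies on (unique atom keys, finite coordinates, no insertion
# codes).

#' Create a structure model
#'
#' Builds the atomic container used throughout the package: one conformer of
#' a (possibly multi-chain) molecule, with atoms in file order.
#'
#' @param model_id Unique identifier, conventionally
#'   `"<source>#<model index>"` for models read from multi-model files.
#' @param atoms A `data.frame` with columns `chain_id`, `res_seq` (integer
#'   author numbering), `res_name`, `atom_name`, `element`, `x`, `y`, `z`,
#'   and optionally `het` (logical, HETATM record). Row order is atom order.
#' @param meta Named list of free annotations (e.g. quality score, the
#'   synthetic generator's ground-truth progress).
#'
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(model_id, atoms, meta = list()) {
  check_that(is.character(model_id) && length(model_id) == 1L && nzchar(model_id),
             "model_id must be a non-empty string")
  needed <- c("chain_id", "res_seq", "res_name", "atom_name", "element",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  check_that(length(missing_cols) == 0L,
             "atoms is missing column(s): %s", paste(missing_cols, collapse = ", "))
  check_that(nrow(atoms) >= 1L, "a StructureModel needs at least one atom")
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$element <- toupper(as.character(atoms$element))
  if (is.null(atoms$het)) atoms$het <- FALSE
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  check_that(all(is.finite(coords)), "model '%s': non-finite coordinates", model_id)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$atom_name, sep = "|")
  dup <- key[duplicated(key)]
  check_that(length(dup) == 0L,
             "model '%s': duplicate atom key(s): %s",
             model_id, paste(unique(dup), collapse = "; "))
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms, meta = meta),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- table(x$atoms$chain_id)
  cat(sprintf("StructureModel '%s': %d atoms, %d chain(s) [%s], %d HETATM\n",
              x$model_id, nrow(x$atoms), length(ch),
              paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
              sum(x$atoms$het)))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coordinates of a model (or atom table) as an n x 3 matrix
#'
#' @param x A `StructureModel` or an atom `data.frame` with `x`, `y`, `z`.
#' @return Numeric matrix with one row per atom.
#' @export
coords <- function(x) {
  atoms <- if (inherits(x, "StructureModel")) x$atoms else x
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a model
#'
#' @param model A `StructureModel`.
#' @param xyz Numeric n x 3 matrix matching the model's atom count.
#' @return The model with updated coordinates.
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  check_that(nrow(xyz) == nrow(model$atoms) && ncol(xyz) == 3L,
             "coordinate matrix must be %d x 3", nrow(model$atoms))
  check_that(all(is.finite(xyz)), "non-finite coordinates")
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# Pre-scan of a PDB file: line-numbered errors for records bio3d would
# silently tolerate, and rejection of insertion codes (the transporter
# ensembles this package targets use plain author numbering).
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop(sprintf("read error at line %d of '%s': truncated atom record", i, path),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop(sprintf("read error at line %d of '%s': unparsable coordinates", i, path),
           call. = FALSE)
    }
    if (substr(ln, 27, 27) != " ") {
      stop(sprintf("read error at line %d of '%s': insertion codes are not supported",
                   i, path), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# altloc policy: keep the highest-occupancy conformer, ties resolved by file
# order; the choice is reported via message() so pipeline logs record it.
# Returns a logical keep-vector over atom rows.
altloc_keep <- function(atom, path) {
  keep <- rep(TRUE, nrow(atom))
  if (is.null(atom$alt)) return(keep)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(keep)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$elety, sep = "|")
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      best <- idx[which.max(occ[idx])]  # ties -> first in file
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  if (any(!keep)) {
    message(sprintf("'%s': kept highest-occupancy altloc for %d atom site(s)",
                    path, sum(!keep)))
  }
  keep
}

#' Read structural models from a PDB or mmCIF file
#'
#' Reads every model of a (multi-model) structure file into a list of
#' [structure_model()] objects. `MODEL`/`ENDMDL` blocks delimit models;
#' single-model files yield a list of length one. HETATM records are kept
#' with their residue names. Duplicate atom keys within a model, insertion
#' codes, and unparsable atom records are errors, not warnings.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`. Defaults from the file extension.
#' @return List of `StructureModel`, ids `"<basename>#<i>"`.
#' @export
read_models <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  check_that(file.exists(path), "file not found: '%s'", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") {
    validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  } else {
    pdb <- bio3d::read.cif(path, verbose = FALSE)
  }
  keep <- altloc_keep(pdb$atom, path)
  atom <- pdb$atom[keep, , drop = FALSE]
  # bio3d stores multi-model coordinates as rows of the xyz matrix
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!all(keep)) {
    xyz <- xyz[, rep(keep, each = 3L), drop = FALSE]
  }
  check_that(ncol(xyz) == 3L * nrow(atom),
             "'%s': coordinate/atom bookkeeping mismatch", path)
  base <- basename(path)
  elem <- atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    # element column absent: fall back to bio3d's atom-name based typing
    elem <- bio3d::atom2ele(atom$elety)
  }
  elem <- trimws(elem)
  out <- vector("list", nrow(xyz))
  for (m in seq_len(nrow(xyz))) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    atoms <- data.frame(
      chain_id = as.character(atom$chain),
      res_seq = as.integer(atom$resno),
      res_name = as.character(atom$resid),
      atom_name = as.character(atom$elety),
      element = elem,
      x = co[, 1L], y = co[, 2L], z = co[, 3L],
      het = atom$type == "HETATM",
      stringsAsFactors = FALSE
    )
    out[[m]] <- structure_model(sprintf("%s#%d", base, m), atoms)
  }
  out
}

#' Write models to a multi-model PDB file
#'
#' Inverse of [read_models()]: writes each model between `MODEL`/`ENDMDL`
#' records at standard PDB coordinate precision (1e-3 Angstrom). All models
#' must share the same atom table.
#'
#' @param models A `StructureModel` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "StructureModel")) models <- list(models)
  check_that(length(models) >= 1L, "no models to write")
  ref <- models[[1L]]$atoms
  xyz <- matrix(0, nrow = length(models), ncol = 3L * nrow(ref))
  for (m in seq_along(models)) {
    a <- models[[m]]$atoms
    check_that(nrow(a) == nrow(ref) &&
                 all(a$chain_id == ref$chain_id) &&
                 all(a$res_seq == ref$res_seq) &&
                 all(a$atom_name == ref$atom_name),
               "model %d does not share the atom table of model 1", m)
    xyz[m, ] <- as.vector(t(coords(a)))
  }
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(ref$het, "HETATM", "ATOM"),
    resno = ref$res_seq,
    resid = ref$res_name,
    eleno = seq_len(nrow(ref)),
    elety = ref$atom_name,
    chain = ref$chain_id,
    elesy = ref$element
  )
  if (any(ref$het)) {
    # bio3d's writer applies the record type only to single-model output;
    # restore HETATM records positionally across every MODEL block
    lines <- readLines(path, warn = FALSE)
    rec_rows <- which(substr(lines, 1L, 6L) %in% c("ATOM  ", "HETATM"))
    pos_in_model <- ((seq_along(rec_rows) - 1L) %% nrow(ref)) + 1L
    fix <- rec_rows[ref$het[pos_in_model]]
    substr(lines[fix], 1L, 6L) <- "HETATM"
    writeLines(lines, path)
  }
  invisible(path)
}
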