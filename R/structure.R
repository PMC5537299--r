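# Coordinate container and PDB input/output.

#' Structure model
#'
#' A flat atom table: one row per atom with chain id, author residue
#' number, 3-letter residue type, atom name, element and Cartesian
#' coordinates in Angstrom.  This is the coordinate currency of the
#' geometry, SASA and ranking functions.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `restype`,
#'   `atom`, `elem`, `x`, `y`, `z`.
#' @param model_id Identifier (integer or text).
#' @return Object of class `structure_model` (a data.frame with a
#'   `model_id` attribute).
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("chain", "resno", "restype", "atom", "elem", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    stop("atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) entries: ",
         key[duplicated(key)][1])
  }
  atoms <- atoms[, need]
  attr(atoms, "model_id") <- model_id
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> id %s: %d atoms, chains %s, residues %d-%d\n",
              format(attr(x, "model_id")), nrow(x),
              paste(sort(unique(x$chain)), collapse = ","),
              min(x$resno), max(x$resno)))
  invisible(x)
}

.coords <- function(model) as.matrix(model[, c("x", "y", "z")])

.elem_from_atom <- function(atom) {
  # first alphabetic character of the (stripped) atom name
  toupper(substr(gsub("[^A-Za-z]", "", atom), 1, 1))
}

#' Select a chain (and optionally a residue range) from a model
#'
#' @param model A [structure_model()].
#' @param chain Chain id.
#' @param range Optional `c(first, last)` residue numbers (inclusive).
#' @return A [structure_model()].
#' @export
select_chain <- function(model, chain, range = NULL) {
  keep <- model$chain == chain
  if (!is.null(range)) {
    keep <- keep & model$resno >= range[1] & model$resno <= range[2]
  }
  if (!any(keep)) {
    stop(sprintf("no atoms for chain '%s'%s", chain,
                 if (is.null(range)) "" else
                   sprintf(" in residue range %d-%d", range[1], range[2])))
  }
  out <- model[keep, , drop = FALSE]
  attr(out, "model_id") <- attr(model, "model_id")
  class(out) <- c("structure_model", "data.frame")
  out
}

#' Read PDB coordinate models
#'
#' Reads ATOM records of a (possibly multi-MODEL) PDB file via
#' `bio3d::read.pdb` and returns one [structure_model()] per MODEL.
#'
#' @param path PDB file.
#' @return list of [structure_model()]s (length 1 for single-model files).
#' @export
read_pdb_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  idx <- which(pdb$atom$type == "ATOM")
  lapply(seq_len(n_models), function(m) {
    cm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- .elem_from_atom(at$elety)
    } else {
      blank <- is.na(elem) | elem == ""
      elem[blank] <- .elem_from_atom(at$elety[blank])
    }
    chain <- at$chain
    chain[is.na(chain) | chain == ""] <- "A"
    structure_model(
      data.frame(chain = chain, resno = at$resno, restype = at$resid,
                 atom = at$elety, elem = toupper(trimws(elem)),
                 x = cm[, 1], y = cm[, 2], z = cm[, 3],
                 stringsAsFactors = FALSE),
      model_id = m)
  })
}

#' Write models to a PDB file
#'
#' Writes one or more [structure_model()]s as a (multi-)MODEL PDB file with
#' plain ATOM records.  The write is atomic: output goes to a temporary
#' file in the target directory which is then renamed into place.
#'
#' @param models A [structure_model()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  multi <- length(models) > 1L
  lines <- character(0)
  for (m in seq_along(models)) {
    mod <- models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    rec <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(mod)) %% 100000L,
      ifelse(nchar(mod$atom) < 4, paste0(" ", mod$atom), mod$atom),
      mod$restype, mod$chain, mod$resno, mod$x, mod$y, mod$z, 1, 0,
      mod$elem)
    lines <- c(lines, rec, "TER")
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".pdb")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
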