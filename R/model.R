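#' Atomic models as atom-level tibbles
#'
#' An `atomic_model` is a tibble with one row per atom and columns
#' `chain`, `resi`, `icode`, `resname`, `atom`, `element`, `x`, `y`, `z`,
#' `occ`, `bfield`, `altloc`.  Coordinates are orthogonal Angstroms in the
#' model frame; `bfield` carries the B-factor column, which for prediction
#' files holds the per-residue confidence estimate (e.g. pLDDT).  The class
#' is deliberately light: a model is still a data frame and can be piped
#' through dplyr verbs; analysis functions re-validate what they need.
#'
#' @param atoms Data frame with the columns listed above.
#' @param model_id Identifier string.
#' @param provenance `"target"` or `"prediction"`.
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms, model_id = "model", provenance = "target") {
  need <- c("chain", "resi", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ", "bfield", "altloc")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atomic_model: missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- tibble::as_tibble(atoms)[, need]
  if (nrow(atoms) == 0L) abort("atomic_model: empty model")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atomic_model: non-finite coordinates")
  }
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  bad_occ <- atoms$occ < 0 | atoms$occ > 1
  if (any(bad_occ)) {
    warn("atomic_model: occupancies outside [0, 1] clamped")
    atoms$occ <- pmin(pmax(atoms$occ, 0), 1)
  }
  # a residue key must name a single residue type
  key <- res_key(atoms$chain, atoms$resi, atoms$icode)
  n_names <- tapply(atoms$resname, key, function(r) length(unique(r)))
  if (any(n_names > 1L)) {
    abort(paste0("atomic_model: duplicate residue key(s) with conflicting ",
                 "residue names: ",
                 paste(head(names(n_names)[n_names > 1L], 3), collapse = ", ")))
  }
  structure(atoms,
            class = c("atomic_model", class(tibble::tibble())),
            model_id = model_id, provenance = provenance)
}

#' @export
print.atomic_model <- function(x, ...) {
  rs <- model_residues(x)
  cat(sprintf("<atomic_model '%s' (%s): %d atoms, %d residues, %d chain(s)>\n",
              attr(x, "model_id") %||% "?", attr(x, "provenance") %||% "?",
              nrow(x), nrow(rs), length(unique(x$chain))))
  NextMethod()
}

res_key <- function(chain, resi, icode) {
  paste(chain, resi, ifelse(is.na(icode), "", icode), sep = "|")
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE", "SEC", "PYL")
NUCLEIC <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI", "DU")

residue_kind <- function(resname) {
  dplyr::case_when(
    toupper(resname) %in% AMINO3  ~ "amino",
    toupper(resname) %in% NUCLEIC ~ "nucleic",
    TRUE ~ "other"
  )
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D", "T")

#' Keep the first alternate location of each atom
#'
#' Atoms with an empty altloc are always kept; where a (residue, atom name)
#' occurs with several altlocs, the alphabetically first is retained.
#'
#' @param model An [atomic_model()].
#' @return The model with at most one copy of each atom.
#' @export
select_altloc <- function(model) {
  model |>
    dplyr::group_by(.data$chain, .data$resi, .data$icode, .data$atom) |>
    dplyr::slice_min(.data$altloc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    restore_model(model)
}

#' Drop hydrogen (and deuterium) atoms
#' @param model An [atomic_model()].
#' @return The model without hydrogens.
#' @export
strip_hydrogens <- function(model) {
  restore_model(dplyr::filter(model, !is_hydrogen(.data$element)), model)
}

# scoring views: unique heavy atoms at first altloc
scoring_atoms <- function(model) {
  strip_hydrogens(select_altloc(model))
}

restore_model <- function(atoms, template) {
  atomic_model(atoms,
               model_id = attr(template, "model_id") %||% "model",
               provenance = attr(template, "provenance") %||% "target")
}

#' Per-residue summary of a model
#'
#' One row per residue, in file order, with the residue kind, whether its
#' representative atom (C-alpha for amino acids, C4' for nucleotides) is
#' present (`usable`), and the representative-atom coordinates and bfield.
#'
#' @param model An [atomic_model()].
#' @return Tibble with columns `chain`, `resi`, `icode`, `resname`, `kind`,
#'   `usable`, `x`, `y`, `z`, `bfield`.
#' @export
model_residues <- function(model) {
  m <- select_altloc(model)
  m$kind <- residue_kind(m$resname)
  m$rep <- (m$kind == "amino" & m$atom == "CA") |
    (m$kind == "nucleic" & m$atom == "C4'")
  m |>
    dplyr::group_by(.data$chain, .data$resi, .data$icode) |>
    dplyr::summarise(
      resname = .data$resname[1],
      kind = .data$kind[1],
      usable = any(.data$rep),
      x = if (any(.data$rep)) .data$x[.data$rep][1] else NA_real_,
      y = if (any(.data$rep)) .data$y[.data$rep][1] else NA_real_,
      z = if (any(.data$rep)) .data$z[.data$rep][1] else NA_real_,
      bfield = if (any(.data$rep)) .data$bfield[.data$rep][1] else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(match(res_key(.data$chain, .data$resi, .data$icode),
                         unique(res_key(model$chain, model$resi, model$icode))))
}

model_coords <- function(model) {
  cbind(model$x, model$y, model$z)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Author chain identifiers and residue numbering are preserved; the
#' B-factor / isotropic-displacement column populates `bfield`.  All altlocs
#' are kept in the returned tibble; analyses select the first altloc.
#' Residues lacking their representative atom load fine and are flagged
#' `usable = FALSE` by [model_residues()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param model_id,provenance Stored as attributes.
#' @return An [atomic_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif"),
                       model_id = NULL, provenance = "prediction") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("read_model: no such file: ", path),
                                class = "cryofit_input_missing")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) abort(paste0("read_model: cannot parse '", path,
                                     "': ", conditionMessage(e)),
                              class = "cryofit_parse_error")
  )
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) {
    abort(paste0("read_model: empty model in ", path),
          class = "cryofit_parse_error")
  }
  elem <- a$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- ifelse(is.na(elem) | elem == "",
                 substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1), elem)
  atoms <- tibble::tibble(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resi = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = a$resid,
    atom = a$elety,
    element = toupper(trimws(elem)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    bfield = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt)
  )
  atomic_model(atoms,
               model_id = model_id %||% sub("\\.[^.]*$", "", basename(path)),
               provenance = provenance)
}

#' Write an atomic model as PDB
#'
#' Thin wrapper around [bio3d::write.pdb()]; used by the synthetic-data
#' command line to emit ground-truth structures.
#'
#' @param model An [atomic_model()].
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model_coords(model))),
    resno = model$resi, chain = ifelse(model$chain == "", " ", model$chain),
    insert = ifelse(model$icode == "", "", model$icode),
    resid = model$resname, elety = model$atom, elesy = model$element,
    o = model$occ, b = model$bfield
  )
  invisible(path)
}

# Apply a rigid transform (rotation matrix R, translation t) to coordinates.
apply_transform <- function(xyz, rot, trans) {
  sweep(xyz %*% rot, 2, trans, "+")
}

transform_model <- function(model, rot, trans) {
  xyz <- apply_transform(model_coords(model), rot, trans)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}
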