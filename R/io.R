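#' Read a QM-summary file into molecule records
#'
#' The QM-summary format is a JSON document holding a top-level array of
#' molecule objects:
#' \preformatted{
#' [{"name": "...", "theory": "...",
#'   "energies": {"neutral": -51573.56, "anion": null, "cation": null,
#'                "homo": -5.49, "lumo": -1.70, "unit": "eV"},
#'   "thermo":   {"zpe": ..., "enthalpy": ..., "free_energy": ...,
#'                "heat_capacity": ..., "entropy": ..., "temperature": 298.15},
#'   "dipole": 5.18, "smiles": "...",
#'   "charges": [{"atom_index": 1, "element": "O",
#'                "q_neutral": -0.066, "q_anion": -0.115, "q_cation": -0.024},
#'               ...]}]
#' }
#' `energies.unit` may be `"eV"` (default) or `"hartree"`; hartree inputs are
#' converted through [unit_constants]. `thermo`, `dipole`, `smiles` and
#' `charges` are optional. Every record is validated on read; violations are
#' reported with the molecule name and offending field.
#'
#' @param path Path to a QM-summary JSON file.
#' @param charge_tol Passed to [validate_molecule_record()].
#' @return A list of [molecule_record()] objects (empty list for an empty
#'   molecule array).
#' @seealso [write_qm_summary()], [read_charge_table()]
#' @export
read_qm_summary <- function(path, charge_tol = 0.02) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("read_qm_summary: cannot parse '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (!is.list(raw)) {
    stop("read_qm_summary: top level must be an array of molecule objects",
         call. = FALSE)
  }
  lapply(raw, function(m) {
    for (f in c("name", "theory", "energies")) {
      if (is.null(m[[f]])) {
        stop(sprintf("read_qm_summary: molecule '%s' missing field '%s'",
                     if (is.null(m$name)) "<unnamed>" else m$name, f),
             call. = FALSE)
      }
    }
    en <- m$energies
    unit <- if (is.null(en$unit)) "eV" else en$unit
    conv <- switch(tolower(unit),
                   "ev" = identity, "hartree" = hartree_to_ev, "ha" = hartree_to_ev,
                   stop(sprintf("read_qm_summary: molecule '%s': unknown energy unit '%s'",
                                m$name, unit), call. = FALSE))
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    thermo <- NULL
    if (!is.null(m$thermo)) {
      th <- m$thermo
      thermo <- thermo_record(
        zpe = num(th$zpe), enthalpy = num(th$enthalpy),
        free_energy = num(th$free_energy),
        heat_capacity = num(th$heat_capacity), entropy = num(th$entropy),
        temperature = if (is.null(th$temperature))
          unit_constants[["t_standard"]] else num(th$temperature)
      )
    }
    charges <- NULL
    if (!is.null(m$charges) && length(m$charges) > 0) {
      rows <- m$charges
      charges <- charge_table(
        atom_index = vapply(rows, function(r) as.integer(r$atom_index), 1L),
        element = vapply(rows, function(r) as.character(r$element), ""),
        q_neutral = vapply(rows, function(r) as.numeric(r$q_neutral), 1.0),
        q_anion = vapply(rows, function(r) as.numeric(r$q_anion), 1.0),
        q_cation = vapply(rows, function(r) as.numeric(r$q_cation), 1.0)
      )
    }
    rec <- molecule_record(
      name = m$name, theory = m$theory,
      e_neutral = conv(num(en$neutral)), e_anion = conv(num(en$anion)),
      e_cation = conv(num(en$cation)),
      e_homo = conv(num(en$homo)), e_lumo = conv(num(en$lumo)),
      charges = charges, thermo = thermo,
      dipole = num(m$dipole),
      smiles = if (is.null(m$smiles)) NA_character_ else m$smiles
    )
    validate_molecule_record(rec, charge_tol = charge_tol)
  })
}

#' Write molecule records to a QM-summary file
#'
#' Serialization is deterministic (stable key order, full precision) so that
#' `read_qm_summary(write_qm_summary(x))` reproduces `x` field for field.
#'
#' @param records List of [molecule_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qm_summary <- function(records, path) {
  if (inherits(records, "molecule_record")) records <- list(records)
  out <- lapply(records, function(rec) {
    m <- list(
      name = rec$name, theory = rec$theory,
      energies = list(neutral = rec$e_neutral, anion = rec$e_anion,
                      cation = rec$e_cation, homo = rec$e_homo,
                      lumo = rec$e_lumo, unit = "eV")
    )
    if (!is.null(rec$thermo)) m$thermo <- unclass(rec$thermo)
    if (!is.na(rec$dipole)) m$dipole <- rec$dipole
    if (!is.na(rec$smiles)) m$smiles <- rec$smiles
    if (!is.null(rec$charges)) {
      ch <- rec$charges
      m$charges <- lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ]))
    }
    m
  })
  # digits = I(17): doubles round-trip bit-exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write a three-state charge table (TSV)
#'
#' Tab-separated with header columns `atom_index`, `element`, `q_neutral`,
#' `q_anion`, `q_cation`, one row per atom in table order.
#'
#' @param path Path to a TSV file.
#' @return [read_charge_table()]: a [charge_table()] tibble.
#' @export
read_charge_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("atom_index", "element", "q_neutral", "q_anion", "q_cation")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_charge_table: '%s' must have columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  }
  charge_table(df$atom_index, df$element, df$q_neutral, df$q_anion, df$q_cation)
}

#' @rdname read_charge_table
#' @param tbl A [charge_table()].
#' @export
write_charge_table <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl)[, c("atom_index", "element",
                                            "q_neutral", "q_anion", "q_cation")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a charge table to a named record in a record list
#'
#' @param records List of [molecule_record()].
#' @param name Name of the record to attach to.
#' @param charges A [charge_table()].
#' @param charge_tol Validation tolerance on the charge sums.
#' @return The record list with the charges attached and re-validated.
#' @export
attach_charges <- function(records, name, charges, charge_tol = 0.02) {
  idx <- which(vapply(records, function(r) r$name, "") == name)
  if (length(idx) != 1L) {
    stop(sprintf("attach_charges: record '%s' not found (or not unique)", name),
         call. = FALSE)
  }
  records[[idx]]$charges <- charges
  validate_molecule_record(records[[idx]], charge_tol = charge_tol)
  records
}
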