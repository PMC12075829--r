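#' Thermochemistry block of a QM summary record
#'
#' Holds the standard harmonic-oscillator thermochemistry quantities printed
#' by quantum-chemistry programs. Energies are in eV; heat capacity and
#' entropy in cal mol^-1 K^-1, the units the source tables use.
#'
#' @param zpe Zero-point vibrational energy (eV), non-negative.
#' @param enthalpy Thermal enthalpy H (eV).
#' @param free_energy Gibbs free energy G (eV).
#' @param heat_capacity Cv (cal mol^-1 K^-1), positive.
#' @param entropy S (cal mol^-1 K^-1), positive.
#' @param temperature Temperature (K) the block refers to.
#' @return A `thermo_record` list.
#' @examples
#' thermo_record(zpe = 16.5, enthalpy = 17.52, free_energy = 14.45,
#'               heat_capacity = 141.6, entropy = 237.0)
#' @export
thermo_record <- function(zpe, enthalpy, free_energy, heat_capacity, entropy,
                          temperature = unit_constants[["t_standard"]]) {
  stopifnot(is.numeric(zpe), is.numeric(enthalpy), is.numeric(free_energy),
            is.numeric(heat_capacity), is.numeric(entropy))
  if (zpe < 0) stop("thermo_record: zpe must be >= 0", call. = FALSE)
  if (heat_capacity <= 0) stop("thermo_record: heat_capacity must be > 0", call. = FALSE)
  if (entropy <= 0) stop("thermo_record: entropy must be > 0", call. = FALSE)
  structure(
    list(zpe = zpe, enthalpy = enthalpy, free_energy = free_energy,
         heat_capacity = heat_capacity, entropy = entropy,
         temperature = temperature),
    class = "thermo_record"
  )
}

#' Per-atom three-state charge table
#'
#' One row per atom: the atomic partial charge in the neutral (N electrons),
#' anionic (N+1) and cationic (N-1) states at the neutral geometry. Atom
#' indices are 1-based and contiguous, matching the row labels of published
#' charge tables.
#'
#' @param atom_index Integer 1-based atom ordinals.
#' @param element Element symbols.
#' @param q_neutral,q_anion,q_cation Atomic charges (e) in the three states.
#' @return A tibble with class `charge_table`.
#' @export
charge_table <- function(atom_index, element, q_neutral, q_anion, q_cation) {
  tbl <- tibble::tibble(
    atom_index = as.integer(atom_index),
    element = as.character(element),
    q_neutral = as.numeric(q_neutral),
    q_anion = as.numeric(q_anion),
    q_cation = as.numeric(q_cation)
  )
  if (nrow(tbl) > 0 && !identical(tbl$atom_index, seq_len(nrow(tbl)))) {
    stop("charge_table: atom_index must be contiguous starting at 1", call. = FALSE)
  }
  class(tbl) <- c("charge_table", class(tbl))
  tbl
}

#' One chemical species with three-state energies and derived inputs
#'
#' The central record of the pipeline: total electronic energies of the
#' neutral, anionic (N+1 electron) and cationic (N-1 electron) states at the
#' neutral geometry, frontier-orbital energies, optional per-atom three-state
#' charges, thermochemistry, dipole moment and a SMILES structure. All
#' energies are in eV. The theory label (e.g. `"B3LYP/6-31G"`) is mandatory:
#' operations that combine records (notably binding energies) refuse to mix
#' theory levels.
#'
#' @param name Identifier for the species.
#' @param theory Theory-level label; never mixed across binding-energy sums.
#' @param e_neutral,e_anion,e_cation Total energies (eV); ion states may be
#'   `NA` when only the neutral-state energy is available.
#' @param e_homo,e_lumo Frontier orbital energies (eV); `e_lumo >= e_homo`.
#' @param charges Optional [charge_table()].
#' @param thermo Optional [thermo_record()].
#' @param dipole Optional total dipole moment (Debye).
#' @param smiles Optional SMILES string for the ADME layer.
#' @return A `molecule_record` list.
#' @export
molecule_record <- function(name, theory,
                            e_neutral = NA_real_, e_anion = NA_real_,
                            e_cation = NA_real_,
                            e_homo = NA_real_, e_lumo = NA_real_,
                            charges = NULL, thermo = NULL,
                            dipole = NA_real_, smiles = NA_character_) {
  stopifnot(is.character(name), nzchar(name), is.character(theory), nzchar(theory))
  rec <- structure(
    list(name = name, theory = theory,
         e_neutral = as.numeric(e_neutral), e_anion = as.numeric(e_anion),
         e_cation = as.numeric(e_cation),
         e_homo = as.numeric(e_homo), e_lumo = as.numeric(e_lumo),
         charges = charges, thermo = thermo,
         dipole = as.numeric(dipole), smiles = as.character(smiles)),
    class = "molecule_record"
  )
  validate_molecule_record(rec)
}

#' Validate a molecule record against its invariants
#'
#' Checks: `e_lumo >= e_homo`; finite state energies when all three are
#' present; contiguous 1-based atom indices; and closure of the summed
#' three-state charges (sum of q over a neutral species is ~0, over the anion
#' ~-1, over the cation ~+1).
#'
#' @param rec A `molecule_record`.
#' @param charge_tol Tolerance on the charge sums; the default 0.02 absorbs
#'   3-decimal rounding over tables of 30-44 atoms.
#' @param net_charge Net molecular charge of the neutral-state species.
#' @return `rec`, invisibly unchanged, or an error naming molecule and field.
#' @export
validate_molecule_record <- function(rec, charge_tol = 0.02, net_charge = 0) {
  fail <- function(field, msg) {
    stop(sprintf("molecule_record '%s', field '%s': %s", rec$name, field, msg),
         call. = FALSE)
  }
  states <- c(rec$e_neutral, rec$e_anion, rec$e_cation)
  if (!anyNA(states) && !all(is.finite(states))) {
    fail("e_neutral/e_anion/e_cation", "state energies must be finite")
  }
  if (!is.na(rec$e_homo) && !is.na(rec$e_lumo) && rec$e_lumo < rec$e_homo) {
    fail("e_lumo", sprintf("e_lumo (%.6f) < e_homo (%.6f)", rec$e_lumo, rec$e_homo))
  }
  if (!is.null(rec$thermo) && !inherits(rec$thermo, "thermo_record")) {
    fail("thermo", "must be a thermo_record")
  }
  if (!is.null(rec$charges)) {
    ch <- rec$charges
    if (!all(c("atom_index", "q_neutral", "q_anion", "q_cation") %in% names(ch))) {
      fail("charges", "missing charge-table columns")
    }
    if (!identical(as.integer(ch$atom_index), seq_len(nrow(ch)))) {
      fail("charges", "atom_index must be contiguous starting at 1")
    }
    sums <- c(q_neutral = net_charge, q_anion = net_charge - 1,
              q_cation = net_charge + 1)
    for (col in names(sums)) {
      got <- sum(ch[[col]])
      if (abs(got - sums[[col]]) > charge_tol) {
        fail(col, sprintf("summed %s = %.4f, expected %.4f (+-%g)",
                          col, got, sums[[col]], charge_tol))
      }
    }
  }
  invisible(rec)
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s [%s]\n", x$name, x$theory))
  cat(sprintf("  E(N) %s eV; E(N+1) %s; E(N-1) %s\n",
              format(x$e_neutral), format(x$e_anion), format(x$e_cation)))
  cat(sprintf("  HOMO %s eV; LUMO %s eV; dipole %s D\n",
              format(x$e_homo), format(x$e_lumo), format(x$dipole)))
  if (!is.null(x$charges)) cat(sprintf("  charges: %d atoms\n", nrow(x$charges)))
  if (!is.null(x$thermo)) cat("  thermo block present\n")
  invisible(x)
}

#' One modeled composite pose with its contact geometry
#'
#' Describes how the two parent molecules were joined in one candidate pose:
#' the interaction sites on each parent, the labelled contact, and its bond
#' length before and after geometry optimization (angstrom). Site and bond
#' labels use the source's own atom-numbering scheme and are stored as opaque
#' text.
#'
#' @param pose_id Pose label, e.g. `"01"`.
#' @param genistein_site,hyoscyamine_site Interaction-site labels.
#' @param bond_label Contact label, e.g. `"H30...O2"`.
#' @param pre_opt_length,post_opt_length Contact lengths (angstrom), positive.
#' @return A `composite_pose` list.
#' @export
composite_pose <- function(pose_id, genistein_site, hyoscyamine_site,
                           bond_label, pre_opt_length, post_opt_length) {
  if (pre_opt_length <= 0 || post_opt_length <= 0) {
    stop("composite_pose: bond lengths must be > 0", call. = FALSE)
  }
  structure(
    list(pose_id = as.character(pose_id),
         genistein_site = genistein_site,
         hyoscyamine_site = hyoscyamine_site,
         bond_label = bond_label,
         pre_opt_length = as.numeric(pre_opt_length),
         post_opt_length = as.numeric(post_opt_length)),
    class = "composite_pose"
  )
}

#' Externally supplied ADME flags
#'
#' Machine-learned or proprietary ADME endpoints (P-glycoprotein substrate
#' call, GI absorption class, solubility class, consensus logP, synthetic
#' accessibility) are consumed as inputs, never recomputed; this container
#' restricts the categorical fields to their documented vocabularies.
#'
#' @param pgp_substrate Logical: predicted P-glycoprotein substrate.
#' @param gi_absorption `"high"` or `"low"`.
#' @param solubility_class Free-text solubility class label.
#' @param consensus_logp Optional externally supplied consensus logP.
#' @param synthetic_accessibility Optional externally supplied SA score.
#' @return An `adme_flags` list.
#' @export
adme_flags <- function(pgp_substrate, gi_absorption,
                       solubility_class = NA_character_,
                       consensus_logp = NA_real_,
                       synthetic_accessibility = NA_real_) {
  stopifnot(is.logical(pgp_substrate), length(pgp_substrate) == 1L)
  gi_absorption <- match.arg(tolower(gi_absorption), c("high", "low"))
  structure(
    list(pgp_substrate = pgp_substrate, gi_absorption = gi_absorption,
         solubility_class = as.character(solubility_class),
         consensus_logp = as.numeric(consensus_logp),
         synthetic_accessibility = as.numeric(synthetic_accessibility)),
    class = "adme_flags"
  )
}
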