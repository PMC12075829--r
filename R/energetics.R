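#' A composite complex with its fragments and pose metadata
#'
#' Couples the complex record with the fragment records it was assembled
#' from, plus the pose geometry. All records must share a theory-level tag:
#' a binding energy computed across theory levels is meaningless, which is
#' why fragment energies are re-derived at the complex's level in the first
#' place.
#'
#' @param complex A [molecule_record()] for the complex.
#' @param fragments List of at least two [molecule_record()] fragments.
#' @param pose Optional [composite_pose()].
#' @return A `composite_set` list.
#' @export
composite_set <- function(complex, fragments, pose = NULL) {
  stopifnot(inherits(complex, "molecule_record"))
  if (length(fragments) < 2) {
    stop("composite_set: need at least 2 fragments", call. = FALSE)
  }
  theories <- vapply(c(list(complex), fragments), function(r) r$theory, "")
  if (length(unique(theories)) != 1L) {
    stop(sprintf("composite_set: mixed theory levels: %s",
                 paste(unique(theories), collapse = " vs ")), call. = FALSE)
  }
  if (!is.null(pose)) stopifnot(inherits(pose, "composite_pose"))
  structure(list(complex = complex, fragments = fragments, pose = pose),
            class = "composite_set")
}

#' Non-covalent binding energy of a composite
#'
#' `BE = E_complex - sum(E_fragments)` over neutral-state total energies.
#' Negative values indicate favorable association. Refuses mixed theory
#' levels (enforced at [composite_set()] construction, re-checked here).
#'
#' @param cs A [composite_set()].
#' @return Binding energy in eV.
#' @export
binding_energy <- function(cs) {
  stopifnot(inherits(cs, "composite_set"))
  theories <- vapply(c(list(cs$complex), cs$fragments), function(r) r$theory, "")
  if (length(unique(theories)) != 1L) {
    stop("binding_energy: mixed theory levels", call. = FALSE)
  }
  e_frag <- vapply(cs$fragments, function(r) r$e_neutral, 1.0)
  if (anyNA(c(cs$complex$e_neutral, e_frag))) {
    stop("binding_energy: missing neutral-state energies", call. = FALSE)
  }
  cs$complex$e_neutral - sum(e_frag)
}

#' Entropy recomputed from enthalpy and free energy
#'
#' `S = (H - G) / T`, converted from eV to cal mol^-1 K^-1 through
#' [unit_constants]. Used as an internal-consistency check on thermochemistry
#' blocks whose H, G and S are reported independently. A free energy above
#' the enthalpy (negative entropy) is flagged with a warning, not rejected,
#' so the checker stays usable on arbitrary inputs.
#'
#' @param enthalpy,free_energy H and G (eV).
#' @param temperature Temperature (K), positive.
#' @return Entropy in cal mol^-1 K^-1.
#' @examples
#' entropy_from_hg(17.517219586, 14.4533266)  # ~236.98
#' @export
entropy_from_hg <- function(enthalpy, free_energy,
                            temperature = unit_constants[["t_standard"]]) {
  stopifnot(temperature > 0)
  s <- (enthalpy - free_energy) * unit_constants[["cal_per_ev"]] / temperature
  if (any(s < 0)) {
    warning("entropy_from_hg: free energy exceeds enthalpy (negative entropy)",
            call. = FALSE)
  }
  s
}

#' Classify a pose contact from its optimized length
#'
#' A rule-of-thumb geometric classification: an H...O or H...N contact at or
#' under `hb_cutoff` is a hydrogen bond; any contact at or under `vdw_cutoff`
#' is van der Waals; longer contacts are `"none"`. The defaults (2.5 and 3.6
#' angstrom) are conventional geometric criteria for moderate hydrogen bonds
#' and van der Waals contact distances.
#'
#' @param post_opt_length Contact length after optimization (angstrom), > 0.
#' @param donor_acceptor Character vector of the two contact elements,
#'   e.g. `c("H", "O")`.
#' @param hb_cutoff,vdw_cutoff Classification cutoffs (angstrom).
#' @return `"hydrogen_bond"`, `"van_der_waals"` or `"none"`.
#' @examples
#' classify_contact(1.68825, c("H", "O"))  # hydrogen_bond
#' classify_contact(3.15105, c("C", "O"))  # van_der_waals
#' @export
classify_contact <- function(post_opt_length, donor_acceptor,
                             hb_cutoff = 2.5, vdw_cutoff = 3.6) {
  stopifnot(post_opt_length > 0, length(donor_acceptor) == 2)
  el <- toupper(donor_acceptor)
  hb_pair <- "H" %in% el && any(el %in% c("O", "N"))
  if (hb_pair && post_opt_length <= hb_cutoff) return("hydrogen_bond")
  if (post_opt_length <= vdw_cutoff) return("van_der_waals")
  "none"
}

# Pull the two contact elements out of a bond label like "H30...O2" or
# "C12...O3" (any non-alphanumeric run as separator).
contact_elements <- function(bond_label) {
  sides <- strsplit(bond_label, "[^A-Za-z0-9]+")[[1]]
  sides <- sides[nzchar(sides)]
  if (length(sides) != 2) {
    stop(sprintf("cannot parse contact elements from bond label '%s'", bond_label),
         call. = FALSE)
  }
  vapply(sides, function(s) sub("^([A-Za-z]+).*$", "\\1", s), "",
         USE.NAMES = FALSE)
}

#' Energetics and thermochemistry summary table for composite sets
#'
#' One row per pose (sorted by pose id): total energy, HOMO-LUMO gap via
#' [band_gap()], binding energy via [binding_energy()], dipole moment, the
#' thermochemistry block, the entropy recomputed from `(H - G)/T` as a
#' consistency check, and the geometric contact class of the pose.
#'
#' @param sets Non-empty list of [composite_set()] objects.
#' @param hb_cutoff,vdw_cutoff Passed to [classify_contact()].
#' @return A tibble with columns `pose_id`, `total_energy`, `gap`,
#'   `binding_energy`, `dipole`, `zpe`, `enthalpy`, `free_energy`,
#'   `heat_capacity`, `entropy`, `entropy_recomputed`, `contact_class`.
#' @export
energetics_table <- function(sets, hb_cutoff = 2.5, vdw_cutoff = 3.6) {
  if (length(sets) == 0) stop("energetics_table: empty set list", call. = FALSE)
  rows <- lapply(sets, function(cs) {
    stopifnot(inherits(cs, "composite_set"))
    rec <- cs$complex
    th <- rec$thermo
    s_re <- if (is.null(th)) NA_real_ else
      entropy_from_hg(th$enthalpy, th$free_energy, th$temperature)
    contact <- NA_character_
    if (!is.null(cs$pose)) {
      contact <- classify_contact(cs$pose$post_opt_length,
                                  contact_elements(cs$pose$bond_label),
                                  hb_cutoff, vdw_cutoff)
    }
    tibble::tibble(
      pose_id = if (is.null(cs$pose)) rec$name else cs$pose$pose_id,
      total_energy = rec$e_neutral,
      gap = band_gap(rec$e_homo, rec$e_lumo),
      binding_energy = binding_energy(cs),
      dipole = rec$dipole,
      zpe = if (is.null(th)) NA_real_ else th$zpe,
      enthalpy = if (is.null(th)) NA_real_ else th$enthalpy,
      free_energy = if (is.null(th)) NA_real_ else th$free_energy,
      heat_capacity = if (is.null(th)) NA_real_ else th$heat_capacity,
      entropy = if (is.null(th)) NA_real_ else th$entropy,
      entropy_recomputed = s_re,
      contact_class = contact
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$pose_id), ]
}
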