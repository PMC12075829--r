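#' Vertical ionization potential and electron affinity
#'
#' Computed from single-point total energies of the ions at the neutral
#' geometry (not from Koopmans-theorem orbital energies):
#' `IP = E(N-1) - E(N)`, `EA = E(N) - E(N+1)`. Negative electron affinities
#' are legitimate (an unbound anion) and are returned unclamped.
#'
#' @param e_neutral Total energy of the N-electron state (eV).
#' @param e_cation Total energy of the N-1-electron state (eV).
#' @param e_anion Total energy of the N+1-electron state (eV).
#' @return Energy in eV.
#' @examples
#' vertical_ip(-100, -92.38)   # 7.62
#' vertical_ea(-100, -100.35)  # 0.35
#' @export
vertical_ip <- function(e_neutral, e_cation) {
  stopifnot(is.finite(e_neutral), is.finite(e_cation))
  e_cation - e_neutral
}

#' @rdname vertical_ip
#' @export
vertical_ea <- function(e_neutral, e_anion) {
  stopifnot(is.finite(e_neutral), is.finite(e_anion))
  e_neutral - e_anion
}

#' HOMO-LUMO band gap
#'
#' `E_gap = E_LUMO - E_HOMO`, a kinetic-stability proxy: larger gaps mean
#' lower reactivity.
#'
#' @param e_homo,e_lumo Frontier orbital energies (eV), `e_lumo >= e_homo`.
#' @return Gap in eV.
#' @examples
#' band_gap(-6.24, -1.82)  # 4.42
#' @export
band_gap <- function(e_homo, e_lumo) {
  stopifnot(is.finite(e_homo), is.finite(e_lumo))
  if (e_lumo < e_homo) {
    stop(sprintf("band_gap: e_lumo (%.6f) below e_homo (%.6f)", e_lumo, e_homo),
         call. = FALSE)
  }
  e_lumo - e_homo
}

#' Global conceptual-DFT reactivity indices
#'
#' From the vertical IP and EA: Mulliken electronegativity
#' `chi = (IP + EA) / 2`, chemical potential `mu = -chi`, hardness
#' `eta = IP - EA`, softness `S = 1 / eta`, electrophilicity index
#' `omega = chi^2 / (2 eta)`, nucleophilicity index `eps = 1 / omega`.
#'
#' Two hardness conventions circulate. The default, `"difference"`
#' (`eta = IP - EA`), matches the finite-difference usage of the reference
#' tables this package reproduces; `"halved"` selects the textbook
#' `eta = (IP - EA) / 2` (softness and electrophilicity scale accordingly).
#'
#' @param record A [molecule_record()] with all three state energies, or use
#'   [global_indices_from_energies()] with explicit values.
#' @param convention `"difference"` (default) or `"halved"`.
#' @return A one-row tibble with columns `name`, `ip`, `ea`, `gap`,
#'   `electronegativity`, `chemical_potential`, `hardness`, `softness`,
#'   `electrophilicity`, `nucleophilicity`, `convention`. `gap` is `NA` when
#'   orbital energies are absent.
#' @examples
#' global_indices_from_energies(ip = 7.93, ea = -0.35)  # hardness 8.28
#' @export
global_indices <- function(record, convention = c("difference", "halved")) {
  stopifnot(inherits(record, "molecule_record"))
  states <- c(record$e_neutral, record$e_anion, record$e_cation)
  if (anyNA(states)) {
    stop(sprintf("global_indices: record '%s' lacks one of the three state energies",
                 record$name), call. = FALSE)
  }
  global_indices_from_energies(
    ip = vertical_ip(record$e_neutral, record$e_cation),
    ea = vertical_ea(record$e_neutral, record$e_anion),
    e_homo = record$e_homo, e_lumo = record$e_lumo,
    name = record$name, convention = convention
  )
}

#' @rdname global_indices
#' @param ip,ea Vertical ionization potential and electron affinity (eV).
#' @param e_homo,e_lumo Optional frontier orbital energies (eV) for the gap.
#' @param name Optional identifier carried into the output row.
#' @export
global_indices_from_energies <- function(ip, ea, e_homo = NA_real_,
                                         e_lumo = NA_real_, name = NA_character_,
                                         convention = c("difference", "halved")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(ip), is.finite(ea))
  eta <- switch(convention, difference = ip - ea, halved = (ip - ea) / 2)
  if (eta <= 0) {
    stop("global_indices: hardness <= 0 (IP must exceed EA); softness undefined",
         call. = FALSE)
  }
  chi <- (ip + ea) / 2
  omega <- chi^2 / (2 * eta)
  gap <- if (is.na(e_homo) || is.na(e_lumo)) NA_real_ else band_gap(e_homo, e_lumo)
  tibble::tibble(
    name = name, ip = ip, ea = ea, gap = gap,
    electronegativity = chi, chemical_potential = -chi,
    hardness = eta, softness = 1 / eta,
    electrophilicity = omega,
    nucleophilicity = if (omega == 0) Inf else 1 / omega,
    convention = convention
  )
}

#' Global indices for a list of records
#'
#' @param records List of [molecule_record()].
#' @inheritParams global_indices
#' @return A tibble, one row per record.
#' @export
global_indices_table <- function(records, convention = c("difference", "halved")) {
  convention <- match.arg(convention)
  do.call(rbind, lapply(records, global_indices, convention = convention))
}
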