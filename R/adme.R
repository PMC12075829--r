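# SMILES handling is delegated to Open Babel through ChemmineOB; this module
# owns the Ertl TPSA contribution table, the drug-likeness rules and the
# bioavailability rule table.

ob_parse <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("invalid structure: SMILES must be a single string", call. = FALSE)
  }
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  ok <- !is.null(mol) && !is.character(mol)
  if (ok) {
    p <- tryCatch(ChemmineOB::prop_OB(mol), error = function(e) NULL)
    if (is.null(p) || nrow(p) == 0 || p$MW[1] <= 0) ok <- FALSE
  }
  if (!ok) {
    stop(sprintf("invalid structure: cannot parse SMILES '%s' (or no atoms)",
                 smiles), call. = FALSE)
  }
  list(mol = mol, props = p)
}

n_matches <- function(mol, smarts) {
  ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE)
}

#' Ertl polar-fragment contribution table (N/O set)
#'
#' Fragment contributions (angstrom^2) of the topological polar surface area
#' scheme of Ertl, Rohde & Selzer (J. Med. Chem. 2000, 43, 3714-3717),
#' restricted to the nitrogen and oxygen environments. Each environment is
#' encoded as a SMARTS pattern centred on a single atom; the patterns are
#' mutually exclusive by construction (partitioned on element, aromaticity,
#' connectivity X, hydrogen count, formal charge, total valence and 3-ring
#' membership), so each polar atom contributes exactly once. The S/P
#' extension is deliberately omitted; structures containing polar S or P
#' raise an unsupported-fragment error.
#'
#' @return A tibble with columns `smarts`, `contribution`, `description`.
#' @export
ertl_tpsa_table <- function() {
  tibble::tribble(
    ~smarts,                                   ~contribution, ~description,
    # --- oxygen ---
    "[OX2H1+0]",                               20.23, "hydroxyl -OH",
    "[OX2H0+0;r3]",                            12.53, "3-ring ether",
    "[OX2H0+0;!r3]",                            9.23, "ether / ester -O-",
    "[OX1+0]",                                 17.07, "carbonyl =O",
    "[OX1-]",                                  23.06, "oxide anion -O(-)",
    "[o+0]",                                   13.14, "aromatic o",
    # --- nitrogen, neutral aliphatic ---
    "[NX3H0+0;v3;!r3]",                         3.24, "tertiary amine N",
    "[NX3H0+0;v3;r3]",                          3.01, "3-ring tertiary N",
    "[NX2H0+0;v3]",                            12.36, "imine -N=",
    "[NX1H0+0]",                               23.79, "nitrile N",
    "[NX3H0+0;v5]",                            11.68, "N(-)(=)= e.g. neutral nitro",
    "[NX2H0+0;v5]",                            13.60, "N(=)#",
    "[NX3H1+0;v3;!r3]",                        12.03, "secondary amine NH",
    "[NX3H1+0;v3;r3]",                         21.94, "3-ring NH",
    "[NX2H1+0]",                               23.85, "imine =NH",
    "[NX3H2+0]",                               26.02, "primary amine NH2",
    # --- nitrogen, cations ---
    "[NX4H0+]",                                 0.00, "quaternary N+",
    "[NX3H0+;v4]",                              3.01, "N+(-)(-)=",
    "[NX2H0+;v4]",                              4.36, "N+(-)#",
    "[NX4H1+]",                                 4.44, "NH+(-)(-)-",
    "[NX3H1+;v4]",                             13.97, "NH+(-)=",
    "[NX4H2+]",                                16.61, "NH2+(-)-",
    "[NX3H2+;v4]",                             25.59, "NH2+=",
    "[NX4H3+]",                                27.64, "NH3+-",
    # --- nitrogen, aromatic ---
    "[nX2H0+0]",                               12.89, "pyridine-type n",
    "[nX3H0+0;$(n=*)]",                         8.39, "aromatic n with exocyclic =",
    "[nX3H0+0;!$(n=*);$(n(:a)(:a):a)]",         4.41, "bridging aromatic n",
    "[nX3H0+0;!$(n=*);!$(n(:a)(:a):a)]",        4.93, "substituted pyrrole-type n",
    "[nX3H1+0]",                               15.79, "pyrrole nH",
    "[nX3H0+;$(n(:a)(:a):a)]",                  4.10, "bridging aromatic n+",
    "[nX3H0+;!$(n(:a)(:a):a)]",                 3.88, "substituted aromatic n+",
    "[nX3H1+]",                                14.14, "aromatic nH+"
  )
}

#' Topological polar surface area (Ertl fragment scheme, N/O set)
#'
#' Sums the [ertl_tpsa_table()] contributions over all matched polar-atom
#' environments of a structure. SMARTS matching runs on Open Babel's
#' aromaticity model, the same model whose canonical TPSA the test suite
#' cross-checks against. Any nitrogen or oxygen environment absent from the
#' table, and any polar sulfur/phosphorus atom, raises an
#' unsupported-fragment error rather than silently contributing zero.
#'
#' @param smiles A SMILES string.
#' @return TPSA in angstrom^2 (0 for structures without polar atoms).
#' @examples
#' \dontrun{
#' tpsa("CN1C2CCC1CC(C2)OC(=O)C(CO)C3=CC=CC=C3")  # 49.77
#' tpsa("CC")                                      # 0
#' }
#' @export
tpsa <- function(smiles) {
  parsed <- ob_parse(smiles)
  mol <- parsed$mol
  n_sp <- n_matches(mol, "[#16,#15]")
  if (n_sp > 0) {
    stop(sprintf(
      "unsupported fragment: %d S/P atom(s); only the N/O contribution set is implemented",
      n_sp), call. = FALSE)
  }
  tab <- ertl_tpsa_table()
  counts <- vapply(tab$smarts, function(p) n_matches(mol, p), 1)
  n_polar <- n_matches(mol, "[#7]") + n_matches(mol, "[#8]")
  if (sum(counts) != n_polar) {
    stop(sprintf(
      "unsupported fragment: %d N/O atom(s) with no tabulated environment (matched %d of %d)",
      n_polar - sum(counts), sum(counts), n_polar), call. = FALSE)
  }
  sum(counts * tab$contribution)
}

#' Atomic-contribution lipophilicity estimate
#'
#' Wildman-Crippen atomic-contribution logP, computed by Open Babel's
#' implementation of the published contribution table. Deterministic and
#' additive over disconnected components. This is a single-model estimate;
#' it tracks, but does not reproduce, consensus logP values averaged over
#' several predictors.
#'
#' @param smiles A SMILES string.
#' @return Estimated logP (unitless).
#' @export
logp_atomic <- function(smiles) {
  ob_parse(smiles)$props$logP[1]
}

#' Charge class of a structure
#'
#' Detected from explicit formal charges in the SMILES; structures without
#' explicit charges default to neutral.
#'
#' @param smiles A SMILES string.
#' @return `"neutral"`, `"anion"`, `"cation"` or `"zwitterion"`.
#' @export
charge_class <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^][]*\\]", smiles))[[1]]
  has_neg <- any(grepl("-", brackets, fixed = TRUE))
  has_pos <- any(grepl("+", brackets, fixed = TRUE))
  if (has_neg && has_pos) "zwitterion"
  else if (has_neg) "anion"
  else if (has_pos) "cation"
  else "neutral"
}

#' Rule-based oral bioavailability score
#'
#' The Martin (J. Med. Chem. 2005, 48, 3164-3170) rule table. Anions are
#' scored on polar surface area: TPSA <= 75 A^2 -> 0.85, TPSA <= 150 -> 0.56,
#' else 0.11. All other charge classes are scored on the rule-of-five:
#' at most one Lipinski violation -> 0.55, otherwise 0.17. The score can
#' therefore only take the values 0.11, 0.17, 0.55, 0.56 and 0.85.
#'
#' @param tpsa TPSA in angstrom^2.
#' @param lipinski_violations Number of Lipinski rule violations (0-4).
#' @param charge_class One of `"neutral"`, `"anion"`, `"cation"`,
#'   `"zwitterion"`.
#' @return The bioavailability score.
#' @examples
#' bioavailability_score(90.90, 0, "neutral")  # 0.55
#' @export
bioavailability_score <- function(tpsa, lipinski_violations,
                                  charge_class = c("neutral", "anion",
                                                   "cation", "zwitterion")) {
  charge_class <- match.arg(charge_class)
  stopifnot(tpsa >= 0, lipinski_violations >= 0)
  if (charge_class == "anion") {
    if (tpsa <= 75) 0.85 else if (tpsa <= 150) 0.56 else 0.11
  } else {
    if (lipinski_violations <= 1) 0.55 else 0.17
  }
}

#' Full rule-based ADME profile of a structure
#'
#' Computes the rule-based descriptor subset from a SMILES - Ertl TPSA,
#' atomic logP, molecular weight, H-bond donor/acceptor counts (Lipinski
#' definitions: donors = OH + NH hydrogens, acceptors = N + O atoms),
#' rotatable bonds, Lipinski and Veber filters, and the Martin
#' bioavailability score - and attaches externally supplied machine-learned
#' flags untouched. The `provenance` field labels every value as computed
#' here or supplied from outside.
#'
#' @param smiles A SMILES string.
#' @param external An optional [adme_flags()] object passed through.
#' @param name Optional identifier.
#' @return An `adme_profile` list with fields `name`, `tpsa`, `logp_atomic`,
#'   `mol_weight`, `hbd`, `hba`, `rotatable_bonds`, `charge_class`,
#'   `lipinski_violations` (character vector of violated rules),
#'   `lipinski_pass`, `veber_pass`, `bioavailability_score`, `external`,
#'   `provenance`.
#' @export
adme_profile <- function(smiles, external = NULL, name = NA_character_) {
  parsed <- ob_parse(smiles)
  p <- parsed$props
  mw <- p$MW[1]
  hbd <- p$HBD[1]
  hba <- p$HBA2[1]  # Lipinski acceptor count: all N + O
  rot <- n_matches(parsed$mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  tpsa_val <- tpsa(smiles)
  logp <- p$logP[1]
  cls <- charge_class(smiles)

  viol <- c(
    if (mw > 500) "MW > 500",
    if (logp > 5) "logP > 5",
    if (hbd > 5) "HBD > 5",
    if (hba > 10) "HBA > 10"
  )
  score <- bioavailability_score(tpsa_val, length(viol), cls)

  structure(
    list(
      name = name, smiles = smiles,
      tpsa = tpsa_val, logp_atomic = logp, mol_weight = mw,
      hbd = hbd, hba = hba, rotatable_bonds = rot,
      charge_class = cls,
      lipinski_violations = viol %||% character(0),
      lipinski_pass = length(viol) <= 1,
      veber_pass = rot <= 10 && tpsa_val <= 140,
      bioavailability_score = score,
      external = external,
      provenance = c(
        tpsa = "computed", logp_atomic = "computed", mol_weight = "computed",
        hbd = "computed", hba = "computed", rotatable_bonds = "computed",
        lipinski_pass = "computed", veber_pass = "computed",
        bioavailability_score = "computed",
        external = if (is.null(external)) NA_character_ else "supplied"
      )
    ),
    class = "adme_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adme_profile <- function(x, ...) {
  cat(sprintf("<adme_profile> %s\n", if (is.na(x$name)) x$smiles else x$name))
  cat(sprintf("  TPSA %.2f A^2; logP %.2f; MW %.2f; HBD %d; HBA %d; rotors %d\n",
              x$tpsa, x$logp_atomic, x$mol_weight, x$hbd, x$hba, x$rotatable_bonds))
  cat(sprintf("  Lipinski %s (%d violations); Veber %s; bioavailability %.2f\n",
              if (x$lipinski_pass) "pass" else "fail", length(x$lipinski_violations),
              if (x$veber_pass) "pass" else "fail", x$bioavailability_score))
  invisible(x)
}
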