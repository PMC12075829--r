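#' Condensed Fukui functions from three-state atomic charges
#'
#' Per-atom susceptibility indices from charges of the same geometry in the
#' N-1, N, and N+1 electron states:
#' \itemize{
#'   \item `f_minus = q_cation - q_neutral` - susceptibility to electrophilic
#'     attack (where the electron that leaves comes from);
#'   \item `f_plus  = q_neutral - q_anion` - susceptibility to nucleophilic
#'     attack (where an added electron goes);
#'   \item `f_zero  = (f_minus + f_plus) / 2` - radical attack.
#' }
#' This is the charge-difference convention: expressed in electron
#' populations `p = Z - q` it is identical to the population-difference form
#' `f_minus = p(N) - p(N-1)`, `f_plus = p(N+1) - p(N)`. Published tables that
#' label `q` an "electron population" while printing values that are clearly
#' charges are reproduced by exactly this convention; the equivalence is
#' exercised in the test suite.
#'
#' @param q_neutral,q_anion,q_cation Atomic charges (e) in the three states;
#'   vectors are handled element-wise.
#' @return A tibble with columns `f_minus`, `f_plus`, `f_zero`.
#' @examples
#' fukui_from_charges(-0.237, -0.339, -0.211)  # f- 0.026, f+ 0.102, f0 0.064
#' @export
fukui_from_charges <- function(q_neutral, q_anion, q_cation) {
  stopifnot(length(q_neutral) == length(q_anion),
            length(q_neutral) == length(q_cation))
  f_minus <- q_cation - q_neutral
  f_plus <- q_neutral - q_anion
  tibble::tibble(f_minus = f_minus, f_plus = f_plus,
                 f_zero = (f_minus + f_plus) / 2)
}

#' Condensed dual descriptor
#'
#' `CDD = f_plus - f_minus`. Positive values mark sites prone to nucleophilic
#' attack, negative values sites prone to electrophilic attack.
#'
#' @param f_plus,f_minus Condensed Fukui functions (e).
#' @return CDD (e), element-wise.
#' @examples
#' cdd(0.102, 0.026)  # 0.076
#' @export
cdd <- function(f_plus, f_minus) f_plus - f_minus

#' Per-atom Fukui / dual-descriptor table with site classification
#'
#' Computes `f_minus`, `f_plus`, `f_zero` and CDD for every atom of a record
#' and flags candidate attack sites: `cdd > tau` marks a
#' `nucleophilic_site`, `cdd < -tau` an `electrophilic_site`, anything else
#' `none`. The default threshold `tau = 0.05` e separates the handful of
#' chemically discussed sites from background rounding noise in 3-decimal
#' charge tables; it is freely configurable.
#'
#' @param record A [molecule_record()] with a charge table, or a
#'   [charge_table()] directly.
#' @param tau Site-flagging threshold (e), non-negative.
#' @return A `fukui_table` tibble: `atom_index`, `element`, `f_minus`,
#'   `f_plus`, `f_zero`, `cdd`, `site`. The sign convention is recorded in
#'   the `"convention"` attribute.
#' @export
fukui_table <- function(record, tau = 0.05) {
  ch <- if (inherits(record, "molecule_record")) record$charges else record
  if (is.null(ch) || nrow(ch) == 0) {
    stop("fukui_table: no atomic charges present", call. = FALSE)
  }
  stopifnot(tau >= 0)
  fk <- fukui_from_charges(ch$q_neutral, ch$q_anion, ch$q_cation)
  d <- cdd(fk$f_plus, fk$f_minus)
  site <- rep("none", nrow(ch))
  site[d > tau] <- "nucleophilic_site"
  site[d < -tau] <- "electrophilic_site"
  out <- tibble::tibble(
    atom_index = ch$atom_index, element = ch$element,
    f_minus = fk$f_minus, f_plus = fk$f_plus, f_zero = fk$f_zero,
    cdd = d,
    site = factor(site, levels = c("nucleophilic_site", "electrophilic_site", "none"))
  )
  attr(out, "convention") <-
    "charge-difference: f- = q(N-1)-q(N), f+ = q(N)-q(N+1) on charges q"
  attr(out, "tau") <- tau
  class(out) <- c("fukui_table", class(out))
  out
}

#' Top-k reactive sites from a Fukui table
#'
#' Ranks atoms by `|cdd|` (descending) when `which = "cdd"`, otherwise by the
#' chosen Fukui function value descending. Ties break by ascending atom
#' index, so rankings are deterministic.
#'
#' @param table A [fukui_table()].
#' @param which `"cdd"`, `"f_minus"` or `"f_plus"`.
#' @param k Number of sites; values above the atom count are truncated with
#'   a message.
#' @param sign For `which = "cdd"`, optionally restrict to `"positive"`
#'   (nucleophilic) or `"negative"` (electrophilic) CDD before ranking;
#'   default `"both"` ranks on magnitude alone.
#' @return Integer vector of atom indices, best site first.
#' @export
top_sites <- function(table, which = c("cdd", "f_minus", "f_plus"), k = 1L,
                      sign = c("both", "positive", "negative")) {
  which <- match.arg(which)
  sign <- match.arg(sign)
  stopifnot(k >= 1)
  tbl <- table
  if (which == "cdd" && sign != "both") {
    tbl <- tbl[if (sign == "positive") tbl$cdd > 0 else tbl$cdd < 0, ]
  }
  key <- if (which == "cdd") abs(tbl$cdd) else tbl[[which]]
  ord <- order(-key, tbl$atom_index)
  if (k > nrow(tbl)) {
    message(sprintf("top_sites: k = %d exceeds %d atoms; truncating", k, nrow(tbl)))
    k <- nrow(tbl)
  }
  tbl$atom_index[ord][seq_len(k)]
}

#' Atoms flagged as attack sites
#'
#' @param table A [fukui_table()].
#' @param type `"nucleophilic_site"` or `"electrophilic_site"`.
#' @return Integer vector of flagged atom indices.
#' @export
flagged_sites <- function(table, type = c("nucleophilic_site", "electrophilic_site")) {
  type <- match.arg(type)
  table$atom_index[table$site == type]
}
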