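#' Unit constants and tolerance policy
#'
#' All energies in the pipeline are stored in electron-volts (eV); every
#' conversion routes through this single constants table so that hartree /
#' kcal mixes in published tables cannot drift.
#'
#' @format A named numeric vector with elements:
#' \describe{
#'   \item{ev_per_hartree}{1 hartree in eV (CODATA).}
#'   \item{kcal_per_ev}{1 eV in kcal mol^-1.}
#'   \item{cal_per_ev}{1 eV in cal mol^-1.}
#'   \item{t_standard}{standard thermochemistry temperature, K.}
#' }
#' @export
unit_constants <- c(
  ev_per_hartree = 27.211386245988,
  kcal_per_ev    = 23.060548,
  cal_per_ev     = 23060.548,
  t_standard     = 298.15
)

#' Named tolerance levels for comparisons against printed table values
#'
#' Published descriptor tables mix precisions: two-decimal global indices,
#' three-decimal charge tables, and nine-decimal energy totals. Comparisons
#' against such values use one of three named levels rather than ad hoc
#' numbers.
#'
#' @param level One of `"2dp"` (+-0.01), `"3dp"` (+-0.005), `"full"` (1e-6).
#' @return The numeric tolerance.
#' @examples
#' tolerance_level("2dp")
#' @export
tolerance_level <- function(level = c("2dp", "3dp", "full")) {
  level <- match.arg(level)
  switch(level, "2dp" = 0.01, "3dp" = 0.005, "full" = 1e-6)
}

#' Convert energies between eV and hartree
#'
#' @param x Numeric energies.
#' @return Converted numeric vector.
#' @export
hartree_to_ev <- function(x) x * unit_constants[["ev_per_hartree"]]

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) x / unit_constants[["ev_per_hartree"]]
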