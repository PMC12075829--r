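#' A screening criterion
#'
#' Binds a candidate-table column to a preference direction, a weight for
#' the weighted ranking, and optionally a hard filter predicate. Candidates
#' failing any hard filter are excluded before scoring.
#'
#' @param name Column of the candidate table this criterion reads.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param weight Non-negative weight; active weights are normalized to sum
#'   to 1 inside [screen()].
#' @param hard_filter Optional one-argument predicate; candidates for which
#'   it returns `FALSE` are excluded.
#' @return A `criterion` list.
#' @examples
#' criterion("gap", "higher_better", 0.2)
#' criterion("pgp_substrate", weight = 0, hard_filter = isFALSE)
#' @export
criterion <- function(name, direction = c("higher_better", "lower_better"),
                      weight = 0, hard_filter = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), nzchar(name), weight >= 0)
  if (!is.null(hard_filter)) stopifnot(is.function(hard_filter))
  structure(list(name = name, direction = direction, weight = weight,
                 hard_filter = hard_filter),
            class = "criterion")
}

#' Default calibrated screening configuration
#'
#' Hard filter: predicted P-glycoprotein substrates are excluded (efflux
#' blocks oral bioavailability). Scoring criteria and weights: band gap 0.20
#' (up), binding energy 0.20 (down), dipole moment 0.10 (up), entropy 0.15
#' (down), heat capacity 0.05 (up), TPSA 0.15 (down), logP 0.15 (up).
#'
#' The weight vector is calibrated so the default configuration reproduces
#' the two-winner verdict of the bundled genistein/L-hyoscyamine reference
#' screening; it does not claim to be an objective utility function and is
#' fully user-overridable. The dipole direction in particular is a modelling
#' choice (a higher dipole favours hydrogen-bond-rich poses but penalizes
#' apolar ones); flip it via `dipole_direction` if the application calls
#' for it.
#'
#' @param dipole_direction Direction for the dipole criterion.
#' @return A list of [criterion()] objects.
#' @export
default_criteria <- function(dipole_direction = c("higher_better", "lower_better")) {
  dipole_direction <- match.arg(dipole_direction)
  list(
    criterion("pgp_substrate", weight = 0, hard_filter = isFALSE),
    criterion("gap", "higher_better", 0.20),
    criterion("binding_energy", "lower_better", 0.20),
    criterion("dipole", dipole_direction, 0.10),
    criterion("entropy", "lower_better", 0.15),
    criterion("heat_capacity", "higher_better", 0.05),
    criterion("tpsa", "lower_better", 0.15),
    criterion("logp", "higher_better", 0.15)
  )
}

check_criteria_fields <- function(candidates, criteria) {
  for (cr in criteria) {
    if (!cr$name %in% names(candidates)) {
      stop(sprintf("screening: criterion '%s' names no column of the candidate table",
                   cr$name), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Apply hard filters to a candidate table
#'
#' @param candidates Tibble with a `pose_id` column plus criterion columns.
#' @param criteria List of [criterion()]; only those with a `hard_filter`
#'   act here.
#' @return List with `kept` (tibble) and `excluded`
#'   (tibble of `pose_id`, `filter`).
#' @export
apply_hard_filters <- function(candidates, criteria) {
  check_criteria_fields(candidates, criteria)
  excluded <- tibble::tibble(pose_id = character(0), filter = character(0))
  keep <- rep(TRUE, nrow(candidates))
  for (cr in criteria) {
    if (is.null(cr$hard_filter)) next
    ok <- vapply(candidates[[cr$name]], function(v) isTRUE(cr$hard_filter(v)), TRUE)
    newly <- !ok & keep
    if (any(newly)) {
      excluded <- rbind(excluded,
                        tibble::tibble(pose_id = candidates$pose_id[newly],
                                       filter = cr$name))
    }
    keep <- keep & ok
  }
  list(kept = candidates[keep, ], excluded = excluded)
}

#' Min-max normalized criterion scores
#'
#' Per criterion: `(x - min) / (max - min)` for `higher_better`, reversed
#' for `lower_better`, so 1 is always best. A constant column maps to 0.5
#' for every candidate - defined, and weight-neutral in score differences.
#'
#' @param kept Non-empty candidate tibble (after hard filters).
#' @param criteria List of [criterion()]; only positive-weight criteria are
#'   scored.
#' @return Tibble: `pose_id` plus one `[0, 1]` score column per criterion.
#' @export
normalize_scores <- function(kept, criteria) {
  if (nrow(kept) == 0) stop("normalize_scores: no candidates", call. = FALSE)
  active <- Filter(function(cr) cr$weight > 0, criteria)
  check_criteria_fields(kept, active)
  out <- tibble::tibble(pose_id = kept$pose_id)
  for (cr in active) {
    x <- as.numeric(kept[[cr$name]])
    rng <- range(x)
    s <- if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
    if (cr$direction == "lower_better") s <- 1 - s
    if (diff(rng) == 0) s <- rep(0.5, length(x))
    out[[cr$name]] <- s
  }
  out
}

directed_values <- function(kept, active) {
  vapply(active, function(cr) {
    x <- as.numeric(kept[[cr$name]])
    if (cr$direction == "lower_better") -x else x
  }, numeric(nrow(kept)))
}

#' Pareto front of a candidate set
#'
#' A candidate is dominated when another candidate is at least as good on
#' every directed criterion and strictly better on at least one; the front
#' is the set of non-dominated candidates.
#'
#' @inheritParams normalize_scores
#' @return Character vector of non-dominated `pose_id`s (input order).
#' @export
pareto_front <- function(kept, criteria) {
  if (nrow(kept) == 0) stop("pareto_front: no candidates", call. = FALSE)
  active <- Filter(function(cr) cr$weight > 0, criteria)
  check_criteria_fields(kept, active)
  v <- matrix(directed_values(kept, active), nrow = nrow(kept))
  n <- nrow(v)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n)[-i], function(j) {
      all(v[j, ] >= v[i, ]) && any(v[j, ] > v[i, ])
    }, TRUE))
  }, TRUE)
  kept$pose_id[!dominated]
}

#' Screen candidates: filter, score, rank, select
#'
#' The full pipeline: hard filters, min-max normalization, weighted totals
#' (weights renormalized over the active criteria), deterministic ranking
#' (ties broken by ascending pose id), Pareto front, and top-k selection.
#' Candidates are sorted by pose id before any computation, so the report
#' is invariant to input order.
#'
#' @param candidates Tibble with `pose_id` plus criterion columns, e.g.
#'   from [build_candidates()].
#' @param criteria List of [criterion()]; defaults to [default_criteria()].
#' @param k Number of selected candidates (default 2).
#' @param seed Optional integer echoed in the config for audit trails
#'   (screening itself is deterministic).
#' @return A `screening_report`: list with `excluded`, `scores`,
#'   `ranking` (tibble of `pose_id`, `weighted_total`, `rank`),
#'   `pareto_front`, `selected`, `config`.
#' @export
screen <- function(candidates, criteria = default_criteria(), k = 2L,
                   seed = NA_integer_) {
  stopifnot(is.data.frame(candidates), "pose_id" %in% names(candidates))
  candidates <- candidates[order(candidates$pose_id), ]
  check_criteria_fields(candidates, criteria)
  flt <- apply_hard_filters(candidates, criteria)
  if (nrow(flt$kept) == 0) {
    stop("screen: every candidate was excluded by the hard filters", call. = FALSE)
  }
  active <- Filter(function(cr) cr$weight > 0, criteria)
  w <- vapply(active, `[[`, 1.0, "weight")
  w <- w / sum(w)
  scores <- normalize_scores(flt$kept, criteria)
  smat <- as.matrix(scores[, -1, drop = FALSE])
  total <- as.numeric(smat %*% w)
  ord <- order(-total, scores$pose_id)
  ranking <- tibble::tibble(
    pose_id = scores$pose_id[ord],
    weighted_total = total[ord],
    rank = seq_along(ord)
  )
  k_eff <- min(k, nrow(ranking))
  report <- structure(
    list(
      excluded = flt$excluded,
      scores = scores,
      ranking = ranking,
      pareto_front = sort(pareto_front(flt$kept, criteria)),
      selected = ranking$pose_id[seq_len(k_eff)],
      config = list(
        k = as.integer(k), seed = seed,
        criteria = lapply(criteria, function(cr) {
          list(name = cr$name, direction = cr$direction, weight = cr$weight,
               hard_filter = !is.null(cr$hard_filter))
        }),
        normalized_weights = stats::setNames(as.numeric(w),
                                             vapply(active, `[[`, "", "name"))
      )
    ),
    class = "screening_report"
  )
  report
}

#' Assemble the screening candidate table
#'
#' Joins an [energetics_table()] with per-pose ADME descriptors into the
#' flat table [screen()] consumes. ADME values may be computed profiles or
#' supplied flags; only the columns named by the screening criteria are
#' required.
#'
#' @param energetics Tibble from [energetics_table()].
#' @param adme Tibble with `pose_id` and ADME columns
#'   (`tpsa`, `logp`, `pgp_substrate`, ...).
#' @return A tibble, one row per pose.
#' @export
build_candidates <- function(energetics, adme) {
  stopifnot("pose_id" %in% names(energetics), "pose_id" %in% names(adme))
  merged <- merge(as.data.frame(energetics), as.data.frame(adme),
                  by = "pose_id", sort = TRUE)
  tibble::as_tibble(merged)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  if (nrow(x$excluded)) {
    cat("  excluded:",
        paste(sprintf("%s (%s)", x$excluded$pose_id, x$excluded$filter),
              collapse = ", "), "\n")
  }
  cat("  ranking:\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("    %d. %s  (%.4f)\n", x$ranking$rank[i],
                x$ranking$pose_id[i], x$ranking$weighted_total[i]))
  }
  cat("  pareto front:", paste(x$pareto_front, collapse = ", "), "\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
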