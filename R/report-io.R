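#' Write a screening report to disk
#'
#' Two formats: `"json"` is a full-fidelity, deterministically ordered
#' serialization (stable key order, full precision) whose re-parse via
#' [read_screening_report()] reproduces the report; `"tsv"` is a flat
#' per-pose table (one row per pose, excluded poses included with their
#' filter name) for spreadsheet consumption.
#'
#' @param report A `screening_report` from [screen()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "screening_report"))
  format <- match.arg(format)
  if (format == "json") {
    cfg <- report$config
    # a named numeric would serialize as a bare array; a list keeps the names
    cfg$normalized_weights <- as.list(cfg$normalized_weights)
    payload <- list(
      excluded = as.data.frame(report$excluded),
      scores = as.data.frame(report$scores),
      ranking = as.data.frame(report$ranking),
      pareto_front = report$pareto_front,
      selected = report$selected,
      config = cfg
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", pretty = TRUE)
  } else {
    flat <- report_as_table(report)
    utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Flatten a screening report to one row per pose
#'
#' @param report A `screening_report`.
#' @return A data frame: `pose_id`, `status`, `filter`, per-criterion
#'   scores, `weighted_total`, `rank`, `pareto`, `selected`.
#' @export
report_as_table <- function(report) {
  sc <- as.data.frame(report$scores)
  rk <- as.data.frame(report$ranking)
  ranked <- merge(sc, rk, by = "pose_id", sort = TRUE)
  ranked$status <- "ranked"
  ranked$filter <- NA_character_
  ranked$pareto <- ranked$pose_id %in% report$pareto_front
  ranked$selected <- ranked$pose_id %in% report$selected
  ex <- as.data.frame(report$excluded)
  if (nrow(ex)) {
    for (col in setdiff(names(ranked), c("pose_id", "status", "filter"))) {
      ex[[col]] <- if (is.logical(ranked[[col]])) NA else NA_real_
    }
    ex$status <- "excluded"
    flat <- rbind(ranked, ex[, names(ranked)])
  } else {
    flat <- ranked
  }
  flat[order(flat$pose_id), ]
}

#' Read a JSON screening report back
#'
#' @param path Path written by [write_screening_report()] with
#'   `format = "json"`.
#' @return A `screening_report`.
#' @export
read_screening_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- raw$config
  cfg$seed <- if (is.null(cfg$seed)) NA_integer_ else cfg$seed
  cfg$k <- as.integer(cfg$k)
  cfg$criteria <- lapply(seq_len(nrow(raw$config$criteria)), function(i) {
    as.list(raw$config$criteria[i, ])
  })
  cfg$normalized_weights <- unlist(raw$config$normalized_weights)
  structure(
    list(
      excluded = tibble::as_tibble(as.data.frame(raw$excluded,
                                                 stringsAsFactors = FALSE)),
      scores = tibble::as_tibble(raw$scores),
      ranking = tibble::as_tibble(raw$ranking),
      pareto_front = as.character(raw$pareto_front),
      selected = as.character(raw$selected),
      config = cfg
    ),
    class = "screening_report"
  )
}
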