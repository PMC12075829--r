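test_that("the efflux hard filter splits the reference poses as published", {
  cand <- reference_candidates(ref)
  flt <- apply_hard_filters(cand, default_criteria())
  expect_setequal(flt$kept$pose_id, c("01", "02", "04"))
  expect_setequal(flt$excluded$pose_id, c("03", "05", "06"))
  expect_true(all(flt$excluded$filter == "pgp_substrate"))
  # no hard filters keeps everything
  soft <- Filter(function(cr) is.null(cr$hard_filter), default_criteria())
  expect_equal(nrow(apply_hard_filters(cand, soft)$kept), 6)
  # an unsatisfiable filter excludes everything, and screen() refuses to rank
  impossible <- list(criterion("gap", weight = 1, hard_filter = function(x) FALSE))
  expect_equal(nrow(apply_hard_filters(cand, impossible)$kept), 0)
  expect_error(screen(cand, impossible), "every candidate")
  # a criterion naming a missing column is a configuration error
  expect_error(apply_hard_filters(cand, list(criterion("nope", weight = 1))),
               "nope")
})

test_that("min-max normalization is directed and handles constant columns", {
  two <- tibble::tibble(pose_id = c("a", "b"), gap = c(1, 3))
  sc <- normalize_scores(two, list(criterion("gap", "higher_better", 1)))
  expect_equal(sc$gap, c(0, 1))
  sc <- normalize_scores(two, list(criterion("gap", "lower_better", 1)))
  expect_equal(sc$gap, c(1, 0))
  const <- tibble::tibble(pose_id = c("a", "b"), gap = c(2, 2))
  sc <- normalize_scores(const, list(criterion("gap", "higher_better", 1)))
  expect_equal(sc$gap, c(0.5, 0.5))
  # on the kept reference poses the widest gap scores 1
  cand <- reference_candidates(ref)
  kept <- apply_hard_filters(cand, default_criteria())$kept
  sc <- normalize_scores(kept, default_criteria())
  expect_equal(sc$gap[sc$pose_id == "02"], 1)
  expect_equal(sc$gap[sc$pose_id == "04"], 0)
  expect_true(all(as.matrix(sc[, -1]) >= 0 & as.matrix(sc[, -1]) <= 1))
})

test_that("the Pareto front matches a brute-force dominance oracle", {
  crits <- list(criterion("x", "higher_better", 1),
                criterion("y", "lower_better", 1),
                criterion("z", "higher_better", 1))
  # independent oracle: literal double loop over the dominance definition
  oracle <- function(df) {
    dir <- c(x = 1, y = -1, z = 1)
    v <- sweep(as.matrix(df[, names(dir)]), 2, dir, `*`)
    keep <- character(0)
    for (i in seq_len(nrow(v))) {
      dominated <- FALSE
      for (j in seq_len(nrow(v))) {
        if (i == j) next
        if (all(v[j, ] >= v[i, ]) && any(v[j, ] > v[i, ])) dominated <- TRUE
      }
      if (!dominated) keep <- c(keep, df$pose_id[i])
    }
    keep
  }
  withr::with_seed(314159, {
    for (n in c(1, 2, 10, 50)) {
      df <- tibble::tibble(pose_id = sprintf("p%02d", seq_len(n)),
                           x = round(stats::runif(n), 2),
                           y = round(stats::runif(n), 2),
                           z = round(stats::runif(n), 2))
      expect_setequal(pareto_front(df, crits), oracle(df))
    }
  })
  # degenerate cases
  one <- tibble::tibble(pose_id = "solo", x = 1, y = 1, z = 1)
  expect_equal(pareto_front(one, crits), "solo")
  pair <- tibble::tibble(pose_id = c("worse", "better"),
                         x = c(0, 1), y = c(1, 0), z = c(0, 1))
  expect_equal(pareto_front(pair, crits), "better")
})

test_that("default screening of the reference poses selects 02 and 04", {
  rep <- screen(reference_candidates(ref))
  expect_setequal(rep$selected, c("02", "04"))
  expect_true(all(c("02", "04") %in% rep$pareto_front))
  expect_equal(rep$ranking$pose_id[1], "04")
  expect_equal(sum(rep$config$normalized_weights), 1)
})

test_that("screening is invariant to candidate order and fully deterministic", {
  cand <- reference_candidates(ref)
  a <- screen(cand)
  b <- screen(cand[sample.int(nrow(cand)), ])
  expect_equal(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_screening_report(a, p1, "json")
  write_screening_report(b, p2, "json")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a single-criterion screen is just a sort on that criterion", {
  cand <- reference_candidates(ref)
  rep <- screen(cand, list(criterion("gap", "higher_better", 1)), k = 6)
  expect_equal(rep$ranking$pose_id,
               cand$pose_id[order(-cand$gap)])
})

test_that("weighted ranking is invariant under positive affine rescaling", {
  cand <- reference_candidates(ref)
  a <- screen(cand)
  cand2 <- cand
  cand2$gap <- 1000 * cand2$gap + 5   # positive affine transform
  b <- screen(cand2)
  expect_equal(a$ranking$pose_id, b$ranking$pose_id)
  expect_equal(a$ranking$weighted_total, b$ranking$weighted_total,
               tolerance = 1e-12)
})

test_that("reports round-trip through JSON and flatten to one row per pose", {
  rep <- screen(reference_candidates(ref))
  path <- withr::local_tempfile(fileext = ".json")
  write_screening_report(rep, path, "json")
  back <- read_screening_report(path)
  expect_equal(as.data.frame(back$scores), as.data.frame(rep$scores))
  expect_equal(as.data.frame(back$ranking), as.data.frame(rep$ranking))
  expect_equal(as.data.frame(back$excluded), as.data.frame(rep$excluded))
  expect_equal(back$pareto_front, rep$pareto_front)
  expect_equal(back$selected, rep$selected)
  expect_equal(back$config$normalized_weights, rep$config$normalized_weights)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_screening_report(rep, tsv, "tsv")
  flat <- utils::read.delim(tsv, colClasses = c(pose_id = "character"))
  expect_equal(flat$pose_id, sprintf("%02d", 1:6))
  expect_equal(flat$status[flat$pose_id == "03"], "excluded")
  expect_true(flat$selected[flat$pose_id == "04"])
})
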