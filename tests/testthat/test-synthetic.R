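test_that("generation is deterministic in the seed", {
  a <- gen_molecule(base_spec(42))
  b <- gen_molecule(base_spec(42))
  expect_identical(a, b)
  c <- gen_molecule(base_spec(43))
  expect_false(identical(a$record$e_neutral, c$record$e_neutral))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(1, target_ip = 1, target_ea = 2), "target_ip")
  expect_error(synthetic_spec(1, target_gap = -1), "target_gap")
  expect_error(synthetic_spec(1, n_atoms = 3, fukui_minus = c(0.5, 0.6, 0.1)),
               "sum to 1")
  expect_error(synthetic_spec(1, n_atoms = 3, fukui_plus = c(1, 0)), "n_atoms")
})

test_that("generated records recover every target descriptor exactly", {
  for (seed in c(1, 17, 900)) {
    out <- gen_molecule(base_spec(seed))
    rec <- out$record
    gi <- global_indices(rec)
    # recovery limited only by cancellation against ~1e4 eV absolute totals
    expect_equal(gi$ip, out$truth$ip, tolerance = 1e-9)
    expect_equal(gi$ea, out$truth$ea, tolerance = 1e-9)
    expect_equal(gi$gap, out$truth$gap, tolerance = 1e-12)
    ft <- fukui_table(rec)
    expect_equal(ft$f_minus, out$truth$f_minus, tolerance = 1e-12)
    expect_equal(ft$f_plus, out$truth$f_plus, tolerance = 1e-12)
    expect_equal(ft$cdd, out$truth$cdd, tolerance = 1e-12)
    s <- entropy_from_hg(rec$thermo$enthalpy, rec$thermo$free_energy,
                         rec$thermo$temperature)
    expect_equal(s, out$truth$entropy, tolerance = 1e-9)
  }
})

test_that("charge closure is exact on synthetic records", {
  rec <- gen_molecule(base_spec(5))$record
  ch <- rec$charges
  expect_equal(sum(ch$q_neutral), 0, tolerance = 1e-12)
  expect_equal(sum(ch$q_anion), sum(ch$q_neutral) - 1, tolerance = 1e-12)
  expect_equal(sum(ch$q_cation), sum(ch$q_neutral) + 1, tolerance = 1e-12)
})

test_that("a unit-vector Fukui profile puts all weight on the designated atom", {
  n <- 6
  e1 <- c(1, rep(0, n - 1))
  spec <- synthetic_spec(9, n_atoms = n, fukui_minus = e1)
  ft <- fukui_table(gen_molecule(spec)$record)
  expect_equal(ft$f_minus, e1)
  expect_equal(top_sites(ft, "f_minus", k = 1), 1L)
})

test_that("composite generation plants an exactly recoverable binding energy", {
  frag_specs <- list(base_spec(21), base_spec(22))
  zero <- gen_composite_set(base_spec(20, binding_energy = 0), frag_specs)
  expect_equal(binding_energy(zero$set), 0, tolerance = 1e-12)
  half <- gen_composite_set(base_spec(20, binding_energy = -0.5), frag_specs)
  expect_equal(binding_energy(half$set), -0.5, tolerance = 1e-12)

  withr::with_seed(2468, {
    bes <- stats::runif(50, -1, 0)
  })
  for (i in seq_along(bes)) {
    out <- gen_composite_set(
      base_spec(1000 + i, binding_energy = bes[i]),
      list(base_spec(2000 + i), base_spec(3000 + i))
    )
    expect_equal(binding_energy(out$set), bes[i], tolerance = 1e-9)
    # additivity: fragments + BE reassemble the complex total exactly
    e_frag <- sum(vapply(out$set$fragments, function(r) r$e_neutral, 1.0))
    expect_equal(out$set$complex$e_neutral, e_frag + bes[i], tolerance = 1e-9)
  }
})

test_that("composite generation refuses mixed theory tags and missing BE", {
  expect_error(
    gen_composite_set(base_spec(1, binding_energy = -0.1),
                      list(base_spec(2), base_spec(3, theory = "other"))),
    "mixed theory"
  )
  expect_error(gen_composite_set(base_spec(1), list(base_spec(2), base_spec(3))),
               "binding_energy")
  expect_error(gen_composite_set(base_spec(1, binding_energy = 0),
                                 list(base_spec(2))), ">= 2")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(-0.1735, 3), -0.174)
  expect_equal(round_half_away(0.1735, 3), 0.174)
  expect_equal(round_half_away(2.5, 0), 3)
  expect_equal(round_half_away(-2.5, 0), -3)
  x <- c(-1.23456789, 0.5, 3.14159)
  expect_equal(round_half_away(x, 12), x)
})

test_that("table-style rounding perturbs the dual descriptor by at most 2e-3", {
  out <- gen_molecule(base_spec(77))
  rounded <- round_to_printed(out$record, dp = 3)
  ft <- fukui_table(rounded)
  expect_true(all(abs(ft$cdd - out$truth$cdd) <= 0.002 + 1e-12))
  # a very high dp is the identity
  same <- round_to_printed(out$record, dp = 12)
  expect_equal(same$charges, out$record$charges)
})
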