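test_that("the charge-difference convention reproduces bolded reference atoms", {
  # genistein carbonyl-region O (atom 3)
  fk <- fukui_from_charges(-0.237, -0.339, -0.211)
  expect_equal(fk$f_minus, 0.026)
  expect_equal(fk$f_plus, 0.102)
  expect_equal(fk$f_zero, 0.064)
  expect_equal(cdd(fk$f_plus, fk$f_minus), 0.076)
  # hyoscyamine tropane N (atom 4); printed f+ 0.001 is a rounding of 0.002
  fk <- fukui_from_charges(-0.104, -0.106, 0.070)
  expect_equal(fk$f_minus, 0.174)
  expect_equal(fk$f_plus, 0.002)
  expect_equal(cdd(fk$f_plus, fk$f_minus), -0.172)
  # identical charges across states give zeros
  fk <- fukui_from_charges(0.1, 0.1, 0.1)
  expect_equal(unlist(fk), c(f_minus = 0, f_plus = 0, f_zero = 0))
})

test_that("every printed Fukui cell reproduces from the printed charges within 0.002", {
  for (mol in c("genistein", "hyoscyamine")) {
    computed <- fukui_table(ref$parents_apfd[[mol]])
    printed <- ref$printed$fukui[[mol]]
    for (col in c("f_minus", "f_plus", "f_zero", "cdd")) {
      delta <- abs(computed[[col]] - printed[[col]])
      expect_true(all(delta <= 0.002 + 1e-12),
                  info = sprintf("%s %s: max |delta| = %.4f", mol, col, max(delta)))
    }
  }
})

test_that("site flags at the default threshold recover the discussed sites", {
  gen <- fukui_table(ref$parents_apfd$genistein, tau = 0.05)
  expect_setequal(flagged_sites(gen, "nucleophilic_site"), c(3, 9, 12))
  expect_setequal(flagged_sites(gen, "electrophilic_site"), 10)
  hyo <- fukui_table(ref$parents_apfd$hyoscyamine, tau = 0.05)
  expect_setequal(flagged_sites(hyo, "electrophilic_site"), 4)
  expect_setequal(flagged_sites(hyo, "nucleophilic_site"), c(39, 42))
  # an infinite threshold flags nothing
  all_none <- fukui_table(ref$parents_apfd$genistein, tau = Inf)
  expect_true(all(all_none$site == "none"))
})

test_that("top_sites ranks by the requested key with deterministic ties", {
  gen <- fukui_table(ref$parents_apfd$genistein)
  expect_equal(top_sites(gen, "cdd", k = 1), 9L)
  expect_setequal(top_sites(gen, "cdd", k = nrow(gen)), gen$atom_index)
  expect_message(got <- top_sites(gen, "cdd", k = 999), "truncating")
  expect_length(got, nrow(gen))
  # hyoscyamine's two strongest electrophilic sites by |CDD|
  hyo <- fukui_table(ref$parents_apfd$hyoscyamine)
  expect_equal(top_sites(hyo, "cdd", k = 2, sign = "negative"), c(4L, 21L))
  # ties break by ascending atom index
  tied <- fukui_table(charge_table(1:3, c("C", "C", "C"),
                                   q_neutral = c(0.2, 0.2, -0.4),
                                   q_anion = c(-0.2, -0.2, -0.6),
                                   q_cation = c(0.5, 0.5, 0)))
  expect_equal(top_sites(tied, "f_plus", k = 2), c(1L, 2L))
})

test_that("charge-difference equals population-difference with explicit Z", {
  out <- gen_molecule(base_spec(31))
  ch <- out$record$charges
  z <- rep(c(6, 8, 1), length.out = nrow(ch))  # arbitrary atomic numbers
  p_n <- z - ch$q_neutral; p_a <- z - ch$q_anion; p_c <- z - ch$q_cation
  ft <- fukui_table(out$record)
  expect_equal(ft$f_minus, p_n - p_c, tolerance = 1e-12)
  expect_equal(ft$f_plus, p_a - p_n, tolerance = 1e-12)
})

test_that("a record without charges is rejected", {
  expect_error(fukui_table(molecule_record("bare", "T")), "charges")
})
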