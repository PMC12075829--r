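test_that("parent TPSA values match the published panel to 0.01 A^2", {
  expect_equal(tpsa(ref$parents_apfd$genistein$smiles), 90.90, tolerance = 0.01 / 90.9)
  expect_equal(tpsa(ref$parents_apfd$hyoscyamine$smiles), 49.77, tolerance = 0.01 / 49.77)
  expect_equal(tpsa("CC"), 0)  # no polar atoms
})

test_that("TPSA agrees with Open Babel's Ertl implementation on a mixed panel", {
  panel <- c("Oc1ccccc1", "c1ccncc1", "Nc1ccccc1", "CN(C)C=O", "CCOC(C)=O",
             "c1c[nH]cn1", "C1COCCN1", "CN(C)C", "CC#N",
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
             ref$parents_apfd$genistein$smiles,
             ref$parents_apfd$hyoscyamine$smiles)
  for (smi in panel) {
    mol <- ChemmineOB::forEachMol("SMILES", smi, identity)
    expect_equal(tpsa(smi), ChemmineOB::prop_OB(mol)$TPSA[1],
                 tolerance = 1e-6, label = smi)
  }
})

test_that("TPSA is additive over components and invariant to atom reordering", {
  expect_equal(tpsa("Oc1ccccc1.Oc1ccccc1"), 2 * tpsa("Oc1ccccc1"))
  # the same genistein skeleton written from a different starting atom
  alt <- "O=c1c2c(O)cc(O)cc2occ1-c1ccc(O)cc1"
  expect_equal(tpsa(alt), tpsa(ref$parents_apfd$genistein$smiles))
})

test_that("a charge-separated nitro group is typed as drawn", {
  # N+(=O)(O-): 3.01 + 17.07 + 23.06; the neutral hypervalent drawing N(=O)=O
  # types as 11.68 + 2 x 17.07 instead - contributions follow the structure
  # as written, which is the fragment scheme's own behavior
  expect_equal(tpsa("C[N+](=O)[O-]"), 43.14)
})

test_that("structures outside the N/O contribution set are refused loudly", {
  expect_error(tpsa("CSC"), "S/P")
  expect_error(tpsa("not a smiles"), "invalid structure")
  expect_error(tpsa(""), "invalid structure")
  expect_error(adme_profile("["), "invalid structure")
})

test_that("atomic logP is deterministic, additive, and tracks the consensus value", {
  # single-carbon baseline of the embedded contribution scheme: C + 4 H
  expect_equal(logp_atomic("C"), 0.6361, tolerance = 1e-6)
  expect_equal(logp_atomic("C.C"), 2 * logp_atomic("C"), tolerance = 1e-9)
  expect_lt(abs(logp_atomic(ref$parents_apfd$genistein$smiles) - 2.04), 1.5)
})

test_that("charge classes come from explicit SMILES charges only", {
  expect_equal(charge_class("CCO"), "neutral")
  expect_equal(charge_class("CC(=O)[O-]"), "anion")
  expect_equal(charge_class("C[N+](C)(C)C"), "cation")
  expect_equal(charge_class("[NH3+]CC(=O)[O-]"), "zwitterion")
})

test_that("the bioavailability rule table is a pure function of its inputs", {
  expect_equal(bioavailability_score(90.90, 0, "neutral"), 0.55)
  expect_equal(bioavailability_score(49.77, 0, "neutral"), 0.55)
  expect_equal(bioavailability_score(300, 1, "neutral"), 0.55)  # one violation ok
  expect_equal(bioavailability_score(100, 3, "neutral"), 0.17)
  expect_equal(bioavailability_score(100, 2, "cation"), 0.17)
  expect_equal(bioavailability_score(60, 0, "anion"), 0.85)
  expect_equal(bioavailability_score(100, 0, "anion"), 0.56)
  expect_equal(bioavailability_score(160, 0, "anion"), 0.11)
})

test_that("the full profile reproduces the parent drug-likeness panel", {
  g <- adme_profile(ref$parents_apfd$genistein$smiles, name = "genistein")
  expect_equal(g$mol_weight, 270.24, tolerance = 0.01 / 270.24)
  expect_equal(g$hbd, 3)
  expect_equal(g$hba, 5)
  expect_equal(g$rotatable_bonds, 1)
  expect_true(g$lipinski_pass)
  expect_length(g$lipinski_violations, 0)
  expect_true(g$veber_pass)
  expect_equal(g$bioavailability_score, 0.55)

  h <- adme_profile(ref$parents_apfd$hyoscyamine$smiles,
                    external = adme_flags(FALSE, "high", "Soluble", 2.04, 4.33),
                    name = "hyoscyamine")
  expect_equal(h$tpsa, 49.77, tolerance = 1e-9)
  expect_equal(h$bioavailability_score, 0.55)
  # supplied flags pass through untouched, labelled as supplied
  expect_identical(h$external$consensus_logp, 2.04)
  expect_identical(h$external$pgp_substrate, FALSE)
  expect_equal(unname(h$provenance[["external"]]), "supplied")
  expect_equal(unname(h$provenance[["tpsa"]]), "computed")
})
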