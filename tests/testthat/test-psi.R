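test_that("derivatization converts exactly the pseudouridines, idempotently", {
  ala <- trna_ala()
  ce <- derivatize(ala)
  expect_equal(sum(trna_residues(ce)$symbol == "ce1Y"), 3)
  expect_equal(trna_residues(ce)$label[trna_residues(ce)$symbol == "ce1Y"],
               c("28", "39", "57"))
  # everything else untouched
  other <- trna_residues(ala)$symbol != "Y"
  expect_equal(trna_residues(ce)$symbol[other],
               trna_residues(ala)$symbol[other])
  # idempotence and identity on psi-free records
  expect_equal(trna_residues(derivatize(ce)), trna_residues(ce))
  plain <- toy_trna(c("G", "A", "U", "C"))
  expect_equal(trna_residues(derivatize(plain)), trna_residues(plain))
})

test_that("pairing counts cyanoethyl adducts from the +53.0265 mass shift", {
  native <- digest(toy_trna(c("G", "C", "A", "U", "Y", "C", "G", "A")),
                   cleavage_rule("RNaseT1"))
  ce <- digest(derivatize(toy_trna(c("G", "C", "A", "U", "Y", "C", "G", "A"))),
               cleavage_rule("RNaseT1"))
  pc <- pair_and_count(native, ce)
  span <- pc[pc$seq == "CAUYCG", ]
  expect_equal(span$delta_count, 1L)
  expect_lt(abs(span$delta_residual), 1e-9)
  expect_equal(span$ce_mass - span$native_mass, 53.0266, tolerance = 1e-4)
  # unshifted spans count zero
  expect_equal(pc$delta_count[pc$seq == "G"], 0L)
  # two pseudouridines give a double shift
  rec2 <- toy_trna(c("G", "U", "Y", "A", "Y", "U", "G", "C"))
  pc2 <- pair_and_count(digest(rec2), digest(derivatize(rec2)))
  expect_equal(max(pc2$delta_count), 2L)
})

test_that("total cyanoethyl count equals the pseudouridine count", {
  recs <- list(trna_ala(),
               toy_trna(c("Y", "G", "A", "Y", "U", "G", "Y", "C")),
               toy_trna(c("G", "A", "C", "U")))
  for (rec in recs) {
    pc <- pair_and_count(
      digest(rec, cleavage_rule("RNaseT1")),
      digest(derivatize(rec), cleavage_rule("RNaseT1"))
    )
    pc <- pc[!duplicated(paste(pc$start, pc$end)), ]
    expect_equal(sum(pc$delta_count, na.rm = TRUE), count_psi(rec))
  }
})

test_that("pseudouridine is invisible without derivatization", {
  with_psi <- toy_trna(c("G", "C", "A", "Y", "U", "G"))
  with_u <- toy_trna(c("G", "C", "A", "U", "U", "G"))
  f1 <- digest(with_psi, cleavage_rule("RNaseT1"))
  f2 <- digest(with_u, cleavage_rule("RNaseT1"))
  expect_equal(f1$mono_mass, f2$mono_mass, tolerance = 1e-12)
  # and at the formula level
  expect_formula_equal(
    oligo_formula(trna_residues(with_psi)$symbol, "phosphate", "hydroxyl"),
    oligo_formula(trna_residues(with_u)$symbol, "phosphate", "hydroxyl")
  )
})

test_that("swapped channels and inconsistent spans are rejected", {
  rec <- toy_trna(c("G", "C", "Y", "U", "G", "A"))
  nat <- digest(rec)
  ce <- digest(derivatize(rec))
  expect_error(pair_and_count(ce, nat), "swapped")
  expect_error(pair_and_count(nat[-2, ], ce, strict = TRUE), "inconsistent")
})
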