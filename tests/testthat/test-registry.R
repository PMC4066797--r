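test_that("registry carries the full modification inventory with valid flags", {
  reg <- default_registry()
  needed <- c("A", "G", "C", "U", "m1A", "m1G", "m2G", "m22G", "m3C", "m5C",
              "D", "Y", "ce1Y", "t6A", "i6A", "ms2i6A", "tm5U", "tm5s2U",
              "f5C", "Q", "m5U")
  expect_true(all(needed %in% reg$symbol))
  expect_false(anyDuplicated(reg$symbol) > 0)
  # alias spellings resolve to the same rows
  expect_identical(reg_lookup("Ψ")$symbol, "Y")
  expect_identical(reg_lookup("τm5s2U")$symbol, "tm5s2U")
  expect_error(reg_lookup("xyz"), "xyz")
  expect_error(validate_registry(rbind(reg, reg[1, ])), "duplicate")
})

test_that("modification deltas are the expected chemical groups", {
  # pseudouridine is mass-silent: an isomer of uridine
  expect_formula_equal(reg_formula("Y"), reg_formula("U"))
  # methylation
  expect_formula_equal(reg_formula("m1A") - reg_formula("A"),
                       chem_formula("CH2"))
  # cyanoethylation adds acrylonitrile (+53 Da nominal)
  expect_formula_equal(reg_formula("ce1Y") - reg_formula("Y"),
                       chem_formula("C3H3N"))
  expect_equal(delta_mass("ce1Y") - delta_mass("Y"), 53.0266,
               tolerance = 1e-4)
  # thio layering: S replaces O; methylthio adds CH2S
  expect_formula_equal(reg_formula("tm5s2U") + chem_formula("O"),
                       reg_formula("tm5U") + chem_formula("S"))
  expect_formula_equal(reg_formula("ms2i6A") - reg_formula("i6A"),
                       chem_formula("CH2S"))
  # among the registry, only pseudouridine is mass-silent
  mods <- setdiff(default_registry()$symbol, c("A", "G", "C", "U"))
  silent <- mods[vapply(mods, function(s) delta_mass(s) == 0, logical(1))]
  expect_identical(silent, "Y")
})

test_that("nucleoside and base ions reproduce the reference detection masses", {
  expect_equal(round(nucleoside_mh("m1A")), 282)
  expect_equal(round(nucleoside_mh("m2G")), 298)
  expect_equal(round(nucleoside_mh("Y")), 245)
  expect_equal(round(base_ion_mz("m1A")), 150)
  expect_equal(round(base_ion_mz("m2G")), 166)
  # C-glycoside: no base ion for pseudouridine
  expect_true(is.na(base_ion_mz("Y")))
  expect_error(nucleoside_mh("nope"), "nope")
})

test_that("every catalog modification resolves in the registry", {
  cat22 <- mt_catalog()
  expect_silent(reg_lookup(unique(cat22$symbol)))
})

test_that("registry survives a TSV round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  reg <- default_registry()
  write_registry_tsv(reg, path)
  expect_equal(as.data.frame(read_registry_tsv(path)), as.data.frame(reg))
})
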