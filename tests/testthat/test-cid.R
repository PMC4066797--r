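ce_fragment <- function() {
  # CAU(ce1Y)CAAUUG with internal 5'OH/3'p chemistry
  rec <- toy_trna(c("G", "C", "A", "U", "ce1Y", "C", "A", "A", "U", "U", "G",
                    "C"))
  fr <- digest(rec, cleavage_rule("RNaseT1"))
  fr[fr$n_res == 10, ]
}

test_that("c ions coincide with the corresponding 5' sub-fragment masses", {
  fr <- ce_fragment()
  ions <- predict_product_ions(fr, charges = 1L, series = "c")
  syms <- fr$symbols[[1]]
  for (i in c(1, 3, 7)) {
    expect_equal(ions$neutral_mass[ions$index == i],
                 oligo_mass(syms[1:i], "hydroxyl", "phosphate"),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ion ladders have the expected shape and bounds", {
  fr <- ce_fragment()
  ions <- predict_product_ions(fr, charges = 1L)
  # a 10-mer gives y1..y9
  expect_equal(sort(ions$index[ions$series == "y"]), 1:9)
  # all singly charged c/y ions lie below the neutral precursor mass
  pre <- fr$mono_mass
  expect_equal(pre, 3237.43, tolerance = 5e-3)  # m/z 1617.7 at z = 2
  expect_true(all(ions$neutral_mass[ions$series %in% c("c", "y")] < pre))
  # the pseudouridine-derived residue (4th) yields no a-B ion
  expect_false(4 %in% ions$index[ions$series == "a-B"])
  expect_error(predict_product_ions("G"), "length >= 2")
})

test_that("c/y complementarity holds exactly at the formula level", {
  rec <- toy_trna(c("C", "A", "U", "Y", "C", "A", "A", "U", "U", "G"),
                  five_prime = "hydroxyl", three_prime = "phosphate")
  syms <- trna_residues(rec)$symbol
  n <- length(syms)
  whole <- oligo_formula(syms, "hydroxyl", "phosphate")
  h2o <- chem_formula("H2O")
  for (i in 1:(n - 1)) {
    c_i <- oligo_formula(syms[1:i], "hydroxyl", "phosphate")
    y_ni <- oligo_formula(syms[(i + 1):n], "hydroxyl", "phosphate")
    expect_formula_equal(c_i + y_ni, whole + h2o)
  }
})

test_that("noiseless CID localizes the generating placement uniquely", {
  # the dimethylated fragment: m1A and m2G at the 5th and 6th residues
  truth <- digest(toy_trna(c("G", "A", "U", "U", "U", "m1A", "m2G", "C")),
                  cleavage_rule("RNaseT1"))
  truth <- truth[truth$n_res == 6, ]
  spec <- simulate_cid(truth, sim_config(seed = 2, da_noise_sd = 0))
  shell <- truth
  shell$symbols <- list(c("A", "U", "U", "U", "A", "G"))
  loc <- localize(spec, shell, mod_set = c("m1A", "m2G"))
  expect_equal(loc$verdict, "unique")
  expect_equal(loc$winner$site, c(5L, 6L))
  expect_equal(loc$winner$symbol, c("m1A", "m2G"))
})

test_that("cyanoethylated pseudouridine localizes to the 4th residue", {
  fr <- ce_fragment()
  spec <- simulate_cid(fr, sim_config(seed = 3, da_noise_sd = 0))
  shell <- fr
  shell$symbols <- list(c("C", "A", "U", "U", "C", "A", "A", "U", "U", "G"))
  loc <- localize(spec, shell, mod_set = "ce1Y")
  expect_equal(loc$verdict, "unique")
  expect_equal(loc$winner$site, 4L)
})

test_that("spectra without discriminating ions are ambiguous, not guessed", {
  fr <- ce_fragment()
  shell <- fr
  shell$symbols <- list(c("C", "A", "U", "U", "C", "A", "A", "U", "U", "G"))
  full <- simulate_cid(fr, sim_config(seed = 4, da_noise_sd = 0))
  # keep only ions whose span covers every U site: non-discriminating
  ions <- predict_product_ions(fr, charges = 1L)
  cover_all <- ions$mz[ions$first_site <= 3 & ions$last_site >= 10]
  stripped <- peaklist(full$mz[vapply(full$mz, function(m) {
    any(abs(cover_all - m) < 0.3)
  }, logical(1))], ms_level = 2)
  loc <- localize(stripped, shell, mod_set = "ce1Y")
  expect_true(loc$verdict %in% c("ambiguous", "none"))
  expect_null(loc$winner)
})

test_that("support scores are monotone under peak removal", {
  fr <- ce_fragment()
  shell <- fr
  shell$symbols <- list(c("C", "A", "U", "U", "C", "A", "A", "U", "U", "G"))
  spec <- simulate_cid(fr, sim_config(seed = 5, da_noise_sd = 0))
  loc_full <- localize(spec, shell, mod_set = "ce1Y")
  for (drop_n in c(3, 8)) {
    fewer <- peaklist(spec$mz[-seq_len(drop_n)], ms_level = 2)
    loc_sub <- localize(fewer, shell, mod_set = "ce1Y")
    full_scores <- loc_full$candidates[order(loc_full$candidates$placement), ]
    sub_scores <- loc_sub$candidates[order(loc_sub$candidates$placement), ]
    expect_true(all(sub_scores$score <= full_scores$score))
  }
})

test_that("an impossible precursor is an error distinct from missing support", {
  fr <- ce_fragment()
  shell <- fr
  shell$symbols <- list(c("C", "A", "U", "U", "C", "A", "A", "U", "U", "G"))
  bad <- peaklist(c(500, 700), ms_level = 2,
                  precursor_mz = 3000, precursor_z = 1L)
  expect_error(localize(bad, shell, mod_set = "ce1Y"), "precursor")
})

test_that("parameter recovery is exact on synthetic spectra at zero noise", {
  set.seed(99)
  reg <- default_registry()
  for (i in 1:10) {
    n <- sample(5:10, 1)
    parents <- sample(c("A", "G", "C", "U"), n, replace = TRUE)
    # place one modification away from making the shell trivially unique
    site <- sample(seq_len(n - 1), 1)
    sym <- switch(parents[site], A = "m1A", G = "m1G", C = "m5C", U = "D")
    symbols <- parents
    symbols[site] <- sym
    rec <- toy_trna(c(symbols, "G"), five_prime = "hydroxyl")
    fr <- digest(rec, cleavage_rule("RNaseT1", cleave_after = character()))
    spec <- simulate_cid(fr, sim_config(seed = i, da_noise_sd = 0))
    shell <- fr
    shell$symbols <- list(c(parents, "G"))
    loc <- localize(spec, shell, mod_set = sym)
    expect_equal(loc$verdict, "unique", label = paste("case", i))
    expect_equal(loc$winner$site, site)
  }
})
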