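test_that("oligonucleotide mass arithmetic reproduces the worked examples", {
  # 5'-terminal hexamer with both terminal phosphates
  expect_equal(oligo_mass(c("G", "A", "G", "G", "A", "U"),
                          "phosphate", "phosphate"), 2097.25,
               tolerance = 5e-3)
  # 3'-terminal 12-mer, free hydroxyls
  expect_equal(oligo_mass(strsplit("CAAUCCUUACCA", "")[[1]],
                          "hydroxyl", "hydroxyl"), 3697.54,
               tolerance = 5e-3)
  # single nucleoside with free hydroxyls is just the registry formula
  expect_equal(oligo_mass("G", "hydroxyl", "hydroxyl"),
               formula_mass(reg_formula("G")))
  # cyclic phosphate sits one water below the linear form
  lin <- oligo_mass(c("A", "G"), "hydroxyl", "phosphate")
  cyc <- oligo_mass(c("A", "G"), "hydroxyl", "cyclic_phosphate")
  expect_equal(lin - cyc, formula_mass("H2O"))
})

test_that("RNase digests of tRNA-Ala yield the reference fragments", {
  ala <- trna_ala()
  t1 <- digest(ala, cleavage_rule("RNaseT1"))
  # the dimethylated 9/10 fragment, internal chemistry 5'OH/3'p
  hit <- t1[t1$seq == "AUUUm1Am2G", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$five_prime, "hydroxyl")
  expect_equal(hit$three_prime, "phosphate")
  expect_equal(hit$mono_mass, 1967.270, tolerance = 1e-3)
  # the partial m2G10 variant is co-emitted
  expect_true("AUUUm1AG" %in% t1$seq)
  # RNase A: 5'-terminal fragment inherits the molecular 5'-phosphate
  a <- digest(ala, cleavage_rule("RNaseA"))
  five <- a[a$provenance == "five_terminal", ]
  expect_equal(five$seq[1], "GAGGAU")
  expect_equal(five$five_prime[1], "phosphate")
  expect_equal(five$mono_mass[1], 2097.25, tolerance = 5e-3)
  # 3'-terminal fragment keeps the molecular 3'-hydroxyl
  three <- t1[t1$provenance == "three_terminal" & t1$variant == "", ]
  expect_equal(three$seq, "CAAUCCUUACCA")
  expect_equal(three$three_prime, "hydroxyl")
})

test_that("sequences without a cleavage site stay intact", {
  rec <- toy_trna(c("A", "A", "A", "A"))
  fr <- digest(rec, cleavage_rule("RNaseT1"))
  expect_equal(nrow(fr), 1)
  expect_equal(fr$provenance, "intact")
  empty <- rec
  empty$residues <- rec$residues[0, ]
  expect_error(digest(empty, cleavage_rule("RNaseT1")), "empty")
})

test_that("digestion agrees with a brute-force oracle on short sequences", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    symbols <- sample(c("A", "G", "C", "U"), n, replace = TRUE)
    rec <- toy_trna(symbols)
    for (rule_name in c("RNaseT1", "RNaseA")) {
      cut_set <- if (rule_name == "RNaseT1") "G" else c("C", "U")
      got <- digest(rec, cleavage_rule(rule_name))
      want <- oracle_digest(symbols, cut_set)
      expect_equal(nrow(got), length(want))
      expect_equal(got$mono_mass,
                   vapply(want, function(w) w$mass, numeric(1)),
                   tolerance = 1e-6)
      expect_equal(got$start_idx, vapply(want, function(w) w$start, 1))
    }
  }
})

test_that("fragment masses conserve the intact molecule across both RNases", {
  recs <- list(trna_ala(),
               toy_trna(c("G", "A", "U", "Y", "m2G", "C", "A", "G", "U")))
  h2o <- chem_formula("H2O")
  for (rec in recs) {
    whole <- oligo_formula(trna_residues(rec)$symbol, rec$five_prime,
                           rec$three_prime)
    for (rule_name in c("RNaseT1", "RNaseA")) {
      fr <- digest(rec, cleavage_rule(rule_name))
      fr <- fr[fr$variant == "" & fr$allele_id == "", ]
      total <- chem_formula()
      for (i in seq_len(nrow(fr))) {
        total <- total + oligo_formula(fr$symbols[[i]], fr$five_prime[i],
                                       fr$three_prime[i])
      }
      expect_formula_equal(total, whole + (nrow(fr) - 1) * h2o)
    }
  }
})

test_that("missed cleavages emit contiguous unions with cut-site bookkeeping", {
  rec <- toy_trna(c("A", "G", "C", "G", "U", "G", "A"))
  fr0 <- digest(rec, cleavage_rule("RNaseT1"))
  fr2 <- digest(rec, cleavage_rule("RNaseT1"), max_missed = 2)
  expect_equal(nrow(fr0), 4)
  # unions of <= 3 adjacent pieces: 4 + 3 + 2
  expect_equal(nrow(fr2), 9)
  expect_true(all(fr0$seq %in% fr2$seq))
  two_missed <- fr2[fr2$missed == 2 & fr2$start_idx == 1, ]
  expect_equal(two_missed$seq, "AGCGUG")
  expect_equal(two_missed$internal_cut_idx[[1]], c(2L, 4L))
  expect_error(cleavage_rule("RNaseT1", max_missed = 9))
})

test_that("fragment multisets are deterministic across re-digestion", {
  ala <- trna_ala()
  f1 <- digest(ala, cleavage_rule("RNaseT1"))
  f2 <- digest(ala, cleavage_rule("RNaseT1"))
  expect_identical(f1$seq, f2$seq)
  expect_identical(f1$mono_mass, f2$mono_mass)
})

test_that("fragment_mass agrees with formula-level computation", {
  fr <- digest(trna_ala(), cleavage_rule("RNaseT1"))
  for (i in c(1, 4, nrow(fr))) {
    expect_equal(fr$mono_mass[i], fragment_mass(fr[i, ]), tolerance = 1e-9)
    expect_equal(fr$avg_mass[i], fragment_mass(fr[i, ], "average"),
                 tolerance = 1e-9)
  }
})
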