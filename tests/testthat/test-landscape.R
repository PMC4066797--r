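test_that("landscape counts follow the double-occupancy site rule", {
  cat22 <- mt_catalog()
  ls <- landscape_summary(cat22)
  expect_equal(ls$n_species, 15)
  expect_equal(ls$n_positions, 118)
  # layered thio species share a site with their precursor
  expect_gt(nrow(cat22), ls$n_positions)
  expect_equal(sum(ls$per_position$n_trnas), ls$n_positions)
  expect_equal(sum(ls$per_trna$n_sites), ls$n_positions)
  # empty catalog
  empty <- cat22[0, ]
  ls0 <- landscape_summary(empty)
  expect_equal(ls0$n_species, 0)
  expect_equal(ls0$n_positions, 0)
})

test_that("summaries are invariant under entry-order permutation", {
  cat22 <- mt_catalog()
  withr::with_seed(1, {
    shuffled <- cat22[sample(nrow(cat22)), ]
  })
  a <- landscape_summary(cat22)
  b <- landscape_summary(shuffled)
  expect_equal(a$n_species, b$n_species)
  expect_equal(a$n_positions, b$n_positions)
  expect_equal(dplyr::arrange(a$per_trna, .data$trna),
               dplyr::arrange(b$per_trna, .data$trna))
})

test_that("position counts reproduce the reference tallies", {
  cat22 <- mt_catalog()
  expect_equal(count_position(cat22, "9", c("m1A", "m1G")), 19)
  expect_equal(count_position(cat22, "58", "m1A"), 6)
  expect_equal(count_position(cat22, "9", character()), 0)
  expect_equal(count_symbol_sites(cat22, "Y"), 42)
  expect_equal(count_symbol_sites(cat22, "Y", arm_only = TRUE), 35)
})

test_that("percent modified uses the supplied base total", {
  ls <- landscape_summary(mt_catalog(), total_bases = 1578)
  expect_equal(ls$percent_modified, 100 * 118 / 1578)
  expect_true(is.na(landscape_summary(mt_catalog())$percent_modified))
})

test_that("wobble classification matches the decoding table", {
  w <- classify_wobble(mt_anticodons(), mt_catalog())
  expect_equal(nrow(w), 22)
  expect_true(all(w$verdict == "consistent"))
  # eight family boxes read by unmodified U34
  expect_equal(sum(w$box_class == "family" & w$wobble_symbol == "U"), 8)
  # queuosine marks the four NAY readers
  expect_setequal(w$trna[w$wobble_class == "Q"],
                  c("Tyr", "His", "Asn", "Asp"))
  # all six NNR readers carry taurine-uridines or f5C
  expect_equal(sum(w$box_class == "NNR_pair"), 6)
  expect_true(all(w$wobble_class[w$box_class == "NNR_pair"] %in%
                    c("taurine_U", "f5C")))
  expect_error(classify_wobble(tibble::tibble(trna = "x", a34 = "??",
                                              a35 = "A", a36 = "A")))
})

test_that("misplaced wobble modifications are flagged as violations", {
  ac <- mt_anticodons()
  # put a taurine-uridine on a family-box tRNA
  ac$a34[ac$trna == "Ala"] <- "tm5U"
  w <- classify_wobble(ac, catalog = NULL)
  expect_equal(w$verdict[w$trna == "Ala"], "violation")
  expect_equal(sum(w$verdict == "violation"), 1)
})

test_that("tidy/glance/autoplot work on the landscape object", {
  ls <- landscape_summary(mt_catalog())
  expect_equal(nrow(tidy(ls)), nrow(mt_catalog()))
  expect_equal(glance(ls)$n_positions, 118)
  p <- autoplot(ls)
  expect_s3_class(p, "ggplot")
})
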