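ref_auuuag <- function() {
  # unmodified reference fragment AUUUAG, internal chemistry
  fr <- digest(toy_trna(c("G", "A", "U", "U", "U", "A", "G", "C")),
               cleavage_rule("RNaseT1"))
  fr[fr$seq == "AUUUAG", ]
}

test_that("placement enumeration covers the dimethylated species", {
  fr <- ref_auuuag()
  cfg <- match_config(charges = 2L, max_variable_mods = 2)
  tab <- theoretical_mz_table(fr, c("m1A", "m2G"), cfg)
  # the doubly charged dimethylated species is present at the reference m/z
  expect_true(any(abs(tab$mz - 982.627) < 0.01 & tab$n_mods == 2))
  # no allowed modifications -> unmodified masses only
  tab0 <- theoretical_mz_table(fr, character(), cfg)
  expect_true(all(tab0$n_mods == 0))
  expect_equal(nrow(tab0), 1)
})

test_that("site isomers are enumerated but mass-degenerate", {
  fr <- ref_auuuag()   # two A residues
  cfg <- match_config(charges = 1L, max_variable_mods = 1)
  tab <- theoretical_mz_table(fr, "m1A", cfg)
  expect_equal(nrow(tab), 3)            # none, m1A@1, m1A@6... two A sites
  modded <- tab[tab$n_mods == 1, ]
  expect_equal(nrow(modded), 2)
  expect_equal(diff(modded$mz), 0)      # indistinguishable at MS1
})

test_that("mass-silent species are excluded from MS1 placement search", {
  fr <- ref_auuuag()
  tab <- theoretical_mz_table(fr, c("Y", "m1A"), match_config(charges = 1L))
  expect_false(any(grepl("Y", tab$placement)))
})

test_that("peak matching finds species in tolerance and ranks deterministically", {
  fr <- ref_auuuag()
  cfg <- match_config(charges = 2L, max_variable_mods = 2)
  tab <- theoretical_mz_table(fr, c("m1A", "m2G"), cfg)
  pk <- peaklist(c(982.627, 5000.0))
  m <- match_peaks(pk, tab, cfg)
  hit <- m[!is.na(m$frag_id) & m$peak_mz == 982.627, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$n_mods == 2))
  expect_equal(hit$rank, seq_len(nrow(hit)))
  # far-off peak is reported unmatched
  un <- m[m$peak_mz == 5000, ]
  expect_true(all(is.na(un$frag_id)))
})

test_that("match sets grow monotonically with tolerance", {
  fr <- digest(trna_ala(), cleavage_rule("RNaseT1"))
  tols <- c(2, 10, 50)
  cfg <- function(t) match_config(tol_ppm = t, charges = 1:2)
  tab <- theoretical_mz_table(fr, character(), cfg(10))
  pk <- peaklist(tab$mz * (1 + 4e-6))    # 4 ppm systematic offset
  sets <- lapply(tols, function(t) {
    m <- match_peaks(pk, tab, cfg(t))
    paste(m$peak_id[!is.na(m$frag_id)], m$mz[!is.na(m$frag_id)])
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("noiseless synthetic digests are matched completely", {
  rec <- random_trna(11, mod_density = 0)
  cfg_sim <- sim_config(seed = 11, ppm_noise_sd = 0)
  sim <- simulate_ms1(rec, cleavage_rule("RNaseT1"), cfg_sim)
  frags <- digest(rec, cleavage_rule("RNaseT1"))
  tab <- theoretical_mz_table(frags, character(), match_config())
  m <- match_peaks(sim$peaks, tab, match_config())
  matched_mz <- unique(m$peak_mz[!is.na(m$frag_id)])
  # every fragment of >= 2 nt is recovered
  want <- sim$truth[sim$truth$n_res >= 2, ]
  expect_true(all(vapply(want$mz_true,
                         function(x) any(abs(matched_mz - x) < 1e-6),
                         logical(1))))
})

test_that("nucleoside census applies the MH+/base-ion AND rule", {
  cfg <- match_config()
  # the composition run: m1A (282/150), m2G (298/166), pseudouridine (245)
  run <- peaklist(c(282, 150, 298, 166, 245), polarity = "positive")
  cen <- nucleoside_census(run, cfg = cfg)
  called <- census_symbols(cen, include_mass_silent = TRUE)
  expect_true(all(c("m1A", "m2G", "Y") %in% called))
  # m1G is isobaric with m2G at both ion masses: called too, by construction
  expect_true("m1G" %in% called)
  # canonical-only input calls nothing
  quiet <- peaklist(nucleoside_mh(c("A", "G", "C")), polarity = "positive")
  expect_length(census_symbols(nucleoside_census(quiet, cfg = cfg),
                               include_mass_silent = TRUE), 0)
  # MH+ without the base ion: ambiguous, not called
  lone <- peaklist(282, polarity = "positive")
  cen2 <- nucleoside_census(lone, cfg = cfg)
  expect_false("m1A" %in% census_symbols(cen2))
  expect_true(cen2$ambiguous[cen2$symbol == "m1A"])
  # pseudouridine is flagged mass-silent (uridine isobar)
  expect_true(cen$mass_silent[cen$symbol == "Y"])
})

test_that("peak lists round-trip through the two-column text format", {
  pk <- peaklist(c(500.1, 982.6), c(3, 7), ms_level = 2,
                 precursor_mz = 982.627, precursor_z = 2L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_peaklist(pk, path)
  back <- read_peaklist(path)
  expect_equal(back$mz, pk$mz, tolerance = 1e-6)
  expect_equal(attr(back, "ms_level"), 2L)
  expect_equal(attr(back, "precursor_mz"), 982.627, tolerance = 1e-6)
})
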