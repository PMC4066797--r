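test_that("random records are deterministic in the seed and honor density", {
  r1 <- random_trna(7)
  r2 <- random_trna(7)
  expect_identical(trna_residues(r1), trna_residues(r2))
  expect_false(identical(trna_residues(random_trna(8))$symbol,
                         trna_residues(r1)$symbol))
  plain <- random_trna(3, mod_density = 0)
  expect_true(all(trna_residues(plain)$symbol %in% c("A", "G", "C", "U")))
  # density 1: every residue whose parent has an eligible modification
  reg <- default_registry()
  elig_parents <- unique(reg$parent[reg$symbol %in% default_search_mods()])
  full <- random_trna(4, mod_density = 1)
  res <- trna_residues(full)
  parents <- vapply(res$symbol, function(s) reg_lookup(s)$parent, "")
  expect_true(all(res$symbol[parents %in% elig_parents] !=
                    parents[parents %in% elig_parents]))
})

test_that("MS1 simulation is seed-deterministic with exact truth tables", {
  rec <- random_trna(5)
  s1 <- simulate_ms1(rec, cfg = sim_config(seed = 5))
  s2 <- simulate_ms1(rec, cfg = sim_config(seed = 5))
  expect_identical(s1$peaks$mz, s2$peaks$mz)
  expect_identical(s1$peaks$intensity, s2$peaks$intensity)
  # full dropout empties the spectrum
  s3 <- simulate_ms1(rec, cfg = sim_config(seed = 5, dropout_rate = 1))
  expect_equal(nrow(s3$peaks), 0)
  # zero noise: every peak sits exactly on its truth m/z
  s4 <- simulate_ms1(rec, cfg = sim_config(seed = 5, ppm_noise_sd = 0))
  kept <- s4$truth[s4$truth$kept, ]
  expect_true(all(vapply(s4$peaks$mz,
                         function(m) any(abs(kept$mz_true - m) < 1e-9),
                         logical(1))))
})

test_that("contaminants follow the configured Poisson rate", {
  rec <- random_trna(6)
  n_true <- nrow(simulate_ms1(rec, cfg = sim_config(seed = 1))$peaks)
  extra <- vapply(1:30, function(i) {
    nrow(simulate_ms1(rec, cfg = sim_config(seed = i,
                                            contaminant_rate = 5))$peaks) -
      n_true
  }, numeric(1))
  expect_gt(mean(extra), 2)   # Poisson(5) mean, loose band
  expect_lt(mean(extra), 8)
})

test_that("CID simulation is deterministic and refuses 1-mers", {
  fr <- digest(trna_ala(), cleavage_rule("RNaseT1"))
  long <- fr[fr$n_res >= 6, ][1, ]
  p1 <- simulate_cid(long, sim_config(seed = 9))
  p2 <- simulate_cid(long, sim_config(seed = 9))
  expect_identical(p1$mz, p2$mz)
  expect_error(simulate_cid(fr[fr$n_res == 1, ][1, ], sim_config()),
               "length >= 2")
})

test_that("the paired CE channel shows exactly the pseudouridine spans", {
  pair <- simulate_ce_pair(trna_ala(), cfg = sim_config(seed = 2,
                                                        ppm_noise_sd = 0))
  nat <- pair$native$fragments
  ce <- pair$ce$fragments
  pc <- pair_and_count(nat[nat$variant == "", ], ce[ce$variant == "", ])
  shifted <- pc[pc$delta_count >= 1, ]
  expect_equal(nrow(shifted), 3)   # the three pseudouridine fragments
  expect_setequal(paste(shifted$start, shifted$end),
                  c("27 30", "36 45", "54 60"))
  expect_true(all(shifted$delta_count == 1))
  # psi-free record: no shifts anywhere
  plain <- random_trna(12, mod_density = 0)
  pp <- simulate_ce_pair(plain, cfg = sim_config(seed = 3))
  pc0 <- pair_and_count(pp$native$fragments, pp$ce$fragments)
  expect_true(all(pc0$delta_count == 0))
})

test_that("charge-series simulation is deterministic and charge-correct", {
  ala <- trna_ala()
  s1 <- simulate_charge_series(ala, 19:26, noise_da = 0.02, seed = 4)
  s2 <- simulate_charge_series(ala, 19:26, noise_da = 0.02, seed = 4)
  expect_identical(s1$mz, s2$mz)
  truth <- (intact_mass(ala) - 26:19 * 1.007276) / 26:19
  s0 <- simulate_charge_series(ala, 19:26, noise_da = 0, seed = 4)
  expect_equal(s0$mz, sort(truth), tolerance = 1e-12)
})
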