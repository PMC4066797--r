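# Ground-truthed synthetic data: random annotated tRNAs, MS1 digests, CID
# spectra, paired native/cyanoethylated runs, nucleoside-level runs and
# intact charge series. Every generator is a pure function of
# (inputs, seed): identical seed and configuration give identical output.

#' Simulation configuration
#'
#' The two instrument profiles mirror the two classes of instrument used
#' for this kind of work: `"orbitrap_like"` applies mass-proportional
#' (ppm) m/z noise, `"ion_trap_like"` absolute Da noise. Intensities are
#' log-normal and carry no information for matching (rank-only use).
#'
#' @param seed Integer seed; every simulated quantity derives from it.
#' @param ppm_noise_sd Gaussian m/z noise, ppm (orbitrap-like profile;
#'   default 2 ppm, typical externally calibrated accuracy).
#' @param da_noise_sd Gaussian m/z noise, Da (ion-trap profile and MS2).
#' @param dropout_rate Per-peak Bernoulli dropout probability.
#' @param contaminant_rate Expected spurious peaks per spectrum (Poisson).
#' @param charges MS1 charge states emitted per fragment.
#' @param instrument `"orbitrap_like"` or `"ion_trap_like"`.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @return A list of class `mm_simconfig`.
#' @export
sim_config <- function(seed = 1L, ppm_noise_sd = 2, da_noise_sd = 0.05,
                       dropout_rate = 0, contaminant_rate = 0,
                       charges = 1:3,
                       instrument = c("orbitrap_like", "ion_trap_like"),
                       intensity_meanlog = log(1e5), intensity_sdlog = 1) {
  instrument <- match.arg(instrument)
  stopifnot(dropout_rate >= 0, dropout_rate <= 1, contaminant_rate >= 0,
            ppm_noise_sd >= 0, da_noise_sd >= 0)
  structure(list(seed = as.integer(seed), ppm_noise_sd = ppm_noise_sd,
                 da_noise_sd = da_noise_sd, dropout_rate = dropout_rate,
                 contaminant_rate = contaminant_rate,
                 charges = as.integer(charges), instrument = instrument,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog),
            class = "mm_simconfig")
}

# stage offsets keep the stages of one run decorrelated but reproducible
SIM_STAGE_OFFSET <- c(trna = 101L, ms1 = 211L, cid = 307L, ce = 401L,
                      series = 503L, nucleosides = 601L)

noisy_mz <- function(mz, cfg) {
  if (cfg$instrument == "orbitrap_like") {
    mz * (1 + stats::rnorm(length(mz), 0, cfg$ppm_noise_sd * 1e-6))
  } else {
    mz + stats::rnorm(length(mz), 0, cfg$da_noise_sd)
  }
}

sim_intensity <- function(n, cfg) {
  stats::rlnorm(n, cfg$intensity_meanlog, cfg$intensity_sdlog)
}

#' Generate a random annotated tRNA-like record
#'
#' Uniform random parent sequence; each residue is independently modified
#' with probability `mod_density`, the modification drawn uniformly from
#' the eligible symbols for that parent base. The returned record is its
#' own ground truth (the residue table is the modification map).
#'
#' @param seed Integer seed.
#' @param length_range Inclusive range the sequence length is drawn from.
#' @param mod_density Per-residue modification probability in `[0, 1]`.
#' @param eligible Candidate modification symbols; defaults to
#'   [default_search_mods()], the natural species distinguishable in the
#'   peak-list abstraction.
#' @param registry Nucleoside registry.
#' @return An `mm_trna` record named `synthetic<seed>`.
#' @export
random_trna <- function(seed, length_range = c(60, 75), mod_density = 0.1,
                        eligible = default_search_mods(),
                        registry = default_registry()) {
  stopifnot(mod_density >= 0, mod_density <= 1)
  withr::local_seed(seed + SIM_STAGE_OFFSET[["trna"]])
  n <- sample(length_range[1]:length_range[2], 1)
  parents <- sample(c("A", "G", "C", "U"), n, replace = TRUE)
  elig <- reg_lookup(eligible, registry)
  symbols <- purrr::map_chr(parents, function(p) {
    opts <- elig$symbol[elig$parent == p]
    if (length(opts) && stats::runif(1) < mod_density) sample(opts, 1) else p
  })
  new_trna(paste0("synthetic", seed), symbols, registry = registry)
}

#' Simulate an MS1 run of an RNase digest
#'
#' Digests the record (partial sites and alleles included), emits one peak
#' per (fragment, charge) with the configured noise model, Bernoulli
#' dropout and Poisson-distributed uniform contaminant peaks.
#'
#' @param rec An `mm_trna` (ground truth).
#' @param rule A [cleavage_rule()].
#' @param cfg A [sim_config()].
#' @param registry Nucleoside registry.
#' @return A list: `peaks` (an `mm_peaklist`) and `truth` (tibble of every
#'   theoretical (fragment, z) with its true m/z, whether it was kept, and
#'   whether each peak is a contaminant).
#' @export
simulate_ms1 <- function(rec, rule = cleavage_rule("RNaseT1"),
                         cfg = sim_config(), registry = default_registry()) {
  withr::local_seed(cfg$seed + SIM_STAGE_OFFSET[["ms1"]])
  frags <- digest(rec, rule, registry = registry)
  truth <- tidyr::crossing(
    frags[, c("seq", "start", "end", "mono_mass", "n_res")],
    z = cfg$charges
  )
  truth$mz_true <- (truth$mono_mass - truth$z * PROTON_MASS) / truth$z
  truth$kept <- stats::runif(nrow(truth)) >= cfg$dropout_rate
  obs <- truth[truth$kept, ]
  mz <- noisy_mz(obs$mz_true, cfg)
  intensity <- sim_intensity(nrow(obs), cfg)
  n_cont <- stats::rpois(1, cfg$contaminant_rate)
  if (n_cont > 0 && nrow(obs) > 0) {
    mz <- c(mz, stats::runif(n_cont, min(obs$mz_true), max(obs$mz_true)))
    intensity <- c(intensity, sim_intensity(n_cont, cfg))
  }
  list(
    peaks = if (length(mz)) peaklist(mz, intensity) else
      peaklist(numeric(0), numeric(0)),
    truth = truth,
    fragments = frags
  )
}

#' Simulate a CID (MS2) spectrum of one fragment
#'
#' Emits the c/y/w/a-B product-ion ladder of the fragment as given
#' (modifications placed), with the configured noise model; the generating
#' placement is the ground truth. MS2 noise is always absolute (ion-trap
#' CID), regardless of the MS1 profile.
#'
#' @param fragment A one-row [digest()] tibble with length >= 2.
#' @param cfg A [sim_config()].
#' @param precursor_z Charge of the precursor ion recorded in the metadata.
#' @param charges Product-ion charges.
#' @param registry Nucleoside registry.
#' @return An MS2 `mm_peaklist` with precursor metadata.
#' @export
simulate_cid <- function(fragment, cfg = sim_config(), precursor_z = 2L,
                         charges = 1L, registry = default_registry()) {
  if (fragment$n_res[[1]] < 2) {
    stop("CID simulation requires a fragment of length >= 2", call. = FALSE)
  }
  withr::local_seed(cfg$seed + SIM_STAGE_OFFSET[["cid"]] +
                      fragment$start_idx[[1]] * 7L)
  ions <- predict_product_ions(fragment, charges = charges,
                               registry = registry)
  keep <- stats::runif(nrow(ions)) >= cfg$dropout_rate
  mz <- ions$mz[keep] + stats::rnorm(sum(keep), 0, cfg$da_noise_sd)
  peaklist(mz, sim_intensity(sum(keep), cfg), ms_level = 2,
           precursor_mz = mz_from_neutral(fragment$mono_mass[[1]],
                                          precursor_z, "negative"),
           precursor_z = precursor_z)
}

#' Simulate a paired native / cyanoethylated run
#'
#' The derivatized channel is generated from [derivatize()] of the same
#' record with a shared seed offset, emulating splitting one tRNA
#' preparation into an untreated and an acrylonitrile-treated aliquot.
#'
#' @inheritParams simulate_ms1
#' @return A list with elements `native` and `ce`, each as returned by
#'   [simulate_ms1()].
#' @export
simulate_ce_pair <- function(rec, rule = cleavage_rule("RNaseT1"),
                             cfg = sim_config(),
                             registry = default_registry()) {
  ce_cfg <- cfg
  ce_cfg$seed <- cfg$seed + SIM_STAGE_OFFSET[["ce"]]
  list(
    native = simulate_ms1(rec, rule, cfg, registry),
    ce = simulate_ms1(derivatize(rec, registry), rule, ce_cfg, registry)
  )
}

#' Simulate an ESI charge series of the intact molecule
#'
#' Peaks at `(M - z * 1.007276) / z` for each charge in the range, with
#' absolute Gaussian m/z noise.
#'
#' @param rec An `mm_trna`.
#' @param charge_range Integer charges of the series.
#' @param noise_da Gaussian m/z noise sd in Da.
#' @param seed Integer seed.
#' @param mode Mass mode of the underlying neutral mass.
#' @param registry Nucleoside registry.
#' @return An `mm_peaklist` of the series (ascending m/z).
#' @export
simulate_charge_series <- function(rec, charge_range = 19:26, noise_da = 0,
                                   seed = 1L, mode = "average",
                                   registry = default_registry()) {
  stopifnot(length(charge_range) >= 1)
  withr::local_seed(seed + SIM_STAGE_OFFSET[["series"]])
  mass <- intact_mass(rec, mode, registry)
  z <- sort(unique(as.integer(charge_range)), decreasing = TRUE)
  mz <- (mass - z * PROTON_MASS) / z + stats::rnorm(length(z), 0, noise_da)
  peaklist(mz, sim_intensity(length(z), sim_config(seed)))
}

#' Simulate a positive-mode nucleoside-level run
#'
#' One MH+ peak per distinct nucleoside in the record, plus the BH2+ base
#' ion for every species that can lose its base.
#'
#' @param rec An `mm_trna`.
#' @param cfg A [sim_config()].
#' @param registry Nucleoside registry.
#' @return A positive-mode `mm_peaklist`.
#' @export
simulate_nucleoside_run <- function(rec, cfg = sim_config(),
                                    registry = default_registry()) {
  withr::local_seed(cfg$seed + SIM_STAGE_OFFSET[["nucleosides"]])
  symbols <- unique(trna_residues(rec)$symbol)
  mh <- nucleoside_mh(symbols, registry)
  bi <- base_ion_mz(symbols, registry)
  mz <- c(mh, bi[!is.na(bi)])
  mz <- mz + stats::rnorm(length(mz), 0, cfg$da_noise_sd)
  peaklist(mz, sim_intensity(length(mz), cfg), polarity = "positive")
}

#' Simulate the complete analytical workflow for one record
#'
#' Bundles everything the identification pipeline consumes: the
#' nucleoside-level run, native and cyanoethylated RNase T1 MS1 digests, a
#' parallel native RNase A digest, and CID spectra of every fragment of
#' length >= 2 in each channel — the same trio of runs (two nucleases plus
#' derivatization) used on real tRNA preparations.
#'
#' @inheritParams simulate_ms1
#' @param second_rule Rule of the parallel digest channel; `NULL` disables
#'   it.
#' @return A list: `nucleosides`, `native` (`$peaks`, `$truth`,
#'   `$fragments`, `$ms2` — a list of MS2 peak lists), `rnase_a` (same
#'   shape, or absent), `ce` (same shape), `truth` (the record).
#' @export
simulate_trna_run <- function(rec, rule = cleavage_rule("RNaseT1"),
                              cfg = sim_config(),
                              second_rule = cleavage_rule("RNaseA"),
                              registry = default_registry()) {
  pair <- simulate_ce_pair(rec, rule, cfg, registry)
  ms2_for <- function(channel, seed_shift) {
    frags <- channel$fragments
    idx <- which(frags$n_res >= 2)
    spectra <- purrr::map(idx, function(i) {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + seed_shift + i * 13L
      simulate_cid(frags[i, ], cfg_i, registry = registry)
    })
    stats::setNames(spectra, paste0(frags$start[idx], ":", frags$end[idx]))
  }
  out <- list(
    nucleosides = simulate_nucleoside_run(rec, cfg, registry),
    native = c(pair$native, list(ms2 = ms2_for(pair$native, 0L))),
    ce = c(pair$ce, list(ms2 = ms2_for(pair$ce, SIM_STAGE_OFFSET[["ce"]]))),
    truth = rec
  )
  if (!is.null(second_rule)) {
    cfg_a <- cfg
    cfg_a$seed <- cfg$seed + 977L
    chan_a <- simulate_ms1(rec, second_rule, cfg_a, registry)
    out$rnase_a <- c(chan_a, list(ms2 = ms2_for(chan_a, 977L)))
  }
  out
}
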