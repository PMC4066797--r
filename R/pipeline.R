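# Stage orchestration: file-in / file-out wrappers over the package's
# functions, plus a plain argument-vector entry point so the thin Rscript in
# inst/scripts/ stays a one-liner. Stages communicate through files only, so
# each is independently testable and a rerun with identical inputs is
# idempotent.

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

echo_config <- function(out_dir, stage, params) {
  ensure_dir(out_dir)
  jsonlite::write_json(c(list(stage = stage), params),
                       file.path(out_dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Digest stage: annotated FASTA in, fragment table out
#'
#' @param fasta,mods Input paths (see [read_annotated_fasta()]).
#' @param rule_name `"RNaseT1"` or `"RNaseA"`.
#' @param out_dir Output directory; receives `fragments.tsv` and the echoed
#'   configuration.
#' @param max_missed Missed cleavages.
#' @return The fragment tibble, invisibly.
#' @export
run_digest <- function(fasta, mods = NULL, rule_name = "RNaseT1",
                       out_dir = ".", max_missed = 0) {
  if (!rule_name %in% c("RNaseT1", "RNaseA")) {
    stop("unknown digestion rule: ", rule_name, call. = FALSE)
  }
  recs <- read_annotated_fasta(fasta, mods)
  frags <- purrr::map_dfr(recs, function(r) {
    fr <- digest(r, cleavage_rule(rule_name), max_missed = max_missed)
    fr$record <- r$name
    fr
  })
  echo_config(out_dir, "digest", list(fasta = fasta, mods = mods,
                                      rule = rule_name,
                                      max_missed = max_missed))
  write_fragment_tsv(frags, file.path(out_dir, "fragments.tsv"))
  invisible(frags)
}

#' Landscape stage: catalog TSV in, summary JSON + histograms out
#'
#' @param catalog_path Catalog TSV ([mt_catalog()] format); default the
#'   shipped bovine mitochondrial catalog.
#' @param out_dir Output directory; receives `landscape.json`,
#'   `per_position.tsv`, `per_trna.tsv`, `wobble.tsv`.
#' @return The `mm_landscape`, invisibly.
#' @export
run_landscape <- function(catalog_path = NULL, out_dir = ".") {
  cat22 <- if (is.null(catalog_path)) mt_catalog() else mt_catalog(catalog_path)
  ls <- landscape_summary(cat22)
  ensure_dir(out_dir)
  jsonlite::write_json(
    list(n_species = ls$n_species, n_positions = ls$n_positions,
         n_psi_sites = count_symbol_sites(cat22, "Y"),
         n_psi_anticodon_arm = count_symbol_sites(cat22, "Y", arm_only = TRUE),
         n_m1a9_m1g9 = count_position(cat22, "9", c("m1A", "m1G"))),
    file.path(out_dir, "landscape.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(ls$per_position, file.path(out_dir, "per_position.tsv"))
  readr::write_tsv(ls$per_trna, file.path(out_dir, "per_trna.tsv"))
  readr::write_tsv(classify_wobble(mt_anticodons(), cat22),
                   file.path(out_dir, "wobble.tsv"))
  echo_config(out_dir, "landscape", list(catalog = catalog_path))
  invisible(ls)
}

#' Simulation stage: write a ground-truthed synthetic run to disk
#'
#' @param seed Integer seed.
#' @param out_dir Output directory; receives peak lists, a fragment truth
#'   table, the annotated record, and a manifest.
#' @param length_range,mod_density Passed to [random_trna()].
#' @return The simulated bundle, invisibly.
#' @export
run_simulate <- function(seed = 1, out_dir = ".", length_range = c(60, 75),
                         mod_density = 0.1) {
  rec <- random_trna(seed, length_range, mod_density)
  cfg <- sim_config(seed = seed)
  run <- simulate_trna_run(rec, cfg = cfg)
  ensure_dir(out_dir)
  write_peaklist(run$nucleosides, file.path(out_dir, "nucleosides.txt"))
  write_peaklist(run$native$peaks, file.path(out_dir, "native_ms1.txt"))
  write_peaklist(run$ce$peaks, file.path(out_dir, "ce_ms1.txt"))
  readr::write_tsv(run$native$truth, file.path(out_dir, "native_truth.tsv"))
  write_annotated_fasta(rec, file.path(out_dir, "truth.fasta"),
                        file.path(out_dir, "truth_mods.tsv"))
  echo_config(out_dir, "simulate",
              list(seed = seed, length_range = length_range,
                   mod_density = mod_density))
  invisible(run)
}

#' Intact-mass stage: charge-series peak list in, deconvolution JSON out
#'
#' @param series_path Two-column peak-list file of the charge series.
#' @param out_dir Output directory; receives `deconvolution.json`.
#' @param charge_range Charges considered.
#' @return The `mm_deconv`, invisibly.
#' @export
run_intact <- function(series_path, out_dir = ".", charge_range = 5:40) {
  if (!file.exists(series_path)) {
    stop("missing input file: ", series_path, call. = FALSE)
  }
  dec <- deconvolve(read_peaklist(series_path), charge_range)
  ensure_dir(out_dir)
  jsonlite::write_json(
    list(neutral_mass = dec$neutral_mass, residual_rms = dec$residual_rms,
         n_peaks_used = dec$n_peaks_used,
         charges = dec$assignments$z),
    file.path(out_dir, "deconvolution.json"), auto_unbox = TRUE, digits = NA
  )
  echo_config(out_dir, "intact", list(series = series_path,
                                      charge_range = range(charge_range)))
  invisible(dec)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `modmap` script in `inst/scripts/`:
#' `modmap <digest|landscape|simulate|intact> [options]`.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit status, invisibly.
#' @export
modmap_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: modmap <digest|landscape|simulate|intact> [options]")
    return(invisible(1L))
  }
  sub <- argv[1]
  rest <- argv[-1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--fasta", type = "character", default = NULL),
    optparse::make_option("--mods", type = "character", default = NULL),
    optparse::make_option("--rule", type = "character", default = "RNaseT1"),
    optparse::make_option("--catalog", type = "character", default = NULL),
    optparse::make_option("--series", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = ".")
  ))
  opts <- optparse::parse_args(parser, args = rest)
  status <- tryCatch({
    switch(sub,
      digest = run_digest(opts$fasta, opts$mods, opts$rule, opts$out),
      landscape = run_landscape(opts$catalog, opts$out),
      simulate = run_simulate(opts$seed, opts$out),
      intact = run_intact(opts$series, opts$out),
      stop("unknown subcommand: ", sub, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("modmap ", sub, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
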