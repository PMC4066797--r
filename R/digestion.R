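# In-silico RNase digestion of annotated tRNAs.
#
# Terminal chemistry follows endoribonuclease mechanism: products carry
# 5'-hydroxyl and 3'-phosphate (via a 2',3'-cyclic intermediate), so internal
# fragments are 5'OH/3'p, the 5'-terminal fragment inherits the molecule's
# 5' group, and the 3'-terminal fragment inherits the molecule's 3' group.

HPO3 <- "HPO3"
H2O <- "H2O"

#' Define a cleavage rule
#'
#' Built-in rules are `"RNaseT1"` (cuts 3' of guanosine-ring residues whose
#' `t1_cleavable` registry flag is set: G and m2G by default) and `"RNaseA"`
#' (cuts 3' of pyrimidine-ring residues per the `a_cleavable` flag). A custom
#' rule names the symbols it cuts after explicitly.
#'
#' @param name `"RNaseT1"`, `"RNaseA"`, or a custom name (requires
#'   `cleave_after`).
#' @param cleave_after Optional character vector of symbols the enzyme cuts
#'   3' of; overrides the registry flag.
#' @param max_missed Default number of missed cleavages (0-5) for
#'   [digest()].
#' @return An object of class `mm_rule`.
#' @export
cleavage_rule <- function(name = c("RNaseT1", "RNaseA"), cleave_after = NULL,
                          max_missed = 0) {
  stopifnot(max_missed >= 0, max_missed <= 5)
  if (is.null(cleave_after)) {
    name <- match.arg(name)
    flag <- c(RNaseT1 = "t1_cleavable", RNaseA = "a_cleavable")[[name]]
  } else {
    flag <- NULL
  }
  structure(list(name = name, flag = flag,
                 cleave_after = cleave_after,
                 max_missed = as.integer(max_missed)),
            class = "mm_rule")
}

rule_cuts_after <- function(rule, symbols, registry) {
  if (!is.null(rule$cleave_after)) {
    symbols %in% normalize_symbol(rule$cleave_after)
  } else {
    reg_lookup(symbols, registry)[[rule$flag]]
  }
}

terminal_formula_count <- function(group) {
  switch(group, hydroxyl = 0, phosphate = 1, cyclic_phosphate = 1,
         stop("unknown terminal group: ", group, call. = FALSE))
}

#' Neutral mass of an oligonucleotide
#'
#' Mass arithmetic for a linear oligo of `n` residues: the sum of the free
#' nucleoside formulas, plus `(n-1)` phosphodiester linkages (each HPO3 minus
#' H2O), plus one HPO3 per phosphorylated terminus; hydroxyl termini
#' contribute nothing, and a 2',3'-cyclic phosphate is a linear 3'-phosphate
#' minus H2O.
#'
#' @param symbols Character vector of residue symbols, 5' to 3'.
#' @param five_prime `"hydroxyl"` or `"phosphate"`.
#' @param three_prime `"hydroxyl"`, `"phosphate"` or `"cyclic_phosphate"`.
#' @param mode `"monoisotopic"` or `"average"`.
#' @param registry Nucleoside registry.
#' @return Neutral mass in Da.
#' @examples
#' oligo_mass(c("G","A","G","G","A","U"), "phosphate", "phosphate")  # 2097.25
#' @export
oligo_mass <- function(symbols, five_prime = "hydroxyl",
                       three_prime = "phosphate",
                       mode = c("monoisotopic", "average"),
                       registry = default_registry()) {
  mode <- match.arg(mode)
  formula_mass(oligo_formula(symbols, five_prime, three_prime, registry), mode)
}

#' Elemental formula of an oligonucleotide
#' @inheritParams oligo_mass
#' @return An `mm_formula`.
#' @export
oligo_formula <- function(symbols, five_prime = "hydroxyl",
                          three_prime = "phosphate",
                          registry = default_registry()) {
  symbols <- normalize_symbol(symbols)
  n <- length(symbols)
  stopifnot(n >= 1)
  f <- chem_formula()
  for (s in symbols) f <- f + reg_formula(s, registry)
  n_p <- terminal_formula_count(five_prime) + terminal_formula_count(three_prime)
  f <- f + (n - 1 + n_p) * chem_formula(HPO3)
  n_w <- n - 1 + if (identical(three_prime, "cyclic_phosphate")) 1 else 0
  f - n_w * chem_formula(H2O)
}

# fast numeric version used in bulk fragment/ion work
oligo_mass_fast <- function(symbols, five_prime, three_prime, mass_by_symbol,
                            linkage, hpo3, h2o) {
  n <- length(symbols)
  m <- sum(mass_by_symbol[symbols]) + (n - 1) * linkage +
    (terminal_formula_count(five_prime) + terminal_formula_count(three_prime)) * hpo3
  if (identical(three_prime, "cyclic_phosphate")) m <- m - h2o
  m
}

symbol_mass_table <- function(registry, mode) {
  key <- paste0("mass_tab_", mode)
  cached <- !is.null(.mm_cache$registry) &&
    identical(registry, .mm_cache$registry)
  if (cached && !is.null(.mm_cache[[key]])) return(.mm_cache[[key]])
  tab <- stats::setNames(
    purrr::map_dbl(registry$formula, formula_mass, mode = mode),
    registry$symbol
  )
  if (cached) .mm_cache[[key]] <- tab
  tab
}

digest_resolved <- function(symbols, labels, five_prime, three_prime,
                            cuts_after, max_missed, registry,
                            mono_tab, avg_tab, link_mono, link_avg,
                            hpo3_mono, hpo3_avg, h2o_mono, h2o_avg) {
  n <- length(symbols)
  cut_idx <- which(cuts_after & seq_len(n) < n)   # cut 3' of these residues
  starts <- c(1L, cut_idx + 1L)
  ends <- c(cut_idx, n)
  n_frag <- length(starts)
  pieces <- list()
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + max_missed)) {
      s <- starts[i]; e <- ends[j]
      fp <- if (s == 1L) five_prime else "hydroxyl"
      tp <- if (e == n) three_prime else "phosphate"
      prov <- if (s == 1L && e == n) "intact"
      else if (s == 1L) "five_terminal"
      else if (e == n) "three_terminal"
      else "internal"
      syms <- symbols[s:e]
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        start = labels[s], end = labels[e], start_idx = s, end_idx = e,
        n_res = e - s + 1L,
        seq = paste0(syms, collapse = ""),
        symbols = list(syms),
        five_prime = fp, three_prime = tp, provenance = prov,
        missed = j - i,
        internal_cut_idx = list(if (j > i) ends[i:(j - 1L)] - s + 1L else integer()),
        mono_mass = oligo_mass_fast(syms, fp, tp, mono_tab, link_mono,
                                    hpo3_mono, h2o_mono),
        avg_mass = oligo_mass_fast(syms, fp, tp, avg_tab, link_avg,
                                   hpo3_avg, h2o_avg)
      )
    }
  }
  dplyr::bind_rows(pieces)
}

#' Digest an annotated tRNA record in silico
#'
#' Cuts 3' of every residue the rule recognises. At `max_missed = 0` the
#' fragments tile the sequence exactly once; with `max_missed = k` every
#' contiguous union of up to `k + 1` adjacent zero-missed fragments is also
#' emitted. Heteroplasmic records are expanded before digestion and the
#' fragments carry the `allele_id`; sub-stoichiometric ("partial")
#' modification sites cause both the modified and the unmodified fragment
#' variant to be emitted, flagged in `variant`.
#'
#' @param rec An `mm_trna` record.
#' @param rule An `mm_rule` from [cleavage_rule()].
#' @param max_missed Missed-cleavage count; defaults to the rule's.
#' @param cyclic Also emit 2',3'-cyclic-phosphate variants (linear 3'p minus
#'   H2O) for every fragment ending in a phosphate? Off by default; every
#'   printed fragment mass in the source data is the linear form.
#' @param registry Nucleoside registry.
#' @return A tibble, one row per fragment, ordered 5' to 3' (then by missed
#'   cleavages), with columns `start`, `end`, `start_idx`, `end_idx`,
#'   `n_res`, `seq`, `symbols` (list), `five_prime`, `three_prime`,
#'   `provenance`, `missed`, `internal_cut_idx` (list), `mono_mass`,
#'   `avg_mass`, `variant`, `allele_id`.
#' @examples
#' frags <- digest(trna_ala(), cleavage_rule("RNaseT1"))
#' frags[frags$seq == "AUUUm1Am2G", c("start", "end", "mono_mass")]
#' @export
digest <- function(rec, rule = cleavage_rule("RNaseT1"), max_missed = NULL,
                   cyclic = FALSE, registry = default_registry()) {
  stopifnot(inherits(rec, "mm_trna"), inherits(rule, "mm_rule"))
  if (is.null(max_missed)) max_missed <- rule$max_missed
  res0 <- trna_residues(rec)
  if (nrow(res0) == 0) stop("cannot digest an empty sequence", call. = FALSE)

  mono_tab <- symbol_mass_table(registry, "monoisotopic")
  avg_tab <- symbol_mass_table(registry, "average")
  link_mono <- formula_mass(HPO3) - formula_mass(H2O)
  link_avg <- formula_mass(HPO3, "average") - formula_mass(H2O, "average")

  out <- purrr::map_dfr(expand_alleles(rec), function(arec) {
    res <- trna_residues(arec)
    partial_idx <- which(res$partial)
    # every on/off combination of partial sites, fully modified first
    combos <- if (length(partial_idx)) {
      purrr::map(seq_len(2^length(partial_idx)) - 1L, function(mask) {
        partial_idx[bitwAnd(mask, 2^(seq_along(partial_idx) - 1L)) > 0]
      })
    } else list(integer())
    purrr::map_dfr(combos, function(off_sites) {
      symbols <- res$symbol
      if (length(off_sites)) {
        symbols[off_sites] <- parent_of(symbols[off_sites], registry)
      }
      cuts <- rule_cuts_after(rule, symbols, registry)
      fr <- digest_resolved(symbols, res$label, arec$five_prime,
                            arec$three_prime, cuts, max_missed, registry,
                            mono_tab, avg_tab, link_mono, link_avg,
                            formula_mass(HPO3), formula_mass(HPO3, "average"),
                            formula_mass(H2O), formula_mass(H2O, "average"))
      fr$variant <- if (length(off_sites)) {
        paste0(res$label[off_sites], "->",
               parent_of(res$symbol[off_sites], registry), collapse = "+")
      } else ""
      fr$allele_id <- attr(arec, "allele_id") %||% ""
      fr
    })
  })
  # drop variant duplicates (a partial site outside a fragment leaves it unchanged)
  out <- dplyr::distinct(out, .data$seq, .data$start, .data$end,
                         .data$five_prime, .data$three_prime, .data$missed,
                         .data$allele_id, .keep_all = TRUE)
  if (cyclic) {
    cyc <- dplyr::filter(out, .data$three_prime == "phosphate")
    if (nrow(cyc)) {
      cyc$three_prime <- "cyclic_phosphate"
      cyc$mono_mass <- cyc$mono_mass - formula_mass(H2O)
      cyc$avg_mass <- cyc$avg_mass - formula_mass(H2O, "average")
      out <- dplyr::bind_rows(out, cyc)
    }
  }
  dplyr::arrange(out, .data$start_idx, .data$end_idx, .data$three_prime,
                 .data$variant)
}

#' Neutral mass of a digest fragment row
#'
#' @param fragment One row of a [digest()] table (or a list with `symbols`,
#'   `five_prime`, `three_prime`).
#' @param mode `"monoisotopic"` or `"average"`.
#' @param registry Nucleoside registry.
#' @return Neutral mass in Da.
#' @export
fragment_mass <- function(fragment, mode = c("monoisotopic", "average"),
                          registry = default_registry()) {
  mode <- match.arg(mode)
  symbols <- if (is.data.frame(fragment)) fragment$symbols[[1]] else fragment$symbols
  fp <- fragment$five_prime[[1]]
  tp <- fragment$three_prime[[1]]
  oligo_mass(symbols, fp, tp, mode, registry)
}

#' Write a digest table to TSV
#'
#' List-columns are flattened to comma-separated strings.
#' @param fragments A [digest()] tibble.
#' @param path Output path.
#' @export
write_fragment_tsv <- function(fragments, path) {
  flat <- fragments
  flat$symbols <- purrr::map_chr(flat$symbols, paste0, collapse = ",")
  flat$internal_cut_idx <- purrr::map_chr(flat$internal_cut_idx,
                                          paste0, collapse = ",")
  readr::write_tsv(flat, path)
  invisible(path)
}
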