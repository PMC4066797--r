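# Registry of canonical and modified ribonucleosides.
#
# Formulas are for the free, uncharged nucleoside. Behaviour flags drive
# digestion (cleavability), CID (base loss) and the cyanoethylation workflow
# (derivatizability); all flags are data and can be overridden by editing the
# registry tibble before passing it downstream.

# Anhydro-ribose: what a nucleoside loses when the glycosidic bond breaks.
ANHYDRO_RIBOSE <- 132.042259   # C5H8O4, monoisotopic

REGISTRY_COLUMNS <- c(
  "symbol", "name", "parent", "formula", "ring",
  "t1_cleavable", "a_cleavable", "base_loss", "ce_derivatizable"
)

# Unicode/MODOMICS-style spellings accepted as input aliases.
SYMBOL_ALIASES <- c(
  "Ψ"       = "Y",      # Greek Psi
  "Psi"          = "Y",
  "psi"          = "Y",
  "ce1Ψ"    = "ce1Y",
  "ce1Psi"       = "ce1Y",
  "τm5U"    = "tm5U",   # tau
  "τm5s2U"  = "tm5s2U",
  "taum5U"       = "tm5U",
  "taum5s2U"     = "tm5s2U"
)

#' Normalize a nucleoside symbol
#'
#' Maps accepted alias spellings (Greek letters, MODOMICS-style names) onto
#' the registry's canonical ASCII symbols, e.g. `"Ψ"` to `"Y"`.
#'
#' @param symbol Character vector of symbols.
#' @return Character vector of canonical symbols.
#' @export
normalize_symbol <- function(symbol) {
  hit <- match(symbol, names(SYMBOL_ALIASES))
  ifelse(is.na(hit), symbol, unname(SYMBOL_ALIASES[hit]))
}

#' The default nucleoside registry
#'
#' One row per ribonucleoside: the four canonicals plus every modified
#' species in the bovine mitochondrial tRNA catalog, the cyanoethylated
#' pseudouridine adduct, and the glycosylated queuosines found in cytosolic
#' tRNAs (registered for completeness; they do not occur in the
#' mitochondrial catalog).
#'
#' Flags encode literature-standard enzymology and chemistry:
#' * `t1_cleavable`: RNase T1 cuts 3' of guanosine and of N2-methylguanosine
#'   (m2G-terminated digest products are observed), but N1-methylation,
#'   N2,N2-dimethylation and the queuosine base swap block the enzyme.
#' * `a_cleavable`: RNase A cuts 3' of every pyrimidine-ring residue,
#'   including pseudouridine, dihydrouridine and the 5-substituted species;
#'   N1-cyanoethylation blocks it.
#' * `base_loss`: N-glycosides lose their base under CID / in-source decay;
#'   pseudouridine is a C-glycoside and cannot.
#' * `ce_derivatizable`: acrylonitrile (Michael addition, +C3H3N, +53 Da)
#'   targets pseudouridine N1 only.
#'
#' @return A tibble with columns `symbol`, `name`, `parent`, `formula`,
#'   `ring`, `t1_cleavable`, `a_cleavable`, `base_loss`, `ce_derivatizable`.
#' @examples
#' reg <- default_registry()
#' nucleoside_mh("m1A")   # 282.12, the m/z 282 nucleoside ion
#' @export
default_registry <- function() {
  if (!is.null(.mm_cache$registry)) return(.mm_cache$registry)
  .mm_cache$registry <- build_default_registry()
  .mm_cache$registry
}

# per-session cache: the default registry and its per-mode mass tables are
# immutable, so they are built once
.mm_cache <- new.env(parent = emptyenv())

build_default_registry <- function() {
  tribble_args <- list(
    # symbol  name                                   parent formula         ring          t1     a      bl     ce
    c("A",      "adenosine",                            "A", "C10H13N5O4",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("G",      "guanosine",                            "G", "C10H13N5O5",  "purine",     TRUE,  FALSE, TRUE,  FALSE),
    c("C",      "cytidine",                             "C", "C9H13N3O5",   "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("U",      "uridine",                              "U", "C9H12N2O6",   "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("m1A",    "1-methyladenosine",                    "A", "C11H15N5O4",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("m1G",    "1-methylguanosine",                    "G", "C11H15N5O5",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("m2G",    "N2-methylguanosine",                   "G", "C11H15N5O5",  "purine",     TRUE,  FALSE, TRUE,  FALSE),
    c("m22G",   "N2,N2-dimethylguanosine",              "G", "C12H17N5O5",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("m3C",    "3-methylcytidine",                     "C", "C10H15N3O5",  "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("m5C",    "5-methylcytidine",                     "C", "C10H15N3O5",  "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("f5C",    "5-formylcytidine",                     "C", "C10H13N3O6",  "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("D",      "dihydrouridine",                       "U", "C9H14N2O6",   "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("Y",      "pseudouridine",                        "U", "C9H12N2O6",   "pyrimidine", FALSE, TRUE,  FALSE, TRUE),
    c("ce1Y",   "1-cyanoethylpseudouridine",            "U", "C12H15N3O6",  "pyrimidine", FALSE, FALSE, FALSE, FALSE),
    c("m5U",    "5-methyluridine",                      "U", "C10H14N2O6",  "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("tm5U",   "5-taurinomethyluridine",               "U", "C12H19N3O9S", "pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("tm5s2U", "5-taurinomethyl-2-thiouridine",        "U", "C12H19N3O8S2","pyrimidine", FALSE, TRUE,  TRUE,  FALSE),
    c("t6A",    "N6-threonylcarbamoyladenosine",        "A", "C15H20N6O8",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("i6A",    "N6-isopentenyladenosine",              "A", "C15H21N5O4",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("ms2i6A", "2-methylthio-N6-isopentenyladenosine", "A", "C16H23N5O4S", "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("Q",      "queuosine",                            "G", "C17H23N5O7",  "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("manQ",   "mannosyl-queuosine",                   "G", "C23H33N5O12", "purine",     FALSE, FALSE, TRUE,  FALSE),
    c("galQ",   "galactosyl-queuosine",                 "G", "C23H33N5O12", "purine",     FALSE, FALSE, TRUE,  FALSE)
  )
  reg <- purrr::map_dfr(tribble_args, function(r) {
    tibble::tibble(
      symbol = r[1], name = r[2], parent = r[3], formula = r[4], ring = r[5],
      t1_cleavable = as.logical(r[6]), a_cleavable = as.logical(r[7]),
      base_loss = as.logical(r[8]), ce_derivatizable = as.logical(r[9])
    )
  })
  validate_registry(reg)
}

#' Validate a registry tibble
#'
#' Checks column presence, symbol uniqueness, parent validity and that every
#' formula parses to a non-empty composition. Called on every registry read
#' from disk; useful directly when building a custom registry.
#'
#' @param reg A registry tibble.
#' @return The registry, invisibly unchanged, or an error.
#' @export
validate_registry <- function(reg) {
  stopifnot(all(REGISTRY_COLUMNS %in% names(reg)))
  if (anyDuplicated(reg$symbol)) {
    stop("duplicate registry symbol(s): ",
         paste(unique(reg$symbol[duplicated(reg$symbol)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(reg$parent %in% c("A", "G", "C", "U"))) {
    stop("registry parents must be one of A, G, C, U", call. = FALSE)
  }
  canon <- reg$symbol[reg$symbol %in% c("A", "G", "C", "U")]
  stopifnot(all(reg$parent[match(canon, reg$symbol)] == canon))
  # every formula must parse and be non-empty
  purrr::walk(reg$formula, function(f) {
    if (formula_mass(f) <= 0) stop("empty registry formula", call. = FALSE)
  })
  reg
}

#' Look up registry rows by symbol
#'
#' @param symbol Character vector of symbols (aliases accepted).
#' @param registry A registry tibble, by default [default_registry()].
#' @return The matching registry rows, in input order.
#' @export
reg_lookup <- function(symbol, registry = default_registry()) {
  symbol <- normalize_symbol(symbol)
  idx <- match(symbol, registry$symbol)
  if (anyNA(idx)) {
    stop("unknown nucleoside symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  registry[idx, ]
}

#' Elemental formula of a registered nucleoside
#'
#' @inheritParams reg_lookup
#' @return An `mm_formula` (single symbol only).
#' @export
reg_formula <- function(symbol, registry = default_registry()) {
  chem_formula(reg_lookup(symbol, registry)$formula)
}

#' Formula difference between a modified nucleoside and its parent
#'
#' @inheritParams reg_lookup
#' @return A tibble with `symbol`, `parent` and the signed element-count
#'   difference columns (one per element).
#' @export
residue_delta <- function(symbol, registry = default_registry()) {
  rows <- reg_lookup(symbol, registry)
  purrr::map2_dfr(rows$symbol, rows$parent, function(s, p) {
    d <- unclass(reg_formula(s, registry)) - unclass(reg_formula(p, registry))
    tibble::tibble(symbol = s, parent = p, !!!as.list(d))
  })
}

#' Monoisotopic delta mass of a modification versus its parent
#' @inheritParams reg_lookup
#' @return Numeric vector of delta masses in Da (0 for mass-silent species).
#' @export
delta_mass <- function(symbol, registry = default_registry()) {
  rows <- reg_lookup(symbol, registry)
  purrr::map2_dbl(rows$symbol, rows$parent, function(s, p) {
    formula_mass(reg_formula(s, registry)) - formula_mass(reg_formula(p, registry))
  })
}

#' Protonated nucleoside ion (MH+) m/z
#'
#' Positive-mode nucleoside analysis observes the protonated free
#' nucleoside, e.g. m/z 282 for 1-methyladenosine.
#'
#' @inheritParams reg_lookup
#' @return Numeric vector of MH+ m/z values.
#' @export
nucleoside_mh <- function(symbol, registry = default_registry()) {
  purrr::map_dbl(normalize_symbol(symbol), function(s) {
    formula_mass(reg_formula(s, registry)) + PROTON_MASS
  })
}

#' Protonated base ion (BH2+) m/z, or NA when base loss is disallowed
#'
#' The glycosidic bond of N-glycosides breaks under in-source decay, giving
#' a base ion 132.0423 Da (anhydro-ribose) below MH+; pseudouridine is a
#' C-glycoside and yields none.
#'
#' @inheritParams reg_lookup
#' @return Numeric vector of BH2+ m/z values; `NA` where base loss is
#'   disallowed.
#' @export
base_ion_mz <- function(symbol, registry = default_registry()) {
  rows <- reg_lookup(symbol, registry)
  ifelse(rows$base_loss,
         nucleoside_mh(rows$symbol, registry) - ANHYDRO_RIBOSE,
         NA_real_)
}

#' Naturally occurring modifications distinguishable in peak lists
#'
#' The registry's natural modified species minus one member of each
#' positional-isomer class: m3C is a positional isomer of m5C and the
#' glycosyl-queuosines are isomers of each other, so they share parent base
#' and mass delta and cannot be told apart by any mass measurement alone
#' (on instrument, chromatographic identity separates them; the peak-list
#' abstraction drops retention time). The cyanoethyl adduct is an artifact
#' species, not a natural modification. This set is both the default
#' search space of the identification pipeline and the default sampling
#' pool of the synthetic-data generator.
#'
#' @return Character vector of modification symbols.
#' @export
default_search_mods <- function() {
  c("m1A", "t6A", "i6A", "ms2i6A",
    "m1G", "m2G", "m22G", "Q",
    "m5C", "f5C",
    "Y", "D", "m5U", "tm5U", "tm5s2U")
}

#' Read / write a registry TSV
#'
#' The on-disk form mirrors the registry tibble column-for-column so a
#' registry can be audited or overridden outside R.
#'
#' @param path File path.
#' @return `read_registry_tsv()` returns a validated registry tibble.
#' @export
read_registry_tsv <- function(path) {
  reg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           t1_cleavable = readr::col_logical(),
                           a_cleavable = readr::col_logical(),
                           base_loss = readr::col_logical(),
                           ce_derivatizable = readr::col_logical(),
                           .default = readr::col_character()
                         ))
  validate_registry(reg)
}

#' @rdname read_registry_tsv
#' @param registry A registry tibble.
#' @export
write_registry_tsv <- function(registry, path) {
  readr::write_tsv(validate_registry(registry), path)
  invisible(path)
}
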