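# Landscape statistics over a modification catalog and wobble-position
# decoding rules for the mitochondrial genetic code.

#' Summarize a modification catalog
#'
#' A *site* is a distinct (tRNA, position) pair; layered species that
#' co-occupy one site (2-thiolation over the taurinomethyl group at the
#' wobble position, 2-methylthiolation over the isopentenyl group at 37)
#' are counted once per site but separately per species. This double-
#' occupancy rule is what makes the species and site counts of the bovine
#' mitochondrial catalog come out as 15 and 118.
#'
#' @param catalog An `mm_catalog` tibble ([mt_catalog()]).
#' @param total_bases Optional total base count of the underlying tRNA set;
#'   when given, `percent_modified` is computed.
#' @return An object of class `mm_landscape`: counts, per-position and
#'   per-tRNA histograms, and the entry table. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' summary22 <- landscape_summary(mt_catalog())
#' glance(summary22)   # 15 species at 118 sites
#' @export
landscape_summary <- function(catalog, total_bases = NULL) {
  sites <- dplyr::distinct(tibble::as_tibble(catalog), .data$trna,
                           .data$position)
  per_position <- dplyr::arrange(
    dplyr::count(sites, .data$position, name = "n_trnas"),
    position_key(.data$position)
  )
  per_trna <- dplyr::count(sites, .data$trna, name = "n_sites")
  structure(list(
    n_species = dplyr::n_distinct(catalog$symbol),
    n_positions = nrow(sites),
    per_position = per_position,
    per_trna = per_trna,
    percent_modified = if (!is.null(total_bases)) {
      100 * nrow(sites) / total_bases
    } else NA_real_,
    entries = tibble::as_tibble(catalog)
  ), class = "mm_landscape")
}

#' @export
print.mm_landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d modified-nucleoside species at %d sites in %d tRNAs\n",
              x$n_species, x$n_positions, nrow(x$per_trna)))
  invisible(x)
}

#' @method tidy mm_landscape
#' @export
tidy.mm_landscape <- function(x, ...) {
  x$entries
}

#' @method glance mm_landscape
#' @export
glance.mm_landscape <- function(x, ...) {
  tibble::tibble(n_species = x$n_species, n_positions = x$n_positions,
                 n_trnas = nrow(x$per_trna),
                 percent_modified = x$percent_modified)
}

#' @method autoplot mm_landscape
#' @export
autoplot.mm_landscape <- function(object, ...) {
  pp <- object$per_position
  pp$position <- factor(pp$position,
                        levels = pp$position[order(position_key(pp$position))])
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$position, y = .data$n_trnas)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "tRNA position", y = "tRNAs modified",
                  title = sprintf("%d modification sites, %d species",
                                  object$n_positions, object$n_species)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Count tRNAs carrying given modifications at a position
#'
#' @param catalog An `mm_catalog`.
#' @param position A position label, e.g. `"9"` or `"27a"`.
#' @param symbols Modification symbols of interest (aliases accepted); the
#'   empty set yields 0.
#' @return Integer count of distinct tRNAs.
#' @examples
#' count_position(mt_catalog(), "9", c("m1A", "m1G"))   # 19
#' @export
count_position <- function(catalog, position, symbols) {
  if (!length(symbols)) return(0L)
  symbols <- normalize_symbol(symbols)
  hits <- catalog[catalog$position == as.character(position) &
                    catalog$symbol %in% symbols, ]
  dplyr::n_distinct(hits$trna)
}

#' Sites carrying a modification, optionally restricted to the anticodon arm
#'
#' The anticodon arm is taken as positions 27-43 inclusive (letter-suffixed
#' insertions such as 27a included), the standard arm boundary.
#'
#' @param catalog An `mm_catalog`.
#' @param symbol A modification symbol.
#' @param arm_only Restrict to the anticodon arm?
#' @return Integer count of distinct (tRNA, position) sites.
#' @examples
#' count_symbol_sites(mt_catalog(), "Y")                    # 42
#' count_symbol_sites(mt_catalog(), "Y", arm_only = TRUE)   # 35
#' @export
count_symbol_sites <- function(catalog, symbol, arm_only = FALSE) {
  hits <- catalog[catalog$symbol == normalize_symbol(symbol), ]
  if (arm_only) {
    num <- parse_position_label(hits$position)$number
    hits <- hits[num >= 27 & num <= 43, ]
  }
  nrow(dplyr::distinct(tibble::as_tibble(hits), .data$trna, .data$position))
}

# ---- wobble decoding rules --------------------------------------------------

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

# Codon-box classes of the vertebrate mitochondrial genetic code, keyed by
# the first two codon letters. "family": all four codons one amino acid,
# read by a single tRNA. Split boxes divide into purine-ending (NNR) and
# pyrimidine-ending (NNY) halves (AGR are stop codons in mitochondria).
MT_FAMILY_BOXES <- c("UC", "CU", "CC", "CG", "AC", "GU", "GC", "GG")

wobble_class_of_symbol <- function(symbol, registry = default_registry()) {
  symbol <- normalize_symbol(symbol)
  dplyr::case_when(
    symbol == "U" ~ "unmodified_U",
    symbol %in% c("tm5U", "tm5s2U") ~ "taurine_U",
    symbol == "f5C" ~ "f5C",
    symbol %in% c("Q", "manQ", "galQ") ~ "Q",
    symbol == "G" ~ "unmodified_G",
    TRUE ~ "other"
  )
}

#' Classify wobble positions against mitochondrial decoding rules
#'
#' The minimal mitochondrial decoding system follows a strict pattern at
#' position 34: family boxes (four synonymous codons, one tRNA) are read by
#' an unmodified U via four-way wobble; purine-ending two-codon sets (NNR)
#' require a conformation-restricting modification (taurinomethyl-uridines,
#' or 5-formylcytidine for the AUA/AUG set); NAY sets are read by queuosine;
#' remaining pyrimidine-ending sets by an unmodified G.
#'
#' @param anticodons A tibble like [mt_anticodons()]: `trna`, `a34`, `a35`,
#'   `a36` (wobble symbol in its mature modified form).
#' @param catalog Optional `mm_catalog`; when given, the observed wobble
#'   symbol is taken from catalog entries at position 34 (preferring the
#'   layered thio species), falling back to `a34`.
#' @param registry Nucleoside registry.
#' @return A tibble with `trna`, `anticodon`, `box`, `box_class`,
#'   `wobble_symbol`, `wobble_class`, `expected_class`, `verdict`
#'   (`"consistent"` or `"violation"`).
#' @examples
#' table(classify_wobble(mt_anticodons(), mt_catalog())$verdict)
#' @export
classify_wobble <- function(anticodons = mt_anticodons(), catalog = NULL,
                            registry = default_registry()) {
  needed <- c("trna", "a34", "a35", "a36")
  stopifnot(all(needed %in% names(anticodons)))
  purrr::map_dfr(seq_len(nrow(anticodons)), function(i) {
    row <- anticodons[i, ]
    p34 <- parent_of(normalize_symbol(row$a34), registry)
    p35 <- parent_of(normalize_symbol(row$a35), registry)
    p36 <- parent_of(normalize_symbol(row$a36), registry)
    if (anyNA(c(p34, p35, p36))) {
      stop("unknown anticodon for tRNA ", row$trna, call. = FALSE)
    }
    # codon read 5'->3' pairs anticodon 36-35-34
    box <- paste0(COMPLEMENT[[p36]], COMPLEMENT[[p35]])
    # in a split box, U- and C-wobble tRNAs serve the purine-ending half,
    # G-wobble tRNAs the pyrimidine-ending half (NAY when codon letter 2 is A)
    box_class <- if (box %in% MT_FAMILY_BOXES) {
      "family"
    } else if (p34 %in% c("U", "C")) {
      "NNR_pair"
    } else if (p34 == "G" && COMPLEMENT[[p35]] == "A") {
      "NAY_pair"
    } else {
      "NNY_pair"
    }
    wobble <- normalize_symbol(row$a34)
    if (!is.null(catalog)) {
      at34 <- catalog$symbol[catalog$position == "34" &
                               catalog$trna == row$trna]
      if (length(at34)) {
        # layered thio species supersedes its precursor at the same site
        wobble <- if ("tm5s2U" %in% at34) "tm5s2U" else at34[1]
      }
    }
    wobble_class <- wobble_class_of_symbol(wobble, registry)
    expected <- switch(box_class,
                       family = "unmodified_U",
                       NNR_pair = c("taurine_U", "f5C"),
                       NAY_pair = "Q",
                       NNY_pair = "unmodified_G")
    tibble::tibble(
      trna = row$trna,
      anticodon = paste0(row$a34, row$a35, row$a36),
      box = box, box_class = box_class,
      wobble_symbol = wobble, wobble_class = wobble_class,
      expected_class = paste(expected, collapse = "|"),
      verdict = if (wobble_class %in% expected) "consistent" else "violation"
    )
  })
}
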