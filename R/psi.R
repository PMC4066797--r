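# Differential native-vs-cyanoethylated analysis for pseudouridine mapping.
#
# Pseudouridine is mass-silent (an isomer of uridine), so it is invisible to
# any mass measurement of the native molecule. Acrylonitrile adds a
# cyanoethyl group (+C3H3N, +53.0265 Da) to pseudouridine N1; comparing a
# native and a derivatized digest of the same molecule reveals how many
# pseudouridines each fragment span carries.

CE_DELTA <- 53.026549   # acrylonitrile C3H3N, monoisotopic

# derivatization products, keyed by substrate symbol
CE_PRODUCT <- c(Y = "ce1Y")

#' Cyanoethylate a tRNA record in silico
#'
#' Replaces every derivatizable residue (pseudouridine, per the registry's
#' `ce_derivatizable` flag) with its cyanoethyl adduct. Complete
#' derivatization is assumed; the operation is idempotent.
#'
#' @param rec An `mm_trna`.
#' @param registry Nucleoside registry.
#' @return The derivatized `mm_trna`.
#' @examples
#' derivatize(trna_ala())   # three residues become ce1Y
#' @export
derivatize <- function(rec, registry = default_registry()) {
  res <- trna_residues(rec)
  flag <- reg_lookup(res$symbol, registry)$ce_derivatizable
  symbols <- res$symbol
  symbols[flag] <- CE_PRODUCT[symbols[flag]]
  if (anyNA(symbols)) {
    stop("no cyanoethylation product registered for: ",
         paste(unique(res$symbol[flag][is.na(symbols[flag])]), collapse = ", "),
         call. = FALSE)
  }
  new_trna(rec$name, symbols, res$label, alleles = res$alleles,
           partial = res$partial, five_prime = rec$five_prime,
           three_prime = rec$three_prime, registry = registry)
}

#' Pair native and cyanoethylated fragment identifications and count adducts
#'
#' Fragments from the native and the derivatized run of the same digestion
#' are paired by their (start, end) span; the mass shift divided by
#' 53.0265 Da gives the number of cyanoethyl adducts, i.e. the number of
#' pseudouridines in the span. Spans with `delta_count >= 1` are the
#' pseudouridine candidates handed on to CID localization of the
#' derivatized species.
#'
#' @param native,ce Identification tables for the two channels: any tibble
#'   with columns `start`, `end`, `seq` and a neutral-mass column
#'   (`neutral_mass` from [match_peaks()] output, or `mono_mass` from
#'   [digest()]). When several candidates exist per span the lowest-rank /
#'   first row per span is used.
#' @param strict Error when a span is present in only one channel
#'   (`TRUE`), or report it with `NA` delta (`FALSE`, default)?
#' @return A tibble with columns `start`, `end`, `seq`, `native_mass`,
#'   `ce_mass`, `delta_count`, `delta_residual` (Da deviation from an
#'   integer number of adducts).
#' @export
pair_and_count <- function(native, ce, strict = FALSE) {
  pick <- function(x, channel) {
    mass_col <- intersect(c("neutral_mass", "mono_mass"), names(x))[1]
    if (is.na(mass_col)) {
      stop("no neutral-mass column in ", channel, " table", call. = FALSE)
    }
    x <- x[!is.na(x[[mass_col]]), , drop = FALSE]
    if ("rank" %in% names(x)) x <- dplyr::arrange(x, .data$rank)
    x <- dplyr::distinct(x, .data$start, .data$end, .keep_all = TRUE)
    tibble::tibble(start = x$start, end = x$end, seq = x$seq,
                   mass = x[[mass_col]])
  }
  n <- pick(native, "native")
  d <- pick(ce, "derivatized")
  paired <- dplyr::full_join(n, d, by = c("start", "end"),
                             suffix = c("_native", "_ce"))
  if (strict && (anyNA(paired$mass_native) || anyNA(paired$mass_ce))) {
    stop("native and derivatized channels cover inconsistent fragment spans",
         call. = FALSE)
  }
  delta <- paired$mass_ce - paired$mass_native
  count <- round(delta / CE_DELTA)
  if (any(!is.na(count) & count < 0)) {
    stop("negative cyanoethylation delta; channels are likely swapped",
         call. = FALSE)
  }
  tibble::tibble(
    start = paired$start, end = paired$end,
    seq = dplyr::coalesce(paired$seq_native, paired$seq_ce),
    native_mass = paired$mass_native, ce_mass = paired$mass_ce,
    delta_count = as.integer(count),
    delta_residual = delta - count * CE_DELTA
  )
}

#' Number of pseudouridines in a record
#' @param rec An `mm_trna`.
#' @param registry Nucleoside registry.
#' @return Integer count of derivatizable residues.
#' @export
count_psi <- function(rec, registry = default_registry()) {
  sum(reg_lookup(trna_residues(rec)$symbol, registry)$ce_derivatizable)
}
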