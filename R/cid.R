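# CID product-ion ladders (McLuckey c/y/w/a-B nomenclature for nucleic-acid
# anions) and modification-site localization from MS2 spectra.

#' Predict CID product ions for a fragment
#'
#' Negative-mode RNA CID is dominated by the c/y backbone series; w and a-B
#' (a minus base) are generated as well by default. Conventions:
#' * `c_i`: 5' piece of `i` residues ending in a 3'-phosphate, keeping the
#'   fragment's own 5' group.
#' * `y_i`: 3' piece of `i` residues with a 5'-hydroxyl, keeping the
#'   fragment's own 3' group.
#' * `w_i`: `y_i` plus HPO3 (5'-phosphate form).
#' * `a-B_i`: `c_i` minus H2O minus the base at residue `i`; skipped where
#'   the residue cannot lose its base (pseudouridine, a C-glycoside).
#'
#' @param symbols Character vector of residue symbols (or a one-row
#'   [digest()] tibble), length >= 2.
#' @param five_prime,three_prime Terminal groups of the precursor fragment
#'   (ignored when `symbols` is a digest row).
#' @param charges Product-ion charges (negative mode).
#' @param series Subset of `c("c", "y", "w", "a-B")`.
#' @param registry Nucleoside registry.
#' @return A tibble with columns `series`, `index`, `first_site`,
#'   `last_site`, `neutral_mass`, `z`, `mz`, ordered by series then index.
#' @export
predict_product_ions <- function(symbols, five_prime = "hydroxyl",
                                 three_prime = "phosphate", charges = 1L,
                                 series = c("c", "y", "w", "a-B"),
                                 registry = default_registry()) {
  if (is.data.frame(symbols)) {
    five_prime <- symbols$five_prime[[1]]
    three_prime <- symbols$three_prime[[1]]
    symbols <- symbols$symbols[[1]]
  }
  symbols <- normalize_symbol(symbols)
  n <- length(symbols)
  if (n < 2) stop("product ions require a fragment of length >= 2", call. = FALSE)
  series <- match.arg(series, several.ok = TRUE)
  reg <- reg_lookup(symbols, registry)
  mono <- symbol_mass_table(registry, "monoisotopic")
  link <- formula_mass(HPO3) - formula_mass(H2O)
  hpo3 <- formula_mass(HPO3)
  h2o <- formula_mass(H2O)
  cum5 <- cumsum(mono[symbols])                  # nucleoside sums from 5'
  total <- cum5[n]

  five_p <- terminal_formula_count(five_prime) * hpo3
  three_p <- terminal_formula_count(three_prime) * hpo3 -
    if (identical(three_prime, "cyclic_phosphate")) h2o else 0

  rows <- list()
  idx <- seq_len(n - 1L)
  if ("c" %in% series || "a-B" %in% series) {
    c_mass <- cum5[idx] + (idx - 1) * link + five_p + hpo3
    if ("c" %in% series) {
      rows$c <- tibble::tibble(series = "c", index = idx,
                               first_site = 1L, last_site = idx,
                               neutral_mass = c_mass)
    }
    if ("a-B" %in% series) {
      base_mass <- mono[symbols[idx]] - ANHYDRO_RIBOSE
      keep <- reg$base_loss[idx]
      rows$aB <- tibble::tibble(series = "a-B", index = idx,
                                first_site = 1L, last_site = idx,
                                neutral_mass = c_mass - h2o - base_mass)[keep, ]
    }
  }
  if ("y" %in% series || "w" %in% series) {
    y_mass <- (total - cum5[n - idx]) + (idx - 1) * link + three_p
    if ("y" %in% series) {
      rows$y <- tibble::tibble(series = "y", index = idx,
                               first_site = n - idx + 1L, last_site = n,
                               neutral_mass = y_mass)
    }
    if ("w" %in% series) {
      rows$w <- tibble::tibble(series = "w", index = idx,
                               first_site = n - idx + 1L, last_site = n,
                               neutral_mass = y_mass + hpo3)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$neutral_mass <- unname(out$neutral_mass)
  charges <- as.integer(charges)
  if (length(charges) > 1) {
    out <- out[rep(seq_len(nrow(out)), each = length(charges)), , drop = FALSE]
    out$z <- rep.int(charges, nrow(out) / length(charges))
  } else {
    out$z <- charges
  }
  out$mz <- (out$neutral_mass - out$z * PROTON_MASS) / out$z
  out[order(out$series, out$index, out$z), , drop = FALSE]
}

# placement: anything with $site / $symbol (tibble or plain list)
apply_placement <- function(symbols, placement) {
  if (length(placement$site)) symbols[placement$site] <- placement$symbol
  symbols
}

#' Localize modifications within a fragment from an MS2 spectrum
#'
#' Scores every candidate placement of the fragment's modification set by the
#' number of matched *site-discriminating* product ions (ions whose m/z
#' differs between at least two candidates by more than the MS2 tolerance).
#' The verdict is `"unique"` when exactly one placement attains the maximal
#' score, with support from at least one discriminating ion (or when only a
#' single placement is possible at all); `"ambiguous"` when several
#' co-winners remain (reported in 5'-to-3' order); `"none"` when the
#' spectrum matches no ions of any candidate.
#'
#' @param peaks An MS2 `mm_peaklist`; if precursor metadata is present, every
#'   candidate must be consistent with the precursor mass (an inconsistent
#'   precursor is an error, distinct from absent MS2 support).
#' @param fragment A one-row [digest()] tibble (the fragment shell; residues
#'   at unplaced sites are parent bases).
#' @param mod_set Character vector (multiset) of modification symbols to
#'   place; ignored when `placements` is given.
#' @param placements Optional list of candidate placements, each a
#'   tibble(site, symbol); by default all assignments of `mod_set` onto
#'   parent-compatible sites are enumerated.
#' @param cfg An [match_config()]; `ms2_tol_da` is the matching window.
#' @param charges Product-ion charges to predict.
#' @param series Product-ion series to use.
#' @param registry Nucleoside registry.
#' @return An object of class `mm_localization` with elements `verdict`,
#'   `winner` (placement tibble or `NULL`), `candidates` (tibble of
#'   placements with scores), and `ions` (matched/unmatched ion table of the
#'   winning placement). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
localize <- function(peaks, fragment, mod_set = character(),
                     placements = NULL, cfg = match_config(), charges = 1L,
                     series = c("c", "y", "w", "a-B"),
                     registry = default_registry()) {
  stopifnot(inherits(peaks, "mm_peaklist"))
  syms <- fragment$symbols[[1]]
  parents <- parent_of(syms, registry)
  if (is.null(placements)) {
    placements <- enumerate_mod_set_placements(parents, syms != parents,
                                               normalize_symbol(mod_set),
                                               registry)
  }
  if (!length(placements)) {
    stop("no candidate placement is possible for this fragment", call. = FALSE)
  }
  tol <- cfg$ms2_tol_da

  # precursor consistency (when metadata is present)
  pre_mz <- attr(peaks, "precursor_mz")
  if (!is.na(pre_mz)) {
    z <- attr(peaks, "precursor_z")
    pre_mass <- neutral_from_mz(pre_mz, z, attr(peaks, "polarity"))
    masses <- purrr::map_dbl(placements, function(p) {
      oligo_mass(apply_placement(syms, p), fragment$five_prime[[1]],
                 fragment$three_prime[[1]], registry = registry)
    })
    ok <- abs(masses - pre_mass) <= pmax(1.0, tol * z)
    if (!any(ok)) {
      stop("precursor mass ", round(pre_mass, 3),
           " matches no candidate placement (closest off by ",
           round(min(abs(masses - pre_mass)), 3), " Da)", call. = FALSE)
    }
    placements <- placements[ok]
  }

  ion_tables <- purrr::map(placements, function(p) {
    predict_product_ions(apply_placement(syms, p), fragment$five_prime[[1]],
                         fragment$three_prime[[1]], charges, series, registry)
  })
  # discriminating ions: same (series, index, z) key, m/z spread > tol
  keyed <- purrr::imap_dfr(ion_tables, function(tb, i) {
    tb$cand <- i
    tb
  })
  keyed <- dplyr::group_by(keyed, .data$series, .data$index, .data$z)
  keyed <- dplyr::mutate(keyed,
                         discriminating = max(.data$mz) - min(.data$mz) > tol)
  keyed <- dplyr::ungroup(keyed)
  keyed$matched <- mz_matched(keyed$mz, peaks$mz, tol)

  cand <- dplyr::summarise(
    dplyr::group_by(keyed, .data$cand),
    score = sum(.data$matched & .data$discriminating),
    n_matched = sum(.data$matched),
    n_discriminating = sum(.data$discriminating),
    .groups = "drop"
  )
  cand$placement <- purrr::map_chr(placements[cand$cand], placement_label,
                                   labels = as.character(seq_along(syms)))
  first_site <- purrr::map_int(placements[cand$cand], function(p) {
    if (length(p$site)) min(p$site) else 0L
  })
  cand <- cand[order(-cand$score, first_site), ]

  verdict <- if (sum(cand$n_matched) == 0) {
    "none"
  } else if (length(placements) == 1) {
    "unique"
  } else {
    top <- cand$score == max(cand$score)
    if (sum(top) == 1 && max(cand$score) > 0) "unique" else "ambiguous"
  }
  winner_id <- if (verdict == "unique") cand$cand[1] else NA_integer_
  structure(list(
    verdict = verdict,
    winner = if (!is.na(winner_id)) placements[[winner_id]] else NULL,
    candidates = cand[, c("placement", "cand", "score", "n_matched",
                          "n_discriminating")],
    ions = if (!is.na(winner_id)) {
      dplyr::filter(keyed, .data$cand == winner_id)
    } else keyed,
    fragment = fragment
  ), class = "mm_localization")
}

# all assignments of the multiset `mod_set` onto parent-compatible,
# currently-unmodified sites; one modification per site
enumerate_mod_set_placements <- function(parents, fixed_modified, mod_set,
                                         registry) {
  if (!length(mod_set)) {
    return(list(tibble::tibble(site = integer(), symbol = character())))
  }
  counts <- table(mod_set)
  result <- list(tibble::tibble(site = integer(), symbol = character()))
  for (sym in names(counts)) {
    par <- reg_lookup(sym, registry)$parent
    sites <- which(parents == par & !fixed_modified)
    k <- counts[[sym]]
    if (length(sites) < k) return(list())
    combos <- utils::combn(sites, k, simplify = FALSE)
    result <- purrr::flatten(purrr::map(result, function(p) {
      purrr::map(purrr::keep(combos, ~ !any(.x %in% p$site)), function(cs) {
        dplyr::bind_rows(p, tibble::tibble(site = cs, symbol = sym))
      })
    }))
    if (!length(result)) return(list())
  }
  purrr::map(result, ~ dplyr::arrange(.x, .data$site))
}

#' @export
print.mm_localization <- function(x, ...) {
  cat("<localization>", x$verdict)
  if (!is.null(x$winner) && nrow(x$winner)) {
    cat(":", placement_label(x$winner,
                             as.character(seq_along(x$fragment$symbols[[1]]))))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy mm_localization
#' @export
tidy.mm_localization <- function(x, ...) {
  x$candidates
}

#' @method glance mm_localization
#' @export
glance.mm_localization <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    n_candidates = nrow(x$candidates),
    best_score = if (nrow(x$candidates)) max(x$candidates$score) else NA_integer_,
    winner = if (!is.null(x$winner)) {
      placement_label(x$winner,
                      as.character(seq_along(x$fragment$symbols[[1]])))
    } else NA_character_
  )
}

#' Annotated-spectrum plot for a localization result
#'
#' Observed MS2 peaks with the winning placement's matched c/y/w/a-B ions
#' labelled.
#'
#' @param loc An `mm_localization`.
#' @param peaks The MS2 `mm_peaklist` that was localized.
#' @return A ggplot object.
#' @export
plot_localization <- function(loc, peaks) {
  ions <- dplyr::filter(loc$ions, .data$matched)
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          colour = "grey40") +
    ggplot2::geom_point(data = ions,
                        ggplot2::aes(x = .data$mz, y = 0,
                                     colour = .data$series), shape = 17) +
    ggplot2::geom_text(data = ions,
                       ggplot2::aes(x = .data$mz, y = 0,
                                    label = paste0(.data$series, .data$index),
                                    colour = .data$series),
                       vjust = 1.8, size = 2.8, show.legend = FALSE) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = paste("verdict:", loc$verdict)) +
    ggplot2::theme_minimal()
}
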