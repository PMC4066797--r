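# End-to-end modification identification: nucleoside census -> digest/match
# -> CID localization -> cyanoethylation channel, mirroring the two-stage
# logic of composition-first fragment assignment.

#' Strip a record down to its unmodified (gene-encoded) reference
#'
#' @param rec An `mm_trna`.
#' @param registry Nucleoside registry.
#' @return An `mm_trna` with every residue replaced by its parent base and
#'   allele/partial annotations dropped.
#' @export
unmodified_reference <- function(rec, registry = default_registry()) {
  res <- trna_residues(rec)
  new_trna(rec$name, parent_of(res$symbol, registry), res$label,
           five_prime = rec$five_prime, three_prime = rec$three_prime,
           registry = registry)
}

# score candidate (fragment, placement) pairs against one MS2 spectrum;
# candidates may come from different fragments (mass-coincident precursors).
# Candidates with identical sequence context and relative placement have
# identical ion ladders, so only one representative per signature is
# predicted and scored; members inherit the representative's score.
score_candidates_ms2 <- function(peaks, candidates, cfg, registry) {
  tol <- cfg$ms2_tol_da
  sigs <- vapply(candidates, function(cand) {
    paste(cand$fragment$seq[[1]], cand$fragment$five_prime[[1]],
          cand$fragment$three_prime[[1]],
          paste(cand$placement_sites$site, cand$placement_sites$symbol,
                collapse = ","))
  }, "")
  rep_ids <- which(!duplicated(sigs))
  n_sig <- length(rep_ids)
  keyed <- purrr::map_dfr(seq_along(rep_ids), function(k) {
    cand <- candidates[[rep_ids[k]]]
    syms <- apply_placement(cand$fragment$symbols[[1]],
                            cand$placement_sites)
    tb <- predict_product_ions(syms, cand$fragment$five_prime[[1]],
                               cand$fragment$three_prime[[1]],
                               charges = 1L, registry = registry)
    tb$sig_id <- k
    tb
  })
  keyed <- dplyr::group_by(keyed, .data$series, .data$index, .data$z)
  keyed <- dplyr::ungroup(dplyr::mutate(
    keyed, discriminating = dplyr::n() < n_sig |
      max(.data$mz) - min(.data$mz) > tol
  ))
  keyed$matched <- mz_matched(keyed$mz, peaks$mz, tol)
  sig_scores <- dplyr::summarise(
    dplyr::group_by(keyed, .data$sig_id),
    score = sum(.data$matched & .data$discriminating),
    n_matched = sum(.data$matched), .groups = "drop"
  )
  sig_of <- match(sigs, sigs[rep_ids])
  scores <- tibble::tibble(
    cand = seq_along(candidates),
    score = sig_scores$score[match(sig_of, sig_scores$sig_id)],
    n_matched = sig_scores$n_matched[match(sig_of, sig_scores$sig_id)]
  )
  scores[order(-scores$score), ]
}

ms2_verdict <- function(scores) {
  if (!nrow(scores) || sum(scores$n_matched) == 0) return(list(verdict = "none"))
  if (nrow(scores) == 1) {
    return(list(verdict = "unique", winner = scores$cand[1]))
  }
  top <- scores$score == max(scores$score)
  if (sum(top) == 1 && max(scores$score) > 0) {
    list(verdict = "unique", winner = scores$cand[which(top)])
  } else {
    list(verdict = "ambiguous")
  }
}

# map placement sites (relative to fragment) to reference residue labels
placement_to_labels <- function(fragment, placement_sites, reference) {
  res <- trna_residues(reference)
  idx <- fragment$start_idx[[1]] + placement_sites$site - 1L
  tibble::tibble(label = res$label[idx], symbol = placement_sites$symbol)
}

# Per-species assignment sets ("symbol@residue") of every MS1-matched
# modified species in a channel. A placement in the other nuclease's channel
# is "supported" when one single matched species here carries all of its
# G-site assignments jointly — per-site support alone is positionally
# smeared in G-runs, where every shifted missed-cleavage species matches
# the same peak.
ms1_support_set <- function(matches, ref_frags) {
  hits <- matches[!is.na(matches$frag_id), , drop = FALSE]
  hits <- hits[hits$n_mods > 0, , drop = FALSE]
  if (!nrow(hits)) return(list())
  sets <- purrr::map(seq_len(nrow(hits)), function(i) {
    p <- hits$placement_sites[[i]]
    idx <- ref_frags$start_idx[hits$frag_id[i]] + p$site - 1L
    paste0(p$symbol, "@", idx)
  })
  unique(sets)
}

jointly_supported <- function(assignments, support_sets) {
  if (!length(assignments)) return(TRUE)
  any(vapply(support_sets, function(s) all(assignments %in% s), logical(1)))
}

# Interpret one nuclease channel: match MS1 peaks against the bounded
# placement enumeration of the reference digest, confirm modified species by
# MS2, and call sites. Returns calls plus the per-span accepted species.
#
# `support`: assignments with MS1 evidence in the complementary channel;
# used only to break ties among score-equal co-winners. `assume_complete`:
# with complete peak detection, a repeated fragment whose unmodified species
# is observed in no copy must be modified in every copy.
interpret_channel <- function(peaks, ms2_list, rule, reference, allowed,
                              cfg, registry, channel_tag, support = NULL,
                              assume_complete = TRUE) {
  ref_frags <- digest(reference, rule, max_missed = cfg$max_variable_mods,
                      registry = registry)
  tab <- theoretical_mz_table(ref_frags, allowed, cfg, rule = rule,
                              adaptive = TRUE, registry = registry)
  matches <- match_peaks(peaks, tab, cfg)
  hits <- matches[!is.na(matches$frag_id), , drop = FALSE]
  top_hits <- hits[hits$rank == 1, , drop = FALSE]

  calls <- list()
  verdicts <- list()
  confirmed <- list()
  all_copies_pending <- list()   # per-span species the channel has positively placed
  note_confirmed <- function(cand, registry) {
    key <- paste0(cand$fragment$start[[1]], ":", cand$fragment$end[[1]])
    p <- cand$placement_sites
    list(key = key, species = list(
      fragment = cand$fragment, placement_sites = p,
      n_mods = length(p$site),
      neutral_mass = cand$fragment$mono_mass[[1]] +
        sum(delta_mass(p$symbol, registry)),
      start = cand$fragment$start[[1]], end = cand$fragment$end[[1]],
      seq = cand$fragment$seq[[1]]
    ))
  }

  # one species row per (fragment, placement), sorted for window lookups
  tab1 <- tab[tab$z == min(cfg$charges), , drop = FALSE]
  tab1 <- tab1[ref_frags$n_res[tab1$frag_id] >= 2, , drop = FALSE]
  tab1 <- tab1[order(tab1$neutral_mass), , drop = FALSE]

  # MS2-confirmed placements (candidates selected by precursor mass, so
  # mass-coincident species from other spans compete and must be out-scored)
  for (spec_key in names(ms2_list)) {
    peaks2 <- ms2_list[[spec_key]]
    pre_mass <- neutral_from_mz(attr(peaks2, "precursor_mz"),
                                attr(peaks2, "precursor_z"),
                                attr(peaks2, "polarity"))
    w <- ms1_tol_window(pre_mass, cfg)
    lo <- findInterval(pre_mass - w, tab1$neutral_mass) + 1L
    hi <- findInterval(pre_mass + w, tab1$neutral_mass)
    cand_rows <- if (hi >= lo) tab1[lo:hi, , drop = FALSE] else tab1[0, ]
    if (!nrow(cand_rows) || all(cand_rows$n_mods == 0)) next
    candidates <- purrr::map(seq_len(nrow(cand_rows)), function(i) {
      list(fragment = ref_frags[cand_rows$frag_id[i], ],
           placement_sites = cand_rows$placement_sites[[i]])
    })
    scores <- score_candidates_ms2(peaks2, candidates, cfg, registry)
    v <- ms2_verdict(scores)

    if (v$verdict == "ambiguous") {
      co_ids <- scores$cand[scores$score == max(scores$score)]
      # (a) cleavage-context support from the complementary channel; only
      # sound for symbol choice at fixed sites (the m1G/m2G cleavability
      # isomers) — never for deciding between spans, where a coincidental
      # supported species elsewhere could evict the true candidate
      same_site_set <- length(unique(vapply(co_ids, function(ci) {
        paste0(candidates[[ci]]$fragment$start[[1]], ":",
               candidates[[ci]]$fragment$end[[1]], "/",
               paste(candidates[[ci]]$placement_sites$site, collapse = ","))
      }, ""))) == 1
      if (!is.null(support) && length(co_ids) > 1 && same_site_set) {
        supported <- purrr::keep(co_ids, function(ci) {
          p <- candidates[[ci]]$placement_sites
          idx <- candidates[[ci]]$fragment$start_idx[[1]] + p$site - 1L
          g_site <- parent_of(p$symbol, registry) == "G"
          jointly_supported(paste0(p$symbol, "@", idx)[g_site], support)
        })
        if (length(supported) == 1) {
          v <- list(verdict = "unique", winner = supported[[1]])
        } else if (length(supported) > 1) {
          co_ids <- unlist(supported)
        }
      }
      # (b) repeated identical fragments: stash the tie for the post-pass,
      # which fires only when every spectrum of the span set agrees
      if (v$verdict == "ambiguous" && assume_complete && length(co_ids) > 1) {
        sigs <- vapply(co_ids, function(ci) {
          paste(candidates[[ci]]$fragment$seq,
                placement_label(candidates[[ci]]$placement_sites,
                                as.character(seq_len(10000))))
        }, "")
        spans <- vapply(co_ids, function(ci) {
          paste0(candidates[[ci]]$fragment$start[[1]], ":",
                 candidates[[ci]]$fragment$end[[1]])
        }, "")
        has_support <- max(scores$score[scores$cand %in% co_ids],
                           scores$n_matched[scores$cand %in% co_ids]) > 0
        # only zero-missed spans: the unmodified species of a
        # missed-cleavage span is never observable, so its absence is
        # vacuous and proves nothing
        zero_missed <- all(vapply(co_ids, function(ci) {
          candidates[[ci]]$fragment$missed[[1]] == 0L
        }, logical(1)))
        if (zero_missed &&
            length(unique(sigs)) == 1 && !anyDuplicated(spans) &&
            has_support) {
          all_copies_pending[[length(all_copies_pending) + 1L]] <- list(
            sig = sigs[1], spans = sort(spans), co_ids = co_ids,
            candidates = candidates, spec_key = spec_key
          )
        }
      }
    }

    verdicts[[spec_key]] <- v$verdict
    if (v$verdict == "unique") {
      cand <- candidates[[v$winner]]
      if (length(cand$placement_sites$site)) {
        calls[[length(calls) + 1L]] <-
          dplyr::mutate(placement_to_labels(cand$fragment,
                                            cand$placement_sites, reference),
                        channel = channel_tag)
        nc <- note_confirmed(cand, registry)
        confirmed[[nc$key]] <- nc$species
      }
    }
  }

  # post-pass for repeated identical fragments: when no copy of a repeated
  # span set is observed unmodified, every copy is modified (complete
  # detection); the one placement is assignable to all copies only when
  # every spectrum of that span set nominated the same relative placement
  if (length(all_copies_pending)) {
    unmod_spans <- unique(paste0(
      top_hits$start[top_hits$n_mods == 0], ":",
      top_hits$end[top_hits$n_mods == 0]
    ))
    # distinct matched modified compositions per fragment sequence: if a
    # sequence is observed with more than one modified composition, the
    # copies differ and the shift cannot be apportioned
    mod_hits <- hits[hits$n_mods > 0, , drop = FALSE]
    comp_by_seq <- split(
      vapply(mod_hits$placement_sites,
             function(p) paste(sort(p$symbol), collapse = "+"), ""),
      mod_hits$seq
    )
    span_keys <- vapply(all_copies_pending,
                        function(x) paste(x$spans, collapse = "|"), "")
    for (grp in split(all_copies_pending, span_keys)) {
      sigs <- vapply(grp, function(x) x$sig, "")
      spans <- grp[[1]]$spans
      if (length(unique(sigs)) != 1 || any(spans %in% unmod_spans)) next
      first <- grp[[1]]
      grp_seq <- first$candidates[[first$co_ids[1]]]$fragment$seq[[1]]
      if (length(unique(comp_by_seq[[grp_seq]])) != 1) next
      if (any(spans %in% names(confirmed))) next
      for (ci in first$co_ids) {
        cand <- first$candidates[[ci]]
        calls[[length(calls) + 1L]] <-
          dplyr::mutate(placement_to_labels(cand$fragment,
                                            cand$placement_sites, reference),
                        channel = paste0(channel_tag, "_all_copies"))
        nc <- note_confirmed(cand, registry)
        confirmed[[nc$key]] <- nc$species
      }
      for (x in grp) verdicts[[x$spec_key]] <- "unique_all_copies"
    }
  }

  # MS1-unique single-residue fragments (too short to fragment further)
  short <- top_hits[top_hits$n_mods > 0, , drop = FALSE]
  short <- short[purrr::map_int(short$frag_id,
                                ~ ref_frags$n_res[.x]) == 1L, , drop = FALSE]
  for (i in seq_len(nrow(short))) {
    peak_cands <- hits[hits$peak_id == short$peak_id[i], ]
    n_distinct_species <- nrow(dplyr::distinct(peak_cands, .data$frag_id,
                                               .data$placement))
    if (n_distinct_species == 1) {
      calls[[length(calls) + 1L]] <-
        dplyr::mutate(placement_to_labels(ref_frags[short$frag_id[i], ],
                                          short$placement_sites[[i]],
                                          reference),
                      channel = paste0(channel_tag, "_ms1"))
      nc <- note_confirmed(list(fragment = ref_frags[short$frag_id[i], ],
                                placement_sites = short$placement_sites[[i]]),
                           registry)
      confirmed[[nc$key]] <- nc$species
    }
  }

  list(calls = calls, matches = matches, verdicts = verdicts,
       accepted = accepted_species(top_hits, ref_frags, confirmed),
       ref_frags = ref_frags)
}

#' Identify modifications of a tRNA from a simulated or assembled run
#'
#' Runs the full interpretation pipeline against an unmodified reference
#' sequence:
#' 1. nucleoside census constrains the modification search space;
#' 2. the reference is digested in silico (with enough missed cleavages to
#'    represent cleavage-blocking modifications) and observed MS1 peaks are
#'    matched against the bounded placement enumeration;
#' 3. every MS2 spectrum is scored against all placements consistent with
#'    its precursor mass; only uniquely supported placements become site
#'    calls (single-residue fragments, which cannot be fragmented further,
#'    are accepted when their MS1 identity is unambiguous);
#' 4. when a second nuclease channel is present (parallel RNase A digest of
#'    the same molecule) it is interpreted the same way and its calls are
#'    merged — the two enzymes cut at different residues, so spans that are
#'    ambiguous in one digest (repeated identical fragments) are usually
#'    resolved by the other;
#' 5. the cyanoethylated channel is paired span-by-span with the native one
#'    (+53.0265 Da per adduct) to count pseudouridines, which are then
#'    localized from the derivatized MS2 spectra.
#'
#' Sites are called conservatively: any ambiguity (tied placements, missing
#' discriminating ions, conflicting calls) yields no call rather than a
#' guess.
#'
#' @param run A bundle as produced by [simulate_trna_run()]: elements
#'   `nucleosides`, `native` (`$peaks`, `$ms2`), optionally `rnase_a`
#'   (same shape), and `ce` (`$peaks`, `$ms2`).
#' @param reference The unmodified (gene-encoded) `mm_trna`.
#' @param rule The digestion rule of the primary (and cyanoethylated)
#'   channel.
#' @param second_rule The digestion rule of the optional `rnase_a` channel.
#' @param cfg An [match_config()]. The pipeline's default deepens the
#'   placement search to 4 variable modifications per fragment: a blocked
#'   cleavage site merges fragments, so clusters of co-occurring
#'   modifications end up on one digest product more often than the
#'   per-fragment statistics suggest; oversized enumerations back off
#'   per fragment rather than failing.
#' @param search_mods Modification symbols the interpreter may consider
#'   (intersected with the census calls); defaults to
#'   [default_search_mods()], which carries one representative per
#'   positional-isomer class since isomers sharing a parent base and mass
#'   delta are indistinguishable by mass alone.
#' @param assume_complete Is peak detection complete? When `TRUE` (default),
#'   a fragment sequence that occurs at several spans and whose unmodified
#'   species is observed at none of them must be modified at every copy —
#'   an inference that is only sound without peak dropout; set `FALSE` for
#'   lossy data.
#' @param registry Nucleoside registry.
#' @return An object of class `mm_identification` with elements `calls`
#'   (tibble `label`, `symbol`, `channel`), `census`, `matches`, and
#'   per-spectrum localization verdicts. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
identify_modifications <- function(run, reference,
                                   rule = cleavage_rule("RNaseT1"),
                                   second_rule = cleavage_rule("RNaseA"),
                                   cfg = match_config(max_variable_mods = 4),
                                   search_mods = default_search_mods(),
                                   assume_complete = TRUE,
                                   registry = default_registry()) {
  census <- nucleoside_census(run$nucleosides, cfg = cfg, registry = registry)
  allowed <- intersect(census_symbols(census), normalize_symbol(search_mods))

  t1 <- interpret_channel(run$native$peaks, run$native$ms2, rule, reference,
                          allowed, cfg, registry, "cid",
                          assume_complete = assume_complete)
  calls <- t1$calls
  verdicts <- t1$verdicts

  if (!is.null(run$rnase_a)) {
    support <- ms1_support_set(t1$matches, t1$ref_frags)
    a <- interpret_channel(run$rnase_a$peaks, run$rnase_a$ms2, second_rule,
                           reference, allowed, cfg, registry, "cid_a",
                           support = support,
                           assume_complete = assume_complete)
    calls <- c(calls, a$calls)
    if (length(a$verdicts)) {
      verdicts <- c(verdicts, stats::setNames(a$verdicts,
                                              paste0("A/", names(a$verdicts))))
    }
  }

  # --- pseudouridine via the cyanoethylation channel ------------------------
  ce_result <- ce_channel(run, t1$accepted, t1$ref_frags, reference, cfg,
                          registry)
  calls <- c(calls, ce_result$calls)
  matches <- t1$matches

  calls <- if (length(calls)) dplyr::bind_rows(calls) else {
    tibble::tibble(label = character(), symbol = character(),
                   channel = character())
  }
  calls <- dplyr::distinct(calls, .data$label, .data$symbol, .data$channel)
  # conflicting symbols at one site: call nothing there
  conflicted <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(calls, .data$label),
                     n_sym = dplyr::n_distinct(.data$symbol),
                     .groups = "drop"),
    .data$n_sym > 1
  )$label
  calls <- dplyr::distinct(
    dplyr::filter(calls, !.data$label %in% conflicted),
    .data$label, .data$symbol, .keep_all = TRUE
  )

  structure(list(calls = calls, census = census, matches = matches,
                 verdicts = verdicts, psi = ce_result$pairs,
                 reference = reference),
            class = "mm_identification")
}

# the per-span species the pipeline believes in: positively placed
# (MS2-confirmed or MS1-unique) modified species, plus every unmodified
# zero-mod span the MS1 data supports
accepted_species <- function(top_hits, ref_frags, confirmed) {
  spans <- confirmed
  unmod <- top_hits[top_hits$n_mods == 0, , drop = FALSE]
  for (i in seq_len(nrow(unmod))) {
    row <- unmod[i, ]
    key <- paste0(row$start, ":", row$end)
    if (!is.null(spans[[key]])) next
    spans[[key]] <- list(fragment = ref_frags[row$frag_id, ],
                         placement_sites = row$placement_sites[[1]],
                         n_mods = 0L,
                         neutral_mass = row$neutral_mass,
                         start = row$start, end = row$end, seq = row$seq)
  }
  spans
}

ce_channel <- function(run, accepted, ref_frags, reference, cfg, registry) {
  empty <- list(calls = list(), pairs = NULL)
  if (is.null(run$ce) || !length(accepted)) return(empty)
  dY <- delta_mass("ce1Y", registry) - delta_mass("Y", registry) # = +C3H3N

  # theoretical ce species: accepted native species plus 0..nU cyanoethyls
  ce_tab <- purrr::imap_dfr(accepted, function(sp, key) {
    syms <- apply_placement(sp$fragment$symbols[[1]], sp$placement_sites)
    elig <- which(parent_of(syms, registry) == "U" & syms == "U")
    purrr::map_dfr(0:length(elig), function(k) {
      tibble::tibble(span = key, start = sp$start, end = sp$end,
                     seq = sp$seq, k = k, n_elig = length(elig),
                     neutral_mass = sp$neutral_mass + k * dY)
    })
  })
  if (!nrow(ce_tab)) return(empty)
  ce_ms1 <- tidyr::crossing(ce_tab, z = cfg$charges)
  ce_ms1$mz <- (ce_ms1$neutral_mass - ce_ms1$z * PROTON_MASS) / ce_ms1$z
  ce_ms1 <- dplyr::arrange(ce_ms1, .data$mz)
  ce_ms1$frag_id <- seq_len(nrow(ce_ms1))   # satisfy match_peaks contract
  ce_ms1$n_mods <- ce_ms1$k
  ce_ms1$placement <- as.character(ce_ms1$k)

  cem <- match_peaks(run$ce$peaks, ce_ms1, cfg)
  cem <- cem[!is.na(cem$frag_id) & cem$rank == 1, , drop = FALSE]
  if (!nrow(cem)) return(empty)
  ce_best <- dplyr::distinct(
    dplyr::arrange(cem, .data$start, .data$end, abs(.data$error_ppm)),
    .data$start, .data$end, .keep_all = TRUE
  )
  native_tbl <- purrr::map_dfr(accepted, function(sp) {
    tibble::tibble(start = sp$start, end = sp$end, seq = sp$seq,
                   neutral_mass = sp$neutral_mass)
  })
  pairs <- pair_and_count(native_tbl,
                          tibble::tibble(start = ce_best$start,
                                         end = ce_best$end,
                                         seq = ce_best$seq,
                                         neutral_mass = ce_best$neutral_mass))

  calls <- list()
  ce_seq_counts <- table(ce_tab$seq[ce_tab$k == 0])
  for (i in which(!is.na(pairs$delta_count) & pairs$delta_count >= 1)) {
    key <- paste0(pairs$start[i], ":", pairs$end[i])
    sp <- accepted[[key]]
    if (is.null(sp)) next
    syms <- apply_placement(sp$fragment$symbols[[1]], sp$placement_sites)
    elig <- which(parent_of(syms, registry) == "U" & syms == "U")
    k <- pairs$delta_count[i]
    if (k > length(elig)) next
    placements <- purrr::map(utils::combn(elig, k, simplify = FALSE),
                             ~ tibble::tibble(site = .x, symbol = "ce1Y"))
    winner <- NULL
    peaks2 <- run$ce$ms2[[key]]
    if (!is.null(peaks2) && sp$fragment$n_res[[1]] >= 2) {
      # score against the unmodified baseline too: for a repeated fragment
      # sequence, the +53 shift could belong to another copy, and only a
      # spectrum that positively shows cyanoethylated ions justifies a call
      shell <- ce_fragment_shell(sp, syms, registry)
      candidates <- c(
        purrr::map(placements, function(p) {
          list(fragment = shell, placement_sites = p)
        }),
        list(list(fragment = shell,
                  placement_sites = tibble::tibble(site = integer(),
                                                   symbol = character())))
      )
      scores <- score_candidates_ms2(peaks2, candidates, cfg, registry)
      v <- ms2_verdict(scores)
      if (v$verdict == "unique" && v$winner <= length(placements)) {
        winner <- placements[[v$winner]]
      }
    } else if (length(placements) == 1 && !is.na(pairs$seq[i]) &&
               isTRUE(ce_seq_counts[pairs$seq[i]] == 1)) {
      # no spectrum available: accept only an unambiguous single placement
      # on a fragment sequence that occurs at exactly one span
      winner <- placements[[1]]
    }
    if (!is.null(winner)) {
      calls[[length(calls) + 1L]] <- dplyr::mutate(
        placement_to_labels(sp$fragment,
                            tibble::tibble(site = winner$site, symbol = "Y"),
                            reference),
        channel = "ce"
      )
    }
  }
  list(calls = calls, pairs = pairs)
}

# a fragment shell whose residues carry the accepted native placement, so
# that ce1Y placements are enumerated on top of it
ce_fragment_shell <- function(sp, syms, registry) {
  fr <- sp$fragment
  fr$symbols <- list(syms)
  fr
}

#' @export
print.mm_identification <- function(x, ...) {
  cat(sprintf("<identification> %d site call(s)\n", nrow(x$calls)))
  if (nrow(x$calls)) {
    cat(" ", paste0(x$calls$symbol, x$calls$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy mm_identification
#' @export
tidy.mm_identification <- function(x, ...) {
  x$calls
}

#' @method glance mm_identification
#' @export
glance.mm_identification <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x$calls),
    n_cid = sum(x$calls$channel %in% c("cid", "cid_a")),
    n_ms1 = sum(grepl("_ms1$", x$calls$channel)),
    n_ce = sum(x$calls$channel == "ce"),
    n_census = sum(x$census$called)
  )
}

#' Compare identified modifications with a ground-truth record
#'
#' @param id An `mm_identification` (or its `calls` tibble).
#' @param truth The ground-truth `mm_trna`.
#' @param registry Nucleoside registry.
#' @return A one-row tibble: `n_true` modified sites, `n_called`,
#'   `n_correct` (label and symbol both right), `n_false` (calls not in the
#'   truth), `recovery`, `fdr`.
#' @export
recovery_stats <- function(id, truth, registry = default_registry()) {
  calls <- if (inherits(id, "mm_identification")) id$calls else id
  res <- trna_residues(truth)
  true_mods <- res[res$symbol != parent_of(res$symbol, registry),
                   c("label", "symbol")]
  key <- function(d) paste(d$label, d$symbol)
  correct <- intersect(key(calls), key(true_mods))
  tibble::tibble(
    n_true = nrow(true_mods),
    n_called = nrow(calls),
    n_correct = length(correct),
    n_false = nrow(calls) - length(correct),
    recovery = if (nrow(true_mods)) length(correct) / nrow(true_mods) else NA_real_,
    fdr = if (nrow(calls)) 1 - length(correct) / nrow(calls) else 0
  )
}
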