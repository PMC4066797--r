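# MS1 peak-list matching against theoretical fragment species, with a
# bounded modification-placement search, and nucleoside-level census.

#' Construct a peak list
#'
#' A peak list is the package's abstraction of a centroided spectrum or of
#' the species extracted from a chromatographic run: an m/z-sorted tibble of
#' (mz, intensity) with polarity, MS level and (for MS2) precursor metadata
#' carried as attributes.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Intensities (arbitrary units); recycled.
#' @param polarity `"negative"` or `"positive"`.
#' @param ms_level 1 or 2.
#' @param precursor_mz,precursor_z Precursor ion (MS2 only).
#' @return A tibble of class `mm_peaklist`, sorted by m/z.
#' @export
peaklist <- function(mz, intensity = 1, polarity = c("negative", "positive"),
                     ms_level = 1, precursor_mz = NA_real_,
                     precursor_z = NA_integer_) {
  polarity <- match.arg(polarity)
  stopifnot(all(mz > 0), ms_level %in% c(1, 2))
  pl <- tibble::tibble(mz = as.numeric(mz),
                       intensity = rep_len(as.numeric(intensity), length(mz)))
  pl <- dplyr::arrange(pl, .data$mz)
  structure(pl, polarity = polarity, ms_level = as.integer(ms_level),
            precursor_mz = precursor_mz, precursor_z = precursor_z,
            class = c("mm_peaklist", class(pl)))
}

#' Read / write two-column peak-list text files
#'
#' Plain whitespace-separated `mz intensity` text, `#`-prefixed header
#' comments carrying polarity/ms_level/precursor metadata.
#'
#' @param path File path.
#' @return `read_peaklist()` returns an `mm_peaklist`.
#' @export
read_peaklist <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(polarity = "negative", ms_level = 1,
               precursor_mz = NA_real_, precursor_z = NA_integer_)
  for (ml in meta_lines) {
    kv <- stringr::str_match(ml, "^#\\s*(\\w+)\\s*=\\s*(\\S+)")
    if (!is.na(kv[1]) && kv[2] %in% names(meta)) {
      meta[[kv[2]]] <- utils::type.convert(kv[3], as.is = TRUE)
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    return(peaklist(numeric(0), numeric(0), meta$polarity, meta$ms_level,
                    meta$precursor_mz, meta$precursor_z))
  }
  m <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  peaklist(as.numeric(m[, 1]),
           if (ncol(m) >= 2) as.numeric(m[, 2]) else 1,
           meta$polarity, meta$ms_level, meta$precursor_mz, meta$precursor_z)
}

#' @rdname read_peaklist
#' @param peaks An `mm_peaklist`.
#' @export
write_peaklist <- function(peaks, path) {
  hdr <- c(paste0("# polarity=", attr(peaks, "polarity")),
           paste0("# ms_level=", attr(peaks, "ms_level")))
  if (!is.na(attr(peaks, "precursor_mz"))) {
    hdr <- c(hdr, paste0("# precursor_mz=", attr(peaks, "precursor_mz")),
             paste0("# precursor_z=", attr(peaks, "precursor_z")))
  }
  readr::write_lines(c(hdr, sprintf("%.6f\t%.6g", peaks$mz, peaks$intensity)),
                     path)
  invisible(path)
}

#' Matching configuration
#'
#' @param tol_ppm MS1 relative tolerance in ppm (Orbitrap-class default 10).
#' @param tol_da Optional absolute fallback tolerance in Da for
#'   unit-resolution (ion-trap) data; the effective window is the larger of
#'   the two when both are set.
#' @param charges Integer charges considered at MS1.
#' @param polarity Ion polarity.
#' @param max_variable_mods Placement-search bound per fragment (the largest
#'   co-occurring set in the mitochondrial catalog is 2; default leaves
#'   headroom of 1).
#' @param placement_bound Hard cap on enumerated placements per fragment;
#'   exceeding it is an error naming the count.
#' @param ms2_tol_da MS2 (ion-trap CID) absolute tolerance in Da.
#' @param census_tol_da Nucleoside-census tolerance in Da.
#' @return A list of class `mm_config`.
#' @export
match_config <- function(tol_ppm = 10, tol_da = NA_real_, charges = 1:3,
                         polarity = "negative", max_variable_mods = 3,
                         placement_bound = 50000, ms2_tol_da = 0.3,
                         census_tol_da = 0.5) {
  stopifnot(is.na(tol_da) || tol_da > 0, tol_ppm > 0 || !is.na(tol_da),
            max_variable_mods >= 0)
  structure(list(tol_ppm = tol_ppm, tol_da = tol_da,
                 charges = as.integer(charges), polarity = polarity,
                 max_variable_mods = as.integer(max_variable_mods),
                 placement_bound = placement_bound,
                 ms2_tol_da = ms2_tol_da, census_tol_da = census_tol_da),
            class = "mm_config")
}

# is each target m/z within tol of any (sorted) observed peak?
mz_matched <- function(target, peak_mz, tol) {
  if (!length(peak_mz)) return(rep(FALSE, length(target)))
  idx <- findInterval(target, peak_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peak_mz))
  abs(peak_mz[lo] - target) <= tol | abs(peak_mz[hi] - target) <= tol
}

ms1_tol_window <- function(mz, cfg) {
  w <- mz * cfg$tol_ppm * 1e-6
  if (!is.na(cfg$tol_da)) w <- pmax(w, cfg$tol_da)
  w
}

# Enumerate assignments of <= max_mods modifications onto eligible residues.
# Returns a list of placements; each placement is a list(site = int vector,
# symbol = chr vector). The count is computed first by dynamic programming
# (c_k' = c_k + o_i * c_{k-1} over sites), so an over-bound enumeration is
# rejected before any work is done.
enumerate_placements <- function(parents, fixed_modified, allowed_tbl,
                                 max_mods, bound,
                                 blocking_required = integer(),
                                 must_stay_cleavable = integer(),
                                 cleavable_symbols = character()) {
  n <- length(parents)
  required_at <- seq_len(n) %in% blocking_required & !fixed_modified
  options_by_site <- purrr::map(seq_len(n), function(i) {
    if (fixed_modified[i]) return(character())
    opts <- allowed_tbl$symbol[allowed_tbl$parent == parents[i]]
    if (required_at[i]) opts <- setdiff(opts, cleavable_symbols)
    if (i %in% must_stay_cleavable) opts <- intersect(opts, cleavable_symbols)
    opts
  })
  n_required <- sum(required_at)
  if (n_required > max_mods) return(list())
  if (any(required_at & lengths(options_by_site) == 0)) return(list())

  counts <- c(1, numeric(max_mods))        # counts[k+1] = placements with k mods
  for (i in seq_len(n)) {
    o <- length(options_by_site[[i]])
    if (!o) next
    if (required_at[i]) {
      counts <- c(0, o * counts[seq_len(max_mods)])
    } else if (max_mods >= 1) {
      counts[2:(max_mods + 1)] <- counts[2:(max_mods + 1)] +
        o * counts[seq_len(max_mods)]
    }
  }
  if (sum(counts) > bound) {
    stop("placement enumeration exceeded bound (", bound,
         ") for a fragment; tighten the allowed modification set",
         call. = FALSE)
  }

  placements <- list(list(site = integer(), symbol = character()))
  for (i in seq_len(n)) {
    opts <- options_by_site[[i]]
    if (!length(opts)) next
    new <- vector("list", 0L)
    for (p in placements) {
      if (!required_at[i]) new[[length(new) + 1L]] <- p
      if (length(p$site) < max_mods) {
        for (s in opts) {
          new[[length(new) + 1L]] <- list(site = c(p$site, i),
                                          symbol = c(p$symbol, s))
        }
      }
    }
    placements <- new
    if (!length(placements)) return(list())
  }
  required_sites <- which(required_at)
  purrr::keep(placements, function(p) all(required_sites %in% p$site))
}

placement_label <- function(placement, labels) {
  if (!length(placement$site)) return("")
  paste0(placement$symbol, "@", labels[placement$site], collapse = "+")
}

#' Theoretical m/z table over fragments with bounded modification placement
#'
#' For each digest fragment, enumerates every placement of up to
#' `max_variable_mods` modifications from the allowed set onto residues whose
#' parent base matches (the allowed set normally comes from the nucleoside
#' census, mirroring the two-stage logic of composition-first assignment).
#' Mass-silent species (pseudouridine) are excluded: they are undetectable at
#' MS1 and are handled by the cyanoethylation workflow.
#'
#' When `rule` is supplied, placements are required to be consistent with the
#' digestion chemistry that produced the fragment: a residue at a missed
#' internal cut site must carry a cleavage-blocking modification (otherwise
#' the enzyme would have cut), and the residue at a fragment's own 3' cut
#' site must remain cleavable. This is how, e.g., a +CH2 on a fragment-
#' terminal guanosine is assignable as m2G but not m1G.
#'
#' @param fragments A [digest()] tibble (typically of the unmodified
#'   reference sequence, with `max_missed >= 1` so blocked-cleavage species
#'   are representable).
#' @param allowed Character vector of modification symbols permitted as
#'   variable modifications.
#' @param cfg An [match_config()].
#' @param rule The digestion rule the fragments came from (optional; enables
#'   the cleavage-consistency constraints).
#' @param adaptive Instead of rejecting a fragment whose placement
#'   enumeration exceeds `placement_bound`, back its per-fragment
#'   modification depth off until the enumeration fits (used by the
#'   identification pipeline, where a shallower search on one oversized
#'   fragment beats a failed run).
#' @param registry Nucleoside registry.
#' @return A tibble sorted by m/z with columns `frag_id`, `start`, `end`,
#'   `seq`, `placement`, `placement_sites` (list), `n_mods`, `neutral_mass`,
#'   `z`, `mz`.
#' @export
theoretical_mz_table <- function(fragments, allowed = character(),
                                 cfg = match_config(), rule = NULL,
                                 adaptive = FALSE,
                                 registry = default_registry()) {
  allowed <- unique(normalize_symbol(allowed))
  if (length(allowed)) {
    reg_rows <- reg_lookup(allowed, registry)
    silent <- allowed[delta_mass(allowed, registry) == 0]
    allowed <- setdiff(allowed, silent)
    reg_rows <- reg_rows[reg_rows$symbol %in% allowed, , drop = FALSE]
  } else {
    reg_rows <- reg_lookup(character(0), registry)
  }
  allowed_tbl <- tibble::tibble(symbol = reg_rows$symbol,
                                parent = reg_rows$parent)
  cleavable_symbols <- if (!is.null(rule)) {
    registry$symbol[rule_cuts_after(rule, registry$symbol, registry)]
  } else character()
  dmass <- stats::setNames(delta_mass(allowed_tbl$symbol, registry),
                           allowed_tbl$symbol)

  rows <- purrr::map_dfr(seq_len(nrow(fragments)), function(fi) {
    fr <- fragments[fi, ]
    syms <- fr$symbols[[1]]
    parents <- parent_of(syms, registry)
    fixed_modified <- syms != parents
    blocking_required <- if (!is.null(rule)) fr$internal_cut_idx[[1]] else integer()
    must_cleave <- if (!is.null(rule) && fr$three_prime == "phosphate" &&
                       fr$provenance %in% c("internal", "five_terminal")) {
      length(syms)
    } else integer()
    depth <- cfg$max_variable_mods
    placements <- NULL
    while (is.null(placements)) {
      placements <- tryCatch(
        enumerate_placements(
          parents, fixed_modified, allowed_tbl, depth,
          cfg$placement_bound, blocking_required, must_cleave,
          cleavable_symbols
        ),
        error = function(e) {
          if (adaptive && depth > 0) NULL else stop(e)
        }
      )
      depth <- depth - 1L
    }
    if (!length(placements)) return(NULL)
    labels <- as.character(seq_along(syms))
    tibble::tibble(
      frag_id = fi, start = fr$start, end = fr$end, seq = fr$seq,
      placement = purrr::map_chr(placements, placement_label, labels = labels),
      placement_sites = placements,
      n_mods = purrr::map_int(placements, ~ length(.x$site)),
      neutral_mass = fr$mono_mass +
        purrr::map_dbl(placements, ~ sum(dmass[.x$symbol]))
    )
  })
  if (!nrow(rows)) {
    return(tibble::tibble(frag_id = integer(), start = character(),
                          end = character(), seq = character(),
                          placement = character(), placement_sites = list(),
                          n_mods = integer(), neutral_mass = numeric(),
                          z = integer(), mz = numeric()))
  }
  out <- tidyr::crossing(rows, z = cfg$charges)
  out$mz <- (out$neutral_mass +
               ifelse(cfg$polarity == "negative", -1, 1) * out$z * PROTON_MASS) /
    out$z
  dplyr::arrange(out, .data$mz)
}

#' Match observed MS1 peaks against a theoretical table
#'
#' Every peak is matched to all theoretical species within tolerance, ranked
#' per peak by absolute ppm error, then by fewer modifications, then by 5'
#' position (a deterministic total order). Unmatched peaks are retained with
#' `NA` species columns so they can be reported.
#'
#' @param peaks An `mm_peaklist` (MS1).
#' @param table A [theoretical_mz_table()] tibble.
#' @param cfg An [match_config()].
#' @return A tibble with one row per (peak, candidate species) plus one `NA`
#'   row per unmatched peak; columns include `peak_mz`, `intensity`,
#'   `error_ppm` and `rank`.
#' @export
match_peaks <- function(peaks, table, cfg = match_config()) {
  stopifnot(inherits(peaks, "mm_peaklist"))
  if (is.unsorted(table$mz)) table <- dplyr::arrange(table, .data$mz)
  w <- ms1_tol_window(peaks$mz, cfg)
  lo <- findInterval(peaks$mz - w, table$mz) + 1L
  hi <- findInterval(peaks$mz + w, table$mz)
  n_hit <- pmax(hi - lo + 1L, 0L)
  peak_id <- rep.int(seq_len(nrow(peaks)), n_hit)
  row_id <- unlist(purrr::map2(lo[n_hit > 0], hi[n_hit > 0], seq.int),
                   use.names = FALSE)
  hits <- table[row_id, , drop = FALSE]
  hits$peak_id <- peak_id
  hits$peak_mz <- peaks$mz[peak_id]
  hits$intensity <- peaks$intensity[peak_id]
  hits$error_ppm <- (hits$peak_mz - hits$mz) / hits$mz * 1e6
  ord <- order(hits$peak_id, abs(hits$error_ppm), hits$n_mods, hits$frag_id,
               hits$placement)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$peak_id,
                          FUN = seq_along)
  un <- which(n_hit == 0)
  if (length(un)) {
    hits <- dplyr::bind_rows(
      hits,
      tibble::tibble(peak_id = un, peak_mz = peaks$mz[un],
                     intensity = peaks$intensity[un])
    )
  }
  hits
}

#' Nucleoside census from a positive-mode LC/MS run
#'
#' Determines which modified nucleosides are present before any fragment
#' assignment, mirroring composition-first analysis: a modified nucleoside is
#' called present when its protonated nucleoside ion (MH+) is observed and,
#' for species that can lose their base, the corresponding base ion (BH2+)
#' is observed too. An MH+ without the required base ion is reported as
#' ambiguous, not called.
#'
#' Pseudouridine is flagged `mass_silent`: its MH+ is identical to
#' uridine's, so a peak-level census can suggest but never prove it; the
#' cyanoethylation workflow is the confirmatory channel.
#'
#' @param ms1_positive Positive-mode nucleoside-level `mm_peaklist`.
#' @param paired_base_ions Optional separate peak list for base ions; by
#'   default base ions are looked up in `ms1_positive` itself.
#' @param cfg An [match_config()]; `census_tol_da` is the window.
#' @param registry Nucleoside registry.
#' @return A tibble with columns `symbol`, `mh_mz`, `mh_observed`,
#'   `base_mz`, `base_observed`, `called`, `ambiguous`, `mass_silent`.
#'   The composition constraint for [theoretical_mz_table()] is
#'   `symbol[called]`.
#' @export
nucleoside_census <- function(ms1_positive, paired_base_ions = NULL,
                              cfg = match_config(),
                              registry = default_registry()) {
  stopifnot(identical(attr(ms1_positive, "polarity"), "positive"))
  if (is.null(paired_base_ions)) paired_base_ions <- ms1_positive
  observed <- function(target, pl) {
    !is.na(target) & purrr::map_lgl(target, function(t) {
      if (is.na(t)) return(FALSE)
      any(abs(pl$mz - t) <= cfg$census_tol_da)
    })
  }
  mods <- registry[!registry$symbol %in% c("A", "G", "C", "U"), ]
  out <- tibble::tibble(
    symbol = mods$symbol,
    mh_mz = nucleoside_mh(mods$symbol, registry),
    base_mz = base_ion_mz(mods$symbol, registry),
    mass_silent = delta_mass(mods$symbol, registry) == 0
  )
  out$mh_observed <- observed(out$mh_mz, ms1_positive)
  out$base_observed <- observed(out$base_mz, paired_base_ions)
  needs_base <- mods$base_loss
  out$called <- out$mh_observed & (!needs_base | out$base_observed)
  out$ambiguous <- out$mh_observed & needs_base & !out$base_observed
  out[order(-out$called, out$symbol), ]
}

#' Called symbols from a census table
#' @param census Output of [nucleoside_census()].
#' @param include_mass_silent Keep mass-silent species (pseudouridine) in
#'   the set? They cannot be placed at MS1, so the default drops them.
#' @return Character vector of called modification symbols.
#' @export
census_symbols <- function(census, include_mass_silent = FALSE) {
  s <- census$symbol[census$called]
  if (!include_mass_silent) s <- setdiff(s, census$symbol[census$mass_silent])
  s
}
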