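# Annotated tRNA records with compilation-style position labels, plus the
# bovine mitochondrial tRNA fixtures (modification catalog, anticodons, and
# the fully annotated tRNA-Ala worked example).

#' Parse tRNA position labels
#'
#' Labels follow the tRNA compilation convention: an integer (possibly -1,
#' the 5'-extension of tRNA-His) with an optional single-letter suffix for
#' inserted positions ("27a" sorts between 27 and 28).
#'
#' @param label Character vector of labels.
#' @return A tibble with columns `label`, `number` (integer), `suffix`.
#' @export
parse_position_label <- function(label) {
  m <- stringr::str_match(as.character(label), "^(-?\\d+)([a-z]?)$")
  if (anyNA(m[, 1])) {
    stop("malformed position label(s): ",
         paste(label[is.na(m[, 1])], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(label = as.character(label),
                 number = as.integer(m[, 2]),
                 suffix = m[, 3])
}

#' Ordering key for position labels
#'
#' @param label Character vector of labels.
#' @return A numeric key: `order(position_key(x))` sorts labels so that -1
#'   precedes 1 and "27a" falls between 27 and 28.
#' @export
position_key <- function(label) {
  p <- parse_position_label(label)
  # suffix "" -> 0, "a" -> 1, ...; /100 keeps every suffix below the next integer
  suf <- purrr::map_int(p$suffix, function(s) {
    if (s == "") 0L else utf8ToInt(s) - utf8ToInt("a") + 1L
  })
  p$number + suf / 100
}

#' Construct an annotated tRNA record
#'
#' A record is the unit the digestion, derivatization and intact-mass
#' routines operate on: an ordered list of residues, each a registered
#' nucleoside symbol with a position label, optional heteroplasmic alleles
#' and a sub-stoichiometric ("partial") flag, plus the molecule's terminal
#' chemistry (a mature tRNA carries a 5'-monophosphate and 3'-hydroxyl).
#'
#' @param name tRNA name, e.g. `"Ala"` or `"Leu(UUR)"`.
#' @param symbols Character vector of registered nucleoside symbols, 5' to 3'.
#' @param labels Position labels, one per residue; defaults to `1..n`.
#' @param alleles Optional list (one element per residue) of character
#'   vectors of alternative symbols at heteroplasmic sites, `NULL` elsewhere.
#' @param partial Logical vector: is the modification sub-stoichiometric?
#' @param five_prime,three_prime Terminal groups, `"phosphate"` or
#'   `"hydroxyl"`.
#' @param registry Registry used to validate symbols.
#' @return An object of class `mm_trna`.
#' @examples
#' new_trna("toy", c("G", "A", "U", "Y", "G"))
#' @export
new_trna <- function(name, symbols, labels = as.character(seq_along(symbols)),
                     alleles = NULL, partial = FALSE,
                     five_prime = "phosphate", three_prime = "hydroxyl",
                     registry = default_registry()) {
  symbols <- normalize_symbol(symbols)
  n <- length(symbols)
  stopifnot(n > 0, length(labels) == n)
  five_prime <- match.arg(five_prime, c("phosphate", "hydroxyl"))
  three_prime <- match.arg(three_prime, c("phosphate", "hydroxyl"))
  reg_lookup(symbols, registry)   # errors on unknown symbols
  if (is.null(alleles)) alleles <- rep(list(NULL), n)
  stopifnot(length(alleles) == n)
  alleles <- purrr::map(alleles, function(a) {
    if (is.null(a) || !length(a)) return(NULL)
    a <- normalize_symbol(a)
    reg_lookup(a, registry)
    a
  })
  partial <- rep_len(partial, n)
  pos <- parse_position_label(labels)
  key <- position_key(pos$label)
  if (is.unsorted(key, strictly = TRUE)) {
    stop("position labels must be strictly increasing 5' to 3'", call. = FALSE)
  }
  residues <- tibble::tibble(
    label = pos$label, number = pos$number, suffix = pos$suffix,
    symbol = symbols, alleles = alleles, partial = partial
  )
  structure(list(name = name, residues = residues,
                 five_prime = five_prime, three_prime = three_prime),
            class = "mm_trna")
}

#' @export
print.mm_trna <- function(x, ...) {
  mods <- dplyr::filter(x$residues, .data$symbol != parent_of(.data$symbol))
  cat(sprintf("<tRNA %s> %d nt, 5'-%s / 3'-%s\n", x$name,
              nrow(x$residues), x$five_prime, x$three_prime))
  cat(" ", paste0(x$residues$symbol, collapse = ""), "\n")
  if (nrow(mods)) {
    cat("  modifications:",
        paste0(mods$symbol, mods$label, ifelse(mods$partial, "*", ""),
               collapse = ", "), "\n")
  }
  invisible(x)
}

parent_of <- function(symbol, registry = default_registry()) {
  reg_lookup(symbol, registry)$parent
}

#' Residues of a record as a tibble
#' @param rec An `mm_trna`.
#' @return The residue tibble (label, number, suffix, symbol, alleles, partial).
#' @export
trna_residues <- function(rec) {
  stopifnot(inherits(rec, "mm_trna"))
  rec$residues
}

#' Anticodon of a record
#' @param rec An `mm_trna`.
#' @return Character vector of the three symbols at positions 34-36.
#' @export
trna_anticodon <- function(rec) {
  ac <- dplyr::filter(trna_residues(rec), .data$number %in% 34:36,
                      .data$suffix == "")
  if (nrow(ac) != 3) stop("record lacks anticodon positions 34-36", call. = FALSE)
  ac$symbol
}

#' Expand heteroplasmic alleles into fully resolved records
#'
#' Heteroplasmy (mixed mtDNA alleles, e.g. A/G at position 57 of bovine mt
#' tRNA-Asp) is handled by Cartesian enumeration rather than ambiguity codes
#' so that downstream mass computation stays exact. The reference symbol
#' comes first in each site's expansion, so the first returned record is the
#' reference record.
#'
#' @param rec An `mm_trna`.
#' @return A list of `mm_trna` records, each tagged with an `allele_id`
#'   attribute such as `"57G"` (empty for the reference).
#' @export
expand_alleles <- function(rec) {
  res <- trna_residues(rec)
  het <- which(purrr::map_lgl(res$alleles, ~ !is.null(.x)))
  if (!length(het)) {
    attr(rec, "allele_id") <- ""
    return(list(rec))
  }
  choices <- purrr::map(het, function(i) c(res$symbol[i], res$alleles[[i]]))
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)[, length(het):1, drop = FALSE]
  purrr::map(seq_len(nrow(grid)), function(r) {
    symbols <- res$symbol
    symbols[het] <- unlist(grid[r, ])
    out <- new_trna(rec$name, symbols, res$label, alleles = NULL,
                    partial = res$partial, five_prime = rec$five_prime,
                    three_prime = rec$three_prime)
    changed <- het[symbols[het] != res$symbol[het]]
    attr(out, "allele_id") <-
      paste0(res$label[changed], symbols[changed], collapse = "+")
    out
  })
}

# ---- annotated FASTA + sidecar TSV I/O --------------------------------------

#' Read annotated tRNA records (FASTA + sidecar modification TSV)
#'
#' The FASTA holds parent-base sequences; per-position annotations
#' (compilation-style labels, modification symbols, heteroplasmic alleles,
#' partial flags) live in a sidecar TSV keyed by record id and 1-based
#' physical index, which keeps position labels decoupled from the physical
#' index (mitochondrial tRNAs have non-canonical lengths).
#'
#' Sidecar columns: `record_id`, `index`, `label` (optional; defaults to the
#' index), `symbol` (optional; defaults to the FASTA base), `alleles`
#' (comma-separated, optional), `partial` (logical, optional).
#'
#' @param fasta_path,mods_path File paths; `mods_path` may be `NULL` for
#'   unannotated sequences.
#' @param registry Registry used for validation.
#' @return A named list of `mm_trna` records.
#' @export
read_annotated_fasta <- function(fasta_path, mods_path = NULL,
                                 registry = default_registry()) {
  lines <- readr::read_lines(fasta_path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", fasta_path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- purrr::map_chr(seq_along(hdr), function(i) {
    paste0(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  })
  mods <- if (is.null(mods_path)) NULL else {
    readr::read_tsv(mods_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  recs <- purrr::map2(ids, seqs, function(id, s) {
    symbols <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(symbols), c("A", "G", "C", "U"))
    if (length(bad)) {
      stop("record ", id, ": non-canonical FASTA base(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    labels <- as.character(seq_along(symbols))
    alleles <- rep(list(NULL), length(symbols))
    partial <- rep(FALSE, length(symbols))
    if (!is.null(mods)) {
      rows <- mods[mods$record_id == id, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        i <- as.integer(rows$index[r])
        if (is.na(i) || i < 1 || i > length(symbols)) {
          stop("record ", id, " sidecar line ", r, ": index out of range",
               call. = FALSE)
        }
        if (!is.null(rows$label) && !is.na(rows$label[r])) labels[i] <- rows$label[r]
        if (!is.null(rows$symbol) && !is.na(rows$symbol[r])) {
          sym <- normalize_symbol(rows$symbol[r])
          reg_lookup(sym, registry)
          if (reg_lookup(sym, registry)$parent != symbols[i]) {
            stop("record ", id, " sidecar line ", r, ": symbol ", sym,
                 " is not a derivative of FASTA base ", symbols[i],
                 call. = FALSE)
          }
          symbols[i] <- sym
        }
        if (!is.null(rows$alleles) && !is.na(rows$alleles[r]) &&
            nzchar(rows$alleles[r])) {
          alleles[[i]] <- strsplit(rows$alleles[r], ",")[[1]]
        }
        if (!is.null(rows$partial) && !is.na(rows$partial[r])) {
          partial[i] <- as.logical(rows$partial[r])
        }
      }
    }
    new_trna(id, symbols, labels, alleles = alleles, partial = partial,
             registry = registry)
  })
  stats::setNames(recs, ids)
}

#' Write annotated tRNA records (FASTA + sidecar modification TSV)
#'
#' Inverse of [read_annotated_fasta()]: `read(write(x))` reproduces the
#' records exactly.
#'
#' @param records A list of `mm_trna` records.
#' @inheritParams read_annotated_fasta
#' @export
write_annotated_fasta <- function(records, fasta_path, mods_path) {
  if (inherits(records, "mm_trna")) records <- list(records)
  fasta <- purrr::map(records, function(rec) {
    c(paste0(">", rec$name),
      paste0(parent_of(trna_residues(rec)$symbol), collapse = ""))
  })
  readr::write_lines(unlist(fasta), fasta_path)
  sidecar <- purrr::map_dfr(records, function(rec) {
    res <- trna_residues(rec)
    annotated <- res$label != as.character(seq_len(nrow(res))) |
      res$symbol != parent_of(res$symbol) |
      purrr::map_lgl(res$alleles, ~ !is.null(.x)) | res$partial
    if (!any(annotated)) return(NULL)
    tibble::tibble(
      record_id = rec$name,
      index = which(annotated),
      label = res$label[annotated],
      symbol = res$symbol[annotated],
      alleles = purrr::map_chr(res$alleles[annotated],
                               ~ paste0(.x, collapse = ",")),
      partial = res$partial[annotated]
    )
  })
  readr::write_tsv(sidecar, mods_path)
  invisible(list(fasta = fasta_path, mods = mods_path))
}

# ---- shipped fixtures -------------------------------------------------------

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "modmapr")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  if (!file.exists(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' The bovine mitochondrial tRNA modification catalog
#'
#' The complete per-site catalog over the 22 mitochondrial tRNA species:
#' one row per (position, tRNA, modification). The 2-thio and 2-methylthio
#' layered species (tm5s2U over tm5U at position 34; ms2i6A over i6A at 37)
#' are distinct rows occupying the same site. Candidate modification-enzyme
#' genes ride along as inert annotation strings.
#'
#' @param path Optional path to an alternative catalog TSV.
#' @param registry Registry the symbols must resolve in.
#' @return A tibble of class `mm_catalog` with columns `position`, `trna`,
#'   `symbol`, `gene_confirmed`, `gene_predicted`.
#' @examples
#' cat22 <- mt_catalog()
#' dplyr::count(cat22, symbol, sort = TRUE)
#' @export
mt_catalog <- function(path = fixture_path("mt_catalog.tsv"),
                       registry = default_registry()) {
  cat <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("position", "trna", "symbol")
  if (!all(need %in% names(cat))) {
    stop("catalog is corrupt: missing column(s) ",
         paste(setdiff(need, names(cat)), collapse = ", "), call. = FALSE)
  }
  cat$symbol <- normalize_symbol(cat$symbol)
  reg_lookup(unique(cat$symbol), registry)       # referential closure
  parse_position_label(cat$position)             # label validity
  bad <- setdiff(unique(cat$trna), MT_TRNA_NAMES)
  if (length(bad)) {
    stop("catalog is corrupt: unknown tRNA name(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cat[, need])) {
    stop("catalog is corrupt: duplicate (position, trna, symbol) entries",
         call. = FALSE)
  }
  class(cat) <- c("mm_catalog", class(cat))
  cat
}

#' The 22 mitochondrial tRNA species names
#' @export
MT_TRNA_NAMES <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu(CUN)", "Leu(UUR)", "Lys", "Met", "Phe", "Pro", "Ser(AGY)",
  "Ser(UCN)", "Thr", "Trp", "Tyr", "Val"
)

#' Anticodons of the 22 mitochondrial tRNAs
#'
#' Anticodon symbols 5' to 3' (positions 34, 35, 36), wobble position
#' carrying its mature modified symbol where one exists.
#'
#' @return A tibble with columns `trna`, `a34`, `a35`, `a36`.
#' @export
mt_anticodons <- function() {
  ac <- readr::read_tsv(fixture_path("mt_anticodons.tsv"),
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  ac$a34 <- normalize_symbol(ac$a34)
  ac
}

#' The fully annotated bovine mt tRNA-Ala record
#'
#' 72 nt, base composition U27 C9 A20 G16, 5'-monophosphate / 3'-hydroxyl,
#' with m1A9, partial m2G10, m2G26 and pseudouridines at 28, 39 and 57. The
#' terminal fragments (pGAGGAUp, OH-CAAUCCUUACCA-OH), the anticodon UGC and
#' the two worked-example modified fragments fix positions 1-10, 34-45 and
#' 54-72; the remaining stretches are a reconstruction consistent with the
#' printed base composition and a cloverleaf pairing, and are marked
#' synthetic in the fixture documentation.
#'
#' @return An `mm_trna` record.
#' @export
trna_ala <- function() {
  read_annotated_fasta(fixture_path("trna_ala.fasta"),
                       fixture_path("trna_ala_mods.tsv"))[["Ala"]]
}
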