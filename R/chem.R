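# Elemental-formula arithmetic and m/z conversion for nucleic-acid species.

# Monoisotopic masses: CODATA/NIST principal isotopes (1H, 12C, 14N, 16O, 31P, 32S).
MONO_MASS <- c(
  H = 1.007825, C = 12.000000, N = 14.003074,
  O = 15.994915, P = 30.973762, S = 31.972071
)

# Average masses: IUPAC standard atomic weights (2021 abridged).
AVG_MASS <- c(
  H = 1.008000, C = 12.011000, N = 14.007000,
  O = 15.999000, P = 30.973762, S = 32.060000
)

# Mass of a proton; observed ESI ions are (de)protonated species.
PROTON_MASS <- 1.007276

#' Create an elemental formula
#'
#' An elemental formula is a named integer vector of atom counts over the
#' elements C, H, N, O, P, S. Formulas support `+`, `-` and integer `*`;
#' subtraction that would drive any count negative is an error, so chemically
#' impossible species cannot be constructed silently.
#'
#' @param x A formula string such as `"C9H13N3O5"` (case-sensitive element
#'   symbols, each followed by an optional count), a named numeric vector of
#'   counts, or an existing `mm_formula`.
#' @return An object of class `mm_formula`.
#' @examples
#' chem_formula("H2O")
#' chem_formula("C10H13N5O4") + chem_formula("CH2")
#' @export
chem_formula <- function(x = character()) {
  if (inherits(x, "mm_formula")) return(x)
  if (is.numeric(x)) {
    counts <- x
  } else if (is.character(x)) {
    counts <- parse_formula_string(if (length(x) == 0) "" else x)
  } else {
    stop("cannot interpret `x` as an elemental formula", call. = FALSE)
  }
  new_formula(counts)
}

new_formula <- function(counts) {
  full <- stats::setNames(numeric(length(MONO_MASS)), names(MONO_MASS))
  if (length(counts)) {
    bad <- setdiff(names(counts), names(full))
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    full[names(counts)] <- full[names(counts)] + counts
  }
  if (any(full < 0)) {
    neg <- names(full)[full < 0]
    stop("negative atom count for: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  structure(full, class = "mm_formula")
}

parse_formula_string <- function(s) {
  s <- trimws(s)
  if (identical(s, "")) return(numeric())
  tokens <- stringr::str_match_all(s, "([A-Z][a-z]?)(\\d*)")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, s)) {
    stop("cannot parse formula string: ", s, call. = FALSE)
  }
  counts <- ifelse(tokens[, 3] == "", 1L, as.integer(tokens[, 3]))
  tapply(counts, tokens[, 2], sum)
}

#' @export
print.mm_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Render a formula as a compact string
#' @param f An `mm_formula`.
#' @return A string such as `"C9H13N3O5"`; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- chem_formula(f)
  nz <- f[f != 0]
  if (!length(nz)) return("")
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' @export
`+.mm_formula` <- function(e1, e2) {
  new_formula(unclass(chem_formula(e1)) + unclass(chem_formula(e2)))
}

#' @export
`-.mm_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas", call. = FALSE)
  new_formula(unclass(chem_formula(e1)) - unclass(chem_formula(e2)))
}

#' @export
`*.mm_formula` <- function(e1, e2) {
  if (is.numeric(e1)) { k <- e1; f <- e2 } else { k <- e2; f <- e1 }
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  new_formula(unclass(chem_formula(f)) * k)
}

#' @export
`==.mm_formula` <- function(e1, e2) {
  all(unclass(chem_formula(e1)) == unclass(chem_formula(e2)))
}

#' Mass of an elemental formula
#'
#' @param f An `mm_formula` or formula string.
#' @param mode `"monoisotopic"` (principal-isotope masses) or `"average"`
#'   (standard atomic weights). Fragment and nucleoside work uses
#'   monoisotopic masses; intact-molecule work uses average masses because
#'   the isotope envelope is unresolved.
#' @return Mass in Da.
#' @examples
#' formula_mass("H2O")                      # 18.0106
#' formula_mass("C3H3N")                    # acrylonitrile, 53.0266
#' @export
formula_mass <- function(f, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  f <- chem_formula(f)
  tab <- if (mode == "monoisotopic") MONO_MASS else AVG_MASS
  sum(unclass(f) * tab)
}

check_charge <- function(z) {
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z != round(z)) {
    stop("charge `z` must be a positive integer", call. = FALSE)
  }
  as.integer(z)
}

#' Convert a neutral mass to m/z
#'
#' Negative mode assumes loss of `z` protons (`(M - z*1.007276)/z`), positive
#' mode gain of `z` protons. The proton mass (not the hydrogen atomic weight)
#' is used because the observed ions are (de)protonated species.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z Positive integer charge.
#' @param polarity `"negative"` or `"positive"`.
#' @return m/z.
#' @examples
#' mz_from_neutral(1967.270, 2, "negative")  # 982.628
#' @export
mz_from_neutral <- function(mass, z, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  z <- check_charge(z)
  stopifnot(all(mass > 0))
  sign <- if (polarity == "negative") -1 else 1
  (mass + sign * z * PROTON_MASS) / z
}

#' Convert an observed m/z back to a neutral mass
#'
#' Exact algebraic inverse of [mz_from_neutral()].
#'
#' @param mz Observed m/z (> 0).
#' @inheritParams mz_from_neutral
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz, z, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  z <- check_charge(z)
  stopifnot(all(mz > 0))
  sign <- if (polarity == "negative") -1 else 1
  mz * z - sign * z * PROTON_MASS
}
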