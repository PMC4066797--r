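# Independent oracles: deliberately separate constants and arithmetic from
# the package implementation, so agreement is evidence rather than tautology.

ORACLE_MONO <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                 O = 15.9949146221, P = 30.97376151, S = 31.97207069)

# direct atom-count summation from a formula string
oracle_formula_mass <- function(s) {
  m <- gregexpr("([A-Z])([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z])([0-9]*)", s))[[1]]
  sum(vapply(parts, function(p) {
    el <- substr(p, 1, 1)
    k <- suppressWarnings(as.integer(sub("^[A-Z]", "", p)))
    if (is.na(k)) k <- 1L
    ORACLE_MONO[[el]] * k
  }, numeric(1)))
}

# independent nucleoside masses (free nucleoside formulas written out)
ORACLE_NUC <- c(
  A = "C10H13N5O4", G = "C10H13N5O5", C = "C9H13N3O5", U = "C9H12N2O6",
  m1A = "C11H15N5O4", m2G = "C11H15N5O5", Y = "C9H12N2O6",
  ce1Y = "C12H15N3O6", m1G = "C11H15N5O5"
)

oracle_oligo_mass <- function(symbols, five = "hydroxyl", three = "phosphate") {
  hpo3 <- oracle_formula_mass("HPO3")
  h2o <- oracle_formula_mass("H2O")
  n <- length(symbols)
  n_term_p <- (five == "phosphate") + (three %in% c("phosphate", "cyclic_phosphate"))
  m <- sum(vapply(symbols, function(s) oracle_formula_mass(ORACLE_NUC[[s]]),
                  numeric(1))) +
    (n - 1) * (hpo3 - h2o) + n_term_p * hpo3
  if (three == "cyclic_phosphate") m <- m - h2o
  m
}

# brute-force digestion: enumerate cut points directly on a symbol vector
oracle_digest <- function(symbols, cut_after_symbols, five = "phosphate",
                          three = "hydroxyl") {
  n <- length(symbols)
  cuts <- which(symbols %in% cut_after_symbols & seq_len(n) < n)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    fp <- if (s == 1) five else "hydroxyl"
    tp <- if (e == n) three else "phosphate"
    list(symbols = symbols[s:e], start = s, end = e,
         five = fp, three = tp,
         mass = oracle_oligo_mass(symbols[s:e], fp, tp))
  })
}

# handy record constructors for tests
toy_trna <- function(symbols, ...) new_trna("toy", symbols, ...)

expect_formula_equal <- function(f1, f2) {
  expect_true(f1 == f2,
              label = paste(format_formula(f1), "==", format_formula(f2)))
}
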