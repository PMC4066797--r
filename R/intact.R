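# Intact-molecule masses and deconvolution of multiply charged ESI series.

#' Intact neutral mass of a tRNA record
#'
#' Applies the oligonucleotide linkage arithmetic to the full record with
#' its true terminal chemistry (a mature tRNA is 5'-phosphate /
#' 3'-hydroxyl). Average mass is the default for intact work: the isotope
#' envelope of a ~23 kDa molecule is unresolved on ion-trap instruments, so
#' the deconvoluted mass is an average mass.
#'
#' @param rec An `mm_trna`.
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @param registry Nucleoside registry.
#' @return Neutral mass in Da.
#' @examples
#' intact_mass(trna_ala())   # ~23180.7 Da
#' @export
intact_mass <- function(rec, mode = c("average", "monoisotopic"),
                        registry = default_registry()) {
  mode <- match.arg(mode)
  res <- trna_residues(rec)
  oligo_mass(res$symbol, rec$five_prime, rec$three_prime, mode, registry)
}

#' Deconvolve a multiply charged ESI series to a neutral mass
#'
#' Grid search over anchor charges: adjacent peaks of an ESI charge series
#' are consecutive charge states, so for each candidate charge of the
#' highest-m/z peak the implied neutral masses of all peaks are computed and
#' the assignment minimizing their spread is selected (ties broken toward
#' the lower charge). The reported mass is the intensity-weighted mean of
#' the per-peak implied masses.
#'
#' @param series An `mm_peaklist` (or tibble with `mz`, `intensity`) of at
#'   least two peaks.
#' @param charge_range Integer charges considered (default 5-40, suitable
#'   for tRNA-sized molecules).
#' @param polarity Ion polarity.
#' @param max_rms Reject the best assignment when its RMS residual exceeds
#'   this many Da (reported in the error).
#' @return An object of class `mm_deconv`: `neutral_mass`, `residual_rms`,
#'   `n_peaks_used`, and `assignments` (per-peak charge and implied mass).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
deconvolve <- function(series, charge_range = 5:40,
                       polarity = c("negative", "positive"), max_rms = 5) {
  polarity <- match.arg(polarity)
  stopifnot(length(charge_range) >= 1, all(charge_range >= 1))
  series <- dplyr::arrange(tibble::as_tibble(series)[c("mz", "intensity")],
                           .data$mz)
  n <- nrow(series)
  if (n < 2) stop("deconvolution requires at least two peaks", call. = FALSE)
  sign <- if (polarity == "negative") -1 else 1

  best <- NULL
  for (z_last in sort(charge_range)) {
    z <- z_last + (n - seq_len(n))      # ascending m/z = descending charge
    if (max(z) > max(charge_range)) next
    implied <- series$mz * z - sign * z * PROTON_MASS
    mass <- stats::weighted.mean(implied, series$intensity)
    rms <- sqrt(mean((implied - mass)^2))
    if (is.null(best) || rms < best$rms - 1e-12) {
      best <- list(z = z, implied = implied, mass = mass, rms = rms)
    }
  }
  if (is.null(best)) {
    stop("charge range admits no assignment for ", n, " peaks", call. = FALSE)
  }
  if (best$rms > max_rms) {
    stop("no consistent charge assignment: best RMS residual ",
         round(best$rms, 3), " Da exceeds ", max_rms, " Da", call. = FALSE)
  }
  structure(list(
    neutral_mass = best$mass,
    residual_rms = best$rms,
    n_peaks_used = n,
    assignments = tibble::tibble(mz = series$mz,
                                 intensity = series$intensity,
                                 z = best$z, implied_mass = best$implied)
  ), class = "mm_deconv")
}

#' @export
print.mm_deconv <- function(x, ...) {
  cat(sprintf("<deconvolution> M = %.2f Da (RMS %.3f Da, %d peaks, z %d-%d)\n",
              x$neutral_mass, x$residual_rms, x$n_peaks_used,
              min(x$assignments$z), max(x$assignments$z)))
  invisible(x)
}

#' @method tidy mm_deconv
#' @export
tidy.mm_deconv <- function(x, ...) {
  x$assignments
}

#' @method glance mm_deconv
#' @export
glance.mm_deconv <- function(x, ...) {
  tibble::tibble(neutral_mass = x$neutral_mass,
                 residual_rms = x$residual_rms,
                 n_peaks_used = x$n_peaks_used)
}

#' @method autoplot mm_deconv
#' @export
autoplot.mm_deconv <- function(object, ...) {
  ggplot2::ggplot(object$assignments, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$intensity,
                                    label = paste0("(", .data$z, "-)")),
                       vjust = -0.4, size = 2.8) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = sprintf("deconvoluted mass %.1f Da",
                                  object$neutral_mass)) +
    ggplot2::theme_minimal()
}

#' Compare a measured intact mass with the calculated mass of a record
#'
#' @param rec An `mm_trna`.
#' @param observed Observed neutral mass (Da), e.g. from [deconvolve()].
#' @param mode Mass mode for the calculated value.
#' @param registry Nucleoside registry.
#' @return A one-row tibble: `calculated`, `observed`, `gap` (observed -
#'   calculated).
#' @export
validate_intact_mass <- function(rec, observed, mode = "average",
                                 registry = default_registry()) {
  calc <- intact_mass(rec, mode, registry)
  tibble::tibble(trna = rec$name, calculated = calc, observed = observed,
                 gap = observed - calc)
}
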