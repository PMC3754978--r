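# Drug descriptor: the 256 hex digits of a path-based 2D fingerprint are
# treated as a real-valued digit signal and carried to the frequency domain;
# the complex moduli of the discrete Fourier transform form the 256-component
# drug vector. Moduli are convention-invariant, so the forward unnormalised
# transform with negative exponent (stats::fft) is used throughout.

validate_digits <- function(digits, what = "fingerprint") {
  if (length(digits) != 256L) {
    abort(sprintf("%s must have exactly 256 digits, found %d",
                  what, length(digits)))
  }
  if (anyNA(digits) || any(digits < 0 | digits > 15)) {
    abort(sprintf("%s digits must lie in [0, 15]", what))
  }
  invisible(digits)
}

#' Parse a 256-character hexadecimal fingerprint string
#'
#' Converts the hexadecimal form of a 2D molecular fingerprint (as emitted
#' by path-based fingerprinting tools) into its 256 integer digits, each in
#' \[0, 15\].
#'
#' @param drug_id Drug identifier.
#' @param hex_string 256 hexadecimal characters; embedded whitespace is
#'   stripped.
#' @return A one-row tibble with columns `drug_id` and `digits` (list column
#'   holding one integer vector of length 256).
#' @export
#' @examples
#' parse_fingerprint_hex("D1", strrep("0f", 128))
parse_fingerprint_hex <- function(drug_id, hex_string) {
  s <- gsub("\\s", "", hex_string)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) != 256L) {
    abort(sprintf("fingerprint for '%s': expected 256 hex characters, found %d",
                  drug_id, length(chars)))
  }
  bad <- !grepl("^[0-9a-fA-F]$", chars)
  if (any(bad)) {
    abort(sprintf("fingerprint for '%s': non-hex character '%s' at position %d",
                  drug_id, chars[which(bad)[1]], which(bad)[1]))
  }
  digits <- strtoi(chars, base = 16L)
  tibble(drug_id = drug_id, digits = list(digits))
}

#' Discrete Fourier amplitude spectrum of a fingerprint digit signal
#'
#' Computes `|sum_n digits[n] * exp(-2i * pi * k * n / 256)|` for
#' k = 0..255: the complex moduli of the unnormalised forward discrete
#' Fourier transform of the 256 fingerprint digits. The amplitudes are
#' non-negative and conjugate-symmetric (`amp[k] == amp[256 - k]`), and
#' satisfy Parseval's identity `sum(amp^2) == 256 * sum(digits^2)`.
#'
#' @param digits Integer or numeric vector of 256 fingerprint digits in
#'   \[0, 15\].
#' @return Numeric vector of 256 non-negative amplitudes, ordered by
#'   frequency index k = 0..255 (index 1 is the DC term, the digit sum).
#' @export
#' @examples
#' dft_amplitude(rep(3, 256))[1:4]  # constant signal: only the DC term
dft_amplitude <- function(digits) {
  validate_digits(digits)
  Mod(fft(as.numeric(digits)))
}

#' Drug feature vector from an amplitude spectrum
#'
#' The drug descriptor is the amplitude spectrum itself, in frequency order;
#' this passthrough exists so the feature contract (a 256-component real
#' vector per drug) is explicit and checked.
#'
#' @param spectrum Numeric vector of 256 non-negative amplitudes.
#' @return Numeric vector of length 256.
#' @export
drug_vector <- function(spectrum) {
  if (length(spectrum) != 256L) {
    abort(sprintf("drug spectrum must have 256 components, found %d",
                  length(spectrum)))
  }
  if (anyNA(spectrum) || any(spectrum < 0)) {
    abort("drug spectrum amplitudes must be finite and non-negative")
  }
  as.numeric(spectrum)
}

#' Fourier amplitude spectra for a table of drug fingerprints
#'
#' Maps [dft_amplitude()] over a fingerprint table, producing the
#' 256-component spectral descriptor of every drug.
#'
#' @param fingerprints Tibble with columns `drug_id` and `digits` (list
#'   column of 256-digit integer vectors), as returned by
#'   [read_fingerprint_table()] or [generate_synthetic_benchmark()].
#' @return A tibble with `drug_id` plus 256 amplitude columns
#'   `amp_0` ... `amp_255`.
#' @export
drug_spectrum <- function(fingerprints) {
  stopifnot(is.data.frame(fingerprints),
            all(c("drug_id", "digits") %in% names(fingerprints)))
  amp <- t(vapply(fingerprints$digits,
                  function(d) drug_vector(dft_amplitude(d)),
                  numeric(256)))
  colnames(amp) <- paste0("amp_", 0:255)
  dplyr::bind_cols(tibble(drug_id = fingerprints$drug_id), as_tibble(amp))
}
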