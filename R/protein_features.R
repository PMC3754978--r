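# Receptor descriptor: a 22-component pseudo amino acid composition. The
# first 20 components are the residue frequencies; the last two come from a
# GM(1,1) grey model fitted to the sequence read as a mean-polarity signal,
# so sequence order is not discarded. The polarity scale is offset by +1.20
# because the grey model requires a strictly positive series (the smallest
# mean-polarity value, lysine's -1.18, maps to +0.02).

split_residues <- function(sequence, on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("sequence must be a single non-empty string")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- !res %in% AA_ALPHABET
  if (any(bad)) {
    if (on_nonstandard == "error") {
      abort(sprintf("non-standard residue letter(s): %s",
                    paste(unique(res[bad]), collapse = ", ")))
    }
    warn(sprintf("skipping %d non-standard residue(s)", sum(bad)))
    res <- res[!bad]
  }
  if (length(res) == 0L) abort("sequence has no standard residues")
  res
}

#' Amino acid composition of a protein sequence
#'
#' Normalised occurrence frequencies of the 20 standard amino acids, in
#' fixed alphabetical order (A, C, D, ..., Y); they sum to 1.
#'
#' @param sequence Amino acid sequence (single string; case-insensitive).
#' @param on_nonstandard `"error"` (default) to reject letters outside the
#'   20-residue alphabet, `"skip"` to drop them (with a warning) from both
#'   the counts and the denominator.
#' @return Named numeric vector of 20 frequencies.
#' @export
#' @examples
#' amino_acid_composition("ACDC")
amino_acid_composition <- function(sequence, on_nonstandard = c("error", "skip")) {
  res <- split_residues(sequence, on_nonstandard)
  counts <- table(factor(res, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(res)
  names(out) <- AA_ALPHABET
  out
}

#' Encode a sequence as a positive physicochemical signal
#'
#' Maps each residue to its scale value plus a positivity offset, producing
#' the strictly positive series the GM(1,1) grey model is fitted to. With
#' the default mean-polarity scale and offset 1.20 every standard residue
#' maps to a positive number.
#'
#' @inheritParams amino_acid_composition
#' @param scale Property scale name (see [aa_scale()]); default
#'   `"mean_polarity"`.
#' @param offset Added to every scale value; default 1.20.
#' @return Numeric vector, one positive value per residue in sequence order.
#' @export
#' @examples
#' encode_polarity("ACK")  # 1.14, 2.56, 0.02
encode_polarity <- function(sequence, scale = "mean_polarity", offset = 1.20,
                            on_nonstandard = c("error", "skip")) {
  res <- split_residues(sequence, on_nonstandard)
  vals <- unname(aa_scale(scale)[res]) + offset
  if (any(vals <= 0)) {
    abort("encoded series must be strictly positive; increase `offset` for this scale")
  }
  vals
}

#' Fit a GM(1,1) grey model to a positive series
#'
#' Applies the accumulated generating operation (cumulative sum) to the raw
#' series, forms the background values `z(k) = (x1(k) + x1(k-1)) / 2`, and
#' solves the least-squares system `x0(k) = -a * z(k) + b` (k = 2..L) for
#' the development coefficient `a` and grey input `b` via the normal
#' equations of the (L-1) x 2 design.
#'
#' @param series Numeric vector of length >= 3, all values > 0.
#' @return A list with elements `a` and `b`.
#' @export
#' @examples
#' fit_gm11(c(1, 2, 3))  # a = -0.4, b = 1.2
fit_gm11 <- function(series) {
  if (length(series) < 3L) {
    abort("GM(1,1) requires a series of length >= 3")
  }
  if (anyNA(series) || any(series <= 0)) {
    abort("GM(1,1) requires a strictly positive series")
  }
  x1 <- cumsum(series)
  L <- length(series)
  z <- (x1[-1] + x1[-L]) / 2
  y <- series[-1]
  B <- cbind(-z, 1)
  BtB <- crossprod(B)
  if (abs(det(BtB)) < .Machine$double.eps * max(abs(BtB))^2) {
    abort("singular normal equations in GM(1,1) fit")
  }
  theta <- drop(solve(BtB, crossprod(B, y)))
  list(a = theta[1], b = theta[2])
}

#' Grey-model pseudo amino acid composition
#'
#' Builds the 22-component receptor descriptor: the 20 residue frequencies
#' `f_1..f_20` plus two sequence-order components derived from the GM(1,1)
#' parameters (a, b) fitted to the encoded physicochemical series. With
#' denominator `D = sum(f) + w1*|a| + w2*|b|`, components 1-20 are `f_i / D`,
#' component 21 is `w1*|a| / D` and component 22 is `w2*|b| / D`; the vector
#' is non-negative and sums to 1.
#'
#' @inheritParams encode_polarity
#' @param w1,w2 Positive weights on the two grey-model components. No
#'   default: they are tuning parameters of the descriptor.
#' @return Named numeric vector of length 22 (`A` ... `Y`, `grey_a`,
#'   `grey_b`).
#' @export
#' @examples
#' grey_pseaac(strrep("ACD", 20), w1 = 0.05, w2 = 0.05)
grey_pseaac <- function(sequence, w1, w2, scale = "mean_polarity",
                        on_nonstandard = c("error", "skip")) {
  if (!is.numeric(w1) || !is.numeric(w2) || w1 <= 0 || w2 <= 0) {
    abort("w1 and w2 must be positive numbers")
  }
  f <- amino_acid_composition(sequence, on_nonstandard)
  gm <- fit_gm11(encode_polarity(sequence, scale = scale,
                                 on_nonstandard = on_nonstandard))
  extras <- c(grey_a = w1 * abs(gm$a), grey_b = w2 * abs(gm$b))
  D <- sum(f) + sum(extras)
  c(f, extras) / D
}

#' Pseudo amino acid composition for a table of sequences
#'
#' Maps [grey_pseaac()] over a sequence table.
#'
#' @param sequences Tibble with columns `gpcr_id` and `sequence`, as
#'   returned by [read_fasta()] or [generate_synthetic_benchmark()].
#' @inheritParams grey_pseaac
#' @return A tibble with `gpcr_id` plus 22 descriptor columns
#'   `pse_A` ... `pse_Y`, `pse_grey_a`, `pse_grey_b`.
#' @export
protein_features <- function(sequences, w1, w2, scale = "mean_polarity",
                             on_nonstandard = c("error", "skip")) {
  stopifnot(is.data.frame(sequences),
            all(c("gpcr_id", "sequence") %in% names(sequences)))
  feats <- t(vapply(sequences$sequence, function(s) {
    grey_pseaac(s, w1 = w1, w2 = w2, scale = scale,
                on_nonstandard = on_nonstandard)
  }, numeric(22)))
  colnames(feats) <- paste0("pse_", c(AA_ALPHABET, "grey_a", "grey_b"))
  dplyr::bind_cols(tibble(gpcr_id = sequences$gpcr_id), as_tibble(feats))
}
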