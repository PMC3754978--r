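# Ten physicochemical property scales for the 20 standard amino acids.
# Rows alphabetical by one-letter code; values as printed in standard
# biochemistry references. The mean-polarity column drives the grey-model
# sequence encoding; the others are selectable alternatives.
AA_SCALE_NAMES <- c("hydrophobicity", "hydrophilicity", "side_chain_mass",
                    "pk1", "pk2", "pi", "avg_buried_volume",
                    "molecular_weight", "side_chain_volume", "mean_polarity")

AA_SCALES <- matrix(c(
  # hydroph hydrophil  mass   pk1    pk2    pi     buried  mw      scvol  polarity
   0.62,  -0.50,      15,  2.35,  9.87,  6.11,  91.50,  89.09,  27.5, -0.06,  # A
   0.29,  -1.00,      47,  1.71, 10.78,  5.02, 117.7,  121.2,   44.6,  1.36,  # C
  -0.90,   3.00,      59,  1.88,  9.60,  2.98, 124.5,  133.1,   40.0, -0.80,  # D
  -0.74,   3.00,      73,  2.19,  9.67,  3.08, 155.1,  147.1,   62.0, -0.77,  # E
   1.19,  22.50,      91,  2.58,  9.24,  5.91, 203.4,  165.2,  115.5,  1.27,  # F
   0.48,   0.00,       1,  2.34,  9.60,  6.06,  66.40,  75.07,   0.0, -0.41,  # G
  -0.40,  20.50,      82,  1.78,  8.97,  7.64, 167.3,  155.2,   79.0,  0.49,  # H
   1.38,  21.80,      57,  2.32,  9.76,  6.04, 168.8,  131.2,   93.5,  1.31,  # I
  -1.50,   3.00,      73,  2.20,  8.90,  9.47, 171.3,  146.2,  100.0, -1.18,  # K
   1.06,  21.80,      57,  2.36,  9.60,  6.04, 167.9,  131.2,   93.5,  1.21,  # L
   0.64,  21.30,      75,  2.28,  9.21,  5.74, 170.8,  149.2,   94.1,  1.27,  # M
  -0.78,   0.20,      58,  2.18,  9.09, 10.76, 135.2,  132.1,   58.7, -0.48,  # N
   0.12,   0.00,      42,  1.99, 10.60,  6.30, 129.3,  115.1,   41.9,  0.00,  # P
  -0.85,   0.20,      72,  2.17,  9.13,  5.65, 161.1,  146.2,   80.7, -0.73,  # Q
  -2.53,   3.00,     101,  2.18,  9.09, 10.76, 202.0,  174.2,  105.0, -0.84,  # R
  -0.18,   0.30,      31,  2.21,  9.15,  5.68,  99.10, 105.1,   29.3, -0.50,  # S
  -0.05,  20.40,      45,  2.15,  9.12,  5.60, 122.1,  119.1,   51.3, -0.27,  # T
   1.08,  21.50,      43,  2.29,  9.74,  6.02, 141.7,  117.2,   71.5,  1.09,  # V
   0.81,  23.40,     130,  2.38,  9.39,  5.88, 237.6,  204.2,  145.5,  0.88,  # W
   0.26,  22.30,     107,  2.20,  9.11,  5.63, 203.6,  181.2,  117.3,  0.33   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  AA_SCALE_NAMES))

#' Physicochemical property scales for the 20 standard amino acids
#'
#' Ten classical per-residue property scales (hydrophobicity, hydrophilicity,
#' side-chain mass, pK1, pK2, isoelectric point, average buried volume,
#' molecular weight, side-chain volume, mean polarity). The mean-polarity
#' scale, offset by +1.20 so every value is positive, is the default numeric
#' encoding fed to the GM(1,1) grey model.
#'
#' @return A tibble with a `residue` column and one column per scale,
#'   20 rows in alphabetical residue order.
#' @export
#' @examples
#' aa_property_scales()
aa_property_scales <- function() {
  dplyr::bind_cols(tibble(residue = rownames(AA_SCALES)), as_tibble(AA_SCALES))
}

#' Look up one property scale as a named vector
#'
#' @param scale Scale name; one of
#'   `"hydrophobicity"`, `"hydrophilicity"`, `"side_chain_mass"`, `"pk1"`,
#'   `"pk2"`, `"pi"`, `"avg_buried_volume"`, `"molecular_weight"`,
#'   `"side_chain_volume"`, `"mean_polarity"`.
#' @return Named numeric vector of length 20 (names = residue letters).
#' @export
aa_scale <- function(scale = "mean_polarity") {
  scale <- match.arg(scale, AA_SCALE_NAMES)
  AA_SCALES[, scale]
}
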