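# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# quadratic-time direct evaluation of the DFT amplitude sum
brute_dft_amplitude <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N - 1), function(k) {
    re <- sum(x * cos(2 * pi * k * n / N))
    im <- -sum(x * sin(2 * pi * k * n / N))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# GM(1,1) parameters via an independent least-squares route (QR through
# lm.fit rather than the normal equations)
brute_gm11 <- function(series) {
  x1 <- cumsum(series)
  L <- length(series)
  z <- (x1[-1] + x1[-L]) / 2
  fit <- stats::lm.fit(cbind(neg_z = -z, one = 1), series[-1])
  list(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
}

# fuzzy KNN membership by explicit sorting of all pairwise distances
brute_fknn_mu <- function(X_train, y_pos, query, k, m) {
  d <- sqrt(colSums((t(X_train) - query)^2))
  ord <- order(d)[seq_len(k)]
  if (d[ord[1]] == 0) return(y_pos[ord[1]])
  w <- d[ord]^(-2 / (m - 1))
  sum(w * y_pos[ord]) / sum(w)
}

# embed low-dimensional toy points into the 278-column feature layout so
# classifier tests can use hand-checkable geometry
toy_features <- function(coords, label = NULL) {
  coords <- as.matrix(coords)
  m <- matrix(0, nrow = nrow(coords), ncol = length(gdip:::FEATURE_COLS),
              dimnames = list(NULL, gdip:::FEATURE_COLS))
  m[, seq_len(ncol(coords))] <- coords
  out <- tibble::as_tibble(m)
  if (!is.null(label)) out <- dplyr::bind_cols(tibble::tibble(label = label), out)
  out
}

random_fingerprint <- function() sample(0:15, 256, replace = TRUE)

random_sequence <- function(len) {
  paste(sample(gdip:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}
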