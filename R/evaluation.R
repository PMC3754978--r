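# Performance metrics in both printed parameterisations (TP/TN/FP/FN and the
# subset-wise misprediction counts), leave-one-out (jackknife) evaluation,
# and the (K, m) grid search. The jackknife precomputes one pairwise
# distance matrix and masks the held-out row per fold -- exact, since fuzzy
# KNN has no training beyond storage.

#' Confusion counts for binary interaction labels
#'
#' @param truth,predicted Character vectors of `"interactive"` /
#'   `"non-interactive"` labels, equal length.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn` and the equivalent
#'   subset-wise parameterisation: `n_pos` (= tp + fn), `n_neg` (= tn + fp),
#'   `n_pos_mis` (interactive pairs mispredicted, = fn) and `n_neg_mis`
#'   (non-interactive pairs mispredicted, = fp).
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort(sprintf("length mismatch: %d truth vs %d predicted labels",
                  length(truth), length(predicted)))
  }
  lv <- c("interactive", "non-interactive")
  if (!all(truth %in% lv) || !all(predicted %in% lv)) {
    abort("labels must be 'interactive' or 'non-interactive'")
  }
  tp <- sum(truth == "interactive" & predicted == "interactive")
  tn <- sum(truth == "non-interactive" & predicted == "non-interactive")
  fp <- sum(truth == "non-interactive" & predicted == "interactive")
  fn <- sum(truth == "interactive" & predicted == "non-interactive")
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         n_pos = tp + fn, n_neg = tn + fp, n_pos_mis = fn, n_neg_mis = fp)
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Computes the four metrics in the TP/TN/FP/FN form and, as an internal
#' consistency check, in the equivalent subset-wise form (success rate
#' `1 - n_pos_mis / n_pos` on the interactive subset, and so on); the two
#' must agree. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0, and named in the `undefined` column.
#'
#' @param cc One-row tibble from [confusion_counts()].
#' @return A one-row tibble with `sn`, `sp`, `acc`, `mcc` and a character
#'   column `undefined` (comma-separated names of undefined metrics, `""`
#'   if none).
#' @export
classification_metrics <- function(cc) {
  stopifnot(is.data.frame(cc), nrow(cc) == 1,
            all(c("tp", "tn", "fp", "fn") %in% names(cc)))
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  np <- tp + fn; nn <- tn + fp
  sn  <- if (np > 0) tp / np else NA_real_
  sp  <- if (nn > 0) tn / nn else NA_real_
  tot <- np + nn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mden > 0) (tp * tn - fp * fn) / sqrt(mden) else NA_real_

  # subset-wise formulation must agree wherever defined
  if (np > 0 && nn > 0) {
    l1 <- 1 - fn / np
    l2 <- 1 - fp / nn
    acc2 <- (l1 * np + l2 * nn) / (np + nn)
    stopifnot(abs(acc2 - acc) < 1e-12, abs(l1 - sn) < 1e-12,
              abs(l2 - sp) < 1e-12)
    if (mden > 0) {
      mcc2 <- (1 - (fn / np + fp / nn)) /
        sqrt((1 + (fp - fn) / np) * (1 + (fn - fp) / nn))
      stopifnot(abs(mcc2 - mcc) < 1e-9)
    }
  }
  und <- c("sn", "sp", "acc", "mcc")[is.na(c(sn, sp, acc, mcc))]
  tibble(sn = sn, sp = sp, acc = acc, mcc = mcc,
         undefined = paste(und, collapse = ","))
}

# leave-one-out memberships from a masked distance matrix, vectorised over
# (k, m) reuse: ordm[, i] ranks the neighbours of i (self pushed last by the
# Inf diagonal)
loo_mu <- function(D, y_pos, k, m, ordm = NULL) {
  n <- length(y_pos)
  if (k > n - 1) abort(sprintf("k (%d) exceeds n - 1 (%d)", k, n - 1))
  if (is.null(ordm)) ordm <- apply(D, 2, order)
  nb <- ordm[seq_len(k), , drop = FALSE]
  DK <- matrix(D[cbind(as.vector(nb), rep(seq_len(n), each = k))], nrow = k)
  Y <- matrix(y_pos[nb], nrow = k)
  W <- DK^(-2 / (m - 1))
  mu <- colSums(W * Y) / colSums(W)
  zero <- DK[1, ] == 0
  mu[zero] <- Y[1, zero]
  mu
}

mu_to_labels <- function(mu) {
  ifelse(mu > 0.5, "interactive", "non-interactive")
}

#' Jackknife (leave-one-out) evaluation of the full pipeline
#'
#' Featurises every pair of the benchmark, then predicts each pair from a
#' fuzzy KNN model trained on the remaining N - 1 pairs. One pairwise
#' distance matrix is computed and the held-out pair's row masked per fold,
#' which is exact for a memory-based classifier.
#'
#' @param bench A [benchmark()] object.
#' @param k,m Fuzzy KNN hyperparameters.
#' @param w1,w2 PseAAC grey-component weights.
#' @param lambda Drug-block fusion weight; default 1/700.
#' @param scale Property scale; default `"mean_polarity"`.
#' @return An object of class `gdip_jackknife` with elements `predictions`
#'   (per-pair tibble), `counts`, `metrics` and `params`. `tidy()` returns
#'   the per-pair predictions, `glance()` the one-row metric summary.
#' @export
jackknife <- function(bench, k, m, w1, w2, lambda = 1 / 700,
                      scale = "mean_polarity") {
  feats <- pair_features(bench, w1 = w1, w2 = w2, lambda = lambda,
                         scale = scale)
  X <- feature_matrix(feats)
  if (nrow(X) < k + 1) abort("benchmark too small for this k")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  mu <- loo_mu(D, as.numeric(feats$label == "interactive"), k, m)
  predictions <- tibble(gpcr_id = feats$gpcr_id, drug_id = feats$drug_id,
                        label = feats$label, mu_interactive = mu,
                        predicted = mu_to_labels(mu), tie = mu == 0.5)
  counts <- confusion_counts(predictions$label, predictions$predicted)
  structure(list(predictions = predictions, counts = counts,
                 metrics = classification_metrics(counts),
                 params = list(k = k, m = m, w1 = w1, w2 = w2,
                               lambda = lambda, scale = scale)),
            class = "gdip_jackknife")
}

#' @export
print.gdip_jackknife <- function(x, ...) {
  with(x$metrics, cat(sprintf(
    "<gdip_jackknife> n = %d | Sn %.3f  Sp %.3f  Acc %.3f  MCC %.3f\n",
    nrow(x$predictions), sn, sp, acc, mcc)))
  invisible(x)
}

#' @method tidy gdip_jackknife
#' @export
tidy.gdip_jackknife <- function(x, ...) x$predictions

#' @method glance gdip_jackknife
#' @export
glance.gdip_jackknife <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble(n = nrow(x$predictions),
                                     k = x$params$k, m = x$params$m))
}

#' Grid search over the fuzzy KNN hyperparameters
#'
#' Runs the jackknife at every (K, m) grid point, reusing one feature and
#' distance matrix across the whole grid, and selects the point maximising
#' the objective (overall accuracy by default; MCC optionally). Ties are
#' broken deterministically: smallest K, then smallest m.
#'
#' @param bench A [benchmark()] object.
#' @param k_grid Integer vector of neighbour counts; default `1:30`.
#' @param m_grid Numeric vector of fuzzy coefficients (> 1); default
#'   `seq(1.1, 3.0, by = 0.1)`.
#' @inheritParams jackknife
#' @param objective `"acc"` (default) or `"mcc"`.
#' @return An object of class `gdip_grid` with elements `table` (one row of
#'   metrics per grid point), `best` (the selected row) and `params`.
#'   `tidy()` returns the table, `glance()` the best row;
#'   `autoplot()` draws the accuracy surface.
#' @export
grid_search <- function(bench, k_grid = 1:30,
                        m_grid = seq(1.1, 3.0, by = 0.1),
                        w1, w2, lambda = 1 / 700, scale = "mean_polarity",
                        objective = c("acc", "mcc")) {
  objective <- match.arg(objective)
  if (!length(k_grid) || !length(m_grid)) abort("empty hyperparameter grid")
  if (any(m_grid <= 1)) abort("all m values must be > 1")
  feats <- pair_features(bench, w1 = w1, w2 = w2, lambda = lambda,
                         scale = scale)
  X <- feature_matrix(feats)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (max(k_grid) > nrow(X) - 1) abort("largest k exceeds n - 1")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ordm <- apply(D, 2, order)
  y_pos <- as.numeric(feats$label == "interactive")

  tab <- tidyr::expand_grid(k = k_grid, m = sort(unique(m_grid))) |>
    dplyr::rowwise() |>
    dplyr::mutate(classification_metrics(confusion_counts(
      feats$label,
      mu_to_labels(loo_mu(D, y_pos, .data$k, .data$m, ordm))))) |>
    dplyr::ungroup()

  best <- tab |>
    dplyr::arrange(dplyr::desc(.data[[objective]]), .data$k, .data$m) |>
    dplyr::slice(1)
  structure(list(table = tab, best = best,
                 params = list(w1 = w1, w2 = w2, lambda = lambda,
                               scale = scale, objective = objective,
                               n = nrow(X))),
            class = "gdip_grid")
}

#' @export
print.gdip_grid <- function(x, ...) {
  cat(sprintf("<gdip_grid> %d grid points, best by %s: K = %d, m = %g (Acc %.3f, MCC %.3f)\n",
              nrow(x$table), x$params$objective, x$best$k, x$best$m,
              x$best$acc, x$best$mcc))
  invisible(x)
}

#' @method tidy gdip_grid
#' @export
tidy.gdip_grid <- function(x, ...) x$table

#' @method glance gdip_grid
#' @export
glance.gdip_grid <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble(objective = x$params$objective,
                                  n = x$params$n))
}
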