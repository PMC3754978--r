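# Pair fusion and the fuzzy K-nearest-neighbour engine. A pair vector is the
# drug's amplitude spectrum scaled by lambda (default 1/700) followed by the
# receptor's 22-component pseudo amino acid composition: 278 components in
# all. The lambda weight sits on the drug block because spectrum amplitudes
# are two to four orders of magnitude larger than PseAAC components;
# weighting the protein block instead would annihilate it.

FEATURE_COLS <- c(paste0("amp_", 0:255),
                  paste0("pse_", c("A", "C", "D", "E", "F", "G", "H", "I",
                                   "K", "L", "M", "N", "P", "Q", "R", "S",
                                   "T", "V", "W", "Y", "grey_a", "grey_b")))

feature_matrix <- function(df) {
  miss <- setdiff(FEATURE_COLS, names(df))
  if (length(miss)) {
    abort(sprintf("missing feature column(s), e.g. %s", miss[1]))
  }
  m <- as.matrix(df[, FEATURE_COLS])
  if (!all(is.finite(m))) abort("non-finite pair-vector components")
  m
}

#' Fuse one drug vector and one PseAAC vector into a pair vector
#'
#' Concatenates `lambda * drug_vec` (256 spectrum amplitudes) with the 22
#' PseAAC components, drug block first.
#'
#' @param drug_vec Numeric vector of 256 spectrum amplitudes.
#' @param pseaac Numeric vector of 22 PseAAC components.
#' @param lambda Positive weight on the drug block; default 1/700.
#' @return Numeric vector of length 278.
#' @export
fuse_pair <- function(drug_vec, pseaac, lambda = 1 / 700) {
  if (length(drug_vec) != 256L) {
    abort(sprintf("drug vector must have 256 components, found %d",
                  length(drug_vec)))
  }
  if (length(pseaac) != 22L) {
    abort(sprintf("PseAAC vector must have 22 components, found %d",
                  length(pseaac)))
  }
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be positive")
  out <- c(lambda * as.numeric(drug_vec), as.numeric(pseaac))
  if (!all(is.finite(out))) abort("non-finite pair-vector components")
  out
}

#' Featurise every pair of a benchmark
#'
#' Runs the full representation pipeline: Fourier amplitude spectra for all
#' drugs, grey-model PseAAC for all receptors, then the weighted fusion of
#' the two blocks for every labelled pair.
#'
#' @param bench A [benchmark()] object.
#' @param w1,w2 PseAAC grey-component weights (see [grey_pseaac()]).
#' @param lambda Drug-block fusion weight; default 1/700.
#' @param scale Property scale for the grey model; default `"mean_polarity"`.
#' @return A tibble with `gpcr_id`, `drug_id`, `label` and 278 feature
#'   columns (`amp_0` ... `amp_255`, already scaled by `lambda`, then
#'   `pse_A` ... `pse_grey_b`).
#' @export
pair_features <- function(bench, w1, w2, lambda = 1 / 700,
                          scale = "mean_polarity") {
  stopifnot(inherits(bench, "gdip_benchmark"))
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be positive")
  spec <- drug_spectrum(bench$fingerprints)
  spec[paste0("amp_", 0:255)] <- spec[paste0("amp_", 0:255)] * lambda
  prot <- protein_features(bench$sequences, w1 = w1, w2 = w2, scale = scale)
  out <- bench$pairs |>
    dplyr::inner_join(spec, by = "drug_id") |>
    dplyr::inner_join(prot, by = "gpcr_id")
  if (nrow(out) != nrow(bench$pairs)) {
    abort("featurisation lost pairs: missing sequence or fingerprint")
  }
  dplyr::select(out, "gpcr_id", "drug_id", "label",
                dplyr::all_of(FEATURE_COLS))
}

#' Fit (store) a fuzzy K-nearest-neighbour model
#'
#' Fuzzy KNN has no training beyond storing the labelled pair vectors with
#' crisp class memberships (1 for the observed class, 0 for the other) and
#' the two hyperparameters: the neighbour count `K` and the fuzzy
#' coefficient `m > 1` governing how strongly distance down-weights a
#' neighbour's vote.
#'
#' @param features Feature tibble from [pair_features()] (needs `label` and
#'   the 278 feature columns).
#' @param k Neighbour count, `1 <= k <=` number of training pairs.
#' @param m Fuzzy coefficient, > 1.
#' @param params Optional named list of provenance parameters (`w1`, `w2`,
#'   `lambda`, `scale`) recorded for persistence.
#' @return An object of class `gdip_fknn`.
#' @export
fknn <- function(features, k, m, params = list()) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  X <- feature_matrix(features)
  y <- features$label
  if (!all(y %in% c("interactive", "non-interactive"))) {
    abort("labels must be 'interactive' or 'non-interactive'")
  }
  if (!is.numeric(k) || k < 1 || k != round(k)) abort("k must be a positive integer")
  if (k > nrow(X)) {
    abort(sprintf("k (%d) exceeds the number of training pairs (%d)",
                  as.integer(k), nrow(X)))
  }
  if (!is.numeric(m) || m <= 1) abort("m must be > 1")
  structure(list(X = X, labels = y,
                 ids = features[intersect(c("gpcr_id", "drug_id"),
                                          names(features))],
                 k = as.integer(k), m = as.numeric(m), params = params),
            class = "gdip_fknn")
}

#' @export
print.gdip_fknn <- function(x, ...) {
  cat(sprintf("<gdip_fknn> %d training pairs (%d interactive), K = %d, m = %g\n",
              nrow(x$X), sum(x$labels == "interactive"), x$k, x$m))
  invisible(x)
}

# mu_interactive for each query row; D = query-by-train distance matrix.
# Weights d^(-2/(m-1)); a zero distance short-circuits to the crisp
# membership of the first coincident training point (stable training order).
fknn_mu <- function(D, y_pos, k, m) {
  n_train <- length(y_pos)
  apply(D, 1, function(d) {
    ord <- order(d)[seq_len(k)]          # order() breaks ties by index
    dk <- d[ord]
    if (dk[1] == 0) return(as.numeric(y_pos[ord[1]]))
    w <- dk^(-2 / (m - 1))
    sum(w * y_pos[ord]) / sum(w)
  })
}

cross_dist <- function(Q, X) {
  d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
  sqrt(pmax(d2, 0))
}

#' Fuzzy class memberships for query pair vectors
#'
#' Evaluates the fuzzy KNN membership rule: among the `K` training vectors
#' nearest to the query (Euclidean distance), neighbour `j` contributes its
#' crisp membership weighted by `d_j^(-2/(m-1))`; the two memberships are
#' normalised to sum to 1. A query coinciding with a training point takes
#' that point's crisp membership.
#'
#' @param model A [fknn()] model.
#' @param new_data Feature tibble (as from [pair_features()]) or a numeric
#'   matrix/vector of 278-component pair vectors.
#' @return A tibble with `mu_interactive` and `mu_noninteractive`, one row
#'   per query.
#' @export
fuzzy_membership <- function(model, new_data) {
  stopifnot(inherits(model, "gdip_fknn"))
  Q <- if (is.data.frame(new_data)) feature_matrix(new_data)
       else if (is.matrix(new_data)) new_data
       else matrix(new_data, nrow = 1)
  if (ncol(Q) != ncol(model$X)) {
    abort(sprintf("query has %d components, model expects %d",
                  ncol(Q), ncol(model$X)))
  }
  if (!all(is.finite(Q))) abort("non-finite query components")
  mu <- fknn_mu(cross_dist(Q, model$X),
                as.numeric(model$labels == "interactive"),
                model$k, model$m)
  tibble(mu_interactive = mu, mu_noninteractive = 1 - mu)
}

#' Predict interaction for query pairs
#'
#' A query is called interactive when its interactive membership exceeds the
#' non-interactive one; an exact tie is resolved to non-interactive (the
#' majority class under the 2:1 negative design) and flagged.
#'
#' @param object A [fknn()] model.
#' @param new_data Feature tibble or numeric matrix/vector (see
#'   [fuzzy_membership()]).
#' @param ... Unused.
#' @return A tibble with any id columns present in `new_data`, the two
#'   memberships, `predicted` and a logical `tie` column.
#' @export
predict.gdip_fknn <- function(object, new_data, ...) {
  mu <- fuzzy_membership(object, new_data)
  out <- dplyr::mutate(
    mu,
    predicted = ifelse(.data$mu_interactive > .data$mu_noninteractive,
                       "interactive", "non-interactive"),
    tie = .data$mu_interactive == .data$mu_noninteractive)
  if (is.data.frame(new_data)) {
    ids <- intersect(c("gpcr_id", "drug_id", "label"), names(new_data))
    out <- dplyr::bind_cols(new_data[, ids, drop = FALSE], out)
  }
  as_tibble(out)
}

#' @method glance gdip_fknn
#' @export
glance.gdip_fknn <- function(x, ...) {
  tibble(n_train = nrow(x$X),
         n_interactive = sum(x$labels == "interactive"),
         n_noninteractive = sum(x$labels == "non-interactive"),
         k = x$k, m = x$m)
}

#' @rdname fknn_model_io
#' @export
write_fknn_model <- function(model, dir) {
  stopifnot(inherits(model, "gdip_fknn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- apply(model$X, c(1, 2), function(v) sprintf("%.17g", v))
  utils::write.table(mat, file.path(dir, "training.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FEATURE_COLS)
  utils::write.table(data.frame(label = model$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pars <- c(list(k = model$k, m = sprintf("%.17g", model$m)), model$params)
  writeLines(c(sprintf("version=%s", gdip_version()),
               sprintf("%s=%s", names(pars),
                       vapply(pars, as.character, character(1)))),
             file.path(dir, "params.txt"))
  invisible(dir)
}

#' Persist / restore a fuzzy KNN model
#'
#' The model directory is human-readable plain text: the training matrix
#' (`training.tsv`, full double precision), the labels (`labels.tsv`) and a
#' key-value parameter file (`params.txt`). The round trip is bit-exact.
#'
#' @param model A [fknn()] model.
#' @param dir Model directory.
#' @return `write_fknn_model()` returns `dir` invisibly;
#'   `read_fknn_model()` returns the restored `gdip_fknn` model.
#' @name fknn_model_io
#' @export
read_fknn_model <- function(dir) {
  X <- as.matrix(utils::read.table(file.path(dir, "training.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  labels <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                              sep = "\t")$label
  kv <- strsplit(readLines(file.path(dir, "params.txt")), "=", fixed = TRUE)
  pars <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  extra <- pars[setdiff(names(pars), c("version", "k", "m"))]
  feats <- dplyr::bind_cols(tibble(label = labels), as_tibble(X))
  fknn(feats, k = as.integer(pars$k), m = as.numeric(pars$m), params = extra)
}
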