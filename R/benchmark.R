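# A benchmark bundles the three inputs every downstream step needs: the
# labelled pair list, the receptor sequences, and the per-drug fingerprints.

#' Assemble a GPCR-drug benchmark
#'
#' Bundles a labelled pair table, a sequence table and a fingerprint table
#' into one validated object: every GPCR in `pairs` must have a sequence,
#' every drug a fingerprint, and (gpcr_id, drug_id) pairs must be unique.
#'
#' @param pairs Tibble with `gpcr_id`, `drug_id`, `label` (see
#'   [read_pair_table()]).
#' @param sequences Tibble with `gpcr_id`, `sequence` (see [read_fasta()]).
#' @param fingerprints Tibble with `drug_id`, `digits` (see
#'   [read_fingerprint_table()]).
#' @return An object of class `gdip_benchmark` (a named list of the three
#'   tibbles).
#' @export
benchmark <- function(pairs, sequences, fingerprints) {
  stopifnot(is.data.frame(pairs), is.data.frame(sequences),
            is.data.frame(fingerprints))
  if (!all(c("gpcr_id", "drug_id", "label") %in% names(pairs))) {
    abort("`pairs` needs columns gpcr_id, drug_id, label")
  }
  if (!all(pairs$label %in% c("interactive", "non-interactive"))) {
    abort("pair labels must be 'interactive' or 'non-interactive'")
  }
  key <- paste(pairs$gpcr_id, pairs$drug_id)
  if (anyDuplicated(key)) {
    abort("duplicate (gpcr_id, drug_id) pairs in benchmark")
  }
  miss_g <- setdiff(pairs$gpcr_id, sequences$gpcr_id)
  if (length(miss_g)) {
    abort(sprintf("missing sequence(s) for: %s",
                  paste(utils::head(miss_g, 5), collapse = ", ")))
  }
  miss_d <- setdiff(pairs$drug_id, fingerprints$drug_id)
  if (length(miss_d)) {
    abort(sprintf("missing fingerprint(s) for: %s",
                  paste(utils::head(miss_d, 5), collapse = ", ")))
  }
  structure(list(pairs = as_tibble(pairs),
                 sequences = as_tibble(sequences),
                 fingerprints = as_tibble(fingerprints)),
            class = "gdip_benchmark")
}

#' @export
print.gdip_benchmark <- function(x, ...) {
  n_pos <- sum(x$pairs$label == "interactive")
  cat(sprintf(paste0("<gdip_benchmark> %d pairs (%d interactive, ",
                     "%d non-interactive), %d GPCRs, %d drugs\n"),
              nrow(x$pairs), n_pos, nrow(x$pairs) - n_pos,
              nrow(x$sequences), nrow(x$fingerprints)))
  invisible(x)
}

#' Construct non-interactive pairs by re-coupling
#'
#' Implements the standard negative-set protocol: split the interactive
#' pairs into their distinct GPCRs and drugs, form every cross-product pair
#' that does not occur among the positives, and sample
#' `round(ratio * n_positives)` of them uniformly without replacement.
#'
#' @param positives Tibble of interactive pairs (`gpcr_id`, `drug_id`).
#' @param ratio Number of negatives per positive (the classical design uses
#'   2).
#' @param seed Integer seed; sampling is fully reproducible.
#' @return Tibble of pairs labelled `"non-interactive"`.
#' @export
build_negative_pairs <- function(positives, ratio, seed) {
  stopifnot(is.data.frame(positives), nrow(positives) > 0, ratio > 0)
  n_req <- round(ratio * nrow(positives))
  pool <- tidyr::expand_grid(gpcr_id = unique(positives$gpcr_id),
                             drug_id = unique(positives$drug_id))
  pool <- dplyr::anti_join(pool, positives, by = c("gpcr_id", "drug_id"))
  if (nrow(pool) < n_req) {
    abort(sprintf("candidate pool (%d) smaller than requested negatives (%d)",
                  nrow(pool), n_req))
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pool), n_req))
  dplyr::mutate(pool[idx, ], label = "non-interactive")
}
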