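# Seeded synthetic benchmark. Interaction is planted through two latent
# entity types: each GPCR and each drug is assigned type 1 or 2, interactive
# pairs are drawn (preferentially) from type-matched couples, and `signal`
# shifts each entity's observable features -- fingerprint digits and residue
# composition -- toward its type profile. At signal = 0 both classes have
# identical feature distributions; at signal = 1 type-matched and mismatched
# pairs are nearly disjoint in feature space, so both feature blocks of the
# fused pair vector carry the class signal.

clamp_digits <- function(x) pmin(15L, pmax(0L, as.integer(round(x))))

#' Generate a synthetic GPCR-drug benchmark
#'
#' Produces random receptor sequences (length 50-400, uniform over the 20
#' residues at `signal = 0`), random 256-digit fingerprints, and labelled
#' pairs with a tunable planted class signal. Negatives are built with the
#' same re-coupling protocol as for real data ([build_negative_pairs()]).
#' Given the same arguments and seed the result is identical, run to run.
#'
#' @param n_gpcrs,n_drugs,n_pos Numbers of receptors, drugs and interactive
#'   pairs.
#' @param ratio Negatives per positive.
#' @param signal Planted class separability in \[0, 1\]: 0 = no signal
#'   (class-conditional feature distributions identical), 1 = strongly
#'   separated latent types.
#' @param seed Integer seed.
#' @return A [benchmark()] object; `$pairs` holds positives first, then
#'   negatives.
#' @export
#' @examples
#' b <- generate_synthetic_benchmark(seed = 7)
#' b
generate_synthetic_benchmark <- function(n_gpcrs = 10, n_drugs = 10,
                                         n_pos = 50, ratio = 1,
                                         signal = 1, seed = 1) {
  stopifnot(n_gpcrs >= 1, n_drugs >= 1, n_pos >= 1, ratio > 0,
            signal >= 0, signal <= 1)
  if (n_pos > n_gpcrs * n_drugs) {
    abort(sprintf("n_pos (%d) exceeds the %d possible pairs",
                  n_pos, n_gpcrs * n_drugs))
  }
  gpcr_ids <- sprintf("G%03d", seq_len(n_gpcrs))
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  gpcr_type <- rep_len(1:2, n_gpcrs)
  drug_type <- rep_len(1:2, n_drugs)

  out <- withr::with_seed(seed, {
    # latent type profiles
    res_prof <- lapply(1:2, function(t) {
      p <- stats::rexp(20)
      p / sum(p)
    })
    fp_prof <- lapply(1:2, function(t) sample(0:15, 256, replace = TRUE))

    sequences <- tibble(
      gpcr_id = gpcr_ids,
      sequence = vapply(seq_len(n_gpcrs), function(i) {
        L <- sample(50:400, 1)
        q <- (1 - signal) / 20 + signal * res_prof[[gpcr_type[i]]]
        paste(sample(AA_ALPHABET, L, replace = TRUE, prob = q), collapse = "")
      }, character(1)))

    fingerprints <- tibble(
      drug_id = drug_ids,
      digits = lapply(seq_len(n_drugs), function(i) {
        u <- sample(0:15, 256, replace = TRUE)
        p <- fp_prof[[drug_type[i]]]
        clamp_digits((1 - signal) * u +
                       signal * (p + stats::rnorm(256, sd = 1)))
      }))

    # interactive pairs: type-matched couples first
    grid <- tidyr::expand_grid(gi = seq_len(n_gpcrs), di = seq_len(n_drugs))
    matched <- gpcr_type[grid$gi] == drug_type[grid$di]
    pick <- function(rows, k) rows[sample.int(length(rows), k)]
    n_m <- min(n_pos, sum(matched))
    pos_rows <- pick(which(matched), n_m)
    if (n_m < n_pos) {
      pos_rows <- c(pos_rows, pick(which(!matched), n_pos - n_m))
    }
    positives <- tibble(gpcr_id = gpcr_ids[grid$gi[pos_rows]],
                        drug_id = drug_ids[grid$di[pos_rows]],
                        label = "interactive")
    list(positives = positives, sequences = sequences,
         fingerprints = fingerprints)
  })

  negatives <- build_negative_pairs(out$positives, ratio = ratio,
                                    seed = seed + 1L)
  benchmark(pairs = dplyr::bind_rows(out$positives, negatives),
            sequences = out$sequences,
            fingerprints = out$fingerprints)
}
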