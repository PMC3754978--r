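test_that("confusion counts match a direct tally and interconvert exactly", {
  cc <- confusion_counts(c("interactive", "interactive", "non-interactive",
                           "non-interactive"),
                         c("interactive", "interactive", "non-interactive",
                           "non-interactive"))
  expect_equal(unlist(cc[, c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 0, fn = 0))
  cc2 <- confusion_counts(c("interactive", "non-interactive"),
                          c("non-interactive", "interactive"))
  expect_equal(unlist(cc2[, c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 1, fn = 1))

  withr::with_seed(71, {
    lv <- c("interactive", "non-interactive")
    truth <- sample(lv, 200, replace = TRUE)
    pred <- sample(lv, 200, replace = TRUE)
    cc3 <- confusion_counts(truth, pred)
    tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (i in seq_along(truth)) {  # counting oracle
      if (truth[i] == lv[1] && pred[i] == lv[1]) tally["tp"] <- tally["tp"] + 1
      if (truth[i] == lv[2] && pred[i] == lv[2]) tally["tn"] <- tally["tn"] + 1
      if (truth[i] == lv[2] && pred[i] == lv[1]) tally["fp"] <- tally["fp"] + 1
      if (truth[i] == lv[1] && pred[i] == lv[2]) tally["fn"] <- tally["fn"] + 1
    }
    expect_equal(unlist(cc3[, c("tp", "tn", "fp", "fn")]), tally)
    expect_equal(cc3$n_pos, cc3$tp + cc3$fn)
    expect_equal(cc3$n_neg, cc3$tn + cc3$fp)
    expect_equal(cc3$n_pos_mis, cc3$fn)
    expect_equal(cc3$n_neg_mis, cc3$fp)
  })
  expect_error(confusion_counts("interactive", character(0)), "mismatch")
})

test_that("metrics hit closed-form values and report undefined, not zero", {
  perfect <- classification_metrics(tibble::tibble(tp = 5, tn = 5, fp = 0,
                                                   fn = 0))
  expect_equal(unlist(perfect[, c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))
  inverted <- classification_metrics(tibble::tibble(tp = 0, tn = 0, fp = 5,
                                                    fn = 5))
  expect_equal(inverted$acc, 0)
  expect_equal(inverted$mcc, -1)
  m <- classification_metrics(tibble::tibble(tp = 50, tn = 40, fp = 10,
                                             fn = 0))
  expect_equal(m$sn, 1.0)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.9)
  expect_equal(m$mcc, 2000 / sqrt(6e6), tolerance = 1e-12)

  und <- classification_metrics(tibble::tibble(tp = 3, tn = 0, fp = 0, fn = 1))
  expect_true(is.na(und$sp))
  expect_match(und$undefined, "sp")
  expect_false(identical(und$sp, 0))
})

test_that("the subset-success and TP/TN formulations agree on random tables", {
  withr::with_seed(81, {
    for (i in 1:50) {
      cc <- tibble::tibble(tp = sample(0:40, 1), tn = sample(0:40, 1),
                           fp = sample(0:40, 1), fn = sample(0:40, 1))
      if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) next
      m <- classification_metrics(cc)  # internal cross-assertion runs here
      np <- cc$tp + cc$fn
      nn <- cc$tn + cc$fp
      lambda1 <- 1 - cc$fn / np
      lambda2 <- 1 - cc$fp / nn
      expect_equal(m$acc, (lambda1 * np + lambda2 * nn) / (np + nn),
                   tolerance = 1e-12)
      expect_equal(m$sn, lambda1, tolerance = 1e-12)
      expect_equal(m$sp, lambda2, tolerance = 1e-12)
    }
  })
})

test_that("jackknife on twinned data with K = 1 is perfect and deterministic", {
  b <- generate_synthetic_benchmark(n_gpcrs = 4, n_drugs = 4, n_pos = 8,
                                    ratio = 1, signal = 0.3, seed = 17)
  # twin every entity under a new id so each left-out pair has an exact
  # duplicate at distance zero in the training fold
  twin <- benchmark(
    pairs = dplyr::bind_rows(
      b$pairs,
      dplyr::mutate(b$pairs, gpcr_id = paste0(gpcr_id, "_tw"),
                    drug_id = paste0(drug_id, "_tw"))),
    sequences = dplyr::bind_rows(
      b$sequences, dplyr::mutate(b$sequences,
                                 gpcr_id = paste0(gpcr_id, "_tw"))),
    fingerprints = dplyr::bind_rows(
      b$fingerprints, dplyr::mutate(b$fingerprints,
                                    drug_id = paste0(drug_id, "_tw"))))
  jk <- jackknife(twin, k = 1, m = 2, w1 = 0.05, w2 = 0.05)
  expect_equal(glance(jk)$acc, 1)

  jk1 <- jackknife(b, k = 3, m = 2, w1 = 0.05, w2 = 0.05)
  jk2 <- jackknife(b, k = 3, m = 2, w1 = 0.05, w2 = 0.05)
  expect_identical(tidy(jk1), tidy(jk2))
})

test_that("masked-distance jackknife equals naive per-fold retraining", {
  b <- generate_synthetic_benchmark(n_gpcrs = 5, n_drugs = 5, n_pos = 12,
                                    ratio = 1, signal = 0.5, seed = 23)
  f <- pair_features(b, w1 = 0.05, w2 = 0.05)
  jk <- jackknife(b, k = 3, m = 2, w1 = 0.05, w2 = 0.05)
  for (i in seq_len(nrow(f))) {
    fold_model <- fknn(f[-i, ], k = 3, m = 2)
    mu <- fuzzy_membership(fold_model, f[i, ])$mu_interactive
    expect_equal(jk$predictions$mu_interactive[i], mu, tolerance = 1e-12)
  }
})

test_that("label-shuffled data scores an MCC near zero", {
  b <- generate_synthetic_benchmark(seed = 29)
  mccs <- vapply(1:20, function(s) {
    bs <- b
    bs$pairs$label <- withr::with_seed(1000 + s, sample(bs$pairs$label))
    glance(jackknife(bs, k = 3, m = 2, w1 = 0.05, w2 = 0.05))$mcc
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.1)  # permutation null, Monte-Carlo error
})

test_that("grid search reuses distances without changing single-run results", {
  b <- generate_synthetic_benchmark(n_gpcrs = 6, n_drugs = 6, n_pos = 18,
                                    ratio = 1, signal = 0.6, seed = 37)
  gs <- grid_search(b, k_grid = c(1, 3, 5), m_grid = 2, w1 = 0.05, w2 = 0.05)
  expect_equal(nrow(tidy(gs)), 3L)
  for (i in seq_len(3)) {
    row <- tidy(gs)[i, ]
    jk <- glance(jackknife(b, k = row$k, m = row$m, w1 = 0.05, w2 = 0.05))
    expect_equal(row$acc, jk$acc, tolerance = 1e-12)
    expect_equal(row$mcc, jk$mcc, tolerance = 1e-12)
  }
  # best attains the maximum, deterministic tie-break smallest k then m
  expect_equal(gs$best$acc, max(tidy(gs)$acc))
  top <- tidy(gs)[tidy(gs)$acc == gs$best$acc, ]
  expect_equal(gs$best$k, min(top$k))

  one <- grid_search(b, k_grid = 3, m_grid = 2, w1 = 0.05, w2 = 0.05)
  expect_equal(nrow(tidy(one)), 1L)
  expect_equal(glance(one)$k, 3L)
  expect_error(grid_search(b, k_grid = 3, m_grid = c(0.5, 2),
                           w1 = 0.05, w2 = 0.05), "m values")
})

test_that("result objects expose tidy, glance and autoplot views", {
  b <- generate_synthetic_benchmark(n_gpcrs = 4, n_drugs = 4, n_pos = 8,
                                    seed = 43)
  jk <- jackknife(b, k = 3, m = 2, w1 = 0.05, w2 = 0.05)
  expect_s3_class(tidy(jk), "tbl_df")
  expect_named(glance(jk),
               c("sn", "sp", "acc", "mcc", "undefined", "n", "k", "m"))
  gs <- grid_search(b, k_grid = 1:3, m_grid = c(1.5, 2), w1 = 0.05, w2 = 0.05)
  expect_s3_class(ggplot2::autoplot(gs), "ggplot")
  expect_s3_class(ggplot2::autoplot(jk), "ggplot")
  spec <- drug_spectrum(b$fingerprints)
  expect_s3_class(plot_drug_spectrum(spec), "ggplot")
  f <- pair_features(b, w1 = 0.05, w2 = 0.05)
  expect_named(glance(fknn(f, k = 3, m = 2)),
               c("n_train", "n_interactive", "n_noninteractive", "k", "m"))
})
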