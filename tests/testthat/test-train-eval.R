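test_that("five-fold split partitions the positives evenly and reproducibly", {
  A <- matrix(0, 5, 6)
  A[sample(30, 10)] <- 1
  folds <- five_fold_split(A, seed = 3)
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1))
  expect_identical(sizes, rep(2L, 5))
  all_test <- do.call(rbind, lapply(folds, `[[`, "test"))
  expect_identical(nrow(unique(all_test)), 10L) # disjoint
  expect_setequal(paste(all_test[, 1], all_test[, 2]),
                  paste(which(A == 1, arr.ind = TRUE)[, 1],
                        which(A == 1, arr.ind = TRUE)[, 2]))
  folds2 <- five_fold_split(A, seed = 3)
  expect_identical(folds, folds2)
  expect_false(identical(folds, five_fold_split(A, seed = 4)))
  expect_error(five_fold_split(matrix(c(1, rep(0, 8)), 3, 3), 1), "positive")
})

test_that("weighted cross-entropy matches closed forms and honours masks", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  s_half <- matrix(0.5, 2, 2)
  expect_equal(weighted_bce_loss(s_half, y, pos_weight = 1), log(2))

  # near-perfect scores drive the loss toward 0
  s_good <- ifelse(y == 1, 1 - 1e-9, 1e-9)
  expect_lt(weighted_bce_loss(s_good, y, pos_weight = 1), 1e-6)

  # positive weight scales only the positive terms
  s <- matrix(c(0.8, 0.3, 0.4, 0.6), 2, 2)
  manual <- -(3 * log(0.8) + log(1 - 0.3) + log(1 - 0.4) + 3 * log(0.6)) / 4
  expect_equal(weighted_bce_loss(s, y, pos_weight = 3), manual)

  # masked entries are excluded from the average
  m <- rbind(c(1, 1))
  manual2 <- -(log(1 - 0.3) + log(1 - 0.4) + 3 * log(0.6)) / 3
  expect_equal(weighted_bce_loss(s, y, pos_weight = 3, mask = m), manual2)

  all_pairs <- as.matrix(expand.grid(1:2, 1:2))
  expect_error(weighted_bce_loss(s, y, mask = all_pairs), "every entry is masked")
  expect_error(weighted_bce_loss(matrix(c(0, .5, .5, .5), 2, 2), y), "strictly inside")
})

test_that("rank-based AUC agrees with trapezoidal ROC integration and pROC", {
  expect_equal(ranking_auc(c(0.8, 0.3), c(0.7, 0.2)), 0.75) # 3 of 4 pairs ordered
  expect_equal(ranking_auc(rep(0.4, 5), rep(0.4, 7)), 0.5)  # ties count one half
  expect_equal(ranking_auc(c(0.9, 0.8), c(0.3, 0.2)), 1)

  set.seed(21)
  for (i in 1:10) {
    pos <- round(runif(15), 2) # rounding forces ties
    neg <- round(runif(40), 2)
    a <- ranking_auc(pos, neg)
    expect_equal(a, oracle_trapezoid_auc(pos, neg), tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- pROC::auc(pROC::roc(c(rep(1, 15), rep(0, 40)), c(pos, neg),
                                quiet = TRUE, direction = "<"))
      expect_equal(a, as.numeric(pr), tolerance = 1e-9)
    }
  }
})

test_that("average precision matches a hand cumulative-precision computation", {
  # ranking: pos(0.9), neg(0.8), pos(0.7) -> AP = (1/1 + 2/3)/2
  expect_equal(average_precision(c(0.9, 0.7), c(0.8, 0.1)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(0.9, 0.8), c(0.3, 0.2)), 1) # perfect
  # constant scores: precision equals prevalence
  expect_equal(average_precision(rep(0.5, 3), rep(0.5, 9)), 0.25)
})

test_that("evaluate_scores produces coherent threshold metrics", {
  set.seed(22)
  scores <- matrix(runif(30, 0, 0.8), 5, 6)
  A <- matrix(0, 5, 6)
  A[cbind(1:4, 1:4)] <- 1
  pos <- which(A == 1, arr.ind = TRUE)
  scores[pos] <- 0.9 + runif(4) / 100 # positives on top
  m <- evaluate_scores(scores, pos, Aknown = A)
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$recall, 1)
  vals <- unlist(m[c("aupr", "auc", "recall", "precision", "specificity", "accuracy", "f1")])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-9)

  # fixed threshold policy
  m2 <- evaluate_scores(scores, pos, Aknown = A, threshold = 0.95)
  expect_identical(m2$threshold, 0.95)

  # ranking metrics are invariant to strictly monotone transforms
  m3 <- evaluate_scores(plogis(10 * scores - 5), pos, Aknown = A)
  expect_equal(m3$auc, m$auc)
  expect_equal(m3$aupr, m$aupr)
  expect_error(evaluate_scores(scores, pos[0, ], Aknown = A), "at least one")
})

test_that("training is seeded, bounded, and improves the objective", {
  b <- quiet_bundle(seed = 30, n_drugs = 12, n_diseases = 15, density = 0.2)
  cfg0 <- model_config(embed_dim = 8, n_heads = 2, n_levels = 2,
                       iterations = 0, seed = 1)
  fit0 <- train_model(b, fold = NULL, config = cfg0)
  expect_identical(nrow(fit0$history), 0L) # untouched initialization
  ref <- init_params(27, sapply(b$modalities[cfg0$modalities],
                                function(m) ncol(m$values)), cfg0)
  expect_equal(fit0$params, ref)

  cfg <- model_config(embed_dim = 8, n_heads = 2, n_levels = 2,
                      iterations = 200, learning_rate = 0.01, seed = 1)
  fit <- train_model(b, fold = NULL, config = cfg)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))

  fit2 <- train_model(b, fold = NULL, config = cfg)
  expect_identical(fit$history, fit2$history) # same seed, same trajectory
  expect_equal(fit$params, fit2$params)
})

test_that("cross-validation reports held-out metrics with sane aggregation", {
  b <- quiet_bundle(seed = 31, n_drugs = 12, n_diseases = 15, density = 0.25)
  cfg <- model_config(embed_dim = 6, n_heads = 2, n_levels = 1,
                      iterations = 30, seed = 2)
  rep <- run_cv(b, cfg, folds = 1:5)
  expect_length(rep$folds, 5)
  expect_identical(nrow(rep$per_fold), 5L)
  expect_equal(rep$summary$mean[rep$summary$metric == "auc"],
               mean(rep$per_fold$auc)) # aggregate = arithmetic mean
  expect_true(all(rep$per_fold >= 0 & rep$per_fold <= 1))
})

test_that("fraction experiment spans the requested grid", {
  b <- quiet_bundle(seed = 32, n_drugs = 12, n_diseases = 15, density = 0.25)
  cfg <- model_config(embed_dim = 6, n_heads = 2, n_levels = 1,
                      iterations = 20, seed = 3)
  res <- fraction_experiment(b, cfg, fractions = c(0.6, 1.0))
  expect_identical(nrow(res$table), 2L)
  expect_identical(res$table$fraction, c(0.6, 1.0))
  expect_error(fraction_experiment(b, cfg, fractions = c(0, 0.5)), "fractions")
})

test_that("novel-association ranking matches a full sort and handles edge cases", {
  set.seed(33)
  for (i in 1:5) {
    scores <- matrix(runif(25), 5, 5)
    A <- matrix(rbinom(25, 1, 0.4), 5, 5)
    if (all(A == 1)) A[1, 1] <- 0
    zero <- which(A == 0, arr.ind = TRUE)
    r <- rank_novel(scores, A, top_n = nrow(zero))
    ref_ord <- order(-scores[zero], zero[, 1], zero[, 2])
    expect_equal(r$score, scores[zero][ref_ord])
    expect_true(all(diff(r$score) <= 1e-12))
    expect_true(all(A[cbind(as.integer(r$drug), as.integer(r$disease))] == 0))
  }
  expect_warning(r2 <- rank_novel(matrix(0.5, 2, 2), matrix(1, 2, 2), 1), "known association")
  expect_identical(nrow(r2), 0L)
  expect_warning(rank_novel(matrix(runif(4), 2, 2),
                            matrix(c(1, 0, 1, 1), 2, 2), top_n = 5), "truncating")
})

test_that("paired t-test utility compares fold-level metrics", {
  mk <- function(vals) {
    fm <- lapply(vals, function(v) {
      structure(list(aupr = v, auc = v, recall = v, precision = v,
                     specificity = v, accuracy = v, f1 = v,
                     threshold = 0.5, n_pos = 1, n_neg = 1),
                class = "multidda_metrics")
    })
    multidda:::aggregate_metrics(fm)
  }
  a <- mk(c(0.8, 0.82, 0.79, 0.81, 0.8))
  b <- mk(c(0.7, 0.71, 0.69, 0.72, 0.7))
  tt <- fold_t_test(a, b, "auc")
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 0.01)
  expect_error(fold_t_test(a, b, "nope"), "unknown metric")
})
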