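# Decoding engine: grouped folds, ECOC training/prediction, tuning,
# cross-validation and model transfer.

test_that("grouped folds partition participants into near-equal folds, deterministically", {
  ids <- sprintf("p%03d", 1:711)
  f <- grouped_folds(ids, k = 10, seed = 5)
  sizes <- as.integer(table(f$assignment))
  expect_setequal(sizes, c(71L, 72L))        # 711 = 10 * 71 + 1
  expect_equal(sort(names(f$assignment)), sort(ids))  # union = input set
  expect_true(all(table(names(f$assignment)) == 1L))  # each id exactly once
  expect_equal(f, grouped_folds(ids, k = 10, seed = 5))
  expect_false(identical(f$assignment, grouped_folds(ids, k = 10, seed = 6)$assignment))
  expect_error(grouped_folds(ids[1:5], k = 10), "fewer distinct participants")
  expect_error(grouped_folds(ids, k = 1), ">= 2")
})

test_that("the decoder separates well-separated classes and scores follow the contract", {
  tab <- separable_toy(n_per_class = 12)
  model <- train_decoder(tab, hyperparams(C = 10, gamma = 0.5))
  pred <- predict(model, tab$x)
  expect_equal(as.character(pred$labels), as.character(tab$labels))
  expect_equal(colnames(pred$scores), model$classes)
  # the returned label always attains the row-maximum score
  expect_equal(as.character(pred$labels),
               model$classes[max.col(pred$scores, ties.method = "first")])
  # all-zero input still yields finite scores
  expect_true(all(is.finite(predict(model, matrix(0, 2, 2))$scores)))
  expect_error(predict(model, matrix(0, 2, 5)), "dimensionality mismatch")
  expect_error(train_decoder(subset_toy <- subset_features(tab, tab$labels == "A"),
                             hyperparams()), ">= 2 classes")
})

test_that("uniform prior keeps a 90/10 imbalanced separable toy perfectly recalled", {
  set.seed(8)
  x <- rbind(matrix(rnorm(90 * 2, sd = 0.1), ncol = 2),
             matrix(rnorm(10 * 2, mean = 4, sd = 0.1), ncol = 2))
  tab <- feature_table(x, rep(c("maj", "min"), c(90, 10)),
                       paste0("g", 1:100), task = "country")
  model <- train_decoder(tab, hyperparams(C = 10, gamma = 0.5),
                         uniform_prior = TRUE)
  cm <- confusion(tab$labels, predict(model, tab$x)$labels)
  expect_equal(unname(recall(cm)), c(1, 1))
})

test_that("grid search returns the inner-CV optimum with small-C, small-gamma tie-breaks", {
  single <- hyperparams(C = 3, gamma = 0.3)
  expect_equal(tune_hyperparams(separable_toy(), single, seed = 1)$C, 3)

  # exhaustive evaluation is its own oracle: the winner's accuracy is maximal
  tab <- toy_table(rbind(A = c(0, 0), B = c(1.5, 1.5), C = c(-1.5, 1.5)),
                   n_per_class = 15, sd = 0.6, seed = 3)
  grid <- hyper_grid(C = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1))
  best <- tune_hyperparams(tab, grid, k = 4, seed = 2)
  res <- attr(best, "results")
  expect_equal(max(res$accuracy),
               res$accuracy[res$C == best$C & res$gamma == best$gamma])

  # identical scores on a trivially separable problem: smallest C, then gamma, wins
  tab2 <- separable_toy(n_per_class = 16)
  grid2 <- hyper_grid(C = c(100, 1), gamma = c(0.5, 0.25))
  best2 <- tune_hyperparams(tab2, grid2, k = 4, seed = 2)
  res2 <- attr(best2, "results")
  if (all(res2$accuracy == res2$accuracy[1])) {
    expect_equal(best2$C, 1)
    expect_equal(best2$gamma, 0.25)
  } else {
    succeed("grid not tied; tie-break not exercised")
  }
})

test_that("cross-validation yields one out-of-fold prediction per row and never leaks participants", {
  d <- sim_data(n_per_country = 10, seed = 6, n_countries = 2)
  tab <- colour_feature_table(d)
  cv <- cross_validate(tab, k = 5, grid = fast_params(), seed = 3)
  expect_equal(nrow(cv$predictions), nrow(tab$x))
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  # every participant's rows sit in exactly one fold
  by_p <- tapply(cv$predictions$fold, cv$predictions$participant_id,
                 function(f) length(unique(f)))
  expect_true(all(by_p == 1L))
  # determinism: identical (data, grid, seed) -> identical result
  expect_equal(cv, cross_validate(tab, k = 5, grid = fast_params(), seed = 3))
  # AUC >= 0.5 whenever accuracy is above chance
  expect_gt(cv$accuracy, cv$chance)
  expect_gt(cv$auc_weighted, 0.5)
})

test_that("nested tuning re-tunes inside each fold's training portion", {
  tab <- toy_table(rbind(A = c(0, 0), B = c(2, 2)), n_per_class = 12,
                   sd = 0.4, seed = 5)
  grid <- hyper_grid(C = c(1, 10), gamma = c(0.1, 1))
  cv <- cross_validate(tab, k = 3, grid = grid, seed = 4, tune = "nested")
  expect_length(cv$fold_params, 3L)
  expect_true(all(vapply(cv$fold_params, inherits, TRUE, "gew_hyperparams")))
  cvg <- cross_validate(tab, k = 3, grid = grid, seed = 4, tune = "global")
  expect_length(unique(vapply(cvg$fold_params, function(p) p$C, numeric(1))), 1L)
})

test_that("a trained model transfers to independent samples and degrades to chance on permuted labels", {
  d <- sim_data(n_per_country = 30, s = 2, delta = 0, seed = 7, n_countries = 2)
  tab <- colour_feature_table(d)
  model <- train_decoder(tab, fast_params())

  # resubstitution on its own training table reproduces training accuracy
  self <- apply_model(model, tab)
  pred <- predict(model, tab$x)
  expect_equal(self$accuracy, mean(as.character(pred$labels) == as.character(tab$labels)))

  # held-out synthetic data with permuted labels: accuracy near chance
  d2 <- sim_data(n_per_country = 50, s = 2, delta = 0, seed = 8, n_countries = 2)
  tab2 <- colour_feature_table(d2)  # 1200 rows
  set.seed(11)
  tab2$labels <- tab2$labels[sample(length(tab2$labels))]
  perm <- apply_model(model, tab2)
  expect_lt(abs(perm$accuracy - 1 / 12), 0.05)

  expect_error(apply_model(model, subset_features(tab, integer(0))), "empty")
  bad <- tab2
  levels(bad$labels) <- c(levels(bad$labels)[-1], "magenta")
  expect_error(apply_model(model, bad), "unseen")
})
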