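# Confusion matrices, accuracy, chance levels, multiclass AUC, permutation test.

test_that("confusion counts, proportions and recall match a hand count", {
  cm <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                  classes = c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 2)))
  expect_equal(unname(recall(cm)), c(0.5, 1.0))
  expect_equal(accuracy(cm), 0.75)
  expect_equal(unname(rowSums(cm$proportions)), c(1, 1))

  # all-correct predictions give the identity proportion matrix
  cmi <- confusion(rep(c("A", "B", "C"), 4), rep(c("A", "B", "C"), 4))
  expect_equal(unname(cmi$proportions), diag(3))
  expect_equal(accuracy(cmi), 1)

  # zero-total rows are flagged, not divided
  cm0 <- confusion(c("A", "A"), c("A", "B"), classes = c("A", "B"))
  expect_equal(cm0$zero_rows, "B")
  expect_true(all(is.na(cm0$proportions["B", ])))

  expect_error(confusion(c("A", "B"), "A"), "equal length")
  expect_error(confusion("A", "Z", classes = c("A", "B")), "outside")
  expect_equal(accuracy(confusion(c("A","B"), c("B","A"))), 0)
})

test_that("accuracy from the confusion matrix equals mean(true == predicted) exactly", {
  set.seed(13)
  for (rep in 1:5) {
    true <- sample(letters[1:4], 200, replace = TRUE)
    pred <- sample(letters[1:4], 200, replace = TRUE)
    expect_identical(accuracy(confusion(true, pred, classes = letters[1:4])),
                     mean(true == pred))
  }
  # uniform random predictions over 12 classes hit ~ 1/12
  true <- sample(GEW_COLOUR_TERMS, 12000, replace = TRUE)
  pred <- sample(GEW_COLOUR_TERMS, 12000, replace = TRUE)
  expect_lt(abs(accuracy(confusion(true, pred, classes = GEW_COLOUR_TERMS)) - 1 / 12),
            0.01)
})

test_that("chance level is the reciprocal class count", {
  expect_equal(chance_level(12), 1 / 12)
  expect_equal(round(100 * chance_level(12), 2), 8.33)
  expect_equal(chance_level(4), 0.25)
  expect_equal(chance_level(2), 0.5)
  expect_error(chance_level(1), ">= 2")
})

# independent oracle: explicit comparison of every positive-negative pair
auc_pairwise_oracle <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  wins <- 0
  for (a in s1) for (b in s0) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(s1) * length(s0))
}

test_that("multiclass AUC hits the analytic endpoints and the worked 2-class value", {
  # perfect ranking -> 1.0
  scores <- cbind(A = c(3, 2, -1, -2), B = c(-3, -2, 1, 2))
  true <- c("A", "A", "B", "B")
  expect_equal(multiclass_auc(scores, true), 1.0)
  # constant scores: all ties -> 0.5
  expect_equal(multiclass_auc(matrix(1, 4, 2, dimnames = list(NULL, c("A", "B"))),
                              true), 0.5)
  # positives scored (0.9, 0.4), negatives (0.8, 0.1): 3 wins of 4 pairs
  s <- c(0.9, 0.4, 0.8, 0.1)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_pairwise_oracle(s, pos), 0.75)
  sc <- cbind(pos = s, neg = -s)
  expect_equal(multiclass_auc(sc, ifelse(pos, "pos", "neg"), weighting = "macro"),
               0.75)
})

test_that("multiclass AUC agrees with the exhaustive pairwise oracle and pROC", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    K <- sample(2:5, 1)
    classes <- LETTERS[1:K]
    true <- factor(sample(classes, n, replace = TRUE), levels = classes)
    while (length(unique(true)) < K) true <- factor(sample(classes, n, replace = TRUE),
                                                    levels = classes)
    scores <- matrix(round(rnorm(n * K), 1), n, K,  # rounding forces ties
                     dimnames = list(NULL, classes))
    per_class <- vapply(classes, function(cl)
      auc_pairwise_oracle(scores[, cl], true == cl), numeric(1))
    prev <- as.numeric(table(true))
    expect_equal(multiclass_auc(scores, true, "prevalence"),
                 sum(per_class * prev) / sum(prev), tolerance = 1e-12)
    expect_equal(multiclass_auc(scores, true, "macro"),
                 mean(per_class), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(18)
  s <- rnorm(40); y <- rep(c(1, 0), 20)
  expect_equal(multiclass_auc(cbind(pos = s, neg = -s),
                              ifelse(y == 1, "pos", "neg"), "macro"),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(19)
  scores <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  true <- sample(c("A", "B"), 30, replace = TRUE)
  base <- multiclass_auc(scores, true)
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) atan(x))) {
    expect_equal(multiclass_auc(f(scores), true), base, tolerance = 1e-12)
  }
})

test_that("degenerate classes are skipped from the AUC average with a warning", {
  scores <- cbind(A = c(1, 0, -1), B = c(-1, 0, 1), C = c(0, 0, 0))
  expect_warning(a <- multiclass_auc(scores, c("A", "A", "B")), "skipped")
  expect_true(a >= 0 && a <= 1)
})

test_that("the add-one permutation p-value follows its definition", {
  pp <- gewmvpa:::perm_pvalue
  expect_equal(pp(0.9, rep(0.5, 10)), 1 / 11)     # observed above all nulls
  expect_equal(pp(0.4, rep(0.5, 10)), 1)          # observed below every null
  expect_equal(pp(0.5, rep(0.5, 10)), 1)          # ties count against
  expect_equal(pp(0.7, c(0.6, 0.8, 0.9)), 3 / 4)
})

test_that("label permutation preserves the label multiset and the grouping design", {
  d <- sim_data(n_per_country = 6, seed = 23, n_countries = 2)
  ct <- country_feature_table(d)
  perm <- gewmvpa:::permute_labels(ct, seed = 31)
  expect_equal(sort(as.character(perm)), sort(as.character(ct$labels)))
  tab <- colour_feature_table(d)
  permc <- gewmvpa:::permute_labels(tab, seed = 31)
  expect_equal(sort(as.character(permc)), sort(as.character(tab$labels)))
})

test_that("a strongly decodable dataset earns the smallest attainable p-value", {
  d <- sim_data(n_per_country = 15, s = 2.5, delta = 0, seed = 25, n_countries = 2)
  tab <- colour_feature_table(d)
  pt <- permutation_test(tab, k = 5, grid = fast_params(), n_perm = 5, seed = 2)
  expect_length(pt$null_auc, 5L)
  expect_equal(pt$p_auc, 1 / 6)
  expect_gt(pt$observed$auc_weighted, max(pt$null_auc))
  expect_true(is.finite(pt$z_auc) || is.na(pt$z_auc))
})

test_that("type-I error of the permutation test is controlled on null data", {
  # country task with no divergence: labels carry no signal; at a nominal 0.2
  # threshold the rejection rate over 20 replicates stays modest (n_perm = 10
  # makes the p-value grid coarse: attainable values are k/11)
  rejections <- 0L
  for (r in 1:20) {
    d <- sim_data(n_per_country = 12, s = 1, delta = 0, seed = 100 + r,
                  n_countries = 2)
    ct <- country_feature_table(d)
    pt <- permutation_test(ct, k = 4, grid = fast_params("country"), n_perm = 10,
                           seed = 200 + r)
    rejections <- rejections + (pt$p_auc <= 0.2)
  }
  expect_lte(rejections / 20, 0.35)
})
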