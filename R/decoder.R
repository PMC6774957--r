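# Multiclass decoding engine.
#
# ECOC reduction with one-vs-one coding (all class pairs) over RBF-kernel
# support vector machines (e1071/libsvm binary learners), loss-weighted
# decoding with the hinge loss, participant-grouped k-fold cross-validation,
# hyperparameter grid search, and application of a fitted model to an
# independent sample. Class scores are the negated average binary hinge loss
# per class; AUC over those scores is rank-based, so any monotone transform
# is equivalent.

#' SVM hyperparameters
#'
#' @param C complexity (cost) constant, > 0.
#' @param gamma RBF kernel width parameter of `exp(-gamma * ||u - v||^2)`, > 0.
#' @return An object of class `gew_hyperparams`.
#' @export
hyperparams <- function(C = 1, gamma = 0.05) {
  check_number(C, "C"); check_number(gamma, "gamma")
  if (C <= 0 || gamma <= 0) stop("`C` and `gamma` must be > 0", call. = FALSE)
  structure(list(C = C, gamma = gamma), class = "gew_hyperparams")
}

#' @export
print.gew_hyperparams <- function(x, ...) {
  cat(sprintf("SVM hyperparameters: C = %g, gamma = %g\n", x$C, x$gamma))
  invisible(x)
}

#' Cartesian hyperparameter grid
#'
#' Default grid: C in {0.1, 1, 10, 100} x gamma in {0.001, 0.01, 0.1, 1}.
#'
#' @param C numeric vector of cost values.
#' @param gamma numeric vector of kernel width values.
#' @return A list of [hyperparams()] in row-major (C-major) order.
#' @export
hyper_grid <- function(C = c(0.1, 1, 10, 100), gamma = c(0.001, 0.01, 0.1, 1)) {
  g <- expand.grid(gamma = gamma, C = C)  # C-major for tie-break order
  lapply(seq_len(nrow(g)), function(i) hyperparams(C = g$C[i], gamma = g$gamma[i]))
}

as_grid <- function(grid) {
  if (inherits(grid, "gew_hyperparams")) return(list(grid))
  stopifnot(is.list(grid), length(grid) >= 1L,
            all(vapply(grid, inherits, TRUE, "gew_hyperparams")))
  grid
}

#' Participant-grouped fold assignment
#'
#' Randomly partitions distinct participants (never rows) into `k` folds of
#' sizes differing by at most one. Grouping at the participant level is the
#' validity condition of the whole analysis: a participant's rows never appear
#' on both sides of a fold split.
#'
#' @param participant_ids character vector (repeats allowed; folds are over
#'   the distinct ids).
#' @param k number of folds (default 10).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return An object of class `gew_folds`: list with `k`, `assignment`
#'   (named integer vector participant -> fold) and `seed`.
#' @export
grouped_folds <- function(participant_ids, k = 10L, seed = 1L) {
  ids <- unique(as.character(participant_ids))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (length(ids) < k) {
    stop(sprintf("fewer distinct participants (%d) than folds (%d)",
                 length(ids), k), call. = FALSE)
  }
  assignment <- with_seed(derive_seed(seed, "folds", k), {
    shuffled <- sample(ids)
    stats::setNames(rep_len(seq_len(k), length(ids)),
                    shuffled)[ids]
  })
  names(assignment) <- ids
  structure(list(k = k, assignment = assignment, seed = as.integer(seed)),
            class = "gew_folds")
}

#' @export
print.gew_folds <- function(x, ...) {
  cat(sprintf("Grouped folds: %d participants in %d folds (sizes %s)\n",
              length(x$assignment), x$k,
              paste(as.integer(table(x$assignment)), collapse = ", ")))
  invisible(x)
}

# ---- binary learner -------------------------------------------------------

# Fit one binary RBF-SVM on the rows belonging to a class pair. libsvm's
# decision-value orientation depends on label order of appearance, so the
# orientation is calibrated from the learner's own training predictions and
# stored as a flip flag (positive decision value <=> first class of the pair).
fit_binary <- function(x, y, lev_pos, lev_neg, params, uniform_prior) {
  y <- factor(as.character(y), levels = c(lev_pos, lev_neg))
  cw <- NULL
  if (uniform_prior) {
    n <- table(y)
    cw <- stats::setNames(sum(n) / (2 * pmax(as.numeric(n), 1)), names(n))
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = params$C, gamma = params$gamma,
                    class.weights = cw, scale = FALSE)
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  lab <- as.character(pr)
  s_pos <- dv[lab == lev_pos]; s_neg <- dv[lab == lev_neg]
  flip <- if (length(s_pos) && length(s_neg)) {
    mean(s_pos) < mean(s_neg)
  } else if (length(s_pos)) {
    mean(s_pos) < 0
  } else {
    mean(s_neg) > 0
  }
  list(fit = fit, flip = flip)
}

binary_decision <- function(learner, newx) {
  pr <- stats::predict(learner$fit, newx, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  if (learner$flip) -dv else dv
}

# hinge loss as used in loss-weighted ECOC decoding of SVM margins
hinge_loss <- function(z) pmax(1 - z, 0) / 2

# ---- multiclass model -----------------------------------------------------

#' Train an ECOC multiclass SVM decoder
#'
#' Reduces the multiclass problem to all class pairs (one-vs-one coding
#' matrix) of binary RBF-kernel SVMs and decodes by loss-weighted ECOC with
#' the hinge loss. With `uniform_prior = TRUE` (default) each binary learner
#' weights its two classes inversely to their training frequencies, so class
#' imbalance does not tilt the decision (a uniform prior over classes).
#'
#' @param table a [feature_table()] with at least 2 classes present.
#' @param params a [hyperparams()].
#' @param uniform_prior logical; inverse-frequency class weighting.
#' @return An object of class `gew_decoder`: ordered class vocabulary, coding
#'   matrix, fitted binary learners, hyperparameters.
#' @export
train_decoder <- function(table, params = hyperparams(), uniform_prior = TRUE) {
  stopifnot(inherits(table, "gew_features"), inherits(params, "gew_hyperparams"))
  present <- levels(table$labels)[tabulate(table$labels, nlevels(table$labels)) > 0L]
  if (length(present) < 2L) {
    stop("training requires >= 2 classes present in `table`", call. = FALSE)
  }
  classes <- present  # vocabulary order preserved by levels()
  pairs <- utils::combn(length(classes), 2L)
  coding <- matrix(0L, length(classes), ncol(pairs),
                   dimnames = list(classes, NULL))
  learners <- vector("list", ncol(pairs))
  lab <- as.character(table$labels)
  for (l in seq_len(ncol(pairs))) {
    i <- pairs[1L, l]; j <- pairs[2L, l]
    coding[i, l] <- 1L; coding[j, l] <- -1L
    idx <- lab %in% classes[c(i, j)]
    learners[[l]] <- fit_binary(table$x[idx, , drop = FALSE], lab[idx],
                                classes[i], classes[j], params, uniform_prior)
  }
  structure(list(classes = classes, coding = coding, learners = learners,
                 params = params, uniform_prior = uniform_prior,
                 n_features = ncol(table$x),
                 feature_names = table$feature_names,
                 task = table$task),
            class = "gew_decoder")
}

#' @export
print.gew_decoder <- function(x, ...) {
  cat(sprintf("ECOC SVM decoder: %d classes, %d binary learners, C = %g, gamma = %g\n",
              length(x$classes), length(x$learners), x$params$C, x$params$gamma))
  invisible(x)
}

#' Predict class labels and per-class scores
#'
#' Scores are the negated average hinge loss of the loss-weighted ECOC
#' decoding, one column per class in vocabulary order; the predicted label is
#' always the row-wise argmax of the scores, with ties broken by vocabulary
#' order.
#'
#' @param object a [train_decoder()] model.
#' @param newdata numeric matrix (or `gew_features`) with the training
#'   dimensionality.
#' @param ... unused.
#' @return list with `labels` (factor over the model's classes) and `scores`
#'   (numeric matrix, one column per class).
#' @export
predict.gew_decoder <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "gew_features")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature dimensionality mismatch: model expects %d, got %d",
                 object$n_features, ncol(x)), call. = FALSE)
  }
  if (nrow(x) == 0L) stop("empty prediction input", call. = FALSE)
  dv <- vapply(object$learners, binary_decision, numeric(nrow(x)), newx = x)
  dv <- matrix(dv, nrow = nrow(x))  # n x L
  K <- length(object$classes)
  loss <- matrix(0, nrow(x), K, dimnames = list(NULL, object$classes))
  for (k in seq_len(K)) {
    active <- object$coding[k, ] != 0L
    z <- sweep(dv[, active, drop = FALSE], 2L, object$coding[k, active], `*`)
    loss[, k] <- rowMeans(hinge_loss(z))
  }
  scores <- -loss
  labels <- factor(object$classes[max.col(scores, ties.method = "first")],
                   levels = object$classes)
  list(labels = labels, scores = scores)
}

# ---- tuning ---------------------------------------------------------------

#' Grid search for SVM hyperparameters under grouped cross-validation
#'
#' Evaluates every grid point with the same participant-grouped k-fold split
#' and returns the point with maximal CV accuracy. Ties are broken towards
#' smaller `C`, then smaller `gamma`, in grid order.
#'
#' @param table a [feature_table()].
#' @param grid list of [hyperparams()] (e.g. [hyper_grid()]).
#' @param k inner folds (default 5).
#' @param seed integer seed for the fold split.
#' @param uniform_prior passed to [train_decoder()].
#' @return The winning [hyperparams()], with the full evaluation attached as
#'   attribute `"results"` (data.frame C, gamma, accuracy).
#' @export
tune_hyperparams <- function(table, grid, k = 5L, seed = 1L, uniform_prior = TRUE) {
  grid <- as_grid(grid)
  if (length(grid) == 1L) {
    res <- data.frame(C = grid[[1]]$C, gamma = grid[[1]]$gamma, accuracy = NA_real_)
    return(structure(grid[[1]], results = res))
  }
  folds <- grouped_folds(table$groups, k = k, seed = derive_seed(seed, "inner"))
  fold_of_row <- folds$assignment[table$groups]
  acc <- vapply(grid, function(p) {
    correct <- 0L
    for (f in seq_len(folds$k)) {
      tr <- subset_features(table, fold_of_row != f)
      te <- subset_features(table, fold_of_row == f)
      model <- train_decoder(tr, p, uniform_prior = uniform_prior)
      pred <- predict(model, te$x)
      correct <- correct + sum(as.character(pred$labels) == as.character(te$labels))
    }
    correct / nrow(table$x)
  }, numeric(1))
  Cs <- vapply(grid, `[[`, numeric(1), "C")
  gs <- vapply(grid, `[[`, numeric(1), "gamma")
  best <- order(-acc, Cs, gs)[1L]
  structure(grid[[best]],
            results = data.frame(C = Cs, gamma = gs, accuracy = acc))
}

# ---- cross-validation -----------------------------------------------------

assert_no_leakage <- function(train_groups, test_groups) {
  leaked <- intersect(unique(train_groups), unique(test_groups))
  if (length(leaked)) {
    stop("participant-level leakage detected across a fold boundary: ",
         paste(utils::head(leaked, 3L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Participant-grouped k-fold cross-validation of the decoder
#'
#' Folds are drawn over participants, so a participant's rows are never split
#' between training and test (asserted on every fold). With a multi-point
#' grid, hyperparameters are tuned inside each fold's training portion by an
#' inner grouped CV (`tune = "nested"`, default) or once on the full table
#' (`tune = "global"`, faster but slightly optimistic). A singleton grid skips
#' tuning entirely.
#'
#' @param table a [feature_table()].
#' @param k outer folds (default 10).
#' @param grid list of [hyperparams()] or a single [hyperparams()].
#' @param seed integer seed controlling fold splits (outer and inner).
#' @param uniform_prior passed to [train_decoder()].
#' @param tune `"nested"` or `"global"`.
#' @param inner_k inner folds for nested tuning (default 5).
#' @return An object of class `gew_cv`: out-of-fold `predictions`
#'   (data.frame row, participant_id, fold, true, predicted), `scores`
#'   matrix, `accuracy`, `auc_weighted`, `auc_macro`, `fold_accuracies`,
#'   `folds`, and the per-fold hyperparameters.
#' @export
cross_validate <- function(table, k = 10L, grid = hyperparams(), seed = 1L,
                           uniform_prior = TRUE, tune = c("nested", "global"),
                           inner_k = 5L) {
  stopifnot(inherits(table, "gew_features"))
  tune <- match.arg(tune)
  grid <- as_grid(grid)
  folds <- grouped_folds(table$groups, k = k, seed = seed)
  fold_of_row <- folds$assignment[table$groups]

  global_params <- NULL
  if (length(grid) > 1L && tune == "global") {
    global_params <- tune_hyperparams(table, grid, k = inner_k,
                                      seed = derive_seed(seed, "global-tune"),
                                      uniform_prior = uniform_prior)
  }

  n <- nrow(table$x)
  classes <- levels(table$labels)
  pred_label <- character(n)
  scores <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  fold_acc <- numeric(folds$k)
  fold_params <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    tr_idx <- which(fold_of_row != f)
    te_idx <- which(fold_of_row == f)
    tr <- subset_features(table, tr_idx)
    te <- subset_features(table, te_idx)
    assert_no_leakage(tr$groups, te$groups)
    params <- if (length(grid) == 1L) {
      grid[[1L]]
    } else if (tune == "global") {
      global_params
    } else {
      tune_hyperparams(tr, grid, k = inner_k,
                       seed = derive_seed(seed, "tune", f),
                       uniform_prior = uniform_prior)
    }
    fold_params[[f]] <- params
    model <- train_decoder(tr, params, uniform_prior = uniform_prior)
    pred <- predict(model, te$x)
    pred_label[te_idx] <- as.character(pred$labels)
    scores[te_idx, model$classes] <- pred$scores
    fold_acc[f] <- mean(as.character(pred$labels) == as.character(te$labels))
  }
  stopifnot(!anyNA(pred_label), all(nzchar(pred_label)))

  true <- as.character(table$labels)
  predictions <- data.frame(
    row = seq_len(n), participant_id = table$groups,
    fold = as.integer(fold_of_row), true = true, predicted = pred_label,
    stringsAsFactors = FALSE
  )
  score_ok <- !is.na(scores)
  scores[!score_ok] <- -Inf  # classes absent from a fold's training set
  acc <- mean(pred_label == true)
  auc_w <- multiclass_auc(scores, factor(true, levels = classes),
                          weighting = "prevalence")
  auc_m <- multiclass_auc(scores, factor(true, levels = classes),
                          weighting = "macro")
  structure(list(predictions = predictions, scores = scores,
                 accuracy = acc, auc_weighted = auc_w, auc_macro = auc_m,
                 fold_accuracies = fold_acc, folds = folds,
                 fold_params = fold_params, classes = classes,
                 chance = chance_level(length(classes)), task = table$task),
            class = "gew_cv")
}

#' @export
print.gew_cv <- function(x, ...) {
  cat(sprintf("Grouped %d-fold CV [%s task]: accuracy %.3f (chance %.3f), AUC %.3f (weighted) / %.3f (macro)\n",
              x$folds$k, x$task, x$accuracy, x$chance, x$auc_weighted, x$auc_macro))
  invisible(x)
}

#' Apply a trained decoder to an independent sample
#'
#' Scores a feature table with no refitting and summarises performance, as
#' when a model trained on one set of countries is evaluated on another.
#'
#' @param model a [train_decoder()] model.
#' @param table a [feature_table()] with compatible dimensionality; its labels
#'   must all be classes the model was trained on.
#' @return list with `accuracy`, `auc_weighted`, `auc_macro`,
#'   `confusion` (a [confusion()] matrix over the model's classes),
#'   `predictions` and `scores`.
#' @export
apply_model <- function(model, table) {
  stopifnot(inherits(model, "gew_decoder"), inherits(table, "gew_features"))
  if (nrow(table$x) == 0L) stop("empty test table", call. = FALSE)
  unseen <- setdiff(unique(as.character(table$labels)), model$classes)
  if (length(unseen)) {
    stop("test table contains label(s) unseen in training: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  pred <- predict(model, table$x)
  true <- factor(as.character(table$labels), levels = model$classes)
  cm <- confusion(true, pred$labels, classes = model$classes)
  list(accuracy = accuracy(cm),
       auc_weighted = multiclass_auc(pred$scores, true, weighting = "prevalence"),
       auc_macro = multiclass_auc(pred$scores, true, weighting = "macro"),
       confusion = cm, predictions = pred$labels, scores = pred$scores)
}
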