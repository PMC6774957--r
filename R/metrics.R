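# Performance metrics: confusion matrices, accuracy, chance levels,
# multiclass one-vs-rest ROC AUC (midrank Mann-Whitney), and permutation-null
# significance testing of a cross-validated decoder.

#' Confusion matrix over an ordered class vocabulary
#'
#' Counts `N[i, j]` of instances with true class i predicted as j, and the
#' row-normalised proportions `P` (rows with zero total are flagged and left
#' `NA`, not divided). The diagonal of `P` is the per-class recall.
#'
#' @param true,predicted label vectors of equal length; every label must be in
#'   `classes`.
#' @param classes ordered class vocabulary (defaults to the union of factor
#'   levels of `true`).
#' @return An object of class `gew_confusion`: `counts`, `proportions`,
#'   `classes`, `row_totals`, `col_totals`, `zero_rows`.
#' @export
confusion <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted)) {
    stop("`true` and `predicted` must have equal length", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- if (is.factor(true)) levels(true) else sort(unique(as.character(true)))
  }
  true <- as.character(true); predicted <- as.character(predicted)
  unknown <- setdiff(unique(c(true, predicted)), classes)
  if (length(unknown)) {
    stop("label(s) outside the class vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tf <- factor(true, levels = classes)
  pf <- factor(predicted, levels = classes)
  counts <- unclass(table(true = tf, predicted = pf))
  row_totals <- rowSums(counts)
  props <- counts / ifelse(row_totals == 0, NA_real_, row_totals)
  structure(list(counts = counts, proportions = props, classes = classes,
                 row_totals = row_totals, col_totals = colSums(counts),
                 zero_rows = classes[row_totals == 0]),
            class = "gew_confusion")
}

#' @export
print.gew_confusion <- function(x, digits = 3, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d instances); rows = true, columns = predicted\n",
              length(x$classes), sum(x$counts)))
  print(round(x$proportions, digits))
  invisible(x)
}

#' Overall decoding accuracy of a confusion matrix
#'
#' The proportion of correctly classified instances, `trace(N) / sum(N)`.
#'
#' @param cm a [confusion()] matrix.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "gew_confusion"))
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm$counts)) / total
}

#' Per-class recall (true positive rate)
#'
#' @param cm a [confusion()] matrix.
#' @return named numeric vector, `NA` for classes with no true instances.
#' @export
recall <- function(cm) {
  stopifnot(inherits(cm, "gew_confusion"))
  stats::setNames(diag(cm$proportions), cm$classes)
}

#' Guessing rate of an n-class decoder
#'
#' `1 / n_classes`: 8.33% for the 12-colour task, 25% for the 4-country task.
#'
#' @param n_classes integer >= 2.
#' @return numeric chance level.
#' @export
chance_level <- function(n_classes) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L ||
      n_classes != round(n_classes) || n_classes < 2) {
    stop("`n_classes` must be a single integer >= 2", call. = FALSE)
  }
  1 / n_classes
}

#' Multiclass one-vs-rest ROC AUC
#'
#' For each class, the area under the ROC curve of its score column against
#' a one-vs-rest split of the labels, computed by the rank (Mann-Whitney)
#' formulation with midranks for ties (a tie contributes 1/2). Class AUCs are
#' averaged with class-prevalence weights (`"prevalence"`) or equal weights
#' (`"macro"`). A class with zero positives or zero negatives is skipped with
#' a warning and excluded from the average.
#'
#' @param scores numeric matrix, one column per class (column names or the
#'   levels of `true` fix the class order).
#' @param true label vector/factor of length `nrow(scores)`.
#' @param weighting `"prevalence"` or `"macro"`.
#' @return AUC in `[0, 1]`; 0.5 is chance, 1 perfect.
#' @export
multiclass_auc <- function(scores, true, weighting = c("prevalence", "macro")) {
  weighting <- match.arg(weighting)
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) {
    classes <- if (is.factor(true)) levels(true) else sort(unique(as.character(true)))
    stopifnot(length(classes) == ncol(scores))
    colnames(scores) <- classes
  }
  true <- as.character(true)
  if (length(true) != nrow(scores)) {
    stop("`true` must have one label per score row", call. = FALSE)
  }
  aucs <- weights <- numeric(0)
  for (cl in classes) {
    pos <- true == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warning("class '", cl, "' has no positives or no negatives; skipped",
              call. = FALSE)
      next
    }
    r <- rank(scores[, cl], ties.method = "average")
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
    weights <- c(weights, if (weighting == "prevalence") n1 else 1)
  }
  if (!length(aucs)) stop("no class with both positives and negatives", call. = FALSE)
  sum(aucs * weights) / sum(weights)
}

# add-one permutation p-value
perm_pvalue <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

# Permute labels while preserving the grouping structure the CV respects:
# row-level shuffle for the colour task (each participant's rows receive
# shuffled colour labels drawn from the whole table), participant-level
# shuffle for the country task (each participant keeps one label).
permute_labels <- function(table, seed) {
  with_seed(seed, {
    if (table$task == "country") {
      ids <- unique(table$groups)
      lab_of_id <- table$labels[match(ids, table$groups)]
      new_of_id <- stats::setNames(sample(as.character(lab_of_id)), ids)
      factor(new_of_id[table$groups], levels = levels(table$labels))
    } else {
      table$labels[sample(length(table$labels))]
    }
  })
}

#' Permutation-null significance test of decoding performance
#'
#' Re-runs the full grouped cross-validation on `n_perm` datasets whose class
#' labels were randomly permuted (features untouched), and compares the
#' observed AUC and accuracy against the null distributions with the add-one
#' estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`. With the default
#' `n_perm = 10` the smallest attainable p is 1/11, so a secondary z-statistic
#' comparing the observed AUC with the null mean and sd is also reported
#' (labelled secondary; it assumes an approximately normal null).
#'
#' @inheritParams cross_validate
#' @param n_perm number of label permutations (>= 1, default 10).
#' @return An object of class `gew_permutation`: `observed` (the real-data
#'   [cross_validate()] result), `null_auc`, `null_accuracy`, `p_auc`,
#'   `p_accuracy`, `z_auc` and `p_z_auc` (secondary), `n_perm`, `seed`.
#' @export
permutation_test <- function(table, k = 10L, grid = hyperparams(), n_perm = 10L,
                             seed = 1L, uniform_prior = TRUE,
                             tune = c("nested", "global"), inner_k = 5L) {
  tune <- match.arg(tune)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  observed <- cross_validate(table, k = k, grid = grid, seed = seed,
                             uniform_prior = uniform_prior, tune = tune,
                             inner_k = inner_k)
  null_auc <- null_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- table
    perm$labels <- permute_labels(table, derive_seed(seed, "perm", b))
    stopifnot(identical(sort(as.character(perm$labels)),
                        sort(as.character(table$labels))))
    cv <- cross_validate(perm, k = k, grid = grid,
                         seed = derive_seed(seed, "perm-cv", b),
                         uniform_prior = uniform_prior, tune = tune,
                         inner_k = inner_k)
    null_auc[b] <- cv$auc_weighted
    null_acc[b] <- cv$accuracy
  }
  z <- if (n_perm >= 2L && stats::sd(null_auc) > 0) {
    (observed$auc_weighted - mean(null_auc)) / stats::sd(null_auc)
  } else {
    NA_real_
  }
  structure(list(
    observed = observed,
    null_auc = null_auc, null_accuracy = null_acc,
    p_auc = perm_pvalue(observed$auc_weighted, null_auc),
    p_accuracy = perm_pvalue(observed$accuracy, null_acc),
    z_auc = z,
    p_z_auc = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
    n_perm = n_perm, seed = as.integer(seed)
  ), class = "gew_permutation")
}

#' @export
print.gew_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations):\n", x$n_perm))
  cat(sprintf("  observed AUC %.3f vs null mean %.3f -> p = %.4f (add-one)\n",
              x$observed$auc_weighted, mean(x$null_auc), x$p_auc))
  cat(sprintf("  observed accuracy %.3f vs null mean %.3f -> p = %.4f (add-one)\n",
              x$observed$accuracy, mean(x$null_accuracy), x$p_accuracy))
  if (!is.na(x$z_auc)) {
    cat(sprintf("  secondary z-statistic (AUC vs null mean): z = %.2f, p = %.3g\n",
                x$z_auc, x$p_z_auc))
  }
  invisible(x)
}
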