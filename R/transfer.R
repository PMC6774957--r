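# Cross-country generalisation of the colour decoder: within-country
# cross-validated accuracies on the diagonal, train-on-one-country /
# test-on-another accuracies off the diagonal, and the in-group advantage
# matrix derived from them.

#' Within- and between-country colour-decoding accuracy matrix
#'
#' For every ordered country pair (i, j): the accuracy of the colour decoder
#' trained on country i and tested on country j. Diagonal entries come from
#' participant-grouped k-fold cross-validation within the country (never
#' resubstitution); off-diagonal entries train on all of country i's data and
#' test on all of country j's (disjoint participants by construction).
#' Hyperparameters are tuned per training country by inner grouped CV when the
#' grid has more than one point, mirroring the within-country procedure.
#'
#' @param dataset a [gew_dataset()] with >= 2 countries, each with at least
#'   `k` participants.
#' @param k folds for the within-country CV (default 10).
#' @param grid list of [hyperparams()] or a single [hyperparams()].
#' @param seed integer seed.
#' @param uniform_prior passed to [train_decoder()].
#' @param inner_k inner folds for tuning (default 5).
#' @return An object of class `gew_transfer`: `accuracy` (K x K matrix, rows
#'   = training country, columns = test country), `countries`, `k`, `seed`.
#' @export
transfer_matrix <- function(dataset, k = 10L, grid = hyperparams(), seed = 1L,
                            uniform_prior = TRUE, inner_k = 5L) {
  stopifnot(inherits(dataset, "gew_dataset"))
  grid <- as_grid(grid)
  countries <- intersect(dataset$vocabulary$countries,
                         unique(dataset$participants$country))
  if (length(countries) < 2L) stop("transfer analysis needs >= 2 countries",
                                   call. = FALSE)
  n_by_country <- table(factor(dataset$participants$country, levels = countries))
  short <- countries[n_by_country < k]
  if (length(short)) {
    stop("countries with fewer participants than folds (k = ", k, "): ",
         paste(short, collapse = ", "), call. = FALSE)
  }

  tables <- lapply(countries, function(cn) {
    keep <- dataset$participants$participant_id[dataset$participants$country == cn]
    full <- colour_feature_table(dataset)
    subset_features(full, full$groups %in% keep)
  })
  names(tables) <- countries

  K <- length(countries)
  A <- matrix(NA_real_, K, K, dimnames = list(train = countries, test = countries))
  for (i in seq_len(K)) {
    cv <- cross_validate(tables[[i]], k = k, grid = grid,
                         seed = derive_seed(seed, "within", countries[i]),
                         uniform_prior = uniform_prior, inner_k = inner_k)
    A[i, i] <- cv$accuracy
    params <- if (length(grid) == 1L) {
      grid[[1L]]
    } else {
      tune_hyperparams(tables[[i]], grid, k = inner_k,
                       seed = derive_seed(seed, "tune-src", countries[i]),
                       uniform_prior = uniform_prior)
    }
    model <- train_decoder(tables[[i]], params, uniform_prior = uniform_prior)
    for (j in seq_len(K)[-i]) {
      assert_no_leakage(tables[[i]]$groups, tables[[j]]$groups)
      A[i, j] <- apply_model(model, tables[[j]])$accuracy
    }
  }
  structure(list(accuracy = A, countries = countries, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "gew_transfer")
}

#' @export
print.gew_transfer <- function(x, digits = 3, ...) {
  cat("Colour-decoding transfer accuracies (rows = training country, columns = test country;\n")
  cat("diagonal = within-country grouped CV):\n")
  print(round(x$accuracy, digits))
  invisible(x)
}

#' In-group advantage matrix
#'
#' `D[i, j] = A[j, j] - A[i, j]` for i != j: how much better country j's data
#' are decoded by its own (cross-validated) classifier than by one trained on
#' country i. Positive values indicate an in-group advantage. The diagonal is
#' undefined (`NA`).
#'
#' @param tm a [transfer_matrix()] result, or a plain square accuracy matrix
#'   (rows = training country, columns = test country) such as a published
#'   accuracy panel.
#' @return An object of class `gew_advantage`: `advantage` (K x K matrix,
#'   `NA` diagonal), `countries`, and `summary` (mean, sd, min, max over the
#'   K(K-1) off-diagonal entries; sd uses the n-1 denominator).
#' @export
advantage_matrix <- function(tm) {
  A <- if (inherits(tm, "gew_transfer")) tm$accuracy else as.matrix(tm)
  if (nrow(A) != ncol(A) || nrow(A) < 2L) {
    stop("need a square accuracy matrix with >= 2 countries", call. = FALSE)
  }
  countries <- if (inherits(tm, "gew_transfer")) tm$countries else
    (rownames(A) %||% paste0("country", seq_len(nrow(A))))
  D <- matrix(rep(diag(A), each = nrow(A)), nrow(A)) - A
  diag(D) <- NA_real_
  dimnames(D) <- list(train = countries, test = countries)
  vals <- D[!is.na(D)]
  structure(list(advantage = D, countries = countries,
                 summary = c(mean = mean(vals),
                             sd = stats::sd(vals),
                             min = min(vals), max = max(vals))),
            class = "gew_advantage")
}

#' @export
print.gew_advantage <- function(x, digits = 3, ...) {
  cat("In-group advantage (within-country accuracy minus between-country accuracy):\n")
  print(round(x$advantage, digits))
  s <- x$summary
  cat(sprintf("mean %.3f, sd %.3f, range [%.3f, %.3f] over %d pairs\n",
              s["mean"], s["sd"], s["min"], s["max"],
              sum(!is.na(x$advantage))))
  invisible(x)
}

#' Summary statistics of the in-group advantage
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator), minimum and
#' maximum over the K(K-1) off-diagonal advantage entries.
#'
#' @param d a [advantage_matrix()] result.
#' @return named numeric vector `mean`, `sd`, `min`, `max`.
#' @export
summarize_advantage <- function(d) {
  stopifnot(inherits(d, "gew_advantage"))
  if (sum(!is.na(d$advantage)) < 2L) {
    stop("need >= 2 off-diagonal entries to summarise", call. = FALSE)
  }
  d$summary
}
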