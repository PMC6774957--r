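# Feature tables: the flat numeric matrices the decoders consume, together
# with their labels and participant grouping ids. Column order is fixed by
# the vocabulary, never by input row order.

#' Construct a feature table
#'
#' A feature table is the unit of classifier consumption: a numeric matrix
#' with one class label and one participant grouping id per row. Usually
#' produced by [colour_feature_table()] or [country_feature_table()]; this
#' constructor is exported so externally prepared matrices (e.g. an
#' independent validation sample) can enter the same machinery.
#'
#' @param x numeric matrix, one row per instance.
#' @param labels class label per row; coerced to factor. Supply a factor with
#'   explicit levels to fix class order.
#' @param groups participant id per row (character).
#' @param task `"colour"` or `"country"` (controls permutation granularity and
#'   reporting defaults).
#' @param feature_names optional column names.
#' @return An object of class `gew_features`.
#' @export
feature_table <- function(x, labels, groups, task = c("colour", "country"),
                          feature_names = colnames(x)) {
  task <- match.arg(task)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.factor(labels)) labels <- factor(labels)
  groups <- as.character(groups)
  if (nrow(x) != length(labels) || nrow(x) != length(groups)) {
    stop("`x`, `labels` and `groups` must have one entry per row", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("feature values must be finite", call. = FALSE)
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(x))
    colnames(x) <- feature_names
  }
  structure(list(x = x, labels = labels, groups = groups, task = task,
                 feature_names = colnames(x)),
            class = "gew_features")
}

#' @export
print.gew_features <- function(x, ...) {
  cat(sprintf("GEW feature table [%s task]: %d rows x %d features, %d classes, %d participants\n",
              x$task, nrow(x$x), ncol(x$x), nlevels(x$labels),
              length(unique(x$groups))))
  invisible(x)
}

#' @export
dim.gew_features <- function(x) dim(x$x)

# Row subset preserving class levels (so fold models share one class order).
subset_features <- function(table, idx) {
  structure(list(x = table$x[idx, , drop = FALSE],
                 labels = table$labels[idx],
                 groups = table$groups[idx],
                 task = table$task,
                 feature_names = table$feature_names),
            class = "gew_features")
}

#' Colour-task feature table: decode the colour term from 20 emotion ratings
#'
#' One row per (participant, colour): the row's 20 features are the
#' participant's intensity ratings of the 20 emotions for that colour, in
#' emotion-vocabulary order; the label is the colour term and the grouping id
#' the participant. A dataset with n participants yields 12n rows.
#'
#' @param dataset a [gew_dataset()].
#' @return A `gew_features` object with `task = "colour"`.
#' @export
colour_feature_table <- function(dataset) {
  stopifnot(inherits(dataset, "gew_dataset"))
  v <- dataset$vocabulary
  r <- dataset$ratings
  pids <- dataset$participants$participant_id
  pi <- match(r$participant_id, pids)
  ci <- match(r$colour, v$colour_terms)
  ei <- match(r$emotion, v$emotion_terms)
  n_col <- length(v$colour_terms)
  n_emo <- length(v$emotion_terms)
  n_rows <- length(pids) * n_col
  x <- matrix(NA_real_, n_rows, n_emo, dimnames = list(NULL, v$emotion_terms))
  row_id <- (pi - 1L) * n_col + ci
  x[cbind(row_id, ei)] <- r$intensity
  labels <- factor(rep(v$colour_terms, times = length(pids)),
                   levels = v$colour_terms)
  groups <- rep(pids, each = n_col)
  feature_table(x, labels, groups, task = "colour")
}

#' Country-task feature table: decode the country from all 240 ratings
#'
#' One row per participant; the 240 features are the intensity ratings in
#' colour-major, emotion-minor vocabulary order (columns named
#' `<colour>_<emotion>`); the label is the participant's country.
#'
#' @param dataset a [gew_dataset()].
#' @return A `gew_features` object with `task = "country"`.
#' @export
country_feature_table <- function(dataset) {
  stopifnot(inherits(dataset, "gew_dataset"))
  v <- dataset$vocabulary
  r <- dataset$ratings
  pids <- dataset$participants$participant_id
  pi <- match(r$participant_id, pids)
  ci <- match(r$colour, v$colour_terms)
  ei <- match(r$emotion, v$emotion_terms)
  n_emo <- length(v$emotion_terms)
  feat_names <- as.vector(t(outer(v$colour_terms, v$emotion_terms, paste, sep = "_")))
  x <- matrix(NA_real_, length(pids), length(feat_names),
              dimnames = list(NULL, feat_names))
  x[cbind(pi, (ci - 1L) * n_emo + ei)] <- r$intensity
  countries_present <- intersect(v$countries, dataset$participants$country)
  labels <- factor(dataset$participants$country, levels = countries_present)
  feature_table(x, labels, pids, task = "country")
}

#' Rating-category proportions per country and pooled across countries
#'
#' For every (country, colour, emotion) cell, the proportion of that
#' country's participants choosing each intensity category 0-5; and the
#' pooled summary as the unweighted arithmetic mean of the per-country
#' proportion vectors (equal country weights, so countries with unequal
#' sample sizes contribute equally).
#'
#' @param dataset a [gew_dataset()].
#' @return An object of class `gew_proportions`: list with `per_country`
#'   (4-d array country x colour x emotion x category) and `pooled`
#'   (3-d array colour x emotion x category).
#' @export
rating_proportions <- function(dataset) {
  stopifnot(inherits(dataset, "gew_dataset"))
  v <- dataset$vocabulary
  r <- dataset$ratings
  countries <- intersect(v$countries, dataset$participants$country)
  cf <- factor(r$country, levels = countries)
  kf <- factor(r$colour, levels = v$colour_terms)
  ef <- factor(r$emotion, levels = v$emotion_terms)
  qf <- factor(r$intensity, levels = 0:5)
  counts <- table(country = cf, colour = kf, emotion = ef, category = qf)
  n_per_country <- table(factor(dataset$participants$country, levels = countries))
  per_country <- array(
    as.numeric(counts) / rep(as.numeric(n_per_country), times = length(counts) / length(countries)),
    dim = dim(counts), dimnames = dimnames(counts)
  )
  pooled <- apply(per_country, c(2, 3, 4), mean)
  structure(list(per_country = per_country, pooled = pooled,
                 countries = countries),
            class = "gew_proportions")
}

#' @export
print.gew_proportions <- function(x, ...) {
  cat(sprintf("GEW rating proportions: %d countries, pooled over %d x %d cells\n",
              length(x$countries), dim(x$pooled)[1], dim(x$pooled)[2]))
  invisible(x)
}
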