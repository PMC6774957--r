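# Rating dataset container, validation and I/O.
#
# A dataset is a complete grid: every participant contributes exactly one
# intensity rating (0-5, 0 = no association) for each of the 12 x 20 = 240
# (colour, emotion) cells. "No emotion" responses for a colour are represented
# as the all-zero 20-vector for that colour; free-text "different emotion"
# responses are not part of the data model.

#' Colour-emotion rating dataset
#'
#' Builds and validates a complete rating dataset: one intensity rating in
#' 0..5 per (participant, colour, emotion) cell, 240 cells per participant,
#' one country per participant. Colour/emotion tokens are matched
#' case-insensitively against the vocabulary and stored canonically; rows are
#' normalised to a deterministic order (participant id, colour vocabulary
#' order, emotion vocabulary order).
#'
#' @param ratings data.frame with columns `participant_id`, `country`,
#'   `colour`, `emotion`, `intensity` (integer 0-5).
#' @param participants optional data.frame with columns `participant_id`,
#'   `country` and optionally `age`, `gender`; derived from `ratings` when
#'   omitted. Demographics may be missing (`NA`); ratings may not.
#' @param vocabulary a [gew_vocabulary()].
#' @return An object of class `gew_dataset`: list with `ratings`,
#'   `participants`, `vocabulary`.
#' @examples
#' d <- simulate_gew(generator_config(n_per_country = 2, seed = 1))
#' nrow(d$ratings)  # 2 participants x 4 countries x 240 cells
#' @export
gew_dataset <- function(ratings, participants = NULL, vocabulary = gew_vocabulary()) {
  stopifnot(inherits(vocabulary, "gew_vocabulary"))
  req <- c("participant_id", "country", "colour", "emotion", "intensity")
  if (!is.data.frame(ratings) || !all(req %in% names(ratings))) {
    stop("`ratings` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(ratings) == 0L) stop("empty dataset: no ratings", call. = FALSE)

  ratings <- data.frame(
    participant_id = as.character(ratings$participant_id),
    country = match_terms(as.character(ratings$country), vocabulary$countries, "country"),
    colour = match_terms(as.character(ratings$colour), vocabulary$colour_terms, "colour"),
    emotion = match_terms(as.character(ratings$emotion), vocabulary$emotion_terms, "emotion"),
    intensity = ratings$intensity,
    stringsAsFactors = FALSE
  )

  ints <- ratings$intensity
  ok <- is.numeric(ints) & is.finite(ints) & ints == round(ints) & ints >= 0 & ints <= 5
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf(
      "intensity out of range 0-5 for participant '%s', cell (%s, %s): %s",
      ratings$participant_id[bad], ratings$colour[bad], ratings$emotion[bad],
      ratings$intensity[bad]), call. = FALSE)
  }
  ratings$intensity <- as.integer(ints)

  key <- paste(ratings$participant_id, ratings$colour, ratings$emotion, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate rating cell for participant '%s': (%s, %s)",
                 ratings$participant_id[d], ratings$colour[d], ratings$emotion[d]),
         call. = FALSE)
  }

  # one country per participant, complete 240-cell grid
  by_p <- split(seq_len(nrow(ratings)), ratings$participant_id)
  n_cells <- length(vocabulary$colour_terms) * length(vocabulary$emotion_terms)
  for (pid in names(by_p)) {
    idx <- by_p[[pid]]
    if (length(unique(ratings$country[idx])) != 1L) {
      stop(sprintf("participant '%s' appears under more than one country", pid),
           call. = FALSE)
    }
    if (length(idx) != n_cells) {
      stop(sprintf("participant '%s' has %d ratings; expected %d (complete 12 x 20 grid)",
                   pid, length(idx), n_cells), call. = FALSE)
    }
  }

  if (is.null(participants)) {
    first <- !duplicated(ratings$participant_id)
    participants <- data.frame(
      participant_id = ratings$participant_id[first],
      country = ratings$country[first],
      age = NA_real_, gender = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(is.data.frame(participants),
              all(c("participant_id", "country") %in% names(participants)))
    participants <- data.frame(
      participant_id = as.character(participants$participant_id),
      country = match_terms(as.character(participants$country),
                            vocabulary$countries, "country"),
      age = if ("age" %in% names(participants)) as.numeric(participants$age) else NA_real_,
      gender = if ("gender" %in% names(participants)) as.character(participants$gender) else NA_character_,
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(participants$participant_id)) {
      stop("duplicate participant_id in `participants`", call. = FALSE)
    }
    if (!setequal(participants$participant_id, unique(ratings$participant_id))) {
      stop("`participants` and `ratings` disagree on the participant set", call. = FALSE)
    }
    m <- match(ratings$participant_id, participants$participant_id)
    if (any(participants$country[m] != ratings$country)) {
      stop("`participants` and `ratings` disagree on some participant's country",
           call. = FALSE)
    }
  }

  # canonical row order: participant id, colour vocab order, emotion vocab order
  participants <- participants[order(participants$participant_id), , drop = FALSE]
  rownames(participants) <- NULL
  o <- order(ratings$participant_id,
             match(ratings$colour, vocabulary$colour_terms),
             match(ratings$emotion, vocabulary$emotion_terms))
  ratings <- ratings[o, , drop = FALSE]
  rownames(ratings) <- NULL

  structure(list(ratings = ratings, participants = participants,
                 vocabulary = vocabulary),
            class = "gew_dataset")
}

#' @export
print.gew_dataset <- function(x, ...) {
  cat(sprintf("GEW rating dataset: %d participants, %d ratings\n",
              nrow(x$participants), nrow(x$ratings)))
  print(table(x$participants$country))
  invisible(x)
}

#' Number of participants in a dataset
#' @param dataset a [gew_dataset()].
#' @return integer count.
#' @export
n_participants <- function(dataset) {
  stopifnot(inherits(dataset, "gew_dataset"))
  nrow(dataset$participants)
}

#' Read a long-format rating CSV
#'
#' Expects a header with columns `participant_id, country, age, gender,
#' colour, emotion, intensity` (`age`/`gender` optional). The file is
#' validated on load: unknown colour/emotion/country tokens, non-integer or
#' out-of-range intensities, duplicate cells and incomplete 240-cell
#' participants are rejected with an error naming the offender.
#'
#' @param path CSV file path (UTF-8).
#' @param vocabulary a [gew_vocabulary()].
#' @return A [gew_dataset()].
#' @export
read_gew_csv <- function(path, vocabulary = gew_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    colClasses = "character"),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  req <- c("participant_id", "country", "colour", "emotion", "intensity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("malformed file: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty dataset: no ratings in ", path, call. = FALSE)
  intensity <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(intensity)) {
    bad <- which(is.na(intensity))[1L]
    stop(sprintf("non-numeric intensity '%s' for participant '%s'",
                 df$intensity[bad], df$participant_id[bad]), call. = FALSE)
  }
  participants <- NULL
  if (all(c("age", "gender") %in% names(df))) {
    first <- !duplicated(df$participant_id)
    participants <- data.frame(
      participant_id = df$participant_id[first],
      country = df$country[first],
      age = suppressWarnings(as.numeric(df$age[first])),
      gender = ifelse(nzchar(df$gender[first]), df$gender[first], NA_character_),
      stringsAsFactors = FALSE
    )
  }
  ratings <- df[req]
  ratings$intensity <- intensity
  gew_dataset(ratings, participants = participants, vocabulary = vocabulary)
}

#' Write a dataset as a long-format rating CSV
#'
#' One row per rating with header `participant_id,country,age,gender,colour,
#' emotion,intensity`, rows in the dataset's canonical order (participant id,
#' colour vocabulary order, emotion vocabulary order). Output is byte-stable:
#' writing the same dataset twice yields identical files.
#'
#' @param dataset a [gew_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gew_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "gew_dataset"))
  r <- dataset$ratings
  m <- match(r$participant_id, dataset$participants$participant_id)
  age <- dataset$participants$age[m]
  gender <- dataset$participants$gender[m]
  out <- data.frame(
    participant_id = r$participant_id,
    country = r$country,
    age = ifelse(is.na(age), "", format(age, trim = TRUE, scientific = FALSE)),
    gender = ifelse(is.na(gender), "", gender),
    colour = r$colour, emotion = r$emotion, intensity = r$intensity,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  }
  invisible(path)
}

#' Write an empty (header-only) rating CSV
#'
#' Convenience for exporting the canonical header with no rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gew_header <- function(path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("participant_id,country,age,gender,colour,emotion,intensity", con)
  invisible(path)
}

#' Export a dataset in wide format
#'
#' One row per participant with 240 rating columns named
#' `<colour>_<emotion>` in colour-major vocabulary order, preceded by
#' `participant_id` and `country`.
#'
#' @param dataset a [gew_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gew_wide <- function(dataset, path) {
  ft <- country_feature_table(dataset)
  out <- data.frame(participant_id = ft$groups, country = as.character(ft$labels),
                    stringsAsFactors = FALSE)
  mat <- as.data.frame(ft$x)
  names(mat) <- ft$feature_names
  utils::write.csv(cbind(out, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
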