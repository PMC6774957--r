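# Vocabulary of colour terms, emotion terms and country codes. The ordering
# of the vocabulary is part of the analysis contract: it fixes feature-column
# order for the decoders and class order in every confusion and similarity
# matrix.

# The 11 basic colour terms plus turquoise, and the 20 Geneva Emotion Wheel
# emotion terms (English), in alphabetical order.
GEW_COLOUR_TERMS <- c(
  "black", "blue", "brown", "green", "grey", "orange",
  "pink", "purple", "red", "turquoise", "white", "yellow"
)

GEW_EMOTION_TERMS <- c(
  "admiration", "amusement", "anger", "compassion", "contempt",
  "contentment", "disappointment", "disgust", "fear", "guilt",
  "hate", "interest", "joy", "love", "pleasure",
  "pride", "regret", "relief", "sadness", "shame"
)

GEW_COUNTRIES <- c("CN", "DE", "GB", "GR")

#' Rating vocabulary: colour terms, emotion terms and countries
#'
#' A vocabulary fixes the identity and the order of the 12 colour terms, the
#' 20 emotion terms and the country codes of a study. The order is load-bearing:
#' it defines feature-column order in [colour_feature_table()] and
#' [country_feature_table()] and class order in confusion and similarity
#' matrices. Defaults are the 11 basic colour terms plus turquoise, the 20
#' Geneva Emotion Wheel (GEW) emotion terms in English, and the country codes
#' CN, DE, GB, GR.
#'
#' @param colour_terms character vector of exactly 12 unique colour terms.
#' @param emotion_terms character vector of exactly 20 unique emotion terms.
#' @param countries character vector of at least 2 unique country codes.
#' @return An object of class `gew_vocabulary`: a list with elements
#'   `colour_terms`, `emotion_terms`, `countries`.
#' @examples
#' v <- gew_vocabulary()
#' v$colour_terms
#' @export
gew_vocabulary <- function(colour_terms = GEW_COLOUR_TERMS,
                           emotion_terms = GEW_EMOTION_TERMS,
                           countries = GEW_COUNTRIES) {
  colour_terms <- as.character(colour_terms)
  emotion_terms <- as.character(emotion_terms)
  countries <- as.character(countries)
  if (length(colour_terms) != 12L || anyDuplicated(tolower(colour_terms))) {
    stop("`colour_terms` must be exactly 12 unique terms", call. = FALSE)
  }
  if (length(emotion_terms) != 20L || anyDuplicated(tolower(emotion_terms))) {
    stop("`emotion_terms` must be exactly 20 unique terms", call. = FALSE)
  }
  if (length(countries) < 2L || anyDuplicated(toupper(countries))) {
    stop("`countries` must be >= 2 unique codes", call. = FALSE)
  }
  if (any(!nzchar(colour_terms)) || any(!nzchar(emotion_terms)) || any(!nzchar(countries))) {
    stop("vocabulary identifiers must be non-empty strings", call. = FALSE)
  }
  structure(
    list(colour_terms = colour_terms, emotion_terms = emotion_terms,
         countries = countries),
    class = "gew_vocabulary"
  )
}

#' @export
print.gew_vocabulary <- function(x, ...) {
  cat("GEW vocabulary\n")
  cat("  colours (12): ", paste(x$colour_terms, collapse = ", "), "\n", sep = "")
  cat("  emotions (20): ", paste(x$emotion_terms, collapse = ", "), "\n", sep = "")
  cat("  countries: ", paste(x$countries, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read or write a vocabulary as JSON or YAML
#'
#' The format is chosen from the file extension (`.json`, `.yaml`, `.yml`).
#'
#' @param path file path.
#' @return `read_vocabulary()` returns a [gew_vocabulary()];
#'   `write_vocabulary()` returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported vocabulary format: .", ext, call. = FALSE)
  )
  gew_vocabulary(
    colour_terms = raw$colour_terms,
    emotion_terms = raw$emotion_terms,
    countries = raw$countries %||% GEW_COUNTRIES
  )
}

#' @rdname read_vocabulary
#' @param vocabulary a [gew_vocabulary()].
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "gew_vocabulary"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(vocabulary)
  switch(ext,
    json = jsonlite::write_json(x, path, pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("unsupported vocabulary format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# Case-insensitive canonicalisation of tokens against a vocabulary axis.
# Returns canonical spellings; errors (naming the offenders) on unknowns.
match_terms <- function(tokens, vocab_terms, what) {
  idx <- match(tolower(tokens), tolower(vocab_terms))
  if (anyNA(idx)) {
    bad <- unique(tokens[is.na(idx)])
    stop(sprintf("unknown %s term(s): %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  vocab_terms[idx]
}
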