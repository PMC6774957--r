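# Inter-colour similarity from decoding confusions, via Luce's biased-choice
# model. Under that model the probability of responding j to stimulus i is
# proportional to a response bias b_j times a symmetric similarity eta_ij with
# eta_ii = 1; the moment estimator below inverts a confusion matrix's
# row-normalised proportions:
#   eta_ij = sqrt( (p_ij * p_ji) / (p_ii * p_jj) ),
# which cancels the biases and row normalisers exactly.

#' Estimate biased-choice similarities from a confusion matrix
#'
#' Classes that are more similar (here: colours with more similar emotion
#' associations) are confused more often by the decoder; the biased-choice
#' moment estimator turns those confusions into a symmetric similarity matrix
#' with unit diagonal. Additive smoothing (`smoothing` pseudo-counts per cell,
#' default 0.5) is applied before row normalisation because sparse confusion
#' matrices contain zero cells and the estimator divides by the diagonal.
#' Estimates above 1 are clipped to 1 with a warning (they signal model
#' misfit); clipped pairs are recorded in the result.
#'
#' @param cm a [confusion()] matrix, or a square numeric matrix of counts
#'   (a row-stochastic proportion matrix is equally valid input: the estimator
#'   is invariant to row scale).
#' @param smoothing pseudo-count added to every cell, >= 0.
#' @return An object of class `gew_similarity`: `eta` (symmetric, unit
#'   diagonal, values in `[0, 1]`), `bias` (response-bias vector, normalised to
#'   sum 1; reported for transparency, not used downstream), `classes`,
#'   `clipped` (data.frame of pairs clipped at 1).
#' @examples
#' p <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' estimate_similarity(p, smoothing = 0)$eta["a", "b"]  # 0.25
#' @export
estimate_similarity <- function(cm, smoothing = 0.5) {
  check_number(smoothing, "smoothing", lower = 0)
  if (inherits(cm, "gew_confusion")) {
    N <- cm$counts
    classes <- cm$classes
  } else {
    N <- as.matrix(cm)
    if (nrow(N) != ncol(N)) stop("confusion matrix must be square", call. = FALSE)
    if (any(!is.finite(N)) || any(N < 0)) {
      stop("confusion matrix entries must be finite and >= 0", call. = FALSE)
    }
    classes <- rownames(N) %||% paste0("class", seq_len(nrow(N)))
  }
  K <- length(classes)
  Ns <- N + smoothing
  row_tot <- rowSums(Ns)
  if (any(row_tot == 0) || any(diag(Ns) == 0)) {
    stop("zero diagonal or empty row after smoothing; increase `smoothing`",
         call. = FALSE)
  }
  p <- Ns / row_tot
  eta <- matrix(1, K, K, dimnames = list(classes, classes))
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      eta[i, j] <- eta[j, i] <- sqrt((p[i, j] * p[j, i]) / (p[i, i] * p[j, j]))
    }
  }
  over <- which(eta > 1 & upper.tri(eta), arr.ind = TRUE)
  clipped <- data.frame(class_a = classes[over[, 1L]],
                        class_b = classes[over[, 2L]],
                        eta = eta[over], stringsAsFactors = FALSE)
  if (nrow(clipped)) {
    warning(sprintf("%d similarity estimate(s) > 1 clipped to 1 (model misfit): %s",
                    nrow(clipped),
                    paste(paste(clipped$class_a, clipped$class_b, sep = "-"),
                          collapse = ", ")), call. = FALSE)
    eta <- pmin(eta, 1)
  }
  # response bias: geometric mean over rows of p[i, j] / eta[i, j], sum-normalised
  b <- exp(colMeans(log(p / eta)))
  b <- b / sum(b)
  structure(list(eta = eta, bias = b, classes = classes, clipped = clipped,
                 smoothing = smoothing),
            class = "gew_similarity")
}

#' @export
print.gew_similarity <- function(x, digits = 3, ...) {
  cat(sprintf("Biased-choice similarity matrix (%d classes, smoothing %g):\n",
              length(x$classes), x$smoothing))
  m <- round(x$eta, digits)
  m[lower.tri(m)] <- NA  # symmetric: upper triangle suffices
  print(m, na.print = "")
  invisible(x)
}

#' Ranked list of the most similar class pairs
#'
#' Off-diagonal pairs of the upper triangle (each unordered pair once),
#' sorted by similarity descending; ties are broken by vocabulary order of
#' the first, then second class.
#'
#' @param sm a [estimate_similarity()] result.
#' @param top_n number of pairs to return (default all).
#' @return data.frame with columns `class_a`, `class_b`, `similarity`.
#' @export
similarity_report <- function(sm, top_n = Inf) {
  stopifnot(inherits(sm, "gew_similarity"))
  if (!is.numeric(top_n) || length(top_n) != 1L || is.na(top_n) || top_n < 0) {
    stop("`top_n` must be a single number >= 0", call. = FALSE)
  }
  K <- length(sm$classes)
  ij <- which(upper.tri(sm$eta), arr.ind = TRUE)
  out <- data.frame(class_a = sm$classes[ij[, 1L]],
                    class_b = sm$classes[ij[, 2L]],
                    similarity = sm$eta[ij], stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, ij[, 1L], ij[, 2L]), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Write a similarity matrix as CSV (upper triangle populated)
#'
#' The lower triangle is left blank: the matrix is symmetric, so the upper
#' triangle carries all information.
#'
#' @param sm a [estimate_similarity()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sm, path) {
  stopifnot(inherits(sm, "gew_similarity"))
  m <- sm$eta
  m[lower.tri(m)] <- NA
  utils::write.csv(m, path, na = "", row.names = TRUE)
  invisible(path)
}
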