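# Seeded generator of synthetic colour-emotion rating datasets.
#
# Model: each (colour, emotion) cell has a universal effect U[k,e] ~ N(0, s^2)
# shared by all countries, plus a country deviation V[c,k,e] ~ N(0, delta^2).
# A participant either leaves a cell at 0 ("no association") or, with
# probability squash(logit(base) + U + V + a_p) where a_p ~ N(0, rho^2) is a
# participant propensity offset, rates it 1 + Binomial(4, mu[c,k,e]). This
# zero-inflated binomial emulates the dominant no-association category with
# graded intensities among responders, colour-specific emotion profiles
# shared across countries, smaller country-specific deviations, and
# participant heterogeneity.

#' Configuration for the synthetic rating generator
#'
#' @param vocabulary a [gew_vocabulary()].
#' @param n_per_country participants per country (>= 1). Default 180 per
#'   country, i.e. 720 participants over the default 4 countries, the scale of
#'   a multi-country online rating study.
#' @param colour_specificity s >= 0: sd of the universal cell effects; 0 means
#'   no colour is distinguishable from any other.
#' @param country_divergence delta >= 0: sd of country-specific deviations;
#'   0 means all countries share one profile.
#' @param association_base baseline association probability in (0,1); the
#'   marginal rate at which a cell is rated nonzero when all effects are 0.
#' @param heterogeneity rho >= 0: sd of the participant propensity offset.
#' @param intensity_concentration > 0: scales how sharply the intensity mean
#'   varies across cells (logit scale).
#' @param squash_floor clipping floor for association probabilities, default
#'   0.02; set 0 to allow degenerate all-0/all-5 cells.
#' @param seed integer seed; all randomness is derived from it through
#'   per-participant substreams, so the first m participants of a run are
#'   identical for any n >= m.
#' @return An object of class `gew_generator_config`.
#' @export
generator_config <- function(vocabulary = gew_vocabulary(),
                             n_per_country = 180L,
                             colour_specificity = 1,
                             country_divergence = 0.5,
                             association_base = 0.3,
                             heterogeneity = 0.5,
                             intensity_concentration = 1,
                             squash_floor = 0.02,
                             seed = 1L) {
  stopifnot(inherits(vocabulary, "gew_vocabulary"))
  check_number(n_per_country, "n_per_country", lower = 1)
  check_number(colour_specificity, "colour_specificity", lower = 0)
  check_number(country_divergence, "country_divergence", lower = 0)
  check_number(association_base, "association_base")
  if (association_base <= 0 || association_base >= 1) {
    stop("`association_base` must lie in (0, 1)", call. = FALSE)
  }
  check_number(heterogeneity, "heterogeneity", lower = 0)
  check_number(intensity_concentration, "intensity_concentration")
  if (intensity_concentration <= 0) {
    stop("`intensity_concentration` must be > 0", call. = FALSE)
  }
  check_number(squash_floor, "squash_floor", lower = 0, upper = 0.49)
  check_number(seed, "seed")
  structure(list(
    vocabulary = vocabulary,
    n_per_country = as.integer(n_per_country),
    colour_specificity = colour_specificity,
    country_divergence = country_divergence,
    association_base = association_base,
    heterogeneity = heterogeneity,
    intensity_concentration = intensity_concentration,
    squash_floor = squash_floor,
    seed = as.integer(seed)
  ), class = "gew_generator_config")
}

#' Country-level association and intensity profiles
#'
#' Draws the universal cell effects `U[k,e] ~ N(0, s^2)` and country
#' deviations `V[c,k,e] ~ N(0, delta^2)`, then forms per-country association
#' probabilities `pi = squash(logit(base) + U + V)` and intensity means
#' `mu = 0.1 + 0.8 * plogis(conc * (U + V))` (bounded in (0.1, 0.9)).
#' Deterministic given the config seed. With `country_divergence = 0` all
#' countries share identical profiles; with `colour_specificity = 0` and
#' `country_divergence = 0` every pi equals `association_base`.
#'
#' @param config a [generator_config()].
#' @return An object of class `gew_profiles`: arrays `pi`, `mu`
#'   (country x colour x emotion), matrix `U`, the vocabulary and config.
#' @export
make_profiles <- function(config) {
  stopifnot(inherits(config, "gew_generator_config"))
  v <- config$vocabulary
  nk <- length(v$colour_terms); ne <- length(v$emotion_terms)
  countries <- v$countries
  dn <- list(countries, v$colour_terms, v$emotion_terms)
  with_seed(derive_seed(config$seed, "profiles"), {
    U <- matrix(stats::rnorm(nk * ne), nk, ne,
                dimnames = dn[2:3]) * config$colour_specificity
    V <- array(stats::rnorm(length(countries) * nk * ne),
               dim = c(length(countries), nk, ne), dimnames = dn) *
      config$country_divergence
    eff <- sweep(V, c(2, 3), U, `+`)  # U + V per country
    pi <- squash(stats::qlogis(config$association_base) + eff,
                 floor = config$squash_floor)
    mu <- 0.1 + 0.8 * stats::plogis(config$intensity_concentration * eff)
    dimnames(pi) <- dn; dimnames(mu) <- dn
    structure(list(pi = pi, mu = mu, U = U, vocabulary = v, config = config),
              class = "gew_profiles")
  })
}

#' @export
print.gew_profiles <- function(x, ...) {
  cat(sprintf("GEW generator profiles: %d countries x %d colours x %d emotions\n",
              dim(x$pi)[1], dim(x$pi)[2], dim(x$pi)[3]))
  invisible(x)
}

#' Simulate a rating dataset from country profiles
#'
#' For each participant, a propensity offset `a_p ~ N(0, rho^2)` is drawn;
#' each of the 240 cells is associated with probability
#' `squash(logit(pi) + a_p)` and, if associated, rated
#' `1 + Binomial(4, mu)` (values 1-5), otherwise 0. Each participant draws
#' from an independent substream of the config seed.
#'
#' @param profiles a [make_profiles()] result (fields `pi`, `mu` may be
#'   modified for degenerate scenarios before simulation).
#' @param config a [generator_config()] compatible with the profiles.
#' @return A validated [gew_dataset()].
#' @export
simulate_dataset <- function(profiles, config = profiles$config) {
  stopifnot(inherits(profiles, "gew_profiles"),
            inherits(config, "gew_generator_config"))
  v <- profiles$vocabulary
  nk <- length(v$colour_terms); ne <- length(v$emotion_terms)
  n_cells <- nk * ne
  countries <- v$countries
  colour_rep <- rep(v$colour_terms, each = ne)
  emotion_rep <- rep(v$emotion_terms, times = nk)

  parts <- vector("list", length(countries) * config$n_per_country)
  meta <- vector("list", length(parts))
  idx <- 0L
  for (c_i in seq_along(countries)) {
    country <- countries[c_i]
    # cell parameters in colour-major, emotion-minor order
    pi_c <- as.vector(t(profiles$pi[c_i, , ]))
    mu_c <- as.vector(t(profiles$mu[c_i, , ]))
    logit_pi <- stats::qlogis(pmin(pmax(pi_c, 1e-12), 1 - 1e-12))
    for (p_i in seq_len(config$n_per_country)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%04d", country, p_i)
      with_seed(derive_seed(config$seed, "participant", country, p_i), {
        a_p <- stats::rnorm(1) * config$heterogeneity
        p_assoc <- squash(logit_pi + a_p, floor = 0)
        # keep exactly-1 probabilities deterministic (degenerate scenarios)
        p_assoc[pi_c >= 1] <- 1
        assoc <- stats::runif(n_cells) < p_assoc
        intensity <- integer(n_cells)
        if (any(assoc)) {
          intensity[assoc] <- 1L + stats::rbinom(sum(assoc), 4L, mu_c[assoc])
        }
        age <- sample(18:75, 1L)
        gender <- sample(c("female", "male"), 1L)
        parts[[idx]] <- data.frame(
          participant_id = pid, country = country,
          colour = colour_rep, emotion = emotion_rep,
          intensity = intensity, stringsAsFactors = FALSE
        )
        meta[[idx]] <- data.frame(
          participant_id = pid, country = country, age = age, gender = gender,
          stringsAsFactors = FALSE
        )
      })
    }
  }
  gew_dataset(do.call(rbind, parts), participants = do.call(rbind, meta),
              vocabulary = v)
}

#' Simulate a dataset directly from a generator config
#'
#' Convenience composition of [make_profiles()] and [simulate_dataset()].
#'
#' @param config a [generator_config()].
#' @return A validated [gew_dataset()].
#' @examples
#' d <- simulate_gew(generator_config(n_per_country = 3, seed = 42))
#' n_participants(d)
#' @export
simulate_gew <- function(config) {
  simulate_dataset(make_profiles(config), config)
}
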