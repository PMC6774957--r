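# Shared fixtures: all synthetic, built in code at test time.

# Fast singleton hyperparameters used throughout the suite (the grid is an
# analysis setting, not a property under test, except where tuning itself is).
# gamma follows the 1/(2d) heuristic for the task's dimensionality: 20
# features for the colour task, 240 for the country task.
fast_params <- function(task = "colour") {
  if (task == "country") hyperparams(C = 10, gamma = 0.002)
  else hyperparams(C = 10, gamma = 0.02)
}

# shallow replacement merge (unlike modifyList, never recurses into values)
merge_config <- function(base, ...) {
  upd <- list(...)
  for (nm in names(upd)) base[[nm]] <- upd[[nm]]
  base
}

# Small simulated dataset; countries beyond `n_countries` are dropped by
# restricting the vocabulary.
sim_data <- function(n_per_country = 20, s = 1, delta = 0.5, rho = 0.5,
                     base = 0.3, seed = 1, n_countries = 4) {
  vocab <- gew_vocabulary(countries = GEW_COUNTRIES[seq_len(n_countries)])
  simulate_gew(generator_config(
    vocabulary = vocab, n_per_country = n_per_country,
    colour_specificity = s, country_divergence = delta,
    association_base = base, heterogeneity = rho, seed = seed
  ))
}

# Hand-built two-participant dataset as a long data.frame (all zeros except
# where overridden); returns the data.frame, not the gew_dataset.
tiny_ratings <- function(pids = c("p1", "p2"), countries = c("CN", "DE")) {
  v <- gew_vocabulary()
  grid <- expand.grid(emotion = v$emotion_terms, colour = v$colour_terms,
                      participant_id = pids, stringsAsFactors = FALSE)
  grid$country <- countries[match(grid$participant_id, pids)]
  grid$intensity <- 0L
  grid[c("participant_id", "country", "colour", "emotion", "intensity")]
}

# Two well-separated Gaussian clouds per class in `centers` rows; one
# participant per row (so grouped folds reduce to row folds).
toy_table <- function(centers, n_per_class = 10, sd = 0.05, seed = 42,
                      task = "colour", groups = NULL) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per_class * ncol(centers), mean = 0, sd = sd),
           n_per_class) + matrix(centers[i, ], n_per_class, ncol(centers),
                                 byrow = TRUE)
  }))
  labels <- factor(rep(rownames(centers), each = n_per_class),
                   levels = rownames(centers))
  if (is.null(groups)) groups <- paste0("g", seq_len(nrow(x)))
  feature_table(x, labels, groups, task = task)
}

# Deterministic two-class toy: class A around (0,0), class B around (4,4).
separable_toy <- function(n_per_class = 10, seed = 7) {
  set.seed(seed)
  centers <- rbind(A = c(0, 0), B = c(4, 4))
  toy_table(centers, n_per_class = n_per_class, sd = 0.1, task = "colour")
}
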