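# Configuration-driven orchestration of the full analysis: simulate or load
# ratings, decode colour, permutation test, decode country, cross-country
# transfer, biased-choice similarity, and a reproducible report.

default_tasks <- c("colour", "country", "transfer", "similarity")

#' Validate and default an analysis configuration
#'
#' Accepts a YAML/JSON file path or an R list. Required: `seed` and an
#' `input` block with either `path` (a long-format rating CSV) or `generator`
#' (fields of [generator_config()]). Defaults: `k = 10`, `n_perm = 10`
#' (`permutation: false` skips the permutation stage), `tasks` = colour,
#' country, transfer, similarity; `grid` defaults to a single
#' [hyperparams()] point; list `grid: {C: [...], gamma: [...]}` expands via
#' [hyper_grid()]. Schema violations name the offending field.
#'
#' @param config file path or list.
#' @return An object of class `gew_config` (a validated, fully defaulted list).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      yaml = ,
      yml = yaml::read_yaml(config),
      stop("unsupported config format: .", ext, call. = FALSE)
    )
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path", call. = FALSE)

  fail <- function(field, msg) stop(sprintf("config field `%s`: %s", field, msg),
                                    call. = FALSE)
  if (is.null(config$seed)) fail("seed", "required (no wall-clock seeding)")
  check_number(config$seed, "seed")

  k <- config$k %||% 10L
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2) {
    fail("k", "must be a single integer >= 2")
  }
  n_perm <- config$n_perm %||% 10L
  if (!is.numeric(n_perm) || n_perm < 1 || n_perm != round(n_perm)) {
    fail("n_perm", "must be a positive integer")
  }
  permutation <- isTRUE(config$permutation %||% FALSE)

  tasks <- unlist(config$tasks %||% default_tasks)
  bad <- setdiff(tasks, default_tasks)
  if (length(bad)) fail("tasks", paste("unknown task(s):", paste(bad, collapse = ", ")))
  if ("similarity" %in% tasks && !("colour" %in% tasks)) {
    fail("tasks", "similarity requires the colour task (it reads its confusion matrix)")
  }

  vocabulary <- if (!is.null(config$vocabulary_path)) {
    read_vocabulary(config$vocabulary_path)
  } else {
    gew_vocabulary()
  }

  input <- config$input
  if (is.null(input) || (is.null(input$path) && is.null(input$generator))) {
    fail("input", "must provide `path` or `generator`")
  }
  if (!is.null(input$path) && !file.exists(input$path)) {
    fail("input.path", paste("file not found:", input$path))
  }
  generator <- NULL
  if (is.null(input$path)) {
    g <- input$generator
    generator <- generator_config(
      vocabulary = vocabulary,
      n_per_country = g$n_per_country %||% 180L,
      colour_specificity = g$colour_specificity %||% 1,
      country_divergence = g$country_divergence %||% 0.5,
      association_base = g$association_base %||% 0.3,
      heterogeneity = g$heterogeneity %||% 0.5,
      intensity_concentration = g$intensity_concentration %||% 1,
      squash_floor = g$squash_floor %||% 0.02,
      seed = g$seed %||% derive_seed(config$seed, "generator")
    )
  }

  grid <- if (is.null(config$grid)) {
    hyper_grid()
  } else {
    if (is.null(config$grid$C) || is.null(config$grid$gamma)) {
      fail("grid", "must provide numeric vectors `C` and `gamma`")
    }
    hyper_grid(C = config$grid$C, gamma = config$grid$gamma)
  }

  structure(list(
    seed = as.integer(config$seed), k = as.integer(k),
    n_perm = as.integer(n_perm), permutation = permutation,
    tasks = tasks, vocabulary = vocabulary,
    input_path = input$path, generator = generator, grid = grid,
    smoothing = config$smoothing %||% 0.5,
    tune = config$tune %||% "nested",
    output_dir = config$output_dir
  ), class = "gew_config")
}

cm_to_list <- function(cm) {
  list(classes = cm$classes,
       counts = unname(apply(cm$counts, 1, as.integer, simplify = FALSE)),
       proportions = unname(apply(round(cm$proportions, 6), 1, as.numeric,
                                  simplify = FALSE)),
       recall = as.numeric(round(diag(cm$proportions), 6)))
}

decode_report <- function(cv) {
  cm <- confusion(cv$predictions$true, cv$predictions$predicted,
                  classes = cv$classes)
  list(accuracy = cv$accuracy,
       chance_level = cv$chance,
       auc_weighted = cv$auc_weighted,
       auc_macro = cv$auc_macro,
       fold_accuracies = cv$fold_accuracies,
       confusion = cm_to_list(cm))
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in dependency order (data, colour decoding,
#' optional permutation tests, country decoding, transfer, similarity), logs
#' progress to stderr, optionally writes a JSON report plus CSV matrices to
#' `output_dir`, and returns the report. Identical (config, seed) yield
#' byte-identical reports.
#'
#' @param config a [validate_config()] result, a list, or a YAML/JSON path.
#' @return The report (class `gew_report`): named list with a `provenance`
#'   block and one entry per executed task, each carrying accuracy next to its
#'   chance level, AUC under both weightings, and the confusion matrix.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "gew_config")) config <- validate_config(config)
  log_stage <- function(...) message(sprintf("[gewmvpa] %s", sprintf(...)))

  t0 <- proc.time()[["elapsed"]]
  dataset <- if (!is.null(config$input_path)) {
    log_stage("loading ratings from %s", config$input_path)
    read_gew_csv(config$input_path, vocabulary = config$vocabulary)
  } else {
    log_stage("simulating dataset (seed %d)", config$generator$seed)
    simulate_gew(config$generator)
  }
  log_stage("dataset: %d participants, %d ratings",
            n_participants(dataset), nrow(dataset$ratings))

  report <- list(provenance = list(
    package = "gewmvpa",
    version = as.character(utils::packageVersion("gewmvpa")),
    seed = config$seed,
    config_digest = config_digest(config),
    n_participants = n_participants(dataset)
  ))

  colour_cv <- NULL
  if ("colour" %in% config$tasks) {
    log_stage("colour decoding (12-class, grouped %d-fold CV)", config$k)
    tab <- colour_feature_table(dataset)
    colour_cv <- cross_validate(tab, k = config$k, grid = config$grid,
                                seed = derive_seed(config$seed, "colour"),
                                tune = config$tune)
    report$colour <- decode_report(colour_cv)
    if (config$permutation) {
      log_stage("colour permutation test (%d permutations)", config$n_perm)
      pt <- permutation_test(tab, k = config$k, grid = config$grid,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "colour"),
                             tune = config$tune)
      report$colour$permutation <- list(
        null_auc = pt$null_auc, null_accuracy = pt$null_accuracy,
        p_auc = pt$p_auc, p_accuracy = pt$p_accuracy,
        z_auc = pt$z_auc, p_z_auc = pt$p_z_auc)
    }
  }

  if ("country" %in% config$tasks) {
    log_stage("country decoding (%d-class, grouped %d-fold CV)",
              length(unique(dataset$participants$country)), config$k)
    tab <- country_feature_table(dataset)
    country_cv <- cross_validate(tab, k = config$k, grid = config$grid,
                                 seed = derive_seed(config$seed, "country"),
                                 tune = config$tune)
    report$country <- decode_report(country_cv)
    if (config$permutation) {
      log_stage("country permutation test (%d permutations)", config$n_perm)
      pt <- permutation_test(tab, k = config$k, grid = config$grid,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "country"),
                             tune = config$tune)
      report$country$permutation <- list(
        null_auc = pt$null_auc, null_accuracy = pt$null_accuracy,
        p_auc = pt$p_auc, p_accuracy = pt$p_accuracy,
        z_auc = pt$z_auc, p_z_auc = pt$p_z_auc)
    }
  }

  if ("transfer" %in% config$tasks) {
    log_stage("cross-country transfer matrix")
    tm <- transfer_matrix(dataset, k = config$k, grid = config$grid,
                          seed = derive_seed(config$seed, "transfer"))
    adv <- advantage_matrix(tm)
    report$transfer <- list(
      countries = tm$countries,
      accuracy = unname(apply(round(tm$accuracy, 6), 1, as.numeric,
                              simplify = FALSE)),
      advantage = unname(apply(round(adv$advantage, 6), 1, as.numeric,
                               simplify = FALSE)),
      advantage_summary = as.list(round(adv$summary, 6)))
    attr(report$transfer, "objects") <- list(tm = tm, adv = adv)
  }

  if ("similarity" %in% config$tasks) {
    log_stage("biased-choice similarity from the colour confusion matrix")
    cm <- confusion(colour_cv$predictions$true, colour_cv$predictions$predicted,
                    classes = colour_cv$classes)
    sm <- estimate_similarity(cm, smoothing = config$smoothing)
    report$similarity <- list(
      classes = sm$classes,
      eta = unname(apply(round(sm$eta, 6), 1, as.numeric, simplify = FALSE)),
      bias = as.numeric(round(sm$bias, 6)),
      top_pairs = similarity_report(sm, top_n = 5))
    attr(report$similarity, "objects") <- list(sm = sm)
  }

  log_stage("done in %.1f s", proc.time()[["elapsed"]] - t0)

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
    log_stage("report written to %s", config$output_dir)
  }
  class(report) <- "gew_report"
  report
}

# md5 of the canonical JSON serialisation of the config (vocabulary and grid
# included); deterministic across runs and platforms.
config_digest <- function(config) {
  canon <- list(seed = config$seed, k = config$k, n_perm = config$n_perm,
                permutation = config$permutation, tasks = config$tasks,
                input_path = config$input_path,
                generator = if (!is.null(config$generator)) {
                  c(unclass(config$generator)[-1L],
                    list(vocabulary = unclass(config$generator$vocabulary)))
                },
                grid = lapply(config$grid, unclass),
                smoothing = config$smoothing, tune = config$tune)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

strip_attrs <- function(x) {
  if (is.list(x)) {
    attr(x, "objects") <- NULL
    x[] <- lapply(x, strip_attrs)
  }
  x
}

#' Write an analysis report to disk
#'
#' `report.json` plus CSVs of any confusion, transfer/advantage and
#' similarity matrices the report contains.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(strip_attrs(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_cm <- function(task) {
    cm <- report[[task]]$confusion
    if (is.null(cm)) return(invisible())
    m <- do.call(rbind, cm$proportions)
    dimnames(m) <- list(cm$classes, cm$classes)
    utils::write.csv(m, file.path(dir, paste0(task, "_confusion.csv")))
  }
  write_cm("colour"); write_cm("country")
  if (!is.null(report$transfer)) {
    objs <- attr(report$transfer, "objects")
    if (!is.null(objs)) {
      utils::write.csv(objs$tm$accuracy, file.path(dir, "transfer_accuracy.csv"))
      utils::write.csv(objs$adv$advantage, file.path(dir, "transfer_advantage.csv"),
                       na = "")
    }
  }
  if (!is.null(report$similarity)) {
    objs <- attr(report$similarity, "objects")
    if (!is.null(objs)) write_similarity_csv(objs$sm, file.path(dir, "similarity.csv"))
  }
  invisible(dir)
}

#' @export
print.gew_report <- function(x, ...) {
  cat("GEW analysis report\n")
  for (task in c("colour", "country")) {
    r <- x[[task]]
    if (is.null(r)) next
    cat(sprintf("  %s: accuracy %.3f (chance %.3f), AUC %.3f weighted / %.3f macro\n",
                task, r$accuracy, r$chance_level, r$auc_weighted, r$auc_macro))
    if (!is.null(r$permutation)) {
      cat(sprintf("    permutation p (AUC) = %.4f, p (accuracy) = %.4f\n",
                  r$permutation$p_auc, r$permutation$p_accuracy))
    }
  }
  if (!is.null(x$transfer)) {
    s <- x$transfer$advantage_summary
    cat(sprintf("  transfer: mean in-group advantage %.3f (sd %.3f, range [%.3f, %.3f])\n",
                s$mean, s$sd, s$min, s$max))
  }
  if (!is.null(x$similarity)) {
    tp <- x$similarity$top_pairs[1, ]
    cat(sprintf("  similarity: most similar pair %s-%s (%.3f)\n",
                tp$class_a, tp$class_b, tp$similarity))
  }
  invisible(x)
}
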