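# Data model, validation, I/O and descriptive proportions.

test_that("a well-formed long CSV loads into a validated dataset and round-trips", {
  df <- tiny_ratings()
  df$intensity[df$colour == "red" & df$emotion == "love"] <- 5L
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  d <- read_gew_csv(path)
  expect_s3_class(d, "gew_dataset")
  expect_equal(n_participants(d), 2L)
  expect_equal(nrow(d$ratings), 480L)

  # write -> load is the identity
  out <- withr::local_tempfile(fileext = ".csv")
  write_gew_csv(d, out)
  expect_equal(read_gew_csv(out), d)
  # one participant's block is 240 data rows
  lines <- readLines(out)
  expect_equal(sum(grepl("^p1,", lines)), 240L)
  # repeated writes are byte-identical
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_gew_csv(d, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("malformed files and invariant violations are rejected with named offenders", {
  path <- withr::local_tempfile(fileext = ".csv")

  df <- tiny_ratings()
  df$intensity[1] <- 6L
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gew_csv(path), "intensity out of range.*p1")

  df <- tiny_ratings()
  df$colour[3] <- "beige"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gew_csv(path), "unknown colour")

  df <- tiny_ratings()[-1, ]  # incomplete 240-cell grid
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gew_csv(path), "expected 240")

  df <- tiny_ratings()
  df$country[1] <- "DE"  # p1 under two countries
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gew_csv(path), "more than one country")

  write.csv(tiny_ratings()[, -5], path, row.names = FALSE)
  expect_error(read_gew_csv(path), "missing column")

  # duplicate cell
  df <- tiny_ratings()
  df <- rbind(df, df[1, ])
  expect_error(gew_dataset(df), "duplicate rating cell")
})

test_that("tokens are matched case-insensitively and stored canonically", {
  df <- tiny_ratings()
  df$colour <- toupper(df$colour)
  df$country <- tolower(df$country)
  d <- gew_dataset(df)
  expect_setequal(unique(d$ratings$colour), GEW_COLOUR_TERMS)
  expect_setequal(unique(d$ratings$country), c("CN", "DE"))
})

test_that("header-only export and missing demographics are supported", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gew_header(path)
  expect_equal(readLines(path),
               "participant_id,country,age,gender,colour,emotion,intensity")

  d <- gew_dataset(tiny_ratings())  # no demographics given
  expect_true(all(is.na(d$participants$age)))
  out <- withr::local_tempfile(fileext = ".csv")
  write_gew_csv(d, out)
  expect_equal(read_gew_csv(out), d)
})

test_that("colour feature table has 12 rows per participant with vocabulary-ordered columns", {
  df <- tiny_ratings()
  df$intensity[df$participant_id == "p1" & df$colour == "red" &
                 df$emotion == "admiration"] <- 4L
  # shuffle input row order: the contract must not depend on it
  df <- df[sample(nrow(df)), ]
  d <- gew_dataset(df)
  ft <- colour_feature_table(d)
  expect_equal(dim(ft$x), c(24L, 20L))
  expect_equal(colnames(ft$x), GEW_EMOTION_TERMS)
  expect_equal(as.vector(table(ft$groups)), c(12L, 12L))
  # column 1 is emotion_terms[1] ("admiration") regardless of input order
  red_p1 <- ft$x[ft$groups == "p1" & ft$labels == "red", ]
  expect_equal(unname(red_p1["admiration"]), 4)
  expect_equal(sum(ft$x), 4)
})

test_that("country feature table is one 240-feature row per participant in colour-major order", {
  df <- tiny_ratings()
  df$intensity[df$participant_id == "p2" & df$colour == "blue" &
                 df$emotion == "fear"] <- 3L
  d <- gew_dataset(df)
  ct <- country_feature_table(d)
  expect_equal(dim(ct$x), c(2L, 240L))
  expect_equal(as.character(ct$labels), c("CN", "DE"))
  expect_true(all(as.character(ct$labels) %in% d$vocabulary$countries))
  # feature (colour k, emotion e) = the dataset's intensity for that cell
  expect_equal(unname(ct$x[ct$groups == "p2", "blue_fear"]), 3)
  expect_equal(sum(ct$x), 3)
  # colour-major, emotion-minor column order
  expect_equal(colnames(ct$x)[1:2], c("black_admiration", "black_amusement"))
  expect_equal(colnames(ct$x)[21], "blue_admiration")
})

test_that("feature table row counts scale exactly with participants", {
  d <- sim_data(n_per_country = 3, seed = 11)
  expect_equal(nrow(colour_feature_table(d)$x), 12L * 12L)
  expect_equal(nrow(country_feature_table(d)$x), 12L)
  expect_true(all(colour_feature_table(d)$x >= 0 & colour_feature_table(d)$x <= 5))
})

test_that("rating proportions sum to one and pool countries with equal weight", {
  # p1 (CN) rates (red, love) = 0; p2, p3 (DE) rate it 5 and 0
  df <- tiny_ratings(pids = c("p1", "p2", "p3"), countries = c("CN", "DE", "DE"))
  df$intensity[df$participant_id == "p2" & df$colour == "red" &
                 df$emotion == "love"] <- 5L
  d <- gew_dataset(df)
  pr <- rating_proportions(d)
  expect_true(all(abs(apply(pr$per_country, 1:3, sum) - 1) < 1e-9))
  expect_true(all(abs(apply(pr$pooled, 1:2, sum) - 1) < 1e-9))
  # CN: category 0 proportion 1.0 for (red, love); DE: half in category 5
  expect_equal(pr$per_country["CN", "red", "love", "0"], 1)
  expect_equal(pr$per_country["DE", "red", "love", "5"], 0.5)
  # unweighted pooling: (0 + 0.5) / 2 despite unequal country sizes
  expect_equal(pr$pooled["red", "love", "5"], 0.25)

  # duplicating all participants of one country leaves the pooled value unchanged
  df2 <- rbind(df, within(df[df$country == "DE", ], {
    participant_id <- paste0(participant_id, "_dup")
  }))
  expect_equal(rating_proportions(gew_dataset(df2))$pooled, pr$pooled)
})

test_that("vocabulary enforces its cardinalities and persists through JSON/YAML", {
  expect_error(gew_vocabulary(colour_terms = GEW_COLOUR_TERMS[-1]), "12")
  expect_error(gew_vocabulary(emotion_terms = c(GEW_EMOTION_TERMS, "awe")), "20")
  expect_error(gew_vocabulary(countries = "CN"), ">= 2")
  expect_error(gew_vocabulary(colour_terms = c(GEW_COLOUR_TERMS[-1], "RED")),
               "12 unique")
  for (ext in c(".json", ".yaml")) {
    p <- withr::local_tempfile(fileext = ext)
    write_vocabulary(gew_vocabulary(), p)
    expect_equal(read_vocabulary(p), gew_vocabulary())
  }
  shipped <- system.file("extdata", "gew_vocabulary.json", package = "gewmvpa")
  expect_equal(read_vocabulary(shipped), gew_vocabulary())
})

test_that("wide export has one row per participant and 240 named rating columns", {
  d <- gew_dataset(tiny_ratings())
  p <- withr::local_tempfile(fileext = ".csv")
  write_gew_wide(d, p)
  w <- read.csv(p)
  expect_equal(nrow(w), 2L)
  expect_equal(ncol(w), 242L)
  expect_true("red_love" %in% names(w))
})
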