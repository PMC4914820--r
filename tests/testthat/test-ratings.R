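make_records <- function(df) {
  defaults <- tibble::tibble(
    familiarity = 4L, liking = 4L, endorsed = 0L, confidence = 4L,
    music_years = 0, dance_years = 0
  )
  out <- dplyr::bind_cols(df, defaults[rep(1, nrow(df)), setdiff(names(defaults), names(df))])
  validate_ratings(out)
}

four_cat_meta <- function(n_per_cat = 2) {
  tidyr::crossing(language = c("English", "French"),
                  song_type = c("children", "folk"),
                  i = seq_len(n_per_cat)) |>
    dplyr::mutate(song_id = sprintf("%s_%s_%d", language, song_type, i)) |>
    dplyr::select(song_id, language, song_type)
}

test_that("per-participant category proportions count endorsements over presented songs", {
  meta <- four_cat_meta(4)
  fr_children <- meta$song_id[meta$language == "French" & meta$song_type == "children"]
  folk <- meta$song_id[meta$song_type == "folk"][1:8]
  recs <- make_records(tibble::tibble(
    participant_id = "p1", group = "french",
    song_id = c(fr_children, folk),
    endorsed = c(rep(1L, 4), rep(1L, 3), rep(0L, 5))
  ))
  props <- participant_category_proportions(recs, meta)
  p_frch <- props[props$language == "French" & props$song_type == "children", ]
  expect_equal(p_frch$proportion, 1.0)
  # 3 of 8 folk songs endorsed, split across the two folk categories
  folk_rows <- props[props$song_type == "folk", ]
  expect_equal(sum(folk_rows$proportion * folk_rows$n_songs) / sum(folk_rows$n_songs), 0.375)
  # a category with no presented songs is missing, not zero
  p_ench <- props[props$language == "English" & props$song_type == "children", ]
  expect_equal(p_ench$n_songs, 0L)
  expect_true(is.na(p_ench$proportion))
  # unknown song id errors
  bad <- make_records(tibble::tibble(participant_id = "p1", group = "french",
                                     song_id = "nope"))
  expect_error(participant_category_proportions(bad, meta), "unknown song id")
})

test_that("per-song aggregation averages ratings and joins rhythm features", {
  rhythm <- tibble::tibble(song_id = c("a", "b"), npvi = c(40, 30),
                           mean_note_duration_ms = c(500, 600))
  recs <- make_records(tibble::tibble(
    participant_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    group = "monolingual_american",
    song_id = rep(c("a", "b"), 4),
    familiarity = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 4L),
    endorsed = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L)
  ))
  agg <- aggregate_by_song(recs, rhythm)
  a <- agg[agg$song_id == "a", ]
  expect_equal(a$familiarity, 4)
  expect_equal(a$endorsement, 0.5)
  expect_equal(a$npvi, 40)
  expect_equal(a$tempo, 500)
  expect_equal(a$n_raters, 4L)
  # one rater per song: aggregates equal the raw ratings
  one <- make_records(tibble::tibble(participant_id = "p9", group = "french",
                                     song_id = "b", familiarity = 6L,
                                     liking = 2L, endorsed = 1L))
  agg1 <- aggregate_by_song(one, rhythm)
  expect_equal(agg1$familiarity, 6)
  expect_equal(agg1$preference, 2)
  expect_equal(agg1$endorsement, 1)
  # missing rhythm row errors with the song named
  expect_error(aggregate_by_song(
    make_records(tibble::tibble(participant_id = "p1", group = "french",
                                song_id = "zz")), rhythm), "zz")
})

synthetic_aggregates <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    song_id = sprintf("s%03d", 1:n),
    group = "french",
    n_raters = 8L,
    familiarity = runif(n, 1, 7),
    preference = runif(n, 1, 7),
    tempo = runif(n, 300, 900),
    npvi = runif(n, 5, 70)
  )
}

test_that("an exact linear response is fit perfectly and attributed to its predictor", {
  agg <- synthetic_aggregates()
  agg$endorsement <- 0.5 + 0.001 * agg$familiarity
  fit <- suppressWarnings(regress_child_directedness(agg, "french"))
  expect_equal(fit$r2_full, 1)
  # dropping familiarity leaves only chance-level fit from the noise predictors
  expect_equal(fit$predictors$r2_change[fit$predictors$predictor == "familiarity"], 1,
               tolerance = 0.02)
  others <- fit$predictors$r2_change[fit$predictors$predictor != "familiarity"]
  expect_true(all(abs(others) < 1e-9))
})

test_that("duplicated predictors raise a rank-deficiency error naming them", {
  agg <- synthetic_aggregates()
  agg$preference <- agg$familiarity
  agg$endorsement <- 0.5
  expect_error(
    regress_child_directedness(agg, "french"),
    "rank-deficient.*(familiarity.*preference|preference.*familiarity)")
})

test_that("with orthogonal centered predictors r2_change equals the squared simple r", {
  # constructed orthogonal design: columns of a scaled orthonormal basis
  n <- 32
  set.seed(21)
  qmat <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  agg <- tibble::tibble(
    song_id = sprintf("s%d", 1:n), group = "french", n_raters = 1L,
    familiarity = qmat[, 1] * 2 + 4, preference = qmat[, 2] * 2 + 4,
    tempo = qmat[, 3] * 100 + 500, npvi = qmat[, 4] * 10 + 40
  )
  set.seed(2)
  agg$endorsement <- 0.5 + 0.3 * qmat[, 1] - 0.2 * qmat[, 3] - 0.1 * qmat[, 4] +
    0.05 * rnorm(n)
  fit <- regress_child_directedness(agg, "french", min_songs = 30)
  for (i in seq_len(4)) {
    expect_equal(fit$predictors$r2_change[i], fit$predictors$r_simple[i]^2,
                 tolerance = 1e-8)
  }
})

test_that("R2 change is nonnegative and invariant to affine predictor rescaling", {
  agg <- synthetic_aggregates(seed = 4)
  set.seed(5)
  agg$endorsement <- plogis(0.2 * agg$familiarity - 0.004 * agg$tempo -
                              0.02 * agg$npvi + rnorm(60, 0, 0.3))
  fit <- regress_child_directedness(agg, "french")
  expect_true(all(fit$predictors$r2_change >= -1e-12))
  expect_gte(fit$r2_full, max(fit$predictors$r_simple^2) - 1e-12)
  scaled <- agg
  scaled$tempo <- (scaled$tempo - 500) / 120
  scaled$npvi <- scaled$npvi * 3 + 7
  fit2 <- regress_child_directedness(scaled, "french")
  expect_equal(fit2$predictors$r2_change, fit$predictors$r2_change, tolerance = 1e-9)
  expect_equal(fit2$r2_full, fit$r2_full, tolerance = 1e-9)
})

test_that("correlation helper matches closed-form cases and rejects degenerate input", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  set.seed(6)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(correlate(a, b)), 0.05)
  expect_error(correlate(x, rep(1, 20)), "zero variance")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("balanced panels: averaging participant proportions equals the pooled proportion", {
  meta <- four_cat_meta(2)
  recs <- make_records(tidyr::crossing(
    participant_id = c("p1", "p2", "p3"), song_id = meta$song_id
  ) |> dplyr::mutate(group = "french",
                     endorsed = as.integer((seq_len(dplyr::n()) %% 3) == 0)))
  props <- participant_category_proportions(recs, meta)
  joined <- dplyr::left_join(recs, meta, by = "song_id")
  pooled <- mean(joined$endorsed[joined$language == "English" & joined$song_type == "children"])
  per_part <- props[props$language == "English" & props$song_type == "children", ]
  expect_equal(mean(per_part$proportion), pooled)
})
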