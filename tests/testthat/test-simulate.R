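test_that("the ratio inverse of the pair contrast is exact", {
  expect_equal(npvi_to_ratio(0), 1)
  expect_equal(npvi_to_ratio(100), 3)
  expect_equal(pair_contrast(npvi_to_ratio(100), 1), 100)
  expect_equal(npvi_to_ratio(200 / 3), 2, tolerance = 1e-12)
  expect_error(npvi_to_ratio(200), "\\[0, 200\\)")
  expect_error(npvi_to_ratio(-1), "\\[0, 200\\)")
  # inverse property over the whole range
  v <- seq(0, 199, by = 0.5)
  expect_equal(pair_contrast(npvi_to_ratio(v), rep(1, length(v))), v,
               tolerance = 1e-12)
})

one_cell <- function(target, sd = 0, n = 5L, type = "children",
                     lang = "synthetic:English") {
  tibble::tibble(language = lang, song_type = type, n_songs = as.integer(n),
                 target_npvi = target, npvi_sd = sd)
}

test_that("generation is deterministic: same seed, byte-identical serialization", {
  cfg <- synth_config(n_songs = 4)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_note_table(generate_corpus(cfg, seed = 99), f1)
  write_note_table(generate_corpus(cfg, seed = 99), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the corpus
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_note_table(generate_corpus(cfg, seed = 100), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("a zero-target cell produces perfectly isochronous songs", {
  cfg <- synth_config(cells = one_cell(0, n = 6))
  tbl <- npvi_table(generate_corpus(cfg, seed = 2))
  expect_equal(tbl$npvi, rep(0, 6))
})

test_that("with full alternation and no jitter every song realizes its target exactly", {
  cfg <- synth_config(cells = one_cell(40.43, n = 8))
  tbl <- npvi_table(generate_corpus(cfg, seed = 3))
  expect_equal(tbl$npvi, rep(40.43, 8), tolerance = 1e-12)
  expect_equal(expected_npvi(cfg)$expected_npvi, 40.43, tolerance = 1e-12)
})

test_that("small-jitter cell means land within 1.5 nPVI units of target at n = 60", {
  cfg <- synth_config(cells = one_cell(40.43, sd = 2, n = 60))
  tbl <- npvi_table(generate_corpus(cfg, seed = 4))
  expect_lt(abs(mean(tbl$npvi) - 40.43), 1.5)
})

test_that("songs fill whole measures of their drawn meter", {
  cfg <- synth_config(n_songs = 3, alternation_prob = 0.5)
  corp <- generate_corpus(cfg, seed = 5)
  x <- tibble::as_tibble(corp)
  x$beats <- x$duration_num / x$duration_den
  by_phrase <- dplyr::summarise(dplyr::group_by(x, song_id, meter, phrase_index),
                                total = sum(beats), .groups = "drop")
  num <- as.numeric(sub("/.*", "", by_phrase$meter))
  den <- as.numeric(sub(".*/", "", by_phrase$meter))
  measures <- by_phrase$total / (num * 4 / den)
  expect_equal(measures, round(measures), tolerance = 1e-9)
  expect_true(all(measures >= 1))
})

test_that("meters are drawn from the configured distribution", {
  cfg <- synth_config(n_songs = 150,
                      cells = dplyr::bind_rows(
                        one_cell(40, n = 150),
                        one_cell(34, n = 150, lang = "synthetic:French")))
  meta <- song_meta(generate_corpus(cfg, seed = 6))
  eng <- table(meta$meter[meta$language == "synthetic:English"]) / 150
  # 4/4 dominates the stress-timed marginal; 2/4 the syllable-timed one
  expect_gt(eng[["4/4"]], 0.4)
  fre <- table(meta$meter[meta$language == "synthetic:French"]) / 150
  expect_gt(fre[["2/4"]], 0.3)
  expect_false("2/2" %in% names(fre))
})

test_that("alternation probability extremes pin the analytic expectation", {
  cfg0 <- synth_config(cells = one_cell(50), alternation_prob = 0)
  expect_equal(expected_npvi(cfg0)$expected_npvi, 0)
  cfg1 <- synth_config(cells = one_cell(50), alternation_prob = 1)
  expect_equal(expected_npvi(cfg1)$expected_npvi, 50, tolerance = 1e-12)
})

test_that("analytic expectation matches a simulation oracle for mixed configs", {
  cfg <- synth_config(cells = one_cell(45, sd = 10, n = 2000),
                      alternation_prob = 0.6)
  corp <- generate_corpus(cfg, seed = 7)
  tbl <- npvi_table(corp)
  # pair-count-weighted empirical mean, to match the analytic weighting
  emp <- sum(tbl$npvi * tbl$n_pairs_used) / sum(tbl$n_pairs_used)
  per_song <- tbl$npvi
  mc_se <- stats::sd(per_song) / sqrt(length(per_song))
  expect_lt(abs(emp - expected_npvi(cfg)$expected_npvi), 3 * mc_se)
})

test_that("config validation rejects malformed plans", {
  expect_error(synth_config(cells = one_cell(250)), "target_npvi")
  expect_error(synth_config(cells = dplyr::mutate(one_cell(40), n_songs = -1L)),
               "n_songs")
  expect_error(synth_config(alternation_prob = 1.2), "alternation_prob")
  expect_error(synth_config(meter_probs = list(`synthetic:English` = c(`4/4` = 0.5),
                                               `synthetic:French` = METER_PROBS_FRENCH)),
               "sum to 1")
})

test_that("a saturating intercept endorses every song", {
  corp <- generate_corpus(synth_config(n_songs = 3), seed = 8)
  mod <- rater_model("french", 10, "French",
                     beta = c(intercept = 20, familiarity = 0, tempo = 0, npvi = 0))
  recs <- generate_ratings(corp, list(mod), seed = 9)
  expect_equal(mean(recs$endorsed), 1)
})

test_that("zero coefficients give chance-level endorsement", {
  corp <- generate_corpus(synth_config(n_songs = 6), seed = 10)
  mod <- rater_model("french", 40, "French",
                     beta = c(intercept = 0, familiarity = 0, tempo = 0, npvi = 0))
  recs <- generate_ratings(corp, list(mod), seed = 11)
  p <- mean(recs$endorsed)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(recs)))
})

test_that("a strongly negative nPVI loading yields a negative nPVI-endorsement correlation", {
  cfg <- synth_config(n_songs = 15)
  corp <- generate_corpus(cfg, seed = 12)
  mod <- rater_model("french", 60, "French",
                     beta = c(intercept = 1.5, familiarity = 0, tempo = 0, npvi = -0.04))
  recs <- generate_ratings(corp, list(mod), seed = 13)
  tbl <- npvi_table(corp)
  agg <- aggregate_by_song(recs, tbl)
  expect_lt(correlate(agg$npvi, agg$endorsement), 0)
})

test_that("rating panels are deterministic per seed and respect the list design", {
  corp <- generate_corpus(synth_config(n_songs = 3), seed = 14)
  r1 <- generate_ratings(corpus = corp, seed = 15)
  r2 <- generate_ratings(corpus = corp, seed = 15)
  expect_identical(r1, r2)
  # each participant rates one list of roughly a fifth of the corpus
  per_part <- table(r1$participant_id)
  expect_true(all(per_part <= ceiling(12 / 5) + 1))
  # every song is rated by members of all three default groups
  cover <- table(r1$song_id, r1$group)
  expect_true(all(cover > 0))
})

test_that("own-culture and children's-song familiarity bonuses are visible", {
  cfg <- synth_config(n_songs = 25)
  corp <- generate_corpus(cfg, seed = 16)
  recs <- generate_ratings(corp, seed = 17)
  meta <- song_meta(corp)
  x <- dplyr::left_join(recs, meta[c("song_id", "language", "song_type")], by = "song_id")
  fr <- x[x$group == "french", ]
  own <- mean(fr$familiarity[fr$language == "synthetic:French"])
  other <- mean(fr$familiarity[fr$language == "synthetic:English"])
  expect_gt(own, other)
  child <- mean(x$familiarity[x$song_type == "children"])
  folk <- mean(x$familiarity[x$song_type == "folk"])
  expect_gt(child, folk)
})
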