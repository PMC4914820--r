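# Listener-rating aggregation and the four-predictor child-directedness
# regression: per listener group, the proportion of raters endorsing each
# song as "for children" is regressed on mean familiarity, mean liking
# (preference), tempo (mean note duration in ms) and nPVI, and each
# predictor's unique contribution is measured as the drop in R^2 when it is
# removed from the full model.

RATING_COLS <- c("participant_id", "group", "song_id", "familiarity", "liking",
                 "endorsed", "confidence", "music_years", "dance_years")
RATER_GROUPS <- c("monolingual_american", "bilingual_american", "french")
REG_PREDICTORS <- c("familiarity", "preference", "tempo", "npvi")

#' Read a listener-ratings table
#'
#' CSV with columns `participant_id, group, song_id, familiarity, liking,
#' endorsed (0/1), confidence, music_years, dance_years`. Familiarity,
#' liking and confidence are 1--7 integers; confidence is carried but enters
#' no analysis.
#'
#' @param path CSV path (or literal text via [I()]).
#' @return A validated tibble of rating records.
#' @export
read_ratings <- function(path) {
  x <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    song_id = readr::col_character(),
    familiarity = readr::col_integer(),
    liking = readr::col_integer(),
    endorsed = readr::col_integer(),
    confidence = readr::col_integer(),
    music_years = readr::col_double(),
    dance_years = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error: line %d: expected %s", probs$row[1], probs$expected[1]),
         call. = FALSE)
  }
  validate_ratings(x)
}

validate_ratings <- function(x) {
  x <- tibble::as_tibble(x)[RATING_COLS]
  if (nrow(x) == 0) stop("validation error: empty ratings table", call. = FALSE)
  for (col in c("familiarity", "liking", "confidence")) {
    bad <- which(x[[col]] < 1 | x[[col]] > 7)
    if (length(bad) > 0) {
      stop(sprintf("validation error: row %d: %s %d outside 1-7", bad[1], col, x[[col]][bad[1]]),
           call. = FALSE)
    }
  }
  if (any(!x$endorsed %in% c(0L, 1L))) {
    stop("validation error: endorsed must be 0/1", call. = FALSE)
  }
  if (any(!x$group %in% RATER_GROUPS)) {
    bad <- setdiff(unique(x$group), RATER_GROUPS)
    stop("validation error: unknown rater group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$music_years < 0) || any(x$dance_years < 0)) {
    stop("validation error: training years must be >= 0", call. = FALSE)
  }
  dup <- duplicated(x[c("participant_id", "song_id")])
  if (any(dup)) {
    stop(sprintf("validation error: duplicate rating for participant '%s', song '%s'",
                 x$participant_id[which(dup)[1]], x$song_id[which(dup)[1]]), call. = FALSE)
  }
  x
}

#' Per-participant endorsement proportion in each song category
#'
#' Songs fall in four categories (language of origin x song type). For each
#' participant, returns the proportion of presented songs in each category
#' endorsed as "for children". A category in which the participant heard no
#' songs is `NA` (missing), never 0.
#'
#' @param records Ratings tibble ([read_ratings()]).
#' @param meta Song metadata ([song_meta()]) mapping each rated song to a
#'   category; every rated song id must be present.
#' @return A tibble: `participant_id`, `group`, `language`, `song_type`,
#'   `n_songs`, `proportion`.
#' @export
participant_category_proportions <- function(records, meta) {
  unknown <- setdiff(unique(records$song_id), meta$song_id)
  if (length(unknown) > 0) {
    stop("unknown song id(s) in ratings: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::left_join(records, meta[c("song_id", "language", "song_type")],
                        by = "song_id")
  cats <- unique(meta[c("language", "song_type")])
  grid <- tidyr::crossing(
    unique(x[c("participant_id", "group")]),
    cats
  )
  counts <- dplyr::summarise(
    dplyr::group_by(x, .data$participant_id, .data$group, .data$language, .data$song_type),
    n_songs = dplyr::n(),
    proportion = mean(.data$endorsed),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, counts,
                          by = c("participant_id", "group", "language", "song_type"))
  out$n_songs[is.na(out$n_songs)] <- 0L
  out
}

#' Aggregate ratings per song and listener group
#'
#' For each song and group: mean familiarity, mean liking and the proportion
#' of that group's raters endorsing the song as "for children", joined with
#' the song's nPVI and tempo (mean note duration, ms) from the rhythm table.
#' A song with zero raters in a group simply has no row for that group.
#'
#' @param records Ratings tibble.
#' @param rhythm_tbl Per-song rhythm table ([npvi_table()]).
#' @return A tibble: `song_id`, `group`, `n_raters`, `familiarity`,
#'   `preference`, `endorsement`, `npvi`, `tempo`.
#' @export
aggregate_by_song <- function(records, rhythm_tbl) {
  missing <- setdiff(unique(records$song_id), rhythm_tbl$song_id)
  if (length(missing) > 0) {
    stop("no rhythm data for song(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(records, .data$song_id, .data$group),
    n_raters = dplyr::n(),
    familiarity = mean(.data$familiarity),
    preference = mean(.data$liking),
    endorsement = mean(.data$endorsed),
    .groups = "drop"
  )
  joined <- dplyr::left_join(
    agg,
    tibble::tibble(song_id = rhythm_tbl$song_id, npvi = rhythm_tbl$npvi,
                   tempo = rhythm_tbl$mean_note_duration_ms),
    by = "song_id"
  )
  joined
}

#' Child-directedness regression with per-predictor R-squared change
#'
#' Ordinary least squares of a group's per-song endorsement proportion on
#' familiarity, preference, tempo and nPVI (predictors entered raw). For
#' each predictor reports the simple Pearson correlation with the response,
#' and the R-squared change: the drop in the full model's R-squared when
#' that predictor alone is removed, with the nested-model F test.
#'
#' @param aggregates Output of [aggregate_by_song()].
#' @param group Listener group to fit.
#' @param min_songs Minimum complete songs required (default 10).
#' @return A list: `group`, `n_songs`, `coefficients`, `r2_full`,
#'   `f_full`, `p_full`, and a `predictors` tibble with `r_simple`,
#'   `r2_change`, `f_change`, `p_change`.
#' @export
regress_child_directedness <- function(aggregates, group, min_songs = 10) {
  x <- aggregates[aggregates$group == group, ]
  x <- x[stats::complete.cases(x[c("endorsement", REG_PREDICTORS)]), ]
  if (nrow(x) < min_songs) {
    stop(sprintf("group '%s': only %d complete songs (need >= %d)",
                 group, nrow(x), min_songs), call. = FALSE)
  }
  mm <- as.matrix(x[REG_PREDICTORS])
  qr_rank <- qr(cbind(1, mm))$rank
  if (qr_rank < ncol(mm) + 1) {
    cors <- stats::cor(mm)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop(sprintf("rank-deficient design: predictors '%s' and '%s' are collinear",
                 REG_PREDICTORS[worst[1]], REG_PREDICTORS[worst[2]]), call. = FALSE)
  }
  full <- stats::lm(endorsement ~ familiarity + preference + tempo + npvi, data = x)
  r2_full <- summary(full)$r.squared
  fstat <- summary(full)$fstatistic
  p_full <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)

  pred_rows <- lapply(REG_PREDICTORS, function(v) {
    sub <- stats::lm(stats::reformulate(setdiff(REG_PREDICTORS, v), "endorsement"),
                     data = x)
    cmp <- stats::anova(sub, full)
    tibble::tibble(
      predictor = v,
      r_simple = correlate(x[[v]], x$endorsement),
      r2_change = r2_full - summary(sub)$r.squared,
      f_change = cmp$F[2],
      p_change = cmp$`Pr(>F)`[2]
    )
  })
  list(
    group = group,
    n_songs = nrow(x),
    coefficients = stats::coef(full),
    r2_full = r2_full,
    f_full = unname(fstat[1]),
    p_full = unname(p_full),
    predictors = dplyr::bind_rows(pred_rows)
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("correlate needs equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}
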