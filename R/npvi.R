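# The normalized Pairwise Variability Index (nPVI):
#   nPVI = 100/(m-1) * sum_{k=1}^{m-1} |d_k - d_{k+1}| / ((d_k + d_{k+1})/2)
# with m elements of duration d_k. 0 = perfect isochrony; the statistic
# approaches (never reaches) 200 as adjacent contrast grows. Pairs that
# straddle phrase boundaries are excluded at the song level.

#' Durational contrast of one pair of durations
#'
#' `100 * |d1 - d2| / ((d1 + d2) / 2)`: the contribution of one adjacent pair
#' to the nPVI. Symmetric in its arguments and scale-free; ranges over
#' `[0, 200)`.
#'
#' @param d1,d2 Positive durations (vectorized).
#' @return Numeric contrast values.
#' @export
pair_contrast <- function(d1, d2) {
  if (any(!is.finite(d1) | d1 <= 0) || any(!is.finite(d2) | d2 <= 0)) {
    stop("durations must be positive and finite", call. = FALSE)
  }
  100 * abs(d1 - d2) / ((d1 + d2) / 2)
}

#' nPVI of a single duration sequence
#'
#' Mean of [pair_contrast()] over the `m - 1` adjacent pairs of the sequence.
#' A sequence with fewer than two elements has no pairs: the result carries
#' `npvi = NA` and `n_pairs = 0`, which is distinct from an isochronous
#' sequence (`npvi = 0`).
#'
#' @param durations Numeric vector of positive durations.
#' @return A list with elements `npvi` and `n_pairs`.
#' @export
npvi_series <- function(durations) {
  m <- length(durations)
  if (m < 2) {
    return(list(npvi = NA_real_, n_pairs = 0L))
  }
  contrasts <- pair_contrast(durations[-m], durations[-1])
  list(npvi = mean(contrasts), n_pairs = m - 1L)
}

#' Per-song nPVI with phrase-boundary pair exclusion
#'
#' Computes the song-level statistic from the phrase-segmented duration
#' series, omitting the duration pairs that straddle phrase boundaries.
#' Under the default `"pooled_pairs"` aggregation all within-phrase adjacent
#' contrasts are pooled and averaged; under `"phrase_mean"` each contributing
#' phrase's nPVI is computed first and the per-phrase values are averaged
#' unweighted. Phrases with a single element contribute no pairs and are
#' skipped. The two aggregations coincide for single-phrase songs.
#'
#' @param corpus A `song_corpus`.
#' @param song_id Song to score; may be omitted for a one-song corpus.
#' @param policy Rest policy passed to [duration_series()].
#' @param aggregation `"pooled_pairs"` (default) or `"phrase_mean"`.
#' @return A one-row tibble: `song_id`, `npvi`, `n_pairs_used`,
#'   `n_pairs_excluded` (= contributing phrases minus one).
#' @export
npvi_song <- function(corpus, song_id = NULL, policy = "notated",
                      aggregation = c("pooled_pairs", "phrase_mean")) {
  aggregation <- match.arg(aggregation)
  x <- tibble::as_tibble(corpus)
  if (is.null(song_id)) {
    if (length(unique(x$song_id)) != 1) {
      stop("corpus holds multiple songs; give song_id", call. = FALSE)
    }
    song_id <- x$song_id[1]
  }
  s <- x[x$song_id == song_id, ]
  if (nrow(s) == 0) stop(sprintf("song '%s' not in corpus", song_id), call. = FALSE)
  ds <- suppressWarnings(duration_series(as_song_corpus(s), policy = policy))
  res <- npvi_from_series(ds$duration, ds$phrase_index, song_id, aggregation)
  tibble::tibble(song_id = song_id, npvi = res$npvi,
                 n_pairs_used = res$n_pairs_used,
                 n_pairs_excluded = res$n_pairs_excluded)
}

# Shared core over one song's element durations and their phrase indices.
npvi_from_series <- function(duration, phrase_index, song_id, aggregation) {
  per_phrase <- lapply(split(duration, phrase_index), npvi_series)
  n_pairs <- vapply(per_phrase, function(p) p$n_pairs, integer(1))
  contributing <- n_pairs >= 1L
  if (!any(contributing)) {
    stop(sprintf("undefined nPVI: song '%s' has no phrase with two or more elements",
                 song_id), call. = FALSE)
  }
  vals <- vapply(per_phrase, function(p) p$npvi, numeric(1))[contributing]
  wts <- n_pairs[contributing]
  npvi <- if (aggregation == "pooled_pairs") {
    sum(vals * wts) / sum(wts)
  } else {
    mean(vals)
  }
  # phrases with >=1 element each meet at a junction whose pair is omitted
  list(npvi = npvi, n_pairs_used = sum(wts),
       n_pairs_excluded = max(length(per_phrase) - 1L, 0L))
}

#' Mean note duration of a song in milliseconds
#'
#' The arithmetic mean of the song's element durations (after the same
#' preprocessing as the nPVI) converted to milliseconds using the song's
#' effective tempo: the notated tempo when present, otherwise
#' `default_ms_per_quarter` (600 ms per quarter note, i.e. 100 bpm). Used as
#' the "tempo" predictor of the ratings regression: larger values mean a
#' slower song.
#'
#' @inheritParams npvi_song
#' @param default_ms_per_quarter Tempo applied when no tempo is notated.
#' @return Mean element duration in ms.
#' @export
mean_note_duration_ms <- function(corpus, song_id = NULL, policy = "notated",
                                  default_ms_per_quarter = 600) {
  x <- tibble::as_tibble(corpus)
  if (is.null(song_id)) {
    if (length(unique(x$song_id)) != 1) {
      stop("corpus holds multiple songs; give song_id", call. = FALSE)
    }
    song_id <- x$song_id[1]
  }
  s <- x[x$song_id == song_id, ]
  if (nrow(s) == 0) stop(sprintf("song '%s' not in corpus", song_id), call. = FALSE)
  tempo <- s$tempo_ms_per_quarter[1]
  if (is.na(tempo)) tempo <- default_ms_per_quarter
  ds <- suppressWarnings(duration_series(as_song_corpus(s), policy = policy))
  mean(ds$duration) * tempo
}

#' Batch per-song rhythm table
#'
#' Applies [npvi_song()] and [mean_note_duration_ms()] to every song of a
#' corpus. Songs whose nPVI is undefined (no phrase with two or more
#' elements) get an `NA` row and a warning rather than an error.
#'
#' @inheritParams npvi_song
#' @param default_ms_per_quarter Tempo applied when no tempo is notated.
#' @return A tibble: `song_id`, `language`, `song_type`, `npvi`,
#'   `n_pairs_used`, `n_pairs_excluded`, `mean_note_duration_ms`.
#' @export
npvi_table <- function(corpus, policy = "notated",
                       aggregation = "pooled_pairs",
                       default_ms_per_quarter = 600) {
  ds_all <- suppressWarnings(duration_series(corpus, policy = policy))
  meta <- song_meta(corpus)
  ds_by_song <- split(seq_len(nrow(ds_all)),
                      factor(ds_all$song_id, levels = meta$song_id))
  n <- nrow(meta)
  npvi <- rep(NA_real_, n)
  used <- integer(n)
  excluded <- integer(n)
  mnd <- rep(NA_real_, n)
  undefined <- character(0)
  for (i in seq_len(n)) {
    sid <- meta$song_id[i]
    jj <- ds_by_song[[i]]
    res <- tryCatch(
      npvi_from_series(ds_all$duration[jj], ds_all$phrase_index[jj], sid, aggregation),
      error = function(e) {
        undefined <<- c(undefined, sid)
        NULL
      }
    )
    if (!is.null(res)) {
      npvi[i] <- res$npvi
      used[i] <- res$n_pairs_used
      excluded[i] <- res$n_pairs_excluded
    }
    tempo <- meta$tempo_ms_per_quarter[i]
    if (is.na(tempo)) tempo <- default_ms_per_quarter
    if (length(jj) > 0) mnd[i] <- mean(ds_all$duration[jj]) * tempo
  }
  if (length(undefined) > 0) {
    warning("undefined nPVI for songs: ", paste(undefined, collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    song_id = meta$song_id, language = meta$language, song_type = meta$song_type,
    npvi = npvi, n_pairs_used = used, n_pairs_excluded = excluded,
    mean_note_duration_ms = mnd
  )
}
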