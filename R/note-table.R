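# Tabular note-event dialect: one row per note event, song metadata repeated
# on every row. Durations are exact rationals (duration_num / duration_den in
# quarter-note beats) so tuplets survive serialization without rounding.

NOTE_TABLE_COLS <- c(
  "song_id", "language", "song_type", "meter", "key", "tempo_ms_per_quarter",
  "phrase_index", "note_index", "pitch", "duration_num", "duration_den",
  "tie_to_next", "grace"
)

SONG_TYPES <- c("children", "folk")

#' Construct and validate a song corpus
#'
#' A corpus is a tibble with one row per note event and the columns of the
#' note-table dialect (see [read_note_table()]). `as_song_corpus()` checks all
#' structural invariants: positive rational durations, pitches in 0--127 or
#' `NA` (rest), known song types and languages, meters with denominator 2, 4
#' or 8, phrase and note indices consecutive from 0, constant per-song
#' metadata, unique song ids, and no ties that dangle past a phrase end or
#' involve a rest.
#'
#' @param x A data frame with the note-table columns. `pitch` may be given as
#'   an integer vector with `NA` for rests, or as character using `"rest"`.
#' @param provenance Free-text metadata attached to the corpus.
#' @return A `song_corpus` tibble.
#' @export
as_song_corpus <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(NOTE_TABLE_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("validation error: missing note-table columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[NOTE_TABLE_COLS]
  if (is.character(x$pitch)) {
    p <- trimws(x$pitch)
    is_rest <- p == "rest"
    pn <- suppressWarnings(as.integer(p))
    if (any(!is_rest & is.na(pn))) {
      bad <- which(!is_rest & is.na(pn))[1]
      stop(sprintf("validation error: row %d: pitch '%s' is neither 0-127 nor 'rest'",
                   bad, x$pitch[bad]), call. = FALSE)
    }
    x$pitch <- ifelse(is_rest, NA_integer_, pn)
  }
  x$pitch <- as.integer(x$pitch)
  x$phrase_index <- as.integer(x$phrase_index)
  x$note_index <- as.integer(x$note_index)
  x$duration_num <- as.integer(x$duration_num)
  x$duration_den <- as.integer(x$duration_den)
  x$tie_to_next <- as.logical(x$tie_to_next)
  x$grace <- as.logical(x$grace)
  x$tempo_ms_per_quarter <- as.numeric(x$tempo_ms_per_quarter)

  validate_song_corpus(x)
  structure(x,
            class = c("song_corpus", class(tibble::tibble()))) -> out
  attr(out, "provenance") <- provenance %||% "unspecified"
  out
}

validate_song_corpus <- function(x) {
  if (nrow(x) == 0) stop("validation error: corpus has no note events", call. = FALSE)
  bad <- which(!is.finite(x$duration_num) | !is.finite(x$duration_den) |
                 x$duration_num <= 0 | x$duration_den <= 0)
  if (length(bad) > 0) {
    stop(sprintf("validation error: row %d: duration must be a positive rational (got %s/%s)",
                 bad[1], x$duration_num[bad[1]], x$duration_den[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.na(x$pitch) & (x$pitch < 0 | x$pitch > 127))
  if (length(bad) > 0) {
    stop(sprintf("validation error: row %d: pitch %d outside 0-127", bad[1], x$pitch[bad[1]]),
         call. = FALSE)
  }
  bad <- which(!(x$song_type %in% SONG_TYPES))
  if (length(bad) > 0) {
    stop(sprintf("validation error: row %d: unknown song_type '%s'", bad[1], x$song_type[bad[1]]),
         call. = FALSE)
  }
  lang_ok <- x$language %in% c("English", "French") | startsWith(x$language, "synthetic:")
  if (any(!lang_ok)) {
    bad <- which(!lang_ok)[1]
    stop(sprintf("validation error: row %d: unknown language '%s'", bad, x$language[bad]),
         call. = FALSE)
  }
  mu <- unique(x$meter)
  ok_meter <- grepl("^[0-9]+/(2|4|8)$", mu)
  if (any(!ok_meter)) {
    bad_val <- mu[!ok_meter][1]
    bad <- which(x$meter == bad_val)[1]
    stop(sprintf("validation error: row %d: meter '%s' must be n/d with d in {2,4,8}",
                 bad, bad_val), call. = FALSE)
  }
  bad <- which(!is.na(x$tempo_ms_per_quarter) & x$tempo_ms_per_quarter <= 0)
  if (length(bad) > 0) {
    stop(sprintf("validation error: row %d: tempo_ms_per_quarter must be positive", bad[1]),
         call. = FALSE)
  }
  bad <- which(x$tie_to_next & is.na(x$pitch))
  if (length(bad) > 0) {
    stop(sprintf("validation error: row %d: a rest cannot be tied", bad[1]), call. = FALSE)
  }

  idx_by_song <- split(seq_len(nrow(x)), x$song_id)
  for (sid in names(idx_by_song)) {
    ii <- idx_by_song[[sid]]
    for (col in c("language", "song_type", "meter", "key")) {
      if (length(unique(x[[col]][ii])) != 1) {
        stop(sprintf("validation error: song '%s': column %s not constant within song", sid, col),
             call. = FALSE)
      }
    }
    tempo <- x$tempo_ms_per_quarter[ii]
    if (!(all(is.na(tempo)) || (!anyNA(tempo) && length(unique(tempo)) == 1))) {
      stop(sprintf("validation error: song '%s': tempo_ms_per_quarter not constant", sid),
           call. = FALSE)
    }
    ph_all <- x$phrase_index[ii]
    ph <- sort(unique(ph_all))
    if (!identical(ph, seq(0L, length(ph) - 1L))) {
      stop(sprintf("validation error: song '%s': phrase_index not consecutive from 0 (saw %s)",
                   sid, paste(ph, collapse = ",")), call. = FALSE)
    }
    for (jj in split(ii, ph_all)) {
      p <- x$phrase_index[jj[1]]
      ni <- x$note_index[jj]
      if (!identical(sort(ni), seq(0L, length(ni) - 1L))) {
        stop(sprintf("validation error: song '%s' phrase %d: note_index not consecutive from 0",
                     sid, p), call. = FALSE)
      }
      ord <- order(ni)
      tie <- x$tie_to_next[jj][ord]
      if (tie[length(tie)]) {
        stop(sprintf("validation error: song '%s' phrase %d: tie_to_next set on last note of phrase",
                     sid, p), call. = FALSE)
      }
      nxt_pitch <- x$pitch[jj][ord]
      if (any(tie[-length(tie)] & is.na(nxt_pitch[-1]))) {
        stop(sprintf("validation error: song '%s' phrase %d: note tied into a rest", sid, p),
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Read a corpus from the note-table CSV dialect
#'
#' The dialect is UTF-8 CSV with a header row and columns `song_id, language,
#' song_type, meter, key, tempo_ms_per_quarter, phrase_index, note_index,
#' pitch, duration_num, duration_den, tie_to_next, grace`. `pitch` is an
#' integer 0--127 or the literal `rest`; durations are exact rationals in
#' quarter-note beats; `tempo_ms_per_quarter` may be blank.
#'
#' @param path Path to a CSV file (or literal text via [I()]).
#' @return A validated `song_corpus` tibble.
#' @export
read_note_table <- function(path) {
  x <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      song_id = readr::col_character(),
      language = readr::col_character(),
      song_type = readr::col_character(),
      meter = readr::col_character(),
      key = readr::col_character(),
      tempo_ms_per_quarter = readr::col_double(),
      phrase_index = readr::col_integer(),
      note_index = readr::col_integer(),
      pitch = readr::col_character(),
      duration_num = readr::col_integer(),
      duration_den = readr::col_integer(),
      tie_to_next = readr::col_integer(),
      grace = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error: line %d: expected %s", probs$row[1], probs$expected[1]),
         call. = FALSE)
  }
  as_song_corpus(x, provenance = paste0("read_note_table:", if (inherits(path, "AsIs")) "<inline>" else path))
}

#' Write a corpus to the note-table CSV dialect
#'
#' Inverse of [read_note_table()]: `read_note_table(write_note_table(x, f))`
#' reproduces `x` exactly (rational durations are preserved).
#'
#' @param corpus A `song_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_note_table <- function(corpus, path) {
  x <- tibble::as_tibble(corpus)[NOTE_TABLE_COLS]
  x$pitch <- ifelse(is.na(x$pitch), "rest", as.character(x$pitch))
  x$tie_to_next <- as.integer(x$tie_to_next)
  x$grace <- as.integer(x$grace)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Per-song metadata table
#'
#' @param corpus A `song_corpus`.
#' @return A tibble with one row per song: `song_id, language, song_type,
#'   meter, key, tempo_ms_per_quarter, n_phrases, n_events`.
#' @export
song_meta <- function(corpus) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(corpus), .data$song_id),
    language = .data$language[1],
    song_type = .data$song_type[1],
    meter = .data$meter[1],
    key = .data$key[1],
    tempo_ms_per_quarter = .data$tempo_ms_per_quarter[1],
    n_phrases = dplyr::n_distinct(.data$phrase_index),
    n_events = dplyr::n(),
    .groups = "drop"
  )
}

# measure length of a meter string, in quarter-note beats
meter_beats <- function(meter) {
  g <- regmatches(meter, regexec("^([0-9]+)/([0-9]+)$", meter))
  vapply(g, function(x) as.numeric(x[2]) * 4 / as.numeric(x[3]), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
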