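# Fixture builders and independent oracles, built in code.

# Mini note DSL: each element is "num/den" with optional prefixes
# "r" (rest), "g" (grace) and optional suffix "~" (tie to next).
# e.g. "1/1", "r1/2", "g1/4", "1/1~".
song_rows <- function(phrases, song_id = "s1", language = "English",
                      song_type = "children", meter = "4/4", key = "C",
                      tempo = NA_real_, pitch = 67L) {
  rows <- list()
  for (p in seq_along(phrases)) {
    for (i in seq_along(phrases[[p]])) {
      tok <- phrases[[p]][i]
      tie <- grepl("~$", tok)
      tok <- sub("~$", "", tok)
      rest <- grepl("^r", tok)
      grace <- grepl("^g", tok)
      tok <- sub("^[rg]", "", tok)
      nd <- as.integer(strsplit(tok, "/", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        song_id = song_id, language = language, song_type = song_type,
        meter = meter, key = key, tempo_ms_per_quarter = tempo,
        phrase_index = p - 1L, note_index = i - 1L,
        pitch = if (rest) NA_integer_ else pitch,
        duration_num = nd[1], duration_den = nd[2],
        tie_to_next = tie, grace = grace
      )
    }
  }
  dplyr::bind_rows(rows)
}

make_corpus <- function(...) as_song_corpus(dplyr::bind_rows(...))

# beats -> one-phrase-per-vector song from plain numeric durations
# (denominator 64 keeps typical test values exact)
song_from_beats <- function(phrases, den = 64L, ...) {
  song_rows(lapply(phrases, function(d) sprintf("%d/%d", as.integer(round(d * den)), den)), ...)
}

# Independent naive double-loop oracle for the statistic.
naive_npvi <- function(d) {
  m <- length(d)
  s <- 0
  for (k in 1:(m - 1)) {
    s <- s + abs(d[k] - d[k + 1]) / ((d[k] + d[k + 1]) / 2)
  }
  100 * s / (m - 1)
}

naive_npvi_song <- function(phrase_list, aggregation = "pooled_pairs") {
  phrase_list <- phrase_list[vapply(phrase_list, length, integer(1)) >= 2]
  if (aggregation == "pooled_pairs") {
    contrasts <- c()
    for (d in phrase_list) {
      for (k in 1:(length(d) - 1)) {
        contrasts <- c(contrasts, 100 * abs(d[k] - d[k + 1]) / ((d[k] + d[k + 1]) / 2))
      }
    }
    mean(contrasts)
  } else {
    mean(vapply(phrase_list, naive_npvi, numeric(1)))
  }
}
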