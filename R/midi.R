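# Minimal Standard MIDI File (format 0/1) support for monophonic melodies.
# Writing uses 480 ticks per quarter; reading accepts any resolution.
# Phrase boundaries travel as marker meta-events named "phrase".

MIDI_TPQ <- 480L

vlq_encode <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

uint_be <- function(x, n) {
  out <- integer(n)
  for (i in n:1) {
    out[i] <- x %% 256L
    x <- x %/% 256L
  }
  as.raw(out)
}

KEY_PC <- c(C = 0L, `C#` = 1L, Db = 1L, D = 2L, `D#` = 3L, Eb = 3L, E = 4L,
            F = 5L, `F#` = 6L, Gb = 6L, G = 7L, `G#` = 8L, Ab = 8L, A = 9L,
            `A#` = 10L, Bb = 10L, B = 11L)

# Semitone shift taking `key` to C major (or, for minor keys, to A minor).
# direction: "nearest" (ties resolve downward), "up", or "down".
key_shift_to_c <- function(key, direction = c("nearest", "up", "down")) {
  direction <- match.arg(direction)
  minor <- grepl("m$", key)
  root <- sub("m$", "", key)
  if (!root %in% names(KEY_PC)) {
    stop(sprintf("unknown key label '%s'", key), call. = FALSE)
  }
  target <- if (minor) 9L else 0L
  up <- (target - KEY_PC[[root]]) %% 12L
  down <- up - 12L
  switch(direction,
         up = up,
         down = if (up == 0L) 0L else down,
         nearest = if (up <= 6L) up else down)
}

# Merge tie chains into single sounding notes; returns tibble with
# tick onset/duration (at `tpq`) and pitch (NA = rest), one song.
song_to_tick_events <- function(song_rows, tpq = MIDI_TPQ) {
  s <- song_rows[order(song_rows$phrase_index, song_rows$note_index), ]
  beats_num <- s$duration_num
  beats_den <- s$duration_den
  # absolute onset in ticks, accumulated exactly then rounded once per event
  frac <- beats_num / beats_den
  onset_beats <- cumsum(c(0, frac[-length(frac)]))
  tick_on <- round(onset_beats * tpq)
  tick_off <- round((onset_beats + frac) * tpq)
  out <- tibble::tibble(
    phrase_index = s$phrase_index,
    pitch = s$pitch,
    tick_on = tick_on,
    tick_off = tick_off,
    tie_to_next = s$tie_to_next,
    grace = s$grace
  )
  # merge tie chains: extend first note of the chain, drop continuations
  drop <- logical(nrow(out))
  i <- 1L
  while (i <= nrow(out)) {
    j <- i
    while (j <= nrow(out) && out$tie_to_next[j]) {
      j <- j + 1L
    }
    if (j > i) {
      out$tick_off[i] <- out$tick_off[j]
      drop[(i + 1L):j] <- TRUE
    }
    i <- j + 1L
  }
  out[!drop, ]
}

#' Render a song as a Standard MIDI File
#'
#' Writes a single monophonic format-0 track at 480 ticks per quarter note.
#' The tempo meta-event is the song's notated tempo when present, otherwise
#' the default of 600 ms per quarter (100 bpm). Phrase starts (after the
#' first) are marked with marker meta-events named `"phrase"`. Tied notes are
#' merged into one sounding note; rests become silent gaps.
#'
#' @param corpus A `song_corpus`.
#' @param song_id Song to render; may be omitted when the corpus holds one song.
#' @param path Optional output file; when `NULL` the raw bytes are returned.
#' @param transpose_to_c Transpose to C major (minor keys go to A minor)?
#' @param transpose_direction `"nearest"`, `"up"` or `"down"`.
#' @param default_ms_per_quarter Tempo applied when the song has no notated
#'   tempo (ms per quarter note).
#' @return Raw MIDI bytes (invisibly, when `path` is given).
#' @export
render_midi <- function(corpus, song_id = NULL, path = NULL,
                        transpose_to_c = FALSE,
                        transpose_direction = "nearest",
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

  tempo_ms <- s$tempo_ms_per_quarter[1]
  if (is.na(tempo_ms)) tempo_ms <- default_ms_per_quarter
  shift <- 0L
  if (transpose_to_c) {
    shift <- key_shift_to_c(s$key[1], transpose_direction)
  }

  ev <- song_to_tick_events(s)
  sounding <- ev[!is.na(ev$pitch), ]
  pitches <- sounding$pitch + shift
  if (length(pitches) > 0 && (min(pitches) < 0 || max(pitches) > 127)) {
    shift <- shift + if (min(pitches) < 0) 12L else -12L
    pitches <- sounding$pitch + shift
  }

  meter <- s$meter[1]
  mg <- as.integer(regmatches(meter, regexec("^([0-9]+)/([0-9]+)$", meter))[[1]][2:3])

  # event list: (tick, rank, bytes)
  events <- list()
  add <- function(tick, rank, bytes) {
    events[[length(events) + 1L]] <<- list(tick = tick, rank = rank, bytes = bytes)
  }
  add(0L, 0L, c(as.raw(c(0xFF, 0x51, 0x03)), uint_be(round(tempo_ms * 1000), 3L)))
  add(0L, 1L, as.raw(c(0xFF, 0x58, 0x04, mg[1], as.integer(log2(mg[2])), 24L, 8L)))
  phrase_start_ticks <- vapply(
    split(ev$tick_on, ev$phrase_index), min, numeric(1)
  )
  for (pt in phrase_start_ticks[-1]) {
    add(as.integer(pt), 2L, c(as.raw(c(0xFF, 0x06)), vlq_encode(6L), charToRaw("phrase")))
  }
  if (nrow(sounding) > 0) {
    for (i in seq_len(nrow(sounding))) {
      add(as.integer(sounding$tick_on[i]), 4L,
          as.raw(c(0x90, pitches[i], 64L)))
      add(as.integer(sounding$tick_off[i]), 3L,
          as.raw(c(0x80, pitches[i], 0L)))
    }
  }
  end_tick <- max(vapply(events, function(e) e$tick, numeric(1)), ev$tick_off)
  add(as.integer(end_tick), 5L, as.raw(c(0xFF, 0x2F, 0x00)))

  ord <- order(vapply(events, function(e) e$tick, numeric(1)),
               vapply(events, function(e) e$rank, numeric(1)))
  events <- events[ord]
  track <- raw(0)
  prev <- 0L
  for (e in events) {
    track <- c(track, vlq_encode(e$tick - prev), e$bytes)
    prev <- e$tick
  }
  header <- c(charToRaw("MThd"), uint_be(6L, 4L), uint_be(0L, 2L),
              uint_be(1L, 2L), uint_be(MIDI_TPQ, 2L))
  bytes <- c(header, charToRaw("MTrk"), uint_be(length(track), 4L), track)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

read_vlq <- function(bytes, pos) {
  val <- 0L
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128L + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

parse_midi_track <- function(bytes, pos, len) {
  end <- pos + len
  tick <- 0
  status <- NULL
  out <- list()
  while (pos < end) {
    d <- read_vlq(bytes, pos)
    pos <- d$pos
    tick <- tick + d$value
    b <- as.integer(bytes[pos])
    if (b >= 128L) {
      status <- b
      pos <- pos + 1L
    } else if (is.null(status)) {
      stop("parse error: data byte with no running status", call. = FALSE)
    }
    if (status == 255L) { # meta
      type <- as.integer(bytes[pos]); pos <- pos + 1L
      l <- read_vlq(bytes, pos); pos <- l$pos
      data <- if (l$value > 0) bytes[pos:(pos + l$value - 1L)] else raw(0)
      pos <- pos + l$value
      out[[length(out) + 1L]] <- list(tick = tick, kind = "meta", type = type, data = data)
      status <- NULL
    } else if (status >= 240L) {
      l <- read_vlq(bytes, pos); pos <- l$pos + l$value  # sysex, skip
      status <- NULL
    } else {
      hi <- status %/% 16L
      n_data <- if (hi %in% c(12L, 13L)) 1L else 2L
      d1 <- as.integer(bytes[pos])
      d2 <- if (n_data == 2L) as.integer(bytes[pos + 1L]) else NA_integer_
      pos <- pos + n_data
      out[[length(out) + 1L]] <- list(tick = tick, kind = "channel", status = status,
                                      d1 = d1, d2 = d2)
    }
  }
  out
}

#' Parse a monophonic Standard MIDI File into a song corpus
#'
#' Note-on/off pairs become note events with onsets and durations in
#' quarter-note beats (exact rationals over the file's resolution). Phrases
#' are split either at marker meta-events (`phrase_policy = "marker"`) or at
#' silent gaps of at least `rest_gap_beats` (`phrase_policy = "rest_gap"`).
#' Shorter gaps become rest events. MIDI carries no corpus metadata, so song
#' id, language, song type and key are supplied as arguments; meter and tempo
#' are taken from the file's time-signature and tempo meta-events when
#' present.
#'
#' @param path Path to a MIDI file, or a raw vector of MIDI bytes.
#' @param phrase_policy `"marker"` or `"rest_gap"`.
#' @param rest_gap_beats Silence threshold (beats) starting a new phrase under
#'   the `rest_gap` policy.
#' @param song_id,language,song_type,key Metadata for the resulting song.
#' @return A one-song `song_corpus`.
#' @export
parse_midi <- function(path, phrase_policy = c("marker", "rest_gap"),
                       rest_gap_beats = 2,
                       song_id = "midi_song", language = "synthetic:midi",
                       song_type = "folk", key = "C") {
  phrase_policy <- match.arg(phrase_policy)
  bytes <- if (is.raw(path)) path else readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop("parse error: not a Standard MIDI File", call. = FALSE)
  }
  be <- function(idx) sum(as.integer(bytes[idx]) * 256^((length(idx) - 1):0))
  format <- be(9:10)
  ntrk <- be(11:12)
  division <- be(13:14)
  if (format > 1) stop("parse error: only MIDI formats 0 and 1 supported", call. = FALSE)
  if (division >= 32768) stop("parse error: SMPTE time division unsupported", call. = FALSE)

  pos <- 15L
  events <- list()
  for (t in seq_len(ntrk)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop("parse error: missing MTrk chunk", call. = FALSE)
    }
    len <- be(pos + 4:7)
    events <- c(events, parse_midi_track(bytes, pos + 8L, len))
    pos <- pos + 8L + len
  }
  ticks <- vapply(events, function(e) e$tick, numeric(1))
  events <- events[order(ticks)]

  tempo_ms <- NA_real_
  meter <- "4/4"
  marker_ticks <- numeric(0)
  notes <- list()
  active <- NULL
  for (e in events) {
    if (e$kind == "meta") {
      if (e$type == 81L && is.na(tempo_ms)) {
        tempo_ms <- sum(as.integer(e$data) * 256^(2:0)) / 1000
      } else if (e$type == 88L) {
        meter <- sprintf("%d/%d", as.integer(e$data[1]), 2^as.integer(e$data[2]))
      } else if (e$type == 6L && identical(rawToChar(e$data), "phrase")) {
        marker_ticks <- c(marker_ticks, e$tick)
      }
    } else {
      hi <- e$status %/% 16L
      is_on <- hi == 9L && e$d2 > 0L
      is_off <- hi == 8L || (hi == 9L && e$d2 == 0L)
      if (is_on) {
        if (!is.null(active)) {
          stop(sprintf(
            "polyphony error: note-on at tick %d while note from tick %d still sounding",
            e$tick, active$tick), call. = FALSE)
        }
        active <- list(pitch = e$d1, tick = e$tick)
      } else if (is_off) {
        if (!is.null(active) && active$pitch == e$d1) {
          notes[[length(notes) + 1L]] <- list(pitch = active$pitch,
                                              on = active$tick, off = e$tick)
          active <- NULL
        }
      }
    }
  }
  if (length(notes) == 0) stop("parse error: MIDI file contains no notes", call. = FALSE)

  nt <- tibble::tibble(
    pitch = vapply(notes, function(n) n$pitch, numeric(1)),
    on = vapply(notes, function(n) n$on, numeric(1)),
    off = vapply(notes, function(n) n$off, numeric(1))
  )
  nt <- nt[order(nt$on), ]

  # insert rests for gaps; decide phrase boundaries
  gap_ticks <- rest_gap_beats * division
  rows <- list()
  phrase <- 0L
  prev_off <- nt$on[1] # no leading rest before the first note
  for (i in seq_len(nrow(nt))) {
    gap <- nt$on[i] - prev_off
    new_phrase <- FALSE
    if (phrase_policy == "marker") {
      if (any(marker_ticks > prev_off - 1e-9 & marker_ticks <= nt$on[i] + 1e-9) && i > 1) {
        new_phrase <- TRUE
      }
    } else if (gap >= gap_ticks && i > 1) {
      new_phrase <- TRUE
    }
    if (new_phrase) {
      phrase <- phrase + 1L
      gap <- 0 # silence at a phrase boundary is structural, not a rest
    }
    if (gap > 0) {
      rows[[length(rows) + 1L]] <- list(phrase = phrase, pitch = NA_integer_,
                                        num = gap, den = division)
    }
    rows[[length(rows) + 1L]] <- list(phrase = phrase, pitch = as.integer(nt$pitch[i]),
                                      num = nt$off[i] - nt$on[i], den = division)
    prev_off <- nt$off[i]
  }

  g <- vapply(rows, function(r) {
    d <- gcd_int(r$num, r$den)
    c(r$phrase, r$pitch, r$num / d, r$den / d)
  }, numeric(4))
  phr <- as.integer(g[1, ])
  note_index <- stats::ave(seq_along(phr), phr, FUN = seq_along) - 1L

  as_song_corpus(tibble::tibble(
    song_id = song_id, language = language, song_type = song_type,
    meter = meter, key = key, tempo_ms_per_quarter = tempo_ms,
    phrase_index = phr, note_index = as.integer(note_index),
    pitch = as.integer(g[2, ]),
    duration_num = as.integer(g[3, ]), duration_den = as.integer(g[4, ]),
    tie_to_next = FALSE, grace = FALSE
  ), provenance = "parse_midi")
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  max(a, 1)
}
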