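# From note events to per-phrase duration series (the d_k of the contrast
# statistic). Tie chains are summed in exact rational arithmetic before any
# conversion to double.

#' Extract per-phrase duration series from a corpus
#'
#' For every phrase of every song, produces the ordered sequence of element
#' durations that feeds the nPVI statistic, after (1) merging tied notes into
#' a single element whose duration is the exact rational sum, (2) dropping
#' grace notes, and (3) applying the rest policy. Under the default
#' `"notated"` policy elements are notated note durations and rests are
#' dropped; under the `"ioi"` (inter-onset interval) policy a rest's duration
#' accrues to the preceding note, so elements span onset to onset. A rest
#' with no preceding note in its phrase is dropped under either policy.
#'
#' Phrases reduced to zero elements are dropped with a warning, not an error.
#'
#' @param corpus A `song_corpus`.
#' @param policy `"notated"` (default) or `"ioi"`.
#' @return A tibble with columns `song_id`, `phrase_index`, `element_index`,
#'   `duration` (quarter-note beats, double).
#' @export
duration_series <- function(corpus, policy = c("notated", "ioi")) {
  policy <- match.arg(policy)
  x <- tibble::as_tibble(corpus)
  x <- x[order(x$song_id, x$phrase_index, x$note_index), ]
  key <- paste(x$song_id, x$phrase_index, sep = "\r")
  idx_parts <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))
  durs <- vector("list", length(idx_parts))
  sids <- character(length(idx_parts))
  phrs <- integer(length(idx_parts))
  dropped <- character(0)
  for (i in seq_along(idx_parts)) {
    rows <- idx_parts[[i]]
    d <- phrase_elements_vec(x$duration_num[rows], x$duration_den[rows],
                             x$pitch[rows], x$tie_to_next[rows],
                             x$grace[rows], policy)
    sids[i] <- x$song_id[rows[1]]
    phrs[i] <- x$phrase_index[rows[1]]
    if (length(d) == 0) {
      dropped <- c(dropped, sprintf("%s phrase %d", sids[i], phrs[i]))
    }
    durs[[i]] <- d
  }
  if (length(dropped) > 0) {
    warning("dropped phrases with no duration elements: ",
            paste(dropped, collapse = "; "), call. = FALSE)
  }
  lens <- lengths(durs)
  tibble::tibble(
    song_id = rep(sids, lens),
    phrase_index = rep(phrs, lens),
    element_index = unlist(lapply(lens[lens > 0], seq_len), use.names = FALSE) - 1L,
    duration = unlist(durs, use.names = FALSE)
  )
}

# One phrase (vectors ordered by note_index) -> numeric duration vector.
phrase_elements_vec <- function(num, den, pitch, tie, grace, policy) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (!any(tie) && !any(grace) && !anyNA(pitch)) {
    return(num / den)
  }

  # merge tie chains exactly: num/den -> common denominator sums
  keep <- rep(TRUE, length(num))
  i <- 1L
  n <- length(num)
  while (i <= n) {
    j <- i
    while (j < n && tie[j]) j <- j + 1L
    if (j > i) {
      idx <- i:j
      den_l <- Reduce(function(a, b) a / gcd_int(a, b) * b, den[idx])
      num_s <- sum(num[idx] * (den_l / den[idx]))
      g <- gcd_int(num_s, den_l)
      num[i] <- num_s / g
      den[i] <- den_l / g
      keep[(i + 1L):j] <- FALSE
    }
    i <- j + 1L
  }
  num <- num[keep]; den <- den[keep]; pitch <- pitch[keep]; grace <- grace[keep]

  keep <- !grace
  num <- num[keep]; den <- den[keep]; pitch <- pitch[keep]

  is_rest <- is.na(pitch)
  if (policy == "ioi" && any(is_rest)) {
    # fold each rest into the nearest preceding note element
    beats <- num / den
    note_pos <- which(!is_rest)
    for (r in which(is_rest)) {
      prev <- note_pos[note_pos < r]
      if (length(prev) > 0) {
        beats[max(prev)] <- beats[max(prev)] + beats[r]
      }
    }
    return(beats[!is_rest])
  }
  (num / den)[!is_rest]
}
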