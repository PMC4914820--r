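# Synthetic corpora with analytically controlled nPVI, and simulated rater
# panels. Durational contrast is injected by long-short alternation (the
# musical analogue of vowel reduction): a measure is either "alternating",
# built from (long, short) pairs whose ratio realizes the song's target
# nPVI exactly, or "isochronous" (equal notes, zero contrast). Every
# measure is filled exactly, so songs are metrically well formed.

SYNTH_METERS <- c("2/2", "2/4", "3/4", "3/8", "6/8", "4/4")

# Anthology meter counts by language of origin; the French counts as printed
# sum to 121 of 129 songs and are renormalized.
METER_PROBS_ENGLISH <- c(`2/2` = 2, `2/4` = 26, `3/4` = 29, `3/8` = 1,
                         `6/8` = 6, `4/4` = 76) / 140
METER_PROBS_FRENCH <- c(`2/2` = 0, `2/4` = 55, `3/4` = 23, `3/8` = 3,
                        `6/8` = 20, `4/4` = 20) / 121

run_with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Long:short ratio realizing a target nPVI under strict alternation
#'
#' For a strictly alternating duration sequence `(r, 1, r, 1, ...)` the nPVI
#' is constant across pairs, and solving the pair contrast for the ratio
#' gives `r = (200 + v) / (200 - v)`. This is the generator's inverse link
#' from a target statistic value to a concrete rhythm.
#'
#' @param v Target nPVI in `[0, 200)`.
#' @return The ratio `r >= 1`.
#' @export
npvi_to_ratio <- function(v) {
  if (any(v < 0 | v >= 200)) {
    stop("target nPVI must be in [0, 200)", call. = FALSE)
  }
  (200 + v) / (200 - v)
}

#' Generator configuration for synthetic corpora
#'
#' Default cell targets and dispersions mirror the anthology corpus: target
#' nPVIs 40.43 / 33.8 (children's, stress- vs syllable-timed regime) and
#' 43.6 / 40.1 (folk), with between-song SD back-computed as SEM * sqrt(n)
#' from the printed cell summaries (SEMs 1.9 / 2.26 / 1.8 / 2.13 at
#' n 68 / 61 / 72 / 68). Meters are drawn from each regime's anthology
#' marginal. `alternation_prob` is the probability that a measure is
#' alternating rather than isochronous (1 = every within-phrase pair carries
#' the target contrast).
#'
#' @param n_songs Songs per cell.
#' @param cells Optional tibble overriding the cell plan (columns `language`,
#'   `song_type`, `n_songs`, `target_npvi`, `npvi_sd`).
#' @param alternation_prob Probability a measure alternates (default 1).
#' @param phrase_count Integer vector of possible phrase counts per song.
#' @param measures_per_phrase Integer vector of possible measures per phrase.
#' @param meter_probs Named list (by language) of probabilities over
#'   `r SYNTH_METERS`.
#' @param notated_tempo_prob Probability a song carries a notated tempo.
#' @param tempo_ms_mean,tempo_ms_sd Notated tempo distribution (ms/quarter),
#'   truncated to `[300, 1000]`.
#' @param seed Default seed used by [generate_corpus()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_songs = 60,
                         cells = NULL,
                         alternation_prob = 1,
                         phrase_count = 2:4,
                         measures_per_phrase = 2:4,
                         meter_probs = list(
                           `synthetic:English` = METER_PROBS_ENGLISH,
                           `synthetic:French` = METER_PROBS_FRENCH
                         ),
                         notated_tempo_prob = 0.5,
                         tempo_ms_mean = 600,
                         tempo_ms_sd = 90,
                         seed = 1L) {
  if (is.null(cells)) {
    cells <- tibble::tibble(
      language = rep(c("synthetic:English", "synthetic:French"), 2),
      song_type = rep(c("children", "folk"), each = 2),
      n_songs = as.integer(n_songs),
      target_npvi = c(40.43, 33.8, 43.6, 40.1),
      npvi_sd = c(1.9 * sqrt(68), 2.26 * sqrt(61), 1.8 * sqrt(72), 2.13 * sqrt(68))
    )
  }
  cfg <- list(cells = tibble::as_tibble(cells),
              alternation_prob = alternation_prob,
              phrase_count = as.integer(phrase_count),
              measures_per_phrase = as.integer(measures_per_phrase),
              meter_probs = meter_probs,
              notated_tempo_prob = notated_tempo_prob,
              tempo_ms_mean = tempo_ms_mean, tempo_ms_sd = tempo_ms_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  cells <- cfg$cells
  need <- c("language", "song_type", "n_songs", "target_npvi", "npvi_sd")
  if (!all(need %in% names(cells))) {
    stop("config error: cells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$n_songs < 0)) stop("config error: n_songs must be >= 0", call. = FALSE)
  if (any(cells$target_npvi < 0 | cells$target_npvi >= 200)) {
    stop("config error: target_npvi must be in [0, 200)", call. = FALSE)
  }
  if (any(cells$npvi_sd < 0)) stop("config error: npvi_sd must be >= 0", call. = FALSE)
  if (cfg$alternation_prob < 0 || cfg$alternation_prob > 1) {
    stop("config error: alternation_prob must be in [0, 1]", call. = FALSE)
  }
  for (lang in unique(cells$language)) {
    pr <- cfg$meter_probs[[lang]]
    if (is.null(pr)) stop("config error: no meter_probs for ", lang, call. = FALSE)
    if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      stop("config error: meter_probs for ", lang, " must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Measure templates for a meter at a realized target v (2-decimal grid):
# the long fraction of a one-pair slot of length s is f = (200 + v) / 400
# exactly, so each alternating pair realizes contrast v exactly.
measure_templates <- function(meter, v_q) {
  beats4 <- as.integer(sub("/.*", "", meter)) * 4L
  den <- as.integer(sub(".*/", "", meter))
  g <- gcd_int(beats4, den)
  l_num <- beats4 / g
  l_den <- den / g                      # measure length = l_num / l_den beats
  k <- max(1L, (beats4 %/% den))        # pairs per measure
  s_num <- l_num; s_den <- l_den * k    # pair slot length s = L / k
  g <- gcd_int(s_num, s_den); s_num <- s_num / g; s_den <- s_den / g

  f_num <- 20000 + round(100 * v_q)     # f = (200 + v)/400 on the 2-decimal grid
  f_den <- 40000
  long_num <- f_num * s_num; long_den <- f_den * s_den
  g <- gcd_int(long_num, long_den); long_num <- long_num / g; long_den <- long_den / g
  sh_num <- s_num * long_den - long_num * s_den
  sh_den <- s_den * long_den
  g <- gcd_int(sh_num, sh_den); sh_num <- sh_num / g; sh_den <- sh_den / g
  iso_num <- s_num; iso_den <- 2L * s_den
  g <- gcd_int(iso_num, iso_den); iso_num <- iso_num / g; iso_den <- iso_den / g
  list(
    k = k,
    alt_num = rep(c(long_num, sh_num), k), alt_den = rep(c(long_den, sh_den), k),
    iso_num = rep(iso_num, 2L * k), iso_den = rep(iso_den, 2L * k)
  )
}

C_MAJOR_SCALE <- c(60L, 62L, 64L, 65L, 67L, 69L, 71L, 72L)

#' Generate a synthetic song corpus with controlled nPVI
#'
#' Each song draws a target nPVI from a normal distribution truncated to
#' `[0, 195]` around its cell's target (rounded to two decimals), a meter
#' from its regime's meter distribution, and a phrase plan; measures are
#' filled exactly with alternating long-short pairs (realizing the target
#' contrast) or isochronous notes. Pitches walk a C-major scale and are
#' ignored by all rhythm computations. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Overrides `config$seed`.
#' @return A `song_corpus`.
#' @export
generate_corpus <- function(config = synth_config(), seed = config$seed) {
  validate_synth_config(config)
  run_with_seed(seed, {
    acc <- list() # per-song column chunks, assembled once at the end
    meta <- list()
    for (ci in seq_len(nrow(config$cells))) {
      cell <- config$cells[ci, ]
      pr <- config$meter_probs[[cell$language]]
      for (si in seq_len(cell$n_songs)) {
        v <- cell$target_npvi
        if (cell$npvi_sd > 0) {
          repeat {
            v <- stats::rnorm(1, cell$target_npvi, cell$npvi_sd)
            if (v >= 0 && v <= 195) break
          }
        }
        v_q <- round(v, 2)
        meter <- sample(names(pr), 1, prob = pr)
        tpl <- measure_templates(meter, v_q)
        n_phr <- sample_one(config$phrase_count)
        n_meas <- vapply(seq_len(n_phr), function(p) sample_one(config$measures_per_phrase),
                         integer(1))
        alt <- stats::runif(sum(n_meas)) < config$alternation_prob
        per <- 2L * tpl$k
        num <- ifelse(rep(alt, each = per), rep.int(tpl$alt_num, sum(n_meas)),
                      rep.int(tpl$iso_num, sum(n_meas)))
        den <- ifelse(rep(alt, each = per), rep.int(tpl$alt_den, sum(n_meas)),
                      rep.int(tpl$iso_den, sum(n_meas)))
        phr <- rep(rep(seq_len(n_phr) - 1L, n_meas), each = per)
        note_index <- unlist(lapply(n_meas * per, seq_len), use.names = FALSE) - 1L
        n <- length(num)
        steps <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
        walk <- pmin(pmax(cumsum(steps) + 4L, 1L), length(C_MAJOR_SCALE))
        tempo <- if (stats::runif(1) < config$notated_tempo_prob) {
          min(max(round(stats::rnorm(1, config$tempo_ms_mean, config$tempo_ms_sd)), 300), 1000)
        } else NA_real_
        acc[[length(acc) + 1L]] <- list(phr = phr, note_index = note_index,
                                        pitch = C_MAJOR_SCALE[walk],
                                        num = as.integer(num), den = as.integer(den))
        meta[[length(meta) + 1L]] <- list(
          song_id = sprintf("%s_%s_%03d", sub("^synthetic:", "", cell$language),
                            cell$song_type, si),
          language = cell$language, song_type = cell$song_type,
          meter = meter, tempo = tempo, n = n)
      }
    }
    ns <- vapply(meta, function(m) m$n, integer(1))
    tbl <- tibble::tibble(
      song_id = rep(vapply(meta, function(m) m$song_id, character(1)), ns),
      language = rep(vapply(meta, function(m) m$language, character(1)), ns),
      song_type = rep(vapply(meta, function(m) m$song_type, character(1)), ns),
      meter = rep(vapply(meta, function(m) m$meter, character(1)), ns),
      key = "C",
      tempo_ms_per_quarter = rep(vapply(meta, function(m) m$tempo, numeric(1)), ns),
      phrase_index = unlist(lapply(acc, function(a) a$phr), use.names = FALSE),
      note_index = unlist(lapply(acc, function(a) a$note_index), use.names = FALSE),
      pitch = unlist(lapply(acc, function(a) a$pitch), use.names = FALSE),
      duration_num = unlist(lapply(acc, function(a) a$num), use.names = FALSE),
      duration_den = unlist(lapply(acc, function(a) a$den), use.names = FALSE),
      tie_to_next = FALSE, grace = FALSE
    )
    as_song_corpus(tbl, provenance = sprintf("generate_corpus seed=%s", seed))
  })
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Analytic expected nPVI of the generator, per cell
#'
#' Pair-count-weighted expectation of the pooled song statistic under the
#' generative grammar: within an alternating measure every adjacent pair
#' contributes the song's realized target `v`; isochronous measures
#' contribute 0; junctions between measures contribute `v` (alt-alt),
#' `200 (rho - 1) / (rho + 3)` (alt to iso), `200 (rho - 1) / (3 rho + 1)`
#' (iso to alt) or 0 (iso-iso), with `rho = (200 + v) / (200 - v)`. Phrase
#' junction pairs are excluded by the statistic and do not appear. Target
#' jitter is integrated numerically over the truncated normal on the
#' two-decimal grid.
#'
#' @param config A [synth_config()].
#' @return The cell tibble with an `expected_npvi` column appended.
#' @export
expected_npvi <- function(config = synth_config()) {
  validate_synth_config(config)
  p <- config$alternation_prob
  e_np <- mean(config$phrase_count)
  e_m <- mean(config$measures_per_phrase)
  out <- numeric(nrow(config$cells))
  for (ci in seq_len(nrow(config$cells))) {
    cell <- config$cells[ci, ]
    if (cell$npvi_sd == 0) {
      vq <- round(cell$target_npvi, 2)
      w <- 1
    } else {
      vq <- seq(0, 195, by = 0.01)
      w <- stats::dnorm(vq, cell$target_npvi, cell$npvi_sd)
      w <- w / sum(w)
    }
    rho <- (200 + vq) / (200 - vq)
    e_v <- sum(w * vq)
    e_c1 <- sum(w * 200 * (rho - 1) / (rho + 3))   # alternating short -> iso note
    e_c2 <- sum(w * 200 * (rho - 1) / (3 * rho + 1)) # iso note -> alternating long
    e_junction <- p^2 * e_v + p * (1 - p) * (e_c1 + e_c2)

    pr <- config$meter_probs[[cell$language]]
    num_tot <- 0; pairs_tot <- 0
    for (meter in names(pr)) {
      if (pr[[meter]] == 0) next
      k <- measure_templates(meter, 0)$k
      num_m <- e_np * (e_m * (2 * k - 1) * p * e_v + (e_m - 1) * e_junction)
      pairs_m <- e_np * (2 * k * e_m - 1)
      num_tot <- num_tot + pr[[meter]] * num_m
      pairs_tot <- pairs_tot + pr[[meter]] * pairs_m
    }
    out[ci] <- num_tot / pairs_tot
  }
  dplyr::mutate(config$cells, expected_npvi = out)
}

#' Rater panel model
#'
#' Generative model for one listener group. Familiarity is a clamped 1--7
#' integer from `fam_base` plus an own-culture bonus, a children's-song
#' bonus and Gaussian noise; liking tracks familiarity; the probability of
#' endorsing a song as "for children" is
#' `plogis(b0 + b_fam * familiarity + b_tempo * tempo_ms + b_npvi * npvi)`.
#' Default coefficient signs mirror the observed regression structure:
#' familiarity loads positively and tempo negatively for every group, and
#' nPVI loads negatively only for listeners with a syllable-timed native
#' language (strongly for the French group, weakly for bilingual Americans,
#' zero for monolingual Americans).
#'
#' @param group One of `"monolingual_american"`, `"bilingual_american"`,
#'   `"french"`.
#' @param n_participants Panel size.
#' @param culture `"English"` or `"French"`: which song regime counts as
#'   own-culture for the familiarity bonus.
#' @param beta Named numeric: `intercept`, `familiarity`, `tempo` (per ms),
#'   `npvi` (per nPVI unit), on the logit scale.
#' @param fam_base Baseline latent familiarity (1--7 scale).
#' @param own_culture_bonus,children_bonus Additive familiarity bonuses.
#' @param fam_noise,liking_noise Gaussian noise SDs.
#' @param music_mean,music_sd,dance_mean,dance_sd Training-years
#'   distributions (normal truncated at 0).
#' @return A `rater_model` list.
#' @export
rater_model <- function(group, n_participants, culture,
                        beta = c(intercept = 0, familiarity = 0.9,
                                 tempo = -0.006, npvi = 0),
                        fam_base = 3, own_culture_bonus = 0.8,
                        children_bonus = 0.5, fam_noise = 1.2,
                        liking_noise = 1,
                        music_mean = 2.5, music_sd = 3.5,
                        dance_mean = 1.3, dance_sd = 2.5) {
  stopifnot(n_participants >= 1, fam_noise >= 0, liking_noise >= 0)
  stopifnot(all(c("intercept", "familiarity", "tempo", "npvi") %in% names(beta)))
  structure(list(group = group, n_participants = as.integer(n_participants),
                 culture = culture, beta = beta, fam_base = fam_base,
                 own_culture_bonus = own_culture_bonus,
                 children_bonus = children_bonus, fam_noise = fam_noise,
                 liking_noise = liking_noise,
                 music_mean = music_mean, music_sd = music_sd,
                 dance_mean = dance_mean, dance_sd = dance_sd),
            class = "rater_model")
}

#' Default rater panels for the three listener groups
#'
#' Panel sizes match the rating study (70 monolingual Americans, 30
#' bilingual Americans, 40 French listeners); training-year distributions
#' match the reported group means and SDs. Intercepts center endorsement
#' near 0.5 at corpus-typical predictor values.
#'
#' @return A list of three [rater_model()] objects.
#' @export
default_rater_models <- function() {
  list(
    rater_model("monolingual_american", 70, "English",
                beta = c(intercept = -0.15, familiarity = 0.9,
                         tempo = -0.006, npvi = 0),
                music_mean = 2.57, music_sd = 3.8,
                dance_mean = 1.37, dance_sd = 3.03),
    rater_model("bilingual_american", 30, "English",
                beta = c(intercept = 0.4, familiarity = 0.9,
                         tempo = -0.006, npvi = -0.015),
                music_mean = 2.26, music_sd = 3.26,
                dance_mean = 0.91, dance_sd = 1.94),
    rater_model("french", 40, "French",
                beta = c(intercept = 1.0, familiarity = 0.9,
                         tempo = -0.006, npvi = -0.03),
                music_mean = 4.68, music_sd = 5.49,
                dance_mean = 1.56, dance_sd = 2.5)
  )
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
  round(x, 1)
}

#' Simulate a listener-rating table for a corpus
#'
#' Songs are split into `n_lists` lists (shuffled round-robin, as in a
#' between-lists presentation design) and each participant rates one list.
#' Ratings follow the participant's [rater_model()]; endorsement uses the
#' song's true nPVI and tempo from [npvi_table()]. Deterministic for a
#' fixed seed.
#'
#' @param corpus A `song_corpus`.
#' @param rater_models List of [rater_model()]s (default
#'   [default_rater_models()]).
#' @param seed Integer seed.
#' @param n_lists Number of presentation lists.
#' @param rhythm Optional precomputed [npvi_table()] for `corpus` (computed
#'   internally when `NULL`).
#' @return A ratings tibble in the [read_ratings()] dialect (logical
#'   `endorsed` coerced to 0/1).
#' @export
generate_ratings <- function(corpus, rater_models = default_rater_models(),
                             seed = 1L, n_lists = 5L, rhythm = NULL) {
  if (is.null(rhythm)) rhythm <- suppressWarnings(npvi_table(corpus))
  rhythm <- rhythm[!is.na(rhythm$npvi), ]
  run_with_seed(seed, {
    ids <- sample(rhythm$song_id)
    list_of <- rep_len(seq_len(n_lists), length(ids))
    lists <- split(ids, list_of)
    recs <- list()
    for (mod in rater_models) {
      # one row per participant x song of their list, built column-wise
      list_idx <- (seq_len(mod$n_participants) - 1L) %% n_lists + 1L
      songs <- unlist(lists[list_idx], use.names = FALSE)
      ns_per <- lengths(lists)[list_idx]
      pid <- rep(sprintf("%s_p%03d", mod$group, seq_len(mod$n_participants)), ns_per)
      r <- rhythm[match(songs, rhythm$song_id), ]
      own <- grepl(mod$culture, r$language, fixed = TRUE)
      child <- r$song_type == "children"
      n <- length(songs)
      fam_latent <- mod$fam_base + mod$own_culture_bonus * own +
        mod$children_bonus * child + stats::rnorm(n, 0, mod$fam_noise)
      fam <- pmin(pmax(round(fam_latent), 1L), 7L)
      lik <- pmin(pmax(round(1 + 0.6 * fam + stats::rnorm(n, 0, mod$liking_noise)), 1L), 7L)
      eta <- mod$beta[["intercept"]] + mod$beta[["familiarity"]] * fam +
        mod$beta[["tempo"]] * r$mean_note_duration_ms + mod$beta[["npvi"]] * r$npvi
      pr <- stats::plogis(eta)
      endorsed <- as.integer(stats::runif(n) < pr)
      conf <- pmin(pmax(round(1 + 6 * pr + stats::rnorm(n, 0, 0.8)), 1L), 7L)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        participant_id = pid, group = mod$group, song_id = songs,
        familiarity = as.integer(fam), liking = as.integer(lik),
        endorsed = endorsed, confidence = as.integer(conf),
        music_years = rep(rnorm_trunc0(mod$n_participants, mod$music_mean, mod$music_sd),
                          ns_per),
        dance_years = rep(rnorm_trunc0(mod$n_participants, mod$dance_mean, mod$dance_sd),
                          ns_per)
      )
    }
    validate_ratings(dplyr::bind_rows(recs))
  })
}
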