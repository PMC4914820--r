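# File-in/file-out drivers tying the stages together. Each writes a
# manifest recording inputs, options and seed so a run can be reproduced
# byte for byte. The numbered scripts under analysis/ are thin narrative
# wrappers over these.

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Simulate a corpus and rating panel to disk
#'
#' Writes `notes.csv` (note-table dialect), `ratings.csv` (ratings dialect)
#' and `manifest.json` (config echo + seed) under `out_dir`. Identical
#' seeds produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @param rater_models List of [rater_model()]s.
#' @param seed Integer seed for both generators.
#' @return Named character vector of the three file paths, invisibly.
#' @export
run_simulate <- function(out_dir, config = synth_config(),
                         rater_models = default_rater_models(),
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config, seed = seed)
  ratings <- generate_ratings(corpus, rater_models, seed = seed + 1L)
  notes_path <- file.path(out_dir, "notes.csv")
  ratings_path <- file.path(out_dir, "ratings.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_note_table(corpus, notes_path)
  readr::write_csv(ratings, ratings_path, progress = FALSE)
  manifest <- list(
    seed = seed,
    n_songs = nrow(song_meta(corpus)),
    n_ratings = nrow(ratings),
    cells = config$cells,
    alternation_prob = config$alternation_prob,
    phrase_count = config$phrase_count,
    measures_per_phrase = config$measures_per_phrase,
    notated_tempo_prob = config$notated_tempo_prob,
    tempo_ms_mean = config$tempo_ms_mean,
    tempo_ms_sd = config$tempo_ms_sd,
    rater_groups = lapply(rater_models, function(m) {
      list(group = m$group, n_participants = m$n_participants,
           culture = m$culture, beta = as.list(m$beta))
    })
  )
  write_json_report(manifest, manifest_path)
  message(sprintf("simulated %d songs, %d ratings -> %s",
                  manifest$n_songs, manifest$n_ratings, out_dir))
  invisible(c(notes = notes_path, ratings = ratings_path, manifest = manifest_path))
}

#' Compute the per-song rhythm table for a corpus file
#'
#' Reads a note-table CSV, computes [npvi_table()] and writes it as CSV.
#' Songs with undefined nPVI are kept as `NA` rows with a warning.
#'
#' @param notes_csv Input note-table CSV.
#' @param out_csv Output CSV path.
#' @param policy,aggregation Passed to [npvi_table()].
#' @return The rhythm tibble, invisibly.
#' @export
run_npvi <- function(notes_csv, out_csv, policy = "notated",
                     aggregation = "pooled_pairs") {
  corpus <- read_note_table(notes_csv)
  tbl <- npvi_table(corpus, policy = policy, aggregation = aggregation)
  readr::write_csv(tbl, out_csv, progress = FALSE)
  message(sprintf("%d songs scored (%d undefined), %d boundary pairs excluded -> %s",
                  nrow(tbl), sum(is.na(tbl$npvi)), sum(tbl$n_pairs_excluded), out_csv))
  invisible(tbl)
}

#' Group contrasts from a rhythm table file
#'
#' Reads a [run_npvi()] CSV and writes the cell summaries, language
#' marginals and planned between-language contrasts as JSON.
#'
#' @param npvi_csv Input rhythm-table CSV.
#' @param out_json Output JSON path.
#' @param method,tail Passed to [t_independent()].
#' @return The [corpus_contrasts()] list, invisibly.
#' @export
run_compare <- function(npvi_csv, out_json, method = "pooled", tail = "two") {
  tbl <- readr::read_csv(npvi_csv, show_col_types = FALSE, progress = FALSE)
  rep <- corpus_contrasts(tbl, method = method, tail = tail)
  write_json_report(rep, out_json)
  message(sprintf("contrasts for %d songs -> %s", sum(rep$cells$n), out_json))
  invisible(rep)
}

#' Child-directedness regression report from rating and rhythm files
#'
#' Joins a ratings CSV with a rhythm-table CSV, aggregates per song and
#' group, fits the four-predictor regression for every listener group
#' present, and writes a JSON report shaped like a simple-r / R^2-change
#' table.
#'
#' @param ratings_csv Input ratings CSV.
#' @param npvi_csv Input rhythm-table CSV.
#' @param out_json Output JSON path.
#' @return List of per-group regression results, invisibly.
#' @export
run_ratings <- function(ratings_csv, npvi_csv, out_json) {
  records <- read_ratings(ratings_csv)
  rhythm <- readr::read_csv(npvi_csv, show_col_types = FALSE, progress = FALSE)
  agg <- aggregate_by_song(records, rhythm)
  groups <- unique(records$group)
  fits <- lapply(groups, function(g) regress_child_directedness(agg, g))
  names(fits) <- groups
  report <- lapply(fits, function(f) {
    list(n_songs = f$n_songs,
         r2_full = f$r2_full, f_full = f$f_full, p_full = f$p_full,
         coefficients = as.list(f$coefficients),
         table = f$predictors)
  })
  write_json_report(report, out_json)
  message(sprintf("regressions for %d group(s) -> %s", length(fits), out_json))
  invisible(fits)
}

#' Render every song of a corpus file to MIDI
#'
#' Applies the stimulus-preparation rules: 600 ms per quarter unless a tempo
#' is notated, and optional transposition to C major.
#'
#' @param notes_csv Input note-table CSV.
#' @param out_dir Output directory for `<song_id>.mid` files.
#' @param transpose_to_c Transpose to C major?
#' @return Character vector of written paths, invisibly.
#' @export
run_render_midi <- function(notes_csv, out_dir, transpose_to_c = TRUE) {
  corpus <- read_note_table(notes_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(tibble::as_tibble(corpus)$song_id)
  paths <- vapply(ids, function(sid) {
    p <- file.path(out_dir, paste0(sid, ".mid"))
    render_midi(corpus, sid, path = p, transpose_to_c = transpose_to_c)
    p
  }, character(1))
  message(sprintf("rendered %d songs -> %s", length(paths), out_dir))
  invisible(paths)
}
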