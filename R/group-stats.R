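# Group summaries and two-sample t tests computable from summary statistics
# alone, so printed (mean, SEM, n) triples can be re-analysed without raw
# data.

#' Summarise a sample
#'
#' @param values Numeric vector, length >= 2.
#' @param label Group label.
#' @return A one-row tibble: `label`, `n`, `mean`, `sd` (n-1 denominator),
#'   `sem` (= sd / sqrt(n)).
#' @export
group_summary <- function(values, label = "group") {
  if (length(values) < 2) {
    stop("group_summary needs at least two values", call. = FALSE)
  }
  n <- length(values)
  s <- stats::sd(values)
  tibble::tibble(label = label, n = n, mean = mean(values), sd = s,
                 sem = s / sqrt(n))
}

#' Build a group summary from printed mean, SEM and n
#'
#' Back-computes the sample SD as `sem * sqrt(n)`, allowing t tests to be
#' reproduced from values as printed in a results section.
#'
#' @param label Group label.
#' @param n Sample size.
#' @param mean Printed mean.
#' @param sem Printed standard error of the mean.
#' @return A one-row tibble with the same columns as [group_summary()].
#' @export
summary_from_printed <- function(label, n, mean, sem) {
  if (n < 2 || sem < 0) stop("need n >= 2 and sem >= 0", call. = FALSE)
  tibble::tibble(label = label, n = as.integer(n), mean = mean,
                 sd = sem * sqrt(n), sem = sem)
}

#' Independent-samples t test from group summaries
#'
#' Works from `(n, mean, sd)` alone. The pooled method uses
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` with
#' `df = n1 + n2 - 2`; the Welch method uses unpooled variances with the
#' Welch--Satterthwaite df. Two degenerate cases: both variances zero with
#' equal means gives `t = 0, p = 1`; zero variance with unequal means gives
#' an infinite t (p = 0).
#'
#' @param g1,g2 One-row summaries from [group_summary()] or
#'   [summary_from_printed()].
#' @param method `"pooled"` (default) or `"welch"`.
#' @param tail `"two"` (default) or `"one"`. The one-tailed p is for the
#'   observed direction of the difference.
#' @return A one-row tibble: `t`, `df`, `p`, `tail`, `method`.
#' @export
t_independent <- function(g1, g2, method = c("pooled", "welch"),
                          tail = c("two", "one")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  n1 <- g1$n; n2 <- g2$n; m1 <- g1$mean; m2 <- g2$mean; s1 <- g1$sd; s2 <- g2$sd
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t <- (m1 - m2) / se
  }
  p <- if (tail == "two") 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p = p, tail = tail, method = method)
}

#' Independent-samples t test from raw values
#'
#' Thin wrapper that summarises both samples and delegates to
#' [t_independent()].
#'
#' @param x,y Numeric vectors.
#' @inheritParams t_independent
#' @return A one-row tibble as for [t_independent()].
#' @export
t_independent_values <- function(x, y, method = "pooled", tail = "two") {
  t_independent(group_summary(x, "x"), group_summary(y, "y"),
                method = method, tail = tail)
}

#' Sample-size-weighted mean of group means
#'
#' `sum(n_i * m_i) / sum(n_i)`: reconstructs an overall mean from subgroup
#' summaries (e.g. a language's mean from its children's and folk cells).
#'
#' @param summaries Tibble of group summaries (rows bindable from
#'   [group_summary()] / [summary_from_printed()]).
#' @return The pooled mean.
#' @export
weighted_pooled_mean <- function(summaries) {
  if (nrow(summaries) == 0) stop("no summaries given", call. = FALSE)
  sum(summaries$n * summaries$mean) / sum(summaries$n)
}

#' Corpus contrast report: cell summaries and planned comparisons
#'
#' From a per-song rhythm table ([npvi_table()]), computes the four
#' language-by-song-type cell summaries, the language marginals, and the two
#' planned between-language contrasts (children's songs; folk songs).
#'
#' @param rhythm_tbl Output of [npvi_table()]; rows with `NA` nPVI are
#'   dropped.
#' @param method,tail Passed to [t_independent()].
#' @return A list with elements `cells`, `marginals` (tibbles) and
#'   `contrasts` (tibble with one row per song type).
#' @export
corpus_contrasts <- function(rhythm_tbl, method = "pooled", tail = "two") {
  x <- rhythm_tbl[!is.na(rhythm_tbl$npvi), ]
  if (dplyr::n_distinct(x$language) < 2) {
    stop("contrasts need two language groups", call. = FALSE)
  }
  cells <- dplyr::bind_rows(lapply(
    split(x, list(x$language, x$song_type), drop = TRUE, sep = " / "),
    function(cell) {
      cbind(group_summary(cell$npvi, paste(cell$language[1], cell$song_type[1])),
            language = cell$language[1], song_type = cell$song_type[1])
    }
  ))
  marginals <- dplyr::bind_rows(lapply(
    split(x, x$language),
    function(g) group_summary(g$npvi, g$language[1])
  ))
  langs <- sort(unique(x$language))
  contrasts <- dplyr::bind_rows(lapply(sort(unique(x$song_type)), function(st) {
    g1 <- cells[cells$song_type == st & cells$language == langs[1], ]
    g2 <- cells[cells$song_type == st & cells$language == langs[2], ]
    if (nrow(g1) == 0 || nrow(g2) == 0) {
      stop(sprintf("missing cell for song_type '%s'", st), call. = FALSE)
    }
    cbind(tibble::tibble(song_type = st,
                         groups = sprintf("%s vs %s", langs[1], langs[2])),
          t_independent(g1, g2, method = method, tail = tail))
  }))
  list(cells = tibble::as_tibble(cells),
       marginals = tibble::as_tibble(marginals),
       contrasts = contrasts)
}
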