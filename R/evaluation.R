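#' Pearson product-moment correlation
#'
#' Thin, validated front end to [stats::cor()]: requires equal lengths,
#' at least two complete pairs and non-zero variance in both arguments
#' (a constant column has no defined correlation).
#'
#' @param x,y numeric vectors of equal length (no missing values; use
#'   [correlate_models()] for pairwise-complete handling).
#' @return Pearson's r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("'x' and 'y' must be numeric vectors of equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values: drop incomplete pairs first (see correlate_models)",
      call. = FALSE
    )
  }
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("undefined correlation: 'x' is constant", call. = FALSE)
  if (stats::var(y) == 0) stop("undefined correlation: 'y' is constant", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided significance of a Pearson correlation
#'
#' Uses the exact t transform under the null of zero correlation:
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom. `r = +/-1` gives `p = 0`.
#'
#' @param r Pearson correlation in \[-1, 1\].
#' @param n number of pairs, at least 3.
#' @return two-sided p value in \[0, 1\].
#' @export
pearson_p <- function(r, n) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) > 1 + 1e-12) {
    stop("'r' must be a single value in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 3L) {
    stop("need at least 3 pairs for a defined p value", call. = FALSE)
  }
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Verbal strength of a correlation
#'
#' Maps `|r|` to the conventional five-level scale: \[0, 0.2) very weak,
#' \[0.2, 0.4) weak, \[0.4, 0.6) medium, \[0.6, 0.8) strong and
#' \[0.8, 1\] very strong. The sign is reported separately by
#' [correlation_sign()].
#'
#' @param r correlation in \[-1, 1\] (vectorized).
#' @return character vector of strength labels.
#' @examples
#' strength_category(c(0.61, 0.884, -0.05))
#' @export
strength_category <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1", call. = FALSE)
  labels <- c("very weak", "weak", "medium", "strong", "very strong")
  labels[findInterval(abs(r), c(0.2, 0.4, 0.6, 0.8)) + 1L]
}

#' @rdname strength_category
#' @return `correlation_sign()`: `"negative"`, `"none"` or `"positive"`.
#' @export
correlation_sign <- function(r) {
  c("negative", "none", "positive")[sign(r) + 2L]
}

#' Correlate model-score columns against a measured-affinity column
#'
#' For each model column, rows where either the reference measurement or
#' the model score is missing are dropped (pairwise-complete deletion, so
#' each model is evaluated on the largest usable subset), then n, Pearson's
#' r, the two-sided p value and the verbal strength are reported. A column
#' with fewer than 3 complete pairs yields an error entry (NA values plus a
#' message) rather than aborting the whole report.
#'
#' @param dataset data frame with a `sequence` column and numeric
#'   measurement/score columns; see [nfkb_affinity_dataset()].
#' @param reference_column name of the measured-affinity column.
#' @param model_columns character vector of score columns to evaluate.
#' @return data frame with one row per model column: `model`, `n`, `r`,
#'   `p`, `strength`, `sign`, `error`.
#' @examples
#' d <- nfkb_affinity_dataset()
#' correlate_models(d, "EMSA", c("SNMM", "PWMSA", "Match", "PC"))
#' @export
correlate_models <- function(dataset, reference_column, model_columns) {
  if (!is.data.frame(dataset)) stop("'dataset' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c(reference_column, model_columns), names(dataset))
  if (length(missing_cols)) {
    stop("column(s) not in dataset: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ref <- dataset[[reference_column]]
  rows <- lapply(model_columns, function(col) {
    score <- dataset[[col]]
    ok <- !is.na(ref) & !is.na(score)
    n <- sum(ok)
    if (n < 3L) {
      return(data.frame(
        model = col, n = n, r = NA_real_, p = NA_real_,
        strength = NA_character_, sign = NA_character_,
        error = "fewer than 3 complete pairs", stringsAsFactors = FALSE
      ))
    }
    r <- pearson_r(ref[ok], score[ok])
    data.frame(
      model = col, n = n, r = r, p = pearson_p(r, n),
      strength = strength_category(r), sign = correlation_sign(r),
      error = NA_character_, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
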