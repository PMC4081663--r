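#' False-negative and false-positive rates at a decision threshold
#'
#' Given model scores of known binding sites (`s1_scores`) and known
#' non-sites (`s2_scores`), a score counts as "predicted site" when its
#' 3-decimal rounding is at or above the threshold. The rounding matches
#' the resolution of the 0.001 decision grid and of published score
#' tables, and makes a site whose printed score equals the threshold a
#' positive call. Then `rFN` = fraction of sites missed and `rFP` =
#' fraction of non-sites accepted.
#'
#' @param s1_scores scores of true sites, in \[0, 1\].
#' @param s2_scores scores of non-sites, in \[0, 1\].
#' @param threshold decision threshold in \[0, 1\].
#' @return named numeric vector `c(rFN = ..., rFP = ...)`.
#' @examples
#' classification_rates(c(0.8, 0.7), 0.6, threshold = 0.75)
#' @export
classification_rates <- function(s1_scores, s2_scores, threshold) {
  check_scores(s1_scores, "s1_scores")
  check_scores(s2_scores, "s2_scores")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    threshold < 0 || threshold > 1) {
    stop("'threshold' must be a single value in [0, 1]", call. = FALSE)
  }
  thr <- milli(threshold)
  c(
    rFN = mean(milli(s1_scores) < thr),
    rFP = mean(milli(s2_scores) >= thr)
  )
}

check_scores <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("'", what, "' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop("'", what, "' must lie in [0, 1] with no missing values", call. = FALSE)
  }
  invisible(x)
}

# integer thousandths; round-half-away-from-zero so that printed 3-dp
# scores compare exactly against grid thresholds
milli <- function(x) as.integer(floor(x * 1000 + 0.5))

#' Grid search for the optimal decision threshold
#'
#' Evaluates every threshold on the grid from 0 to 1 (default step 0.001),
#' computing [classification_rates()] at each point, and selects the
#' threshold minimizing `rFN + rFP`. Ties are broken by smaller `rFN`,
#' then by the largest threshold — the most stringent predictor among
#' equally good ones; on cleanly separated inputs this returns exactly the
#' lowest (3-dp rounded) true-site score.
#'
#' @inheritParams classification_rates
#' @param step grid spacing (default 0.001).
#' @return an object of class `threshold_result`: a list with `threshold`,
#'   `rFN`, `rFP`, the full `curve` (a data frame over the grid, for
#'   audit/ROC use) and the tie-break `policy`.
#' @examples
#' res <- optimal_threshold(c(0.9, 0.8), c(0.2, 0.3))
#' res$threshold
#' @export
optimal_threshold <- function(s1_scores, s2_scores, step = 0.001) {
  check_scores(s1_scores, "s1_scores")
  check_scores(s2_scores, "s2_scores")
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1) {
    stop("'step' must be in (0, 1]", call. = FALSE)
  }
  grid <- seq(0, 1, by = step)
  s1 <- milli(s1_scores)
  s2 <- milli(s2_scores)
  gm <- milli(grid)
  # counting via sorted scores: rFN = #(s1 < t)/N, rFP = #(s2 >= t)/M
  rFN <- vapply(gm, function(t) sum(s1 < t), numeric(1L)) / length(s1)
  rFP <- vapply(gm, function(t) sum(s2 >= t), numeric(1L)) / length(s2)
  loss <- rFN + rFP
  cand <- which(loss == min(loss))
  cand <- cand[rFN[cand] == min(rFN[cand])]
  best <- max(cand) # largest threshold among remaining ties
  structure(
    list(
      threshold = grid[best],
      rFN = rFN[best],
      rFP = rFP[best],
      curve = data.frame(threshold = grid, rFN = rFN, rFP = rFP),
      policy = list(
        predicate = "round(score, 3) >= threshold",
        tie_break = "min rFN+rFP, then min rFN, then largest threshold",
        step = step
      )
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(
    "Optimal decision threshold: ", format(x$threshold), "\n",
    "  rFN ", format(x$rFN), "  rFP ", format(x$rFP),
    "  (grid step ", format(x$policy$step), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Select the highest-affinity sequences as the true-site group
#'
#' Ranks a dataset by a measured-affinity column (missing values dropped)
#' and returns the top `n` sequences. Ties at the cut are broken by
#' lexicographic sequence order so the selection is deterministic.
#'
#' @param dataset data frame with a `sequence` column; see
#'   [nfkb_affinity_dataset()].
#' @param measurement_column name of the affinity column to rank by.
#' @param n group size (default 30).
#' @return character vector of `n` sequences.
#' @export
select_s1 <- function(dataset, measurement_column, n = 30L) {
  if (!is.data.frame(dataset) || !"sequence" %in% names(dataset)) {
    stop("'dataset' must be a data frame with a 'sequence' column", call. = FALSE)
  }
  if (!measurement_column %in% names(dataset)) {
    stop("no column '", measurement_column, "' in dataset", call. = FALSE)
  }
  if (n == 0L) return(character())
  usable <- dataset[!is.na(dataset[[measurement_column]]), , drop = FALSE]
  if (nrow(usable) < n) {
    stop("only ", nrow(usable), " rows with a '", measurement_column,
      "' value; cannot select ", n,
      call. = FALSE
    )
  }
  ord <- order(-usable[[measurement_column]], usable$sequence)
  as.character(usable$sequence[ord][seq_len(n)])
}

#' Generate a non-site group by Match-score rejection sampling
#'
#' Draws uniform random 10-mers and keeps the distinct ones the Match
#' model rejects (matrix similarity score below `mss_cutoff`), until `n`
#' sequences are collected. "Rejected by Match" stands in for a literal
#' zero Match score, which only the per-column-minimum sequence attains;
#' the cutoff is configurable.
#'
#' @param n number of non-site sequences to generate.
#' @param pwm the PWM used for Match scoring (e.g. [nfkb_pwm()]).
#' @param mss_cutoff keep candidates with [match_mss()] strictly below
#'   this value (default 0.5).
#' @param seed integer seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @param max_batches sampling budget: candidate batches of 1000 draws
#'   before giving up with diagnostics.
#' @return character vector of `n` distinct 10-mers, each scoring below
#'   the cutoff.
#' @export
generate_s2 <- function(n, pwm, mss_cutoff = 0.5, seed = NULL,
                        max_batches = 1000L) {
  stopifnot(inherits(pwm, "pwm"), n >= 1L)
  run <- function() {
    out <- character()
    tried <- 0L
    for (b in seq_len(max_batches)) {
      cand <- random_10mers(1000L)
      tried <- tried + length(cand)
      cand <- cand[match_mss(cand, pwm) < mss_cutoff]
      out <- unique(c(out, cand))
      if (length(out) >= n) return(out[seq_len(n)])
    }
    stop(
      "sampling budget exhausted: ", tried, " draws yielded only ",
      length(out), " of ", n, " sequences below Match cutoff ", mss_cutoff,
      "; relax the cutoff or raise max_batches",
      call. = FALSE
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
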