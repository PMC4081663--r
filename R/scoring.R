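#' Score 10-mers with a single-nucleotide mutation matrix
#'
#' The raw score of a site is the sum of its per-position matrix cells
#' (the reference site itself sums to 0 by construction). The returned
#' score min-max normalizes that sum over all possible 10-mers:
#' `(sum - s_min) / (s_max - s_min)`, so every score lies in \[0, 1\],
#' the per-column argmax sequence scores exactly 1 and the per-column
#' argmin sequence exactly 0.
#'
#' @param sequences character vector of 10-mers (A/C/G/T; lowercase and U
#'   accepted, ambiguity codes rejected).
#' @param m a [snmm_matrix()].
#' @param allow_degraded score with a matrix that contains imputed cells
#'   (see [build_snmm()]); refused by default.
#' @return numeric vector of scores in \[0, 1\], one per sequence, computed
#'   in full precision (round only when comparing to printed tables).
#' @examples
#' m <- nfkb_snmm_matrix()
#' snmm_score(c("GGGGATTCCC", "GGGACTTTCC"), m)
#' @export
snmm_score <- function(sequences, m, allow_degraded = FALSE) {
  stopifnot(inherits(m, "snmm_matrix"))
  if (length(m$degraded) && !allow_degraded) {
    stop(
      "matrix contains imputed cells for probe(s) ",
      paste(m$degraded, collapse = ", "),
      "; pass allow_degraded = TRUE to score anyway",
      call. = FALSE
    )
  }
  sequences <- clean_dna(sequences, width = SITE_WIDTH)
  lo <- s_min(m)
  hi <- s_max(m)
  bm <- base_matrix(sequences, SITE_WIDTH)
  raw <- vapply(seq_along(sequences), function(k) {
    sum(m$delta[cbind(bm[k, ], seq_len(SITE_WIDTH))])
  }, numeric(1L))
  (raw - lo) / (hi - lo)
}

#' Score sequences with a log-odds PWM (PWMSA)
#'
#' Stormo-style scoring: the raw score is the summed log-odds
#' `sum_i ln(f(b_i, i) / background(b_i))`, min-max normalized to \[0, 1\]
#' using the per-column minimum and maximum log-odds, so the per-column
#' argmax sequence scores exactly 1 and the argmin sequence exactly 0.
#'
#' @param sequences character vector of sequences of width `pwm$width`.
#' @param pwm a [build_pwm()] / [read_transfac()] object.
#' @return numeric vector of scores in \[0, 1\].
#' @export
pwmsa_score <- function(sequences, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(pwm$frequencies == 0)) {
    stop(
      "PWM contains zero frequencies; rebuild it with a positive pseudocount ",
      "before log-odds scoring",
      call. = FALSE
    )
  }
  lods <- log(sweep(pwm$frequencies, 1L, pwm$background, "/"))
  column_normalized_sum(sequences, lods, pwm$width)
}

#' Score sequences with the Match matrix similarity score
#'
#' Kel-style matrix similarity: each position contributes its base
#' frequency weighted by the column's information content,
#' `Current = sum_i I(i) * f(b_i, i)`, normalized as
#' `(Current - Min) / (Max - Min)` where `Min`/`Max` substitute the
#' per-column minimum/maximum frequency. The width-10 matrix is scored in
#' full; no core-region pre-filter is applied.
#'
#' @inheritParams pwmsa_score
#' @return numeric vector of scores in \[0, 1\].
#' @export
match_mss <- function(sequences, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  weighted <- sweep(pwm$frequencies, 2L, pwm$information, "*")
  column_normalized_sum(sequences, weighted, pwm$width)
}

# shared min-max normalized per-column sum used by both PWM scorers
column_normalized_sum <- function(sequences, cell, width) {
  sequences <- clean_dna(sequences, width = width)
  lo <- sum(apply(cell, 2L, min))
  hi <- sum(apply(cell, 2L, max))
  if (hi - lo <= 0) {
    stop("matrix carries no information: all columns are constant", call. = FALSE)
  }
  bm <- base_matrix(sequences, width)
  raw <- vapply(seq_along(sequences), function(k) {
    sum(cell[cbind(bm[k, ], seq_len(width))])
  }, numeric(1L))
  (raw - lo) / (hi - lo)
}

#' Reverse complement of DNA sequences
#'
#' @param sequences character vector of A/C/G/T strings.
#' @return character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement("GGGACTTTCC")
#' @export
reverse_complement <- function(sequences) {
  sequences <- clean_dna(sequences)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences)))
}

#' Scan a sequence for putative binding sites
#'
#' Slides a width-10 (or PWM-width) window over the sequence, scores every
#' window with the chosen model on the requested strand(s), and reports the
#' windows at or above the threshold. Coordinates are 0-based half-open on
#' the input (plus) strand; minus-strand hits report the same window with
#' `strand == "-"` and `site` as the reverse complement of the window, i.e.
#' the site as read 5'-3' on the minus strand.
#'
#' @param sequence a single DNA string of length >= the model width.
#' @param model `"snmm"`, `"pwmsa"` or `"match"`.
#' @param m a [snmm_matrix()] (required for `model = "snmm"`).
#' @param pwm a `pwm` (required for the PWM models).
#' @param threshold report windows scoring at least this much (default
#'   0.747, the optimized NF-kB p50 decision threshold).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param name sequence name copied into the result.
#' @return data frame with columns `name`, `start`, `end`, `strand`,
#'   `site`, `score`, `model`, sorted by `start` then strand. A sequence
#'   shorter than the window emits a warning and an empty result.
#' @export
scan_sequence <- function(sequence, model = c("snmm", "pwmsa", "match"),
                          m = NULL, pwm = NULL,
                          threshold = 0.747, strands = c("both", "+", "-"),
                          name = "seq") {
  model <- match.arg(model)
  strands <- match.arg(strands)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(sequence) == 1L)
  scorer <- switch(model,
    snmm = {
      stopifnot(inherits(m, "snmm_matrix"))
      function(x) snmm_score(x, m)
    },
    pwmsa = {
      stopifnot(inherits(pwm, "pwm"))
      function(x) pwmsa_score(x, pwm)
    },
    match = {
      stopifnot(inherits(pwm, "pwm"))
      function(x) match_mss(x, pwm)
    }
  )
  width <- if (model == "snmm") SITE_WIDTH else pwm$width

  empty <- data.frame(
    name = character(), start = integer(), end = integer(),
    strand = character(), site = character(), score = numeric(),
    model = character(), stringsAsFactors = FALSE
  )
  sequence <- clean_dna(sequence)
  if (nchar(sequence) < width) {
    warning("sequence shorter than the scanning window (", width,
      " bp); returning no hits",
      call. = FALSE
    )
    return(empty)
  }

  starts <- 0:(nchar(sequence) - width) # 0-based
  windows <- substring(sequence, starts + 1L, starts + width)
  hits <- empty
  if (strands %in% c("both", "+")) {
    sc <- scorer(windows)
    keep <- sc >= threshold
    if (any(keep)) {
      hits <- rbind(hits, data.frame(
        name = name, start = starts[keep], end = starts[keep] + width,
        strand = "+", site = windows[keep], score = sc[keep],
        model = model, stringsAsFactors = FALSE
      ))
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- reverse_complement(windows)
    sc <- scorer(rc)
    keep <- sc >= threshold
    if (any(keep)) {
      hits <- rbind(hits, data.frame(
        name = name, start = starts[keep], end = starts[keep] + width,
        strand = "-", site = rc[keep], score = sc[keep],
        model = model, stringsAsFactors = FALSE
      ))
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
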