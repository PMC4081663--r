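#' Build a position weight matrix from aligned sequences
#'
#' Tallies per-column base counts over a set of equal-length aligned binding
#' sites and converts them to frequencies with a background-weighted
#' pseudocount: `f(b, i) = (count(b, i) + pseudocount * background(b)) /
#' (N + pseudocount)`. The per-column information content is
#' `I(i) = sum_b f(b, i) * ln(4 * f(b, i))` with `0 * ln 0 = 0` — natural
#' logarithms throughout; the normalized Match score is invariant to the
#' base of the logarithm.
#'
#' @param sequences character vector of equal-length A/C/G/T strings.
#' @param pseudocount non-negative total pseudocount spread over bases by
#'   the background (default 1, Laplace-style). Comparator scores are
#'   sensitive to this value, so it is an explicit argument, never
#'   hard-coded downstream.
#' @param background base probabilities in A, C, G, T order (default
#'   uniform).
#' @param name free-text label.
#' @return an object of class `pwm` with elements `width`, `counts`,
#'   `frequencies`, `background`, `information`, `name`.
#' @examples
#' p <- build_pwm(c("ACGT", "ACGG", "ACTT"))
#' p$frequencies
#' @export
build_pwm <- function(sequences, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      name = "PWM") {
  sequences <- clean_dna(sequences)
  w <- unique(nchar(sequences))
  if (length(w) != 1L) {
    stop("aligned sequences must all have the same length (got ",
      paste(w, collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("'pseudocount' must be a single non-negative number", call. = FALSE)
  }
  background <- check_background(background)
  bm <- base_matrix(sequences, w)
  counts <- vapply(seq_len(w), function(i) {
    tab <- table(factor(bm[, i], levels = DNA_BASES))
    as.numeric(tab)
  }, numeric(4L))
  dimnames(counts) <- list(DNA_BASES, as.character(seq_len(w)))
  new_pwm(counts, pseudocount, background, name)
}

check_background <- function(background) {
  if (!is.numeric(background) || length(background) != 4L ||
    any(background <= 0) || abs(sum(background) - 1) > 1e-6) {
    stop("'background' must be 4 positive probabilities summing to 1", call. = FALSE)
  }
  names(background) <- DNA_BASES
  background
}

new_pwm <- function(counts, pseudocount, background, name) {
  if (any(counts < 0)) stop("PWM counts must be non-negative", call. = FALSE)
  w <- ncol(counts)
  n <- colSums(counts)
  freqs <- sweep(counts, 2L, n + pseudocount, "/") +
    outer(pseudocount * background, 1 / (n + pseudocount))
  csum <- colSums(freqs)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("internal error: frequency column(s) do not sum to 1", call. = FALSE)
  }
  info <- apply(freqs, 2L, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    sum(terms)
  })
  structure(
    list(
      width = w,
      counts = counts,
      frequencies = freqs,
      background = background,
      information = unname(pmax(info, 0)),
      name = as.character(name)[1L]
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("Position weight matrix: ", x$name, " (width ", x$width, ")\n", sep = "")
  cat("Consensus:", paste(DNA_BASES[apply(x$frequencies, 2L, which.max)],
    collapse = ""
  ), "\n")
  print(round(x$frequencies, 3), ...)
  invisible(x)
}

#' Read a TRANSFAC flat-file count matrix
#'
#' Parses the TRANSFAC matrix dialect: free header lines, a `P0` column
#' header naming the base order, numbered count rows (one per motif
#' position, strictly increasing), and a `//` terminator. Trailing
#' consensus letters on count rows are ignored.
#'
#' @param path file path to a TRANSFAC matrix record.
#' @inheritParams build_pwm
#' @return a `pwm` whose width is the number of count rows.
#' @export
read_transfac <- function(path, pseudocount = 1,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- trimws(readLines(path), which = "right")
  p0 <- grep("^P0\\b|^PO\\b", lines)
  if (length(p0) != 1L) {
    stop("no P0 column header found in TRANSFAC file: ", path, call. = FALSE)
  }
  if (!any(grepl("^//", lines))) {
    stop("missing '//' terminator in TRANSFAC file: ", path, call. = FALSE)
  }
  header <- strsplit(lines[p0], "\\s+")[[1L]][-1L]
  if (!setequal(header[1:4], DNA_BASES)) {
    stop("P0 header must name bases A, C, G, T in ", path, call. = FALSE)
  }
  term <- grep("^//", lines)
  term <- term[term > p0][1L]
  if (is.na(term)) {
    stop("missing '//' terminator after the count block in ", path, call. = FALSE)
  }
  body <- lines[(p0 + 1L):(term - 1L)]
  body <- body[grepl("^[0-9]+\\s", body)]
  if (length(body) == 0L) stop("no count rows found in ", path, call. = FALSE)
  rows <- strsplit(body, "\\s+")
  idx <- as.integer(vapply(rows, `[[`, character(1L), 1L))
  if (any(diff(idx) <= 0L)) {
    stop("count row numbers must be strictly increasing in ", path, call. = FALSE)
  }
  counts <- matrix(NA_real_, 4L, length(rows), dimnames = list(DNA_BASES, idx))
  for (k in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[k]][2:5]))
    if (anyNA(vals)) {
      stop("non-numeric counts on row ", idx[k], " of ", path, call. = FALSE)
    }
    counts[header[1:4], k] <- vals
  }
  nm <- grep("^(NA|ID)\\s", lines, value = TRUE)
  nm <- if (length(nm)) sub("^(NA|ID)\\s+", "", nm[1L]) else basename(path)
  new_pwm(counts, pseudocount, check_background(background), nm)
}
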