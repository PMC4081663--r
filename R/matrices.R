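#' Construct a single-nucleotide mutation matrix object
#'
#' A `snmm_matrix` holds the affinity model for one transcription-factor
#' site: a reference 10-mer and a 4 x 10 grid of normalized signal-intensity
#' differences, one row per base (A, C, G, T) and one column per site
#' position. The cell of the reference base at each position is the
#' normalization anchor and is exactly 0; every other cell is the measured
#' affinity change caused by that single-base substitution.
#'
#' @param reference the 10-character reference site (A/C/G/T).
#' @param delta numeric 4 x 10 matrix with rownames A, C, G, T and one column
#'   per position. Reference-base cells must be 0.
#' @param name free-text label.
#' @param degraded character vector of probe sequences whose cells were
#'   imputed rather than measured (empty for a fully measured matrix).
#' @return an object of class `snmm_matrix`.
#' @seealso [build_snmm()], [read_snmm()], [snmm_score()]
#' @export
snmm_matrix <- function(reference, delta, name = "SNMM", degraded = character()) {
  reference <- clean_dna(reference, width = SITE_WIDTH)
  if (!is.matrix(delta) || !is.numeric(delta)) {
    stop("'delta' must be a numeric matrix", call. = FALSE)
  }
  if (!identical(dim(delta), c(4L, as.integer(SITE_WIDTH)))) {
    stop(
      "'delta' must be 4 x ", SITE_WIDTH, " (got ",
      paste(dim(delta), collapse = " x "), ")",
      call. = FALSE
    )
  }
  if (is.null(rownames(delta)) || !setequal(rownames(delta), DNA_BASES)) {
    stop("'delta' rownames must be A, C, G, T", call. = FALSE)
  }
  delta <- delta[DNA_BASES, , drop = FALSE]
  colnames(delta) <- as.character(seq_len(SITE_WIDTH))
  m <- structure(
    list(
      reference = reference,
      delta = delta,
      name = as.character(name)[1L],
      degraded = as.character(degraded)
    ),
    class = "snmm_matrix"
  )
  validate_snmm_matrix(m)
  m
}

#' Validate the invariants of a mutation matrix
#'
#' Checks the 4 x 10 shape, finiteness of all cells, that every
#' reference-base cell is exactly 0 (the normalization anchor), and that
#' `s_min(m) <= 0 <= s_max(m)` (which follows from the anchor cells).
#'
#' @param m a [snmm_matrix()].
#' @return `m`, invisibly; errors describe the violated invariant.
#' @export
validate_snmm_matrix <- function(m) {
  stopifnot(inherits(m, "snmm_matrix"))
  if (!all(is.finite(m$delta))) {
    stop("mutation matrix contains non-finite cells", call. = FALSE)
  }
  ref <- strsplit(m$reference, "", fixed = TRUE)[[1L]]
  anchor <- m$delta[cbind(ref, seq_len(SITE_WIDTH))]
  if (any(anchor != 0)) {
    bad <- which(anchor != 0)
    stop(
      "reference-base cell(s) must be 0 (the normalization anchor): position ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (s_min(m) > 0 || s_max(m) < 0) {
    stop("invariant s_min <= 0 <= s_max violated", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.snmm_matrix <- function(x, ...) {
  cat(
    "Single-nucleotide mutation matrix: ", x$name, "\n",
    "  reference ", x$reference,
    "  s_min ", format(s_min(x)), "  s_max ", format(s_max(x)), "\n",
    sep = ""
  )
  if (length(x$degraded)) {
    cat("  DEGRADED: imputed cells for probe(s) ",
      paste(x$degraded, collapse = ", "), "\n",
      sep = ""
    )
  }
  print(round(x$delta, 2), ...)
  invisible(x)
}

#' Lowest and highest attainable score sums
#'
#' `s_min()` is the sum over positions of the lowest cell in each column of
#' the mutation matrix; `s_max()` the sum of the highest. They are the
#' extremes of the raw score sum over all 4^10 possible 10-mers and define
#' the min-max normalization of [snmm_score()].
#'
#' @param m a [snmm_matrix()].
#' @return a single numeric value.
#' @export
s_min <- function(m) {
  stopifnot(inherits(m, "snmm_matrix"))
  sum(apply(m$delta, 2L, min))
}

#' @rdname s_min
#' @export
s_max <- function(m) {
  stopifnot(inherits(m, "snmm_matrix"))
  sum(apply(m$delta, 2L, max))
}

#' Build a mutation matrix from microarray probe intensities
#'
#' Takes a table of probe intensities for a reference site and its
#' single-base mutants (each probe spotted in one or more replicates) and
#' normalizes each mutant by subtracting the reference signal:
#' `delta[b, n] = agg(mutant b at position n) - agg(reference)`, with the
#' arithmetic mean as the default replicate aggregator. Reference-base cells
#' are set to exactly 0.
#'
#' A complete panel has all 30 single-base mutants. By default a missing
#' mutant probe is an error, since every scoring column needs all four
#' cells. With `allow_incomplete = TRUE` a missing cell is imputed with the
#' minimum of the measured cells in its column (a conservative
#' lowest-affinity guess) and the matrix is flagged as degraded;
#' [snmm_score()] refuses degraded matrices unless explicitly allowed.
#'
#' @param intensities an intensity table: data frame with a `probe` column of
#'   10-mers and one or more numeric replicate columns (`NA` allowed, each
#'   probe needs at least one value). See [read_intensity_table()].
#' @param reference the reference 10-mer; must be present in the table.
#' @param aggregate replicate aggregator, `"mean"` (default) or `"median"`.
#' @param allow_incomplete impute missing mutant probes instead of failing.
#' @return a [snmm_matrix()].
#' @examples
#' m <- nfkb_snmm_matrix()
#' tab <- simulate_microarray(m, noise_sd = 0)
#' m2 <- build_snmm(tab, reference = m$reference)
#' all.equal(m2$delta, m$delta)
#' @export
build_snmm <- function(intensities, reference,
                       aggregate = c("mean", "median"),
                       allow_incomplete = FALSE) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  reference <- clean_dna(reference, width = SITE_WIDTH)
  if (!is.data.frame(intensities) || !"probe" %in% names(intensities)) {
    stop("'intensities' must be a data frame with a 'probe' column", call. = FALSE)
  }
  probes <- clean_dna(as.character(intensities$probe), width = SITE_WIDTH)
  reps <- as.matrix(intensities[setdiff(names(intensities), "probe")])
  if (!is.numeric(reps) || ncol(reps) < 1L) {
    stop("'intensities' needs at least one numeric replicate column", call. = FALSE)
  }
  if (any(rowSums(!is.na(reps)) == 0L)) {
    stop("probe(s) with no replicate values: ",
      paste(probes[rowSums(!is.na(reps)) == 0L], collapse = ", "),
      call. = FALSE
    )
  }

  # duplicate probes are allowed only when their rows agree
  if (anyDuplicated(probes)) {
    for (p in unique(probes[duplicated(probes)])) {
      rows <- reps[probes == p, , drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop("duplicate probe with conflicting intensities: ", p, call. = FALSE)
      }
    }
    keep <- !duplicated(probes)
    probes <- probes[keep]
    reps <- reps[keep, , drop = FALSE]
  }

  ref_bases <- strsplit(reference, "", fixed = TRUE)[[1L]]
  mism <- vapply(probes, function(p) {
    sum(strsplit(p, "", fixed = TRUE)[[1L]] != ref_bases)
  }, integer(1L))
  if (any(mism > 1L)) {
    stop(
      "probe(s) are not single-base mutants of ", reference, ": ",
      paste(probes[mism > 1L], collapse = ", "),
      call. = FALSE
    )
  }
  if (!reference %in% probes) {
    stop("reference probe ", reference, " absent from the intensity table", call. = FALSE)
  }

  level <- vapply(seq_along(probes), function(i) {
    agg_fun(reps[i, ][!is.na(reps[i, ])])
  }, numeric(1L))
  names(level) <- probes
  ref_level <- level[[reference]]

  delta <- matrix(NA_real_, 4L, SITE_WIDTH,
    dimnames = list(DNA_BASES, as.character(seq_len(SITE_WIDTH)))
  )
  delta[cbind(ref_bases, as.character(seq_len(SITE_WIDTH)))] <- 0
  for (n in seq_len(SITE_WIDTH)) {
    for (b in setdiff(DNA_BASES, ref_bases[n])) {
      mut <- reference
      substr(mut, n, n) <- b
      if (mut %in% probes) {
        delta[b, n] <- level[[mut]] - ref_level
      }
    }
  }

  degraded <- character()
  if (anyNA(delta)) {
    miss <- which(is.na(delta), arr.ind = TRUE)
    missing_probes <- vapply(seq_len(nrow(miss)), function(k) {
      mut <- reference
      substr(mut, miss[k, 2L], miss[k, 2L]) <- DNA_BASES[miss[k, 1L]]
      mut
    }, character(1L))
    if (!allow_incomplete) {
      stop(
        "incomplete mutant panel; missing probe(s): ",
        paste(sort(missing_probes), collapse = ", "),
        " (use allow_incomplete = TRUE to impute)",
        call. = FALSE
      )
    }
    for (n in seq_len(SITE_WIDTH)) {
      col <- delta[, n]
      if (anyNA(col)) delta[is.na(col), n] <- min(col, na.rm = TRUE)
    }
    degraded <- sort(missing_probes)
  }

  snmm_matrix(reference, delta, name = "SNMM (built from intensities)",
    degraded = degraded
  )
}

#' Read and write mutation matrices as TSV
#'
#' The on-disk format is a plain TSV: comment lines `#reference=` (required)
#' and `#name=` (optional), a header row numbering the positions 1..10, and
#' four data rows labelled A, C, G, T. `write_snmm()` followed by
#' `read_snmm()` reproduces every cell exactly.
#'
#' @param path file path.
#' @return `read_snmm()` returns a [snmm_matrix()]; `write_snmm()` returns
#'   `path` invisibly.
#' @export
read_snmm <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  ref <- sub("^#reference=", "", grep("^#reference=", comments, value = TRUE))
  if (length(ref) != 1L) {
    stop("matrix file must carry exactly one '#reference=' line: ", path, call. = FALSE)
  }
  nm <- sub("^#name=", "", grep("^#name=", comments, value = TRUE))
  if (length(nm) == 0L) nm <- "SNMM"

  if (length(body) != 5L) {
    stop("expected a header row plus 4 base rows in ", path,
      " (got ", length(body), " rows)",
      call. = FALSE
    )
  }
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) - 1L != SITE_WIDTH ||
    !identical(header[-1L], as.character(seq_len(SITE_WIDTH)))) {
    stop("header must number positions 1..", SITE_WIDTH,
      " (expected width ", SITE_WIDTH, ") in ", path,
      call. = FALSE
    )
  }
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  labels <- vapply(rows, `[[`, character(1L), 1L)
  if (!setequal(labels, DNA_BASES)) {
    stop("base row labels must be A, C, G, T (got ",
      paste(labels, collapse = ", "), ") in ", path,
      call. = FALSE
    )
  }
  delta <- matrix(NA_real_, 4L, SITE_WIDTH, dimnames = list(labels, NULL))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1L]
    if (length(vals) != SITE_WIDTH) {
      stop("row ", labels[i], " has ", length(vals), " cells; expected width ",
        SITE_WIDTH, " in ", path,
        call. = FALSE
      )
    }
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      stop("non-numeric cell at row ", labels[i], ", column ",
        which(is.na(num))[1L], " in ", path,
        call. = FALSE
      )
    }
    delta[i, ] <- num
  }
  snmm_matrix(ref, delta, name = nm)
}

#' @param m a [snmm_matrix()].
#' @rdname read_snmm
#' @export
write_snmm <- function(m, path) {
  stopifnot(inherits(m, "snmm_matrix"))
  fmt_cell <- function(x) {
    # shortest decimal text (>= 2 dp) that parses back to the same double
    short <- sprintf("%.2f", x)
    if (as.numeric(short) == x) short else sprintf("%.17g", x)
  }
  lines <- c(
    paste0("#reference=", m$reference),
    paste0("#name=", m$name),
    paste(c("", as.character(seq_len(SITE_WIDTH))), collapse = "\t"),
    vapply(DNA_BASES, function(b) {
      paste(c(b, vapply(m$delta[b, ], fmt_cell, character(1L))), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}
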