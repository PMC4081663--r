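#' Bundled NF-kB p50 mutation matrix
#'
#' The published 4 x 10 single-nucleotide mutation matrix for the NF-kB
#' p50 homodimer, measured on a bimolecular dsDNA microarray against the
#' wild-type site `GGGACTTTCC`. Cells are normalized signal-intensity
#' differences (mutant minus wild type); reference-base cells are 0.
#'
#' @return a [snmm_matrix()].
#' @examples
#' m <- nfkb_snmm_matrix()
#' s_min(m) # -301.5
#' s_max(m) # 13.87
#' @export
nfkb_snmm_matrix <- function() {
  read_snmm(system.file("extdata", "nfkb_p50_snmm.tsv",
    package = "snmm", mustWork = TRUE
  ))
}

#' Bundled NF-kB p50 affinity dataset
#'
#' Fifty-two 10-bp sequences with measured and modelled NF-kB p50 binding
#' affinities: `EMSA` (log relative band intensity from radioactive EMSA),
#' `PC` (principal-coordinate model score, consumed as published), `SNMM`,
#' `PWMSA` and `Match` model scores (3 dp), and `PBM` (protein-binding
#' microarray z-score; 11 sequences have none and carry `NA`).
#'
#' @return data frame with columns `sequence`, `EMSA`, `PC`, `SNMM`,
#'   `PWMSA`, `Match`, `PBM`.
#' @examples
#' d <- nfkb_affinity_dataset()
#' nrow(d) # 52
#' sum(!is.na(d$PBM)) # 41
#' @export
nfkb_affinity_dataset <- function() {
  read_affinity_dataset(system.file("extdata", "nfkb_p50_affinities.tsv",
    package = "snmm", mustWork = TRUE
  ))
}

#' Read an affinity dataset from TSV
#'
#' Expects a header row with a `sequence` column plus numeric measurement
#' or score columns; empty cells or `NA` mark missing measurements.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_affinity_dataset <- function(path) {
  d <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE, na.strings = c("NA", "")
  )
  if (!"sequence" %in% names(d)) {
    stop("affinity table needs a 'sequence' column: ", path, call. = FALSE)
  }
  if (anyDuplicated(d$sequence)) {
    stop("duplicate sequences in affinity table: ",
      paste(unique(d$sequence[duplicated(d$sequence)]), collapse = ", "),
      call. = FALSE
    )
  }
  num <- d[setdiff(names(d), "sequence")]
  if (any(rowSums(!is.na(num)) == 0L)) {
    stop("row(s) with no numeric value at all in ", path, call. = FALSE)
  }
  d
}

#' Bundled synthetic NF-kB p50 PWM
#'
#' A TRANSFAC-format count matrix over 18 synthetic SELEX-like NF-kB p50
#' binding sites following the GGGRNTYYCC consensus. It is a constructed
#' stand-in distributed for self-contained examples and for Match-based
#' rejection sampling of non-sites; swap in a curated matrix (e.g. a
#' TRANSFAC NF-kB p50 record) via [read_transfac()] for production
#' comparator scoring.
#'
#' @inheritParams build_pwm
#' @return a `pwm` of width 10.
#' @export
nfkb_pwm <- function(pseudocount = 1,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  read_transfac(
    system.file("extdata", "nfkb_p50_pwm_synthetic.transfac",
      package = "snmm", mustWork = TRUE
    ),
    pseudocount = pseudocount, background = background
  )
}

#' Simulate a single-nucleotide mutant microarray experiment
#'
#' Emulates the data structure of the mutation-matrix microarray: 31
#' probes (the reference site plus its 30 single-base mutants), each
#' spotted in `replicates` spots. Reference spots draw from
#' `Normal(base_intensity, noise_sd)`; each mutant adds its matrix cell to
#' the mean. The Gaussian error model is a synthetic-data convention, not
#' a measured property of any scanner. Negative draws are truncated at 0
#' with a warning.
#'
#' @param m the true [snmm_matrix()].
#' @param base_intensity reference signal level (> 0; default 1000).
#' @param noise_sd Gaussian noise standard deviation per spot (default 0).
#' @param replicates spots per probe (default 3, matching triplicate
#'   arraying).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return an intensity table: data frame with `probe` and `rep1..repK`
#'   columns, reference probe first.
#' @examples
#' m <- nfkb_snmm_matrix()
#' tab <- simulate_microarray(m, noise_sd = 2, seed = 1)
#' head(tab)
#' @export
simulate_microarray <- function(m, base_intensity = 1000, noise_sd = 0,
                                replicates = 3L, seed = NULL) {
  stopifnot(inherits(m, "snmm_matrix"))
  if (!is.numeric(base_intensity) || base_intensity <= 0) {
    stop("'base_intensity' must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("need at least 1 replicate", call. = FALSE)

  ref_bases <- strsplit(m$reference, "", fixed = TRUE)[[1L]]
  probes <- m$reference
  means <- base_intensity
  for (n in seq_len(SITE_WIDTH)) {
    for (b in setdiff(DNA_BASES, ref_bases[n])) {
      mut <- m$reference
      substr(mut, n, n) <- b
      probes <- c(probes, mut)
      means <- c(means, base_intensity + m$delta[b, n])
    }
  }

  draw <- function() {
    vals <- matrix(
      stats::rnorm(length(probes) * replicates,
        mean = rep(means, each = replicates), sd = noise_sd
      ),
      nrow = length(probes), byrow = TRUE
    )
    if (any(vals < 0)) {
      warning("truncating ", sum(vals < 0), " negative intensity draw(s) at 0",
        call. = FALSE
      )
      vals[vals < 0] <- 0
    }
    vals
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- data.frame(probe = probes, vals, stringsAsFactors = FALSE)
  names(out) <- c("probe", paste0("rep", seq_len(replicates)))
  out
}

#' Read and write intensity tables
#'
#' TSV with a `probe` column of 10-mers and one or more numeric replicate
#' columns (`rep1`, `rep2`, ...).
#'
#' @param path TSV file path.
#' @return `read_intensity_table()` returns the data frame;
#'   `write_intensity_table()` returns `path` invisibly.
#' @export
read_intensity_table <- function(path) {
  d <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
  if (!"probe" %in% names(d) || ncol(d) < 2L) {
    stop("intensity table needs 'probe' plus replicate columns: ", path,
      call. = FALSE
    )
  }
  d
}

#' @param intensities intensity table data frame.
#' @rdname read_intensity_table
#' @export
write_intensity_table <- function(intensities, path) {
  utils::write.table(intensities, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Uniform random 10-mers
#'
#' @param n number of sequences (0 allowed).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param weights base sampling probabilities in A, C, G, T order
#'   (default uniform).
#' @return character vector of `n` 10-mers.
#' @export
random_10mers <- function(n, seed = NULL,
                          weights = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  weights <- check_background(weights / sum(weights))
  if (n == 0L) return(character())
  draw <- function() {
    bases <- sample(DNA_BASES, n * SITE_WIDTH, replace = TRUE, prob = weights)
    apply(matrix(bases, nrow = n), 1L, paste, collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
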