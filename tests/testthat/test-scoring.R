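published_scores <- function() {
  d <- nfkb_affinity_dataset()
  m <- nfkb_snmm_matrix()
  data.frame(sequence = d$sequence, printed = d$SNMM,
    computed = snmm_score(d$sequence, m)
  )
}

test_that("mutation-matrix scores reproduce the full published 52-site column", {
  tab <- published_scores()
  expect_true(all(abs(round(tab$computed, 3) - tab$printed) <= 5e-4))
  pick <- function(s) round(tab$computed[tab$sequence == s], 3)
  expect_equal(pick("GGGGATTCCC"), 0.987)
  expect_equal(pick("GGGGAATCCC"), 0.903)
  expect_equal(pick("GGAGAACCCC"), 0.747)
  expect_equal(pick("GGAGACCTCC"), 0.699)
  expect_equal(pick("GGAGGCCTCC"), 0.694)
})

test_that("score extremes and the reference site land where the normalization says", {
  m <- nfkb_snmm_matrix()
  expect_identical(snmm_score("GGGATTTCCC", m), 1) # per-column argmax
  expect_identical(snmm_score("CCCCCCAGGT", m), 0) # per-column argmin
  expect_equal(snmm_score(m$reference, m), 301.50 / 315.37, tolerance = 1e-12)
  expect_equal(round(snmm_score(m$reference, m), 3), 0.956)
})

test_that("scores stay in [0, 1] for any sequence and any valid matrix", {
  for (seed in c(11, 12)) {
    m <- random_snmm_matrix(seed)
    scores <- snmm_score(random_10mers(2000, seed = seed + 100), m)
    expect_true(all(scores >= -1e-12 & scores <= 1 + 1e-12))
    expect_identical(snmm_score(argmax_sequence(m), m), 1)
    expect_identical(snmm_score(argmin_sequence(m), m), 0)
  }
  # exhaustive over one varying column, the rest held at the reference
  m <- nfkb_snmm_matrix()
  for (b in c("A", "C", "G", "T")) {
    s <- m$reference
    substr(s, 5, 5) <- b
    expect_true(snmm_score(s, m) >= 0 && snmm_score(s, m) <= 1)
  }
})

test_that("substituting a strictly better base strictly raises the score", {
  m <- nfkb_snmm_matrix()
  start <- random_10mers(1, seed = 99)
  for (pos in 1:10) {
    for (from in c("A", "C", "G", "T")) {
      for (to in c("A", "C", "G", "T")) {
        if (m$delta[to, pos] <= m$delta[from, pos]) next
        lo <- hi <- start
        substr(lo, pos, pos) <- from
        substr(hi, pos, pos) <- to
        expect_gt(snmm_score(hi, m), snmm_score(lo, m))
      }
    }
  }
})

test_that("scoring agrees with brute-force enumeration on a 3-variable-column matrix", {
  # only positions 2, 5, 8 vary; all other columns are identically 0
  delta <- matrix(0, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  withr::with_seed(7, {
    for (pos in c(2, 5, 8)) delta[, pos] <- rnorm(4, -10, 6)
  })
  reference <- "GGGACTTTCC"
  ref_bases <- strsplit(reference, "")[[1]]
  delta[cbind(match(ref_bases, c("A", "C", "G", "T")), 1:10)] <- 0
  m <- snmm_matrix(reference, delta)

  combos <- expand.grid(b2 = c("A", "C", "G", "T"), b5 = c("A", "C", "G", "T"),
    b8 = c("A", "C", "G", "T"), stringsAsFactors = FALSE
  )
  seqs <- apply(combos, 1, function(b) {
    s <- reference
    substr(s, 2, 2) <- b[["b2"]]
    substr(s, 5, 5) <- b[["b5"]]
    substr(s, 8, 8) <- b[["b8"]]
    s
  })
  md <- m$delta
  raw <- md[cbind(combos$b2, "2")] + md[cbind(combos$b5, "5")] +
    md[cbind(combos$b8, "8")]
  oracle <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(snmm_score(seqs, m), oracle, tolerance = 1e-12)
  expect_equal(oracle[which.max(raw)], 1)
  expect_equal(oracle[which.min(raw)], 0)
})

test_that("PWM scorers hit exactly 1 and 0 at the per-column extremes", {
  pwm <- nfkb_pwm()
  fmax <- paste(rownames(pwm$frequencies)[apply(pwm$frequencies, 2, which.max)],
    collapse = ""
  )
  fmin <- paste(rownames(pwm$frequencies)[apply(pwm$frequencies, 2, which.min)],
    collapse = ""
  )
  expect_equal(pwmsa_score(fmax, pwm), 1, tolerance = 1e-12)
  expect_equal(pwmsa_score(fmin, pwm), 0, tolerance = 1e-12)
  expect_equal(match_mss(fmax, pwm), 1, tolerance = 1e-12)
  expect_equal(match_mss(fmin, pwm), 0, tolerance = 1e-12)
  scores <- c(
    pwmsa_score(random_10mers(500, seed = 3), pwm),
    match_mss(random_10mers(500, seed = 4), pwm)
  )
  expect_true(all(scores >= -1e-12 & scores <= 1 + 1e-12))
})

test_that("log-odds scoring demands a positive pseudocount", {
  sparse <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_error(pwmsa_score("ACGT", sparse), "pseudocount")
  expect_silent(pwmsa_score("ACGT", build_pwm(c("ACGT", "ACGT"), pseudocount = 1)))
})

test_that("reverse complement is the Watson-Crick involution", {
  expect_identical(reverse_complement("GGGACTTTCC"), "GGAAAGTCCC")
  expect_identical(reverse_complement("A"), "T")
  x <- random_10mers(50, seed = 5)
  expect_identical(reverse_complement(reverse_complement(x)), x)
})

test_that("sequence canonicalization uppercases, maps U and rejects ambiguity codes", {
  m <- nfkb_snmm_matrix()
  expect_identical(
    snmm_score("gggacuuucc", m),
    snmm_score("GGGACTTTCC", m)
  )
  expect_error(snmm_score("GGGACTTTCN", m), "A/C/G/T")
  expect_error(snmm_score("GGGACTTT", m), "length")
})

test_that("scanning finds a spliced site on either strand at its true offset", {
  m <- nfkb_snmm_matrix()
  backbone <- strrep("A", 50)
  planted <- paste0(substr(backbone, 1, 5), "GGGGATTCCC", substr(backbone, 16, 50))
  fwd <- scan_sequence(planted, "snmm", m = m, threshold = 0.9, strands = "+")
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$start, 5L)
  expect_identical(fwd$end, 15L)
  expect_identical(fwd$strand, "+")
  expect_equal(round(fwd$score, 3), 0.987)

  rc_planted <- paste0(
    substr(backbone, 1, 5), reverse_complement("GGGGATTCCC"),
    substr(backbone, 16, 50)
  )
  rev <- scan_sequence(rc_planted, "snmm", m = m, threshold = 0.95, strands = "both")
  expect_identical(nrow(rev), 1L)
  expect_identical(rev$start, 5L)
  expect_identical(rev$strand, "-")
  expect_identical(rev$site, "GGGGATTCCC")
  expect_equal(round(rev$score, 3), 0.987)

  solo <- scan_sequence("GGGATTTCCC", "snmm", m = m, threshold = 1, strands = "+")
  expect_identical(nrow(solo), 1L)
  expect_identical(solo$score, 1)
})

test_that("scanning a too-short sequence warns and returns an empty frame", {
  m <- nfkb_snmm_matrix()
  expect_warning(hits <- scan_sequence("ACGTACG", "snmm", m = m), "shorter")
  expect_identical(nrow(hits), 0L)
})

test_that("window scores equal direct scoring of the extracted site", {
  m <- nfkb_snmm_matrix()
  pwm <- nfkb_pwm()
  seq <- paste(random_10mers(4, seed = 21), collapse = "")
  for (model in c("snmm", "pwmsa", "match")) {
    hits <- scan_sequence(seq, model, m = m, pwm = pwm,
      threshold = 0, strands = "+"
    )
    direct <- switch(model,
      snmm = snmm_score(hits$site, m),
      pwmsa = pwmsa_score(hits$site, pwm),
      match = match_mss(hits$site, pwm)
    )
    expect_equal(hits$score, direct)
  }
})

test_that("both-strand scans equal the union of forward scans of each strand", {
  m <- nfkb_snmm_matrix()
  seq <- paste(random_10mers(5, seed = 31), collapse = "")
  both <- scan_sequence(seq, "snmm", m = m, threshold = 0.4, strands = "both")
  plus <- scan_sequence(seq, "snmm", m = m, threshold = 0.4, strands = "+")
  minus_via_rc <- scan_sequence(reverse_complement(seq), "snmm",
    m = m, threshold = 0.4, strands = "+"
  )
  # map coordinates of hits on rc(x) back onto x
  L <- nchar(seq)
  mapped <- data.frame(
    start = L - (minus_via_rc$end), end = L - minus_via_rc$start,
    site = minus_via_rc$site, score = minus_via_rc$score
  )
  mapped <- mapped[order(mapped$start), ]
  from_both <- both[both$strand == "-", c("start", "end", "site", "score")]
  expect_equal(nrow(both), nrow(plus) + nrow(mapped))
  expect_equal(from_both$start, mapped$start)
  expect_equal(from_both$site, mapped$site)
  expect_equal(from_both$score, mapped$score)
})
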