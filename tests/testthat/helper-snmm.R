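# shared generators for property-style tests

# a random but valid mutation matrix: random reference, mostly deleterious
# mutant cells (as real single-mutant panels are), anchor cells 0
random_snmm_matrix <- function(seed) {
  withr::with_seed(seed, {
    reference <- random_10mers(1L)
    delta <- matrix(rnorm(40, mean = -20, sd = 12), 4, 10,
      dimnames = list(c("A", "C", "G", "T"), NULL)
    )
    ref_bases <- strsplit(reference, "")[[1]]
    delta[cbind(match(ref_bases, c("A", "C", "G", "T")), 1:10)] <- 0
    snmm_matrix(reference, delta, name = paste0("random-", seed))
  })
}

# per-column argmax / argmin sequences, ties broken A < C < G < T
argmax_sequence <- function(m) {
  paste(rownames(m$delta)[apply(m$delta, 2, which.max)], collapse = "")
}
argmin_sequence <- function(m) {
  paste(rownames(m$delta)[apply(m$delta, 2, which.min)], collapse = "")
}
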