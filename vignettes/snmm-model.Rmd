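---
title: "Scoring NF-kB p50 binding sites with a single-nucleotide mutation matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring NF-kB p50 binding sites with a single-nucleotide mutation matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snmm)
```

## The model

NF-kB is a sequence-specific transcription factor whose DNA-binding sites
(DBSs) are 10 bp long and highly variable; consensus descriptions such as
GGRRNNYYCC cover only part of the binding landscape. The model at the heart
of this package is a **single-nucleotide mutation matrix (SNMM)**: the
binding affinity of the NF-kB p50 homodimer was measured on a
double-stranded DNA microarray for a wild-type site, `GGGACTTTCC`, and for
each of its 30 single-base mutants, and each mutant's signal was normalized
by subtracting the wild-type signal. The result is a 4 x 10 matrix
$\Delta S(b, n)$ of affinity changes, with the reference base's cell at each
position fixed at 0 by construction.

Under the additivity assumption shared by all mononucleotide models, a
10-mer $s = b_1 \dots b_{10}$ is scored by

$$\mathrm{score}(s) \;=\;
\frac{S_{ref} + \sum_{n=1}^{10} \Delta S(b_n, n) \; - \; S_{min}}
     {S_{max} - S_{min}},
\qquad S_{ref} = 0,$$

where $S_{min}$ and $S_{max}$ are the sums of the per-position column minima
and maxima. The score always lies in $[0, 1]$: the per-column argmax
sequence attains exactly 1, the per-column argmin sequence exactly 0, and
the wild-type site scores $(0 - S_{min})/(S_{max} - S_{min}) = 0.956$ with
the bundled matrix ($S_{min} = -301.50$, $S_{max} = 13.87$).

```{r}
m <- nfkb_snmm_matrix()
m
snmm_score(c("GGGGATTCCC", "GGGACTTTCC", "GGAGGCCTCC"), m)
```

Because the matrix assigns a value to every base at every position, the
model scores *any* 10-mer — unlike regression models restricted to a
consensus (the principal-coordinate model covers only the 256 GGRRNNYYCC
sequences; its scores are consumed here as a published data column, never
recomputed).

## Comparator models

Two classical position-weight-matrix scorers are provided for comparison,
both min-max normalized to $[0, 1]$ so that the per-column argmax sequence
scores 1:

* **PWMSA** (Stormo-style log-odds):
  $\sum_i \ln\!\big(f(b_i, i)/q(b_i)\big)$ with background $q$ (uniform by
  default), normalized by the per-column extreme log-odds.
* **Match MSS** (Kel-style matrix similarity):
  $\sum_i I(i)\, f(b_i, i)$ with per-column information
  $I(i) = \sum_b f(b,i)\ln(4 f(b,i))$, normalized by the per-column extreme
  frequencies. Natural logarithms are used throughout; the normalized score
  is invariant to that choice. The classical 5-bp core pre-filter is not
  applied — for a width-10 site the full-matrix score is the quantity of
  interest.

Frequencies come from counts via a background-spread pseudocount,
$f(b,i) = (c(b,i) + \alpha\, q(b)) / (N + \alpha)$ with $\alpha = 1$ by
default. PWM scores are sensitive to $\alpha$, so it is an explicit
argument everywhere and never baked into a scorer.

The bundled PWM (`nfkb_pwm()`) is a **synthetic** 18-sequence count matrix
following the canonical GGGRNTYYCC-like consensus. It exists so that
examples, non-site generation and tests are self-contained; users comparing
against a curated NF-kB p50 matrix (e.g. a TRANSFAC record) should load it
with `read_transfac()`. Consequently the PWMSA/Match columns of the bundled
affinity dataset are treated as published data to correlate against, not as
values this package re-derives.

## Evaluation against measured affinities

The bundled dataset carries 52 10-bp sites with measured and modelled
affinities: EMSA log band intensities, PBM z-scores (41 of 52 sites; the
rest are missing, stored as `NA`, never 0) and model score columns.
Agreement is quantified by Pearson's r with the two-sided p value from the
exact t transform, $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom
(cross-checked against `cor.test()` in the test suite). Missing data are
handled by pairwise-complete deletion, so each model is evaluated on the
largest usable subset — that is why EMSA comparisons use n = 52 and PBM
comparisons n = 41.

```{r}
d <- nfkb_affinity_dataset()
d$SNMM_recomputed <- snmm_score(d$sequence, m)
correlate_models(d, "EMSA", c("PC", "SNMM_recomputed", "PWMSA", "Match", "PBM"))
```

Verbal strength labels follow the conventional five intervals on $|r|$,
half-open on the left: $[0, 0.2)$ very weak up to $[0.8, 1]$ very strong.
The boundary convention puts 0.8 in "very strong", matching the usual
description of coefficients like 0.884; the sign is reported separately.

## The decision threshold

To turn scores into site/non-site calls, a threshold is optimized by grid
search: S1 is the 30 highest-EMSA sequences of the dataset (deterministic
ranking, lexicographic tie-break at the cut), S2 is 30 random 10-mers the
Match model rejects, and every threshold from 0 to 1 in steps of 0.001 is
evaluated for the false-negative rate rFN (fraction of S1 missed) and
false-positive rate rFP (fraction of S2 accepted).

Three numerical choices matter and are deliberate:

* **Predicate.** A score counts as a predicted site when
  `round(score, 3) >= threshold`. Rounding to the grid resolution makes a
  site whose 3-dp score equals the threshold a positive call — necessary
  for the boundary member of S1 (score 0.747) to be classified correctly —
  and comparisons are done in integer thousandths so grid points and
  rounded scores never disagree by a floating-point ulp.
* **Tie-break.** Among thresholds minimizing rFN + rFP: smaller rFN first,
  then the *largest* threshold (the most stringent equally-good predictor).
  On cleanly separated groups this provably returns exactly the minimum
  rounded S1 score with rFN = rFP = 0.
* **"Rejected by Match".** A literal Match score of zero is attained only
  by the per-column-minimum sequence, so rejection is interpreted as
  `match_mss < 0.5`; the cutoff is an argument. The optimum is insensitive
  to the S2 draw whenever all S2 scores stay below the minimum S1 score,
  which the test suite confirms across 100 seeds.

```{r}
s1 <- snmm_score(select_s1(d, "EMSA", 30), m)
s2 <- snmm_score(generate_s2(30, nfkb_pwm(), seed = 1), m)
optimal_threshold(s1, s2)
```

The full (threshold, rFN, rFP) curve is returned for audit; no ROC/AUC
machinery is layered on top.

## The microarray simulator

`simulate_microarray()` emulates the structure of the measuring experiment:
31 probes (reference + 30 single mutants), each in `replicates` spots
(default 3, as arrayed), reference spots at `base_intensity` (default 1000
signal units) and each mutant offset by its matrix cell. Noise is i.i.d.
Gaussian per spot with negative draws truncated at 0 — a synthetic-data
convention chosen for transparency, not a measured scanner error model; it
has no spatial artefacts, probe-sequence biases or intensity-dependent
variance, so passing recovery tests demonstrates correctness of the
estimator, not robustness to real microarray pathology.

`build_snmm()` inverts the simulation by replicate aggregation (mean by
default, median available) and reference subtraction. With zero noise the
generating matrix is recovered up to IEEE double rounding through the
intensity representation (~1e-13, asserted at 1e-12 in tests); with noise
sd 2 and triplicates the median absolute cell error stays below the noise
scale. Missing mutant probes are an error by default — every scoring column
needs all four cells — or, on request, are imputed with the column minimum
(a conservative lowest-affinity guess) and the matrix is flagged degraded;
scoring refuses degraded matrices unless explicitly allowed.

Problem sizes in the shipped tests were chosen to keep the default suite
quick while still exercising the distributional claims: 40-60 simulated
matrices for convergence properties, 100 seeds for the threshold
replication, 200 seeds for noisy recovery.

## Scanning

`scan_sequence()` deploys the scorers on longer DNA: every 10-bp window on
the requested strand(s) is scored, hits at or above the threshold (default
0.747, the optimized cutoff) are reported in 0-based half-open coordinates
on the input strand, with minus-strand hits giving the site as read 5'-3'
on that strand. Windows shorter than the model width produce a warning and
an empty result rather than an error, so batch FASTA runs survive stray
short records.

## Known limitations

* The model is strictly mononucleotide-additive; dependencies between
  positions (captured by e.g. principal-coordinate regression on consensus
  sequences) are outside its expressive power, and its accuracy on sites
  far from the measured mutant panel rests on the additivity assumption.
* The bundled PWM is synthetic (see above); comparator scores against it
  are illustrative rather than reference values.
* Ambiguity codes are rejected rather than expanded; scanning genomes with
  soft-masked or N-containing regions requires pre-splitting.
* The affinity dataset ships at the precision of the published tables
  (3 dp for scores); analyses needing full-precision model scores should
  recompute them from the matrix, as `correlate_models()` examples do.
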