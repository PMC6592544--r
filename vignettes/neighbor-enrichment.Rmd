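---
title: "Neighbor enrichment against a recombination null: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbor enrichment against a recombination null: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcrenrich)
```

# The statistical model

A RepSeq snapshot is a set of clonotypes: unique nucleotide rearrangements
with a V gene, a J gene, a CDR3 nucleotide sequence, its amino-acid
translation and a read count. The analysis is performed independently within
each VJ class — all statistics condition on the V/J choice, because segment
usage dominates sequence composition and the generative model is cheapest to
evaluate with the segment pair fixed.

For each amino-acid CDR3 $\sigma$ present in a class of $n$ unique
nucleotide clonotypes, define the neighborhood
$N(\sigma) = \{\sigma\} \cup \{\text{same-length single-substitution
variants}\}$ ($|N(\sigma)| = 1 + 19L$). The observed statistic is
$d(\sigma)$: the number of distinct nucleotide clonotypes in the class whose
amino-acid CDR3 lies in $N(\sigma)$. Distinct nucleotide variants of
$\sigma$ itself count, because they descend from different T-cell clones —
convergence at the amino-acid level across independent rearrangements is
exactly the signature of antigen selection.

Under the null hypothesis that the repertoire is shaped only by
recombination (and antigen-independent thymic selection), each of the $n$
rearrangements lands in $N(\sigma)$ independently with probability
$Q \sum_{\sigma' \in N(\sigma)} P_{gen}(\sigma')$, so $d$ is approximately
Poisson with mean

$$\lambda(\sigma) = n \, Q \sum_{\sigma' \in N(\sigma)} P_{gen}(\sigma').$$

$P_{gen}(\sigma' \mid VJ)$ is the probability that recombination with that
segment pair produces the amino-acid sequence $\sigma'$; $Q$ rescales for
thymic selection, which purges a fraction $1 - 1/Q$ of generated sequences
and thereby concentrates the surviving repertoire. The p-value is the
upper Poisson tail $P(d' \ge d(\sigma))$, and hits are declared after
Benjamini–Hochberg correction.

## Pipeline filters

Sequencing errors are the main artifact: an erroneous read of an abundant
clonotype looks like a novel single-mismatch neighbor. Three filters target
this failure mode, in order:

1. **collapse**: clonotypes identical in (CDR3 nucleotide sequence, V, J)
   are merged with summed counts (errors in germline regions upstream of the
   CDR3 produce such duplicates);
2. **singleton-neighbor exclusion**: only clonotypes with
   `min_neighbor_reads` (default 2) or more reads count as neighbors. The
   focal $\sigma$ is tested regardless of its own count — the filter scopes
   what counts as *evidence*, not what may be *tested*;
3. **zero-neighborhood discard**: a gated $\sigma$ whose Monte-Carlo
   neighborhood probability estimate is exactly 0 is discarded before
   testing — the model provides no usable null for it and such sequences
   are disproportionately artifacts. Because the discard happens before
   testing, the BH family is the set of sequences passing both the gate and
   this condition.

Only sequences with $d(\sigma) >$ `d_gate` (default 2, i.e. $d \ge 3$) are
tested at all; below that the test has no power and the gate keeps the
multiple-testing burden (and the Monte-Carlo work) proportional to the
candidate set.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `q` | 9.41 | scalar selection factor (average over VJ classes estimated for human TCR-beta); dimensionless multiplier on the null mean |
| `min_neighbor_reads` | 2 | reads required for a clonotype to count as a neighbor |
| `d_gate` | 2 | test only sequences with more than this many neighbors |
| `alpha` | 0.001 | BH-adjusted significance threshold |
| `n_sim` | 10⁶ | Monte-Carlo draws per VJ class for $P_{gen}$ estimation |
| `bh_scope` | global | pool p-values across VJ classes before adjustment |
| `epsilon` | 0.5 | selection-model learning rate |
| `reg_lambda` | 0.02 | selection-model L2 weight |
| `tol` | 10⁻⁶ | selection-model convergence threshold |

`n_sim` trades Monte-Carlo resolution (the smallest detectable
neighborhood probability is $1/n_{sim}$) against time; 10⁶ resolves the
neighborhood sums of every sequence the toy model can gate and keeps a
full-repertoire analysis in seconds per class. The scalar $Q$ default and
all filter thresholds are the method's standard operating point; they are
recorded in every run manifest.

**BH scope.** Whether the correction should pool across VJ classes or run
within each class is a genuinely open design point; pooling controls the
FDR over the full reported hit list and is the conservative reading, so it
is the default, with `bh_scope = "per_class"` available.

## Length-dependent selection factors

Thymic selection is not length-neutral. Optionally the scalar $Q$ is
replaced, within each VJ class, by

$$Q_{L} = Q \cdot \frac{R_L}{\sum_{L'} R_{L'} P_{data}(L')},
\qquad R_L = \frac{P_{data}(L)}{P_{gen}(L)},$$

where the two distributions are the CDR3-length distributions of the class
in the data and in the model-generated sample. The normalization keeps the
data-weighted mean of $Q_L$ equal to $Q$; when the two distributions
coincide, $R_L \equiv 1$ and $Q_L = Q$ **exactly** — the implementation
computes the ratios in count space so that this identity holds to the last
bit, and the test suite asserts bitwise equality of the two modes under
matched distributions. CDR3 lengths observed in the data but never
simulated get a pseudocount (default 0.5 simulated counts) and are flagged
in the output rather than silently dropped.

## The abundance-aware variant

The basic test discards read counts beyond the singleton filter. The
abundance-aware variant replaces $d$ with $s = \sum_{i=1}^{d} f(c_i)$ over
the neighbors' counts. Under the null, counts are exchangeable across
clonotypes, so the abundances of the $d$ neighbors are i.i.d. draws from the
empirical distribution $P_f$ of transformed counts — computed once per
repertoire over the neighbor-eligible clonotypes — and

$$P(s \mid \sigma) = \sum_d P(s \mid d)\, P(d \mid \sigma), \qquad
P(s \mid d) = P_f^{*d}.$$

Because empirical clone sizes are heavy-tailed (power-law), the default
transform is $f(c) = \log c$. $f(c) = 1$ recovers the basic method exactly
($s = d$); with that transform the mixture tail collapses analytically to
the Poisson survival function and the implementation takes that route, so
basic and indicator-mode results are identical by construction (the general
convolution path is independently tested to agree to $10^{-12}$).

**Discretization.** $\log c$ is continuous, so $P_f$ is histogrammed on a
fixed grid (default 0.1 natural-log units). Every value is snapped to the
grid *before* summation: observed $s$ and the convolved null then live on
the same integer lattice and the $d$-fold convolution is an exact discrete
operation — no interpolation error can reorder observed statistics against
the null. The convolution depth is chosen per run as the smallest $d_{max}$
with Poisson tail mass below $10^{-12}$ at the largest $\lambda$ in play;
the residual mass beyond $d_{max}$ is counted as exceeding (conservative).

## The d/n baseline

The model-free alternative ranks sequences by neighbor density $d(\sigma)/n$
and thresholds it, either directly or calibrated-by-count (the threshold
that selects the top $k$; ties at the threshold are all included and the
actual count reported). It exists to quantify what the recombination null
adds; it has no error control.

## The selection logo

A cluster of responding sequences of common length $L$ is summarized by a
factorized selection model
$P_{sel}(\sigma) = \frac{1}{Z} P_{gen}(\sigma) e^{\sum_i s_i(\sigma_i)}$,
fitted by gradient ascent of the L2-regularized likelihood:

$$s_i(a) \leftarrow s_i(a) + \epsilon\,[P_{data,i}(a) - P_{sel,i}(a)
- 2\lambda s_i(a)],$$

followed after **every** update by a per-position additive shift enforcing
$\sum_a P_{gen,i}(a)\, e^{s_i(a)} = 1$; iteration stops when the summed
squared update difference falls below `tol`. Under the constraint the
predicted marginal is simply $P_{sel,i}(a) = P_{gen,i}(a) e^{s_i(a)}$, and
additive per-position constants are projected out — any constant-shifted
initialization converges to the same solution, so the conventional
$s \equiv 0$ start is a convenience, not a choice that matters.

The background $P_{gen,i}(a)$ comes from model-generated sequences
restricted to the cluster's VJ class **and CDR3 length** — without the
length restriction the germline-encoded flanks would be misaligned. Amino
acids never seen in the background at a position receive a pseudo-probability
($10^{-6}$, renormalized, flagged) so the constraint stays defined. Because
only positional marginals of the background enter the fit, the joint
normalizer $Z$ is exactly 1 only if background positions were independent;
the per-position residual is reported (`z_residual`) rather than forced. An
iteration cap of $10^5$ guards against non-convergence and is reported as an
error with diagnostics, not silently truncated. Cluster sequences are
unweighted by clone size — the cluster is evidence of convergence, and
weighting by expansion would let one clone dominate the motif.

Letter heights are $P_{data,i}(a) \cdot s_i(a)$: enrichment relative to
recombination, not raw conservation — germline-encoded positions, which
dominate a classical information-content logo, are flat here, and depleted
residues plot below the axis.

## The synthetic generator

`synthetic_scenario()` / `simulate_repertoire()` produce the repertoires the
validation runs on:

* **null clonotypes**: distinct productive nucleotide rearrangements drawn
  from the same generative model the test uses as its null, with power-law
  read counts ($P(c) \propto c^{-2.5}$ up to $10^4$ — typical of the
  heavy-tailed clone sizes of bulk RepSeq);
* **planted clusters**: a seed CDR3 picked by default among the *lowest*
  estimated generation probabilities (a convergent cluster that
  recombination cannot explain — the regime the method is built to detect;
  `high_pgen` seeds exercise the false-positive regime a naive neighbor
  count falls for), expanded into $k$ distinct nucleotide clonotypes within
  one amino-acid substitution, sharing the seed's VJ class, with counts
  $\ge 2$ so they pass the neighbor filter (`base_count = 1` is the
  "stealth" mode that must *not* be detected);
* **error injection**: each high-count clonotype spawns
  $\mathrm{Binomial}(c\,L,\ \text{rate})$ distinct single-nucleotide
  variants as count-1 clonotypes, the artifact the singleton filter exists
  for.

Every clonotype carries exactly one ground-truth label (null / planted /
error). The toy recombination model (3 V, 3 J segments, geometric-like
trimming, up to 8 insertions, mildly GC-biased) generates CDR3s of 8–13
amino acids with enough junctional diversity for thousands of distinct
clonotypes.

What the generator does **not** emulate: real human V/J usage (dozens of
segments, strongly non-uniform), D-segment structure, PCR amplification
noise, cross-sample batch effects, or genuine antigen-driven repertoire
structure beyond single planted clusters. Passing the validation therefore
shows the statistics are correct and calibrated *under the model's own
null*, and sensitive to the planted signature — it does not certify
performance on any real cohort.

## Numerical choices

* Poisson tails via the survival function (`ppois(..., lower.tail =
  FALSE)`), never $1 - \mathrm{CDF}$; a positive tail that underflows is
  floored at the smallest positive double rather than reported as 0, and
  $\lambda = 0$ with $d > 0$ is exactly 0.
* The mixture tail of the abundance test is clamped to $[x_{min}, 1]$
  (rounding in the mixture sum can overshoot 1 by an ulp).
* Neighbor counting uses one-wildcard mask hashing (two same-length
  sequences are within Hamming 1 iff they share a masked pattern), which is
  exactly equivalent to the quadratic scan — the suite checks equality
  against an independent brute force on random classes.
* $Q_L$ ratios are computed in count space so the matched-distribution
  identity is exact (see above).
* Per-class Monte-Carlo seeds are derived deterministically from the
  configuration seed; every seeded entry point restores the caller's RNG
  state.

## Validation problem sizes

The shipped suite and `scripts/acceptance.R` run at desk scale, chosen so a
full pass stays within minutes on one CPU while keeping every check
statistically meaningful: Monte-Carlo tables of $10^6$ draws per VJ class;
20 (suite) or 10 (script) null repertoires of 5,000 clonotypes for
calibration; planted clusters of $k = 15$; 100 random classes of up to 500
clonotypes for the neighbor-count oracle; 500-sequence clusters for
selection-model recovery. The vignette states no empirical number that
those runs do not themselves compute.

## Limitations

* Sensitivity requires neighbors: rare, private responding clones without
  similar expanded variants are invisible by construction.
* The method flags *any* ongoing convergent response — it cannot attribute
  hits to a condition; longitudinal contrasts are needed for that.
* The Poisson null assumes independent rearrangements; identical twins of a
  clone produced by sampling noise are handled by the collapse step, but
  true clonal substructure (e.g. somatic variants of one clone) would
  violate it.
* Monte-Carlo $P_{gen}$ resolution is $1/n_{sim}$; sequences whose
  neighborhood probability is far below that are discarded rather than
  tested against a noisy null.
* The exact dynamic-programming computation of $P_{gen}$ is exposed only as
  a backend plugin contract (`register_pgen_backend()`); the shipped backend
  is Monte-Carlo counting.
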