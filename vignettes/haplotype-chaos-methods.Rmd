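---
title: "Methods: chaos-game analysis and phase-space gap filling for binary haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaos-game analysis and phase-space gap filling for binary haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcgr)
```

## The model in one page

`hapcgr` treats a binary haplotype — the 0/1 allele sequence along one
parental chromosome — as the symbolic output of an underlying process, and
asks two questions: *is there deterministic structure in it?* and *can
that structure impute alleles at gap positions?*

The bridge between symbols and dynamics is the chaos game representation
(CGR). With vertices 0 and 1 on the unit segment and the virtual seed
$b_0 = 0.5$ at the center, each allele $v_i$ moves the current point
halfway toward its vertex:

$$b_i = 0.5\,(b_{i-1} + v_i).$$

Because the alphabet has two letters, the classical CGR square degenerates
to a segment and the series is scalar. The map is exactly invertible
($v_i = \mathrm{round}(2 b_i - b_{i-1})$): $b_i$ is the binary number
$0.v_i v_{i-1} v_{i-2}\ldots$, so the coordinate series carries the full
sequence, most recent allele in the most significant digit. Inversion is
exact as long as floating point resolves the $2^{-n}$ contraction, i.e.
for runs up to about 50 symbols — beyond that the early symbols fall below
machine precision, which is irrelevant for analysis (only the decoder
cares) and is verified as a documented limit in the test suite.

Analysis then proceeds with the standard nonlinear time-series toolkit on
the coordinate series: Takens delay embedding, a surrogate-data test on
the correlation dimension, Lyapunov exponents, and multifractal box
counting. Imputation runs the machinery backwards: gap coordinates are
estimated in the reconstructed phase space and thresholded back to
alleles.

## Subsequence extraction

SNPs cluster along chromosomes. Dense runs are obtained by cutting the
haplotype wherever consecutive SNP positions differ by at least `r` bp
(default 30000); membership within a run is therefore "consecutive
distance strictly below r", and a distance of exactly `r` starts a new
subsequence. Runs must be long enough for phase-space statistics, so only
subsequences with strictly more than `Thr = 800` SNPs are analyzed; a run
of exactly 800 is dropped. The slices tile the parent sequence — they are
disjoint, ordered, and concatenate back to it — and splitting any slice
again with the same `r` returns it unchanged.

## Embedding selection

* **Delay** $\tau$: first local minimum of the average mutual information
  AMI($k$), estimated from an equal-width 2-D histogram with
  $\min(32, \lceil\sqrt{n}\rceil)$ bins per axis and the Miller–Madow
  bias correction (clamped at zero). The correction matters: the raw
  plug-in estimator's bias grows like (bins$^2$)/$n$ and would report
  spurious dependence for independent data; with the correction, i.i.d.
  series show AMI($k\ge1$) indistinguishable from zero. If no local
  minimum exists within `max_lag`, the fallback $\tau = 1$ is used and
  reported — never silently.
* **Dimension** $m$: Kennel false-nearest-neighbor criterion with the
  standard thresholds $R_\mathrm{tol} = 10$, $A_\mathrm{tol} = 2$,
  acceptance fraction 0.01, scanned up to $m_\mathrm{max} = 8$. The ratio
  test's denominator is floored at $10^{-8}\,\mathrm{sd}(x)$ so that exact
  recurrences (noise-free periodic data re-visiting a state to within
  $10^{-15}$) do not explode the ratio. When the fraction never drops
  below the threshold — the expected outcome for genuinely stochastic
  series, whose false-neighbor fraction stays high in every dimension —
  $m_\mathrm{max}$ is used and reported.

Both diagnostics are echoed in every report row, since all downstream
metrics depend on $(\tau, m)$.

## Correlation dimension and the surrogate test

The correlation sum over delay vectors uses the maximum norm and a
Theiler window equal to $\tau$ (temporally adjacent pairs are excluded
from both the count and the normalization; with window 0 the normalization
reduces to $2/(N(N-1))$). Radii are 24 log-spaced points between the 1st
and 99th percentile of the admissible pair distances. $D_2$ is the
least-squares slope of $\log C(r)$ vs $\log r$ over the scaling region,
located automatically as the longest contiguous run of local slopes whose
deviation from the run mean stays below 0.3, after discarding the
depopulated ($C = 0$) and saturated ($C > 0.999$) ends; if no run of at
least five radii qualifies, the whole informative range is fitted and the
result is flagged low-confidence. An exact power law $C(r) = r^{D}$ is
recovered to machine precision, and uniform 1-D/2-D samples fall in the
expected brackets (verified in the tests).

Surrogates realize the null hypothesis "linear Gaussian process with the
same power spectrum": the Fourier phases of the positive frequencies are
replaced by i.i.d. uniform draws with conjugate symmetry enforced, DC and
Nyquist kept real. Amplitude spectrum, mean and variance are preserved to
rounding error. Ten surrogates are used by default, each evaluated with
the *same* $(\tau, m)$, radius grid and Theiler window as the original.

The rejection rule is the min/max envelope: the null is rejected when the
original $D_2$ lies on or outside the surrogate range. Two boundary
conventions are deliberate, both forced by consistency with the published
chromosome-1 reference table the package ships: equality with an envelope
bound counts as rejection, and an inverted (min > max) pair of published
bounds is sorted before comparison. A subsequence is classified *chaotic*
when the null is rejected **and** its largest Lyapunov exponent is
positive. With ten surrogates the envelope test is coarse — under a
perfect null the original ranks outside the envelope with probability
2/11 — so the flag should be read per the published workflow (a screen,
aggregated over many subsequences), not as a calibrated p-value.

## Lyapunov spectrum (Eckmann)

At each evaluation point along the trajectory, neighbors within a radius
(initialized at the 5th percentile of pair distances and grown by factor
1.3 until at least $2(m+1)$ are found) define a local least-squares linear
map from their offsets to the offsets of their images one iteration step
($\tau_2 = 1$) ahead. A small Tikhonov term ($10^{-8}$ of the mean normal
diagonal) keeps the fit defined when the neighborhood is rank-deficient,
as on a limit cycle, where it correctly produces a strongly contracting
spurious direction instead of a failure. The Jacobian product along the
trajectory is accumulated with repeated QR decompositions — the
numerically stable equivalent of eigen-analysis of the transposed
product — and exponents are reported per iteration step (dimensionless per
sample), sorted descending. The tests pin the estimator to analytic
oracles: $\ln 2$ for the logistic map and the QR product of the exact
Jacobians along the identical orbit for the Hénon map.

## Multifractal box counting

The CGR point set (the series values on the segment) is covered by boxes
of side $\varepsilon = 2^{-k}$, $k = 1..8$, anchored at 0, half-open with
the last box closed. Only occupied boxes enter the partition sum
$Z_\varepsilon(q) = \sum \mu(B)^q$ — the standard guard for negative-$q$
moments. $\tau(q)$ is the regression slope of $\ln Z$ on
$\ln \varepsilon$; $D_q = \tau(q)/(q-1)$ except at $q = 1$, where the
entropy-sum regression is used directly; $\alpha = d\tau/dq$ by central
differences and $f(\alpha) = q\alpha - \tau$. The default $q$ grid is
$[-5, 5]$ in steps of 0.25: beyond $|q| \approx 5$ the moments of
box-count measures at attainable sample sizes are dominated by single
extreme boxes and the spectrum tails become artifacts, so the wider grids
sometimes seen in the literature buy noise, not information.

`box_partition_sum()` and friends accept point weights, so a measure given
as (cell centers, cell masses) is evaluated exactly. This is how the
binomial cascade generator serves as a closed-form oracle: its mass
exponent is $\tau(q) = -\log_2(p^q + (1-p)^q)$ exactly, with singularity
exponents spanning $[-\log_2 p_{\max}, -\log_2 p_{\min}]$, and the
box-counting pipeline reproduces it to rounding error.

## Gap filling by local projection

The applied method runs in five steps:

1. **Corrupt** (evaluation only): `round(0.10 n)` distinct uniformly drawn
   positions are blanked, so truth is known.
2. **Encode with restarts**: gap positions are emitted as undefined
   (masked), keeping series indices aligned with sequence indices; the
   first allele after a gap run maps from the center again. A coordinate
   after a gap run therefore depends only on alleles after the run, and
   downstream coordinates are *not* re-propagated after filling — updates
   stay local to the gap positions.
3. **Initialize**: each undefined coordinate gets the mean of its nearest
   defined values on the two sides (one-sided copy at sequence
   boundaries; a whole gap run takes the mean of its two flanks).
4. **Local projection**: the initialized series is delay-embedded
   (automatic $(\tau, m)$ unless configured); every embedded point whose
   window covers a gap index is projected onto the best rank-$Q$ affine
   subspace (principal directions) of the $2N+1$ temporally consecutive
   embedded points centered on it, with $N = 10$ and $Q = 1$ by default.
   Windows near the series ends are truncated symmetrically. Only
   coordinates at gap indices are written back, averaging when several
   windows update the same index; three sweeps are performed — more
   over-smooth series derived from binary data. A locally constant window
   projects to its centroid, which is what makes constant sequences an
   exact fixed point of the whole pipeline.
5. **Decode**: $h(i) = 0$ if $cs(i) \le 0.5$, else 1; the boundary maps to
   0 because the midpoint itself is reachable only from the 0 branch of
   the encoding. Values outside $[0, 1]$ (possible after projection) are
   clamped with a warning.

Non-gap alleles are never modified — the tests check this end to end — and
the whole pipeline is deterministic given sequence, mask and
configuration. Recovery is reported both over gap positions only
(`rate_gaps`, the strict headline) and over the full sequence
(`rate_overall`), since an aggregate "reconstruction rate" can denote
either.

The "local curve" of the projection step is realized as a rank-$Q$
principal affine subspace of the centered temporal window, the standard
local-projection construction for noise reduction in deterministic
series. Temporal (rather than spatial) neighborhoods are a deliberate
reading of the method's neighbor rule; they make each update depend on a
contiguous stretch of trajectory, which is what the initialization step
already provides for a gap.

## What the synthetic generators emulate — and what they cannot

The generators supply every input class the pipelines need: binary
sequences from deterministic maps (logistic, tent, Hénon) and stochastic
nulls (i.i.d. Bernoulli, persistent two-state Markov), clustered SNP
positions with controlled within/between-cluster distances, binomial
cascade measures with closed-form spectra, and fragment matrices with
configurable coverage and error rate. Defaults follow the published
workflow where it states values (10 surrogates, 10% gaps, $r = 30000$,
$Thr = 800$, threshold 0.5, symbolization at 0.5 — the generating
partition of the logistic map — burn-in 1000, fair read-parent choice);
remaining choices (Markov stay probability 0.9, cascade $p = 0.7$,
depth 10) are conventional textbook settings for strongly correlated
binary sequences and strongly multifractal measures.

One property of the default chaotic generator deserves an honest
statement, because it bounds what any pipeline can do with it.
Symbolizing the logistic map at $x = 0.5$ uses its *generating*
partition, and the resulting bit process is, in distribution, exactly an
i.i.d. fair coin (the map is isomorphic to a Bernoulli shift; the
symbolic entropy rate $\ln 2$ — the Lyapunov exponent — is the maximum a
binary alphabet admits). Two consequences follow mathematically, not as
implementation limitations. First, thresholded-logistic and
i.i.d.-Bernoulli inputs have identical finite-dimensional distributions,
so every downstream statistic — including the chaotic-classification
flag — has the identical sampling distribution on the two sources; no
test can systematically separate them. Second, after the encode-time
restart rule, no coordinate in a corrupted series carries information
about a deleted symbol, and the deleted symbol is an independent fair
coin, so gap recovery on such input is chance-level by construction.
Determinism that is invisible in distribution is also unexploitable. The
raw real-valued orbits, by contrast, are fully deterministic, and the
chaos metrics are validated on them directly (hence the $\ln 2$ and
Hénon oracles).

This is precisely why the gap-filling value proposition is demonstrated
on *persistent Markov* sequences: real haplotypes owe their
predictability to linkage-disequilibrium-like neighbor correlation, which
a two-state chain with stay probability 0.9 reproduces in the simplest
form, and there the local-projection fill recovers gap alleles far above
the majority-class baseline (tested). What no generator here emulates:
realistic LD block structure, recombination hotspots, allele-frequency
spectra, sequencing error profiles, or mate-pair read geometry — passing
tests say the machinery is correct and the method exploits neighbor
correlation when present, not that a particular accuracy will hold on any
real call set.

## Numerical and degenerate-input policy

* Constant series: AMI warns and returns delay 1; FNN raises a
  degenerate-input error; the gap-filling path catches embedding failures
  and falls back to $(\tau, m) = (1, 2)$ with a message.
* Consensus calling: a tied or uncovered column becomes a gap rather than
  a guess — deferring exactly the positions the gap-filling stage is for.
  Read partitioning itself is an input (simulation truth or an external
  assembler), never computed here.
* Ties and boundaries elsewhere: allele threshold at exactly 0.5 decodes
  to 0; subsequence cut at distance exactly `r`; length filter strictly
  greater than `Thr`; envelope equality rejects.
* All stochastic steps take explicit integer seeds, restore the caller's
  RNG state, and identical seeds give bit-identical outputs, including
  byte-identical report files.

## Problem sizes

The validation suite uses series lengths 800–5000 (5000 for the Lyapunov
oracles, 800–1000 for full-pipeline runs, matching the minimum
subsequence length the extraction step enforces), 20-seed batteries for
rate estimates, 2000–5000 points for dimension estimates, and cascade
depth 10. These sizes put every estimator comfortably inside its
asymptotic regime while keeping a full run of tests plus the acceptance
script in a few minutes on one core.

## Known limitations

* The envelope surrogate test with 10 surrogates has fixed, coarse size;
  it matches the published workflow but is not a calibrated significance
  test.
* $D_2$ scaling-region detection is heuristic; the low-confidence flag
  should be respected in downstream use.
* The Eckmann estimator's spurious contracting directions (rank-deficient
  neighborhoods) make only the *largest* exponent trustworthy for
  stochastic inputs.
* Binary CGR decoding is exact only to ~50 symbols of history (floating
  point), and the multifractal $q$ range is capped at $|q| = 5$ by
  sample-size realism.
* Diploid complementarity (filling $h_1$ and $h_2$ jointly) and use of
  fragment likelihoods during projection are out of scope.
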