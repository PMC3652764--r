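---
title: "Content- and position-based secondary-structure features for structural class prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content- and position-based secondary-structure features for structural class prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psse)
```

## The problem

About 90% of protein domains with known structure fall into four major
folding classes: all-α (helix-dominated), all-β (strand-dominated), α/β
(helices and strands interspersed) and α+β (helices and strands
segregated). For sequences in the twilight zone of pairwise identity
(roughly 25–40%), homology transfer is unreliable, but proteins of the
same structural class still share strong regularities in their *predicted
secondary structure*: the 3-state string over H (helix), E (strand) and C
(coil) that tools such as PSIPRED produce from an amino-acid sequence.
`psse` turns such strings into statistical feature vectors and feeds them
to a Gaussian-kernel SVM to predict the structural class.

Two families of features are implemented. *Content-based* features ask
what the sequence is made of; *position-based* features ask where each
element sits. The distinction matters: moving a block of helices to a
different part of the chain changes no content statistic, but it changes
the class (interspersed vs segregated) and it changes the position
statistics.

## Content-based features

All content-based statistics are functions of the sequence and its
maximal-segment decomposition (`segment_decompose()`, 1-based inclusive
coordinates). For a sequence of length $N$ and element $e$:

* **content**: $\mathrm{Count}_e / N$; the three values sum to 1.
* **composition moment vector** of order $k \in \{1,2\}$:
  $\sum_j p_{e,j}^k \big/ \prod_{d=1}^{k}(N-d)$, with $p_{e,j}$ the
  1-based position of the $j$-th occurrence. The denominator uses the
  sequence length $N$; orders beyond 2 are not part of the feature set.
* **longest / average segment length** and their normalised forms.
  `navg_seg()` is defined as `avg_seg()/N` — the normalisation follows
  the feature's name and the pattern of the normalised longest-segment
  feature.
* **3PATTERN**: each interior position is classified by whether its two
  neighbours match the central element (`eee`, `eex`, `xee`, `xex`),
  giving 12 counts. We divide by the number of windows, $N-2$, so the
  fractions sum to 1 and do not confound with sequence length; raw counts
  are available via `normalize = FALSE` since the original description is
  count-based.
* **alternation frequency** `nalt()`: drop coil segments, map helix
  segments to `a` and strand segments to `b`, and count adjacent state
  switches, divided by $N$.
* **transition probability matrix** `tpm()`: first-order transitions over
  the same coil-free segment sequence; a row with no outgoing pairs stays
  all-zero rather than being renormalised.

Absent elements yield 0 for all segment statistics and moments, so
feature rows are always complete — an all-coil sequence is representable,
merely uninformative.

## Position-based features

For each element $\delta$, the occurrence positions $Po(\delta)$ are
differenced into interval distances; a distance of 1 means successive
occurrences share a segment. The empirical distribution $P(n)$ of these
distances is summarised by truncated moments

$$\mathrm{SemiE}_k = \sum_{n \le k} n\,P(n), \qquad
  \mathrm{SemiD}_k = \sum_{n \le k} n^2 P(n) - \mathrm{SemiE}_k^2,$$

computed **without renormalising** the truncated probabilities — they are
the leading terms of the full moments, not moments of a conditional
distribution. The feature itself is the reciprocal coefficient of
variation

$$C_k(\delta) = \mathrm{SemiE}_k \big/ \sqrt{\mathrm{SemiD}_k},$$

with $k = \infty$ (`CF`) the default and $k = 5$ a cheap surrogate: in
real corpora the overwhelming majority of interval distances are below 5,
and once $k$ reaches the largest observed distance $C_k$ equals $C_F$
exactly (a property-tested identity). The square root is applied to
$\mathrm{SemiD}_k$ because the statistic is a reciprocal *coefficient of
variation*, i.e. mean over standard deviation; the literal mean/variance
ratio is available as `variant = "variance-ratio"` for comparison.

When an element occurs fewer than twice, or all its distances are equal
($\mathrm{SemiD}_k = 0$), $C_k$ is undefined; the package substitutes a
configurable degenerate value, 0 by default. Genuine values are always
positive, so the substitution is distinguishable. This keeps feature
matrices rectangular without row dropping.

## The classifier and parameter selection

`psse_fit()` standardises each feature column to zero mean and unit
variance over the dataset before the RBF kernel — the families live on
wildly different scales (fractions vs raw segment lengths vs moments
around 2–3), and an unscaled kernel would be dominated by the largest
one. Constant columns are centred and left unscaled. `scale = FALSE`
restores raw features.

Cost and kernel width are selected by grid search over the 11 powers of
two $2^{-5}, \dots, 2^5$ for each parameter (121 candidates), scoring
each pair by pooled overall accuracy under seeded 10-fold
cross-validation and breaking ties toward the smaller cost, then the
smaller gamma. Two design points deserve a note:

* **Folds are plain shuffled subsets, not stratified.** With exactly
  class-balanced training folds, an over-regularised candidate (tiny
  cost, essentially a majority voter with class-bias terms that cancel
  under perfect balance) can post a perfect cross-validation score and
  the smaller-cost tie-break would select it — after which leave-one-out
  training sets, which are always imbalanced by one sample, expose it
  catastrophically. Unstratified folds carry the same mild imbalance as
  the leave-one-out splits and price such candidates correctly.
* **Selection is done once per dataset and feature set**, then the chosen
  pair is reused for every jackknife split. This mirrors common practice
  and keeps the cost at one grid search, but it is mildly optimistic
  because each held-out sequence participated in selecting the
  parameters. `jackknife(fit, nested = TRUE)` re-runs the grid inside
  every split for an honest (and roughly $n$-times slower) estimate.

Evaluation is the jackknife: per-class accuracy $TP_j/|C_j|$ and overall
accuracy $\sum_j TP_j / \sum_j |C_j|$, which by construction equals the
size-weighted mean of the per-class accuracies — an identity asserted on
every report. Multi-class decomposition is libsvm's one-vs-one voting. A
random assignment over four balanced classes scores about 25%; that is
the floor any feature set must clear.

The combined 14-dimensional set `pbf11cbf` joins the 3 position-based
statistics with an 11-column content-based selection (`content_H/E/C`,
`maxseg_H/E`, `nmaxseg_H/E`, `avgseg_H/E`, `nalt`, `cmv1_H`). The precise
composition of an "11-dimension widely used" content set is not uniquely
fixed by the literature; this default is the package's own choice,
spanning the content, segment-length, alternation and moment families,
and is fully overridable via `feature_spec(cbf_columns = ...)`.

## The synthetic generator

`generate_dataset()` exists so the whole pipeline is testable without any
external corpus or secondary-structure predictor. It generates at the
segment level — a Markov chain over segment types with geometric segment
lengths (memoryless, one parameter, minimum 1) — because every feature in
the package is a function of segments and gaps, so this gives direct
control over the statistics under test. The four presets caricature the
class phenomenology: all-α alternates long helices with coils and never
emits strands; all-β mirrors it with strands; α/β interleaves helices and
strands through short coils (high alternation); α+β emits a helix/coil
block followed by a strand/coil block (low alternation). Sequence lengths
are uniform on 80–300 residues, the typical domain range. All numeric
preset parameters are arbitrary defaults chosen once for class
separation, not estimates of any corpus.

Determinism: each sequence gets its own seed derived from the master seed
by a fixed counter scheme, so datasets are bit-reproducible and any
single sequence can be regenerated in isolation.

What passing tests on this generator do and do not show: the presets make
the classes separable by design, so near-perfect synthetic accuracies
demonstrate that the feature extractors preserve the class signal and the
selection/evaluation machinery is sound — not that comparable accuracies
are attainable on real twilight-zone benchmarks, where classes overlap,
secondary-structure predictions carry errors, and reported accuracies sit
in the 75–90% range. Real-corpus evaluation requires the user to supply
predicted secondary structures and labels; the pipeline accepts them
unchanged through `read_ss_fasta()`/`read_psipred_ss2()` and
`read_labels()`.

## Numerical choices and degenerate inputs

* Composition moments of order $k$ require $N > k$; shorter sequences are
  a hard error rather than a silent 0.
* Sequences shorter than 3 have no 3PATTERN window; all 12 entries are 0.
* The all-coil sequence has an empty reduced segment sequence: `nalt()`
  is 0 and all four transition entries are 0.
* Feature tables round-trip through CSV at 17 significant digits.
* `.ss2` confidence columns are parsed for format validation and
  discarded; 8-state DSSP letters are rejected, not reduced — the
  features are defined on the 3-state alphabet only.
* The worked-example toy string `CCHHHHEEEEECCCCCHHH` is the canonical
  fixture for every extractor; position sequences are always derived from
  the string itself (the occurrence-indicator definition), never taken as
  separate inputs that could drift out of sync with it.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 50
sequences per class (200 total), with the 121-point grid at 10-fold
cross-validation followed by a 200-fit jackknife — about 5 seconds per
feature set on one core. Property suites run each structural invariant
over 1000 random strings. These sizes are the package's chosen balance
between statistical resolution (binomial SE of about 3 points at
$n = 200$) and a suite that runs in well under a minute.

## Limitations

* The generator's class signal is stronger than real corpora; synthetic
  accuracies are upper bounds on pipeline health, not benchmarks.
* Non-nested parameter selection (the default) carries a known optimism;
  use `nested = TRUE` when the accuracy estimate itself is the result.
* Parallel vs anti-parallel β-sheet content is out of scope: it is not
  computable from the 3-state string alone.
* No amino-acid-level information is used anywhere; the package starts
  where the secondary-structure predictor ends.
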