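---
title: "A mixture-of-motifs model for partitioning ChIP-bound regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mixture-of-motifs model for partitioning ChIP-bound regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifmix)
```

## The problem

A ChIP experiment pulls down every genomic region associated with the
profiled protein — regions it binds directly at its cognate sites, and
regions it reaches through intermediary proteins with their own,
different binding sites. The reported sequence set is therefore often a
*mixture*: several disjoint subsets, each enriched for a different
motif. Conventional motif discovery looks for motifs individually
overrepresented in the whole set; it neither partitions the data nor
guarantees that every region is explained by something.

`motifmix` instead fits a mixture model: the $n$ input sequences are
partitioned into $m$ **binding modes**, each mode characterised by its
own position weight matrix (PWM) with its own width, learned de novo.
The number of modes is itself selected by Bayesian model selection, so
the output is a single best $m$ together with, for every sequence, the
mode it belongs to and the location and strand of its site.

## The model

Sequences $X_1,\dots,X_n$ over $\{A,C,G,T,N\}$ have lengths $L_i$. A
model with $m$ modes has parameters
$\theta_m = \{Z, I, w, \phi, \gamma\}$:

* $Z_i$ — the 0-based start of the single site in sequence $i$
  (one occurrence per sequence; there is no zero-site option),
* $I_i \in 1..m$ — the mode of sequence $i$,
* $w_k$ — the width of mode $k$'s PWM,
* $\phi^k$ — the PWM of mode $k$ ($w_k \times 4$, rows on the simplex),
* $\gamma$ — the categorical distribution over modes,
* $\phi^0$ — a frozen order-2 Markov background fitted once to the
  whole input (given strands only, never resampled).

The likelihood of one sequence factorises into background prefix, PWM
window, and background suffix:

$$
P(X_i \mid \theta_m) \;=\;
P(X_{i,1..Z_i-1}\mid\phi^0)\;
\prod_{a=1}^{w_{I_i}}\phi^{I_i}_{a,\,X_{i,Z_i+a-1}}\;
P(X_{i,Z_i+w_{I_i}..L_i}\mid\phi^0),
$$

with every background base conditioned on its *actual* preceding bases
(contexts may span the motif boundary, which keeps the factorisation a
proper distribution over the full sequence). Sites may fall on either
strand; the reverse-complemented window enters the PWM term and the
count matrices (a `both_strands = FALSE` switch disables this).

### Collapsed sampling

$\phi^k$ and $\gamma$ carry Dirichlet priors and are integrated out.
The sampler state is then purely discrete — $(Z_i, I_i, \text{strand})$
per sequence plus the widths — with cached aligned base-count matrices
as sufficient statistics. The full conditional of one sequence's
assignment is proportional to a Dirichlet-multinomial predictive:

$$
P(I_i{=}k, Z_i{=}z, s)\;\propto\;
\frac{n_k+\alpha_\gamma}{n-1+m\alpha_\gamma}\;
\prod_{a=1}^{w_k}
\frac{c^{(k)}_{a,b_a}+\beta_{b_a}}{c^{(k)}_{a,\cdot}+\beta_0}
\;\Big/\;P_{\phi^0}(\text{window}),
$$

where $c^{(k)}$ are mode $k$'s counts with sequence $i$ removed and
$b_a$ the oriented site bases. `conditional_distribution()` exposes
exactly this table; the test suite verifies it against a brute-force
softmax of the from-scratch log posterior to $10^{-9}$.

One sweep updates every sequence in fixed index order, then every
mode's width. A width may stay, or grow/shrink by one column at the
motif's left or right end; a candidate is feasible only if every member
sequence can host the shifted window, and candidates are scored by the
collapsed marginal of the realigned count matrix minus the background
probability of the newly covered member bases. A mode with no members
keeps its width.

### Convergence, cap, and hill climbing

The target is the MAP configuration, not posterior samples. A chain
stops when the ordinary-least-squares slope of the last
`trace_window` per-sweep log posteriors falls below `slope_tol`
(defaults: `min(n, 50)` sweeps and $10^{-3}$ log-posterior units per
sweep), or after $2n^2$ assignment updates ($2n$ sweeps) — the cap
guards against unlucky initialisations. The slope rule has a known
weakness (an oscillating trace has slope zero); the update cap bounds
the damage, and multiple random starts cover the rest. The
highest-posterior sample of the chain is then refined by deterministic
hill climbing (argmax assignment per sequence, then argmax width move
per mode, until a full round changes nothing); every accepted move is
non-decreasing in log posterior.

### Model selection

For each $m$ in the searched range, `n_starts` chains run from
independent random initialisations and the best MAP is kept. Models are
compared by

$$\text{score}(m) = \log P(X, \hat\theta_m) - \lambda\,|M_m|,
\qquad |M_m| = \sum_k 3\,w_k + (m-1),$$

a MAP plug-in for the model evidence times a prior exponential in the
free-parameter count (3 free entries per PWM column, $m-1$ free mode
proportions, using the *fitted* widths). The default $\lambda = 5$;
larger $\lambda$ never selects more modes (a tested monotonicity), and
ties go to the smaller $m$. Because the collapsed marginal already
integrates $\phi$ and $\gamma$, this plug-in is tighter than one at a
point estimate of the continuous parameters.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `modes` | 1..20 | range of mode counts searched |
| `n_starts` | 5 | random initialisations per m |
| `lambda` | 5 | penalty per free parameter |
| `w_init`, `w_min`, `w_max` | 12, 6, 40 bp | initial and bounding motif widths |
| `bg_order` | 2 | background Markov order |
| `max_masked` | 150 bp | repeat filter on masked bases per sequence |
| `slope_tol` | 1e-3 | convergence slope threshold (log posterior / sweep) |
| `sweep_factor` | 2 | update cap = `sweep_factor` · n² |
| `seed` | 0 | base seed; the entire fit is a pure function of it |

Dirichlet hyperparameters: PWM column pseudocounts are the background
mononucleotide frequencies with total weight $\beta_0 = 1$
(composition-weighted smoothing, standard in Gibbs motif samplers, weak
enough not to wash out short modes); the mode-proportion pseudocount is
$\alpha_\gamma = 1$. Priors over positions, strands and widths are
uniform and drop from all scores.

## Determinism and parallelism

Every chain's seed is a stable integer mix of
`(base_seed, m, start)` — below $2^{31}$ — so adding starts or m values
never perturbs existing chains, and the search result is identical for
any worker count. The production sampler is C++ (Rcpp); a pure-R
reference engine follows the identical draw-for-draw RNG discipline
(same candidate ordering, one uniform per sampling event drawn from R's
generator), and the test suite asserts that both engines produce the
same chain from the same seed. Ties in hill climbing break to the first
candidate in the fixed ordering (mode-major, then position, then `+`
before `-`; width moves list no-change first).

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; all written tables are
  1-based inclusive.
* N bases: skipped when fitting the background, probability 1 in every
  likelihood factor, truncate Markov contexts, and contribute to no
  count cell (per-column totals are the non-N contributions).
* Lowercase input letters are treated as repeat-masked for the
  `max_masked` filter (the soft-masking convention by which genome
  browsers convey repeatMasker annotation in FASTA) but are ordinary
  bases afterwards; ambiguity codes become N.
* Sequences shorter than the widest motif considered are dropped by the
  default filter so every sequence admits a site of every mode; a mode
  wider than a remaining sequence simply contributes no candidates for
  it.
* Conditionals are normalised with a max-subtracted softmax; draws use
  a single uniform by inverse CDF over the fixed candidate order.

## The synthetic generator, and what passing tests show

`generate_dataset()` draws, per sequence: a mode from $\gamma$, a start
uniform over valid positions, a strand uniform, background bases from a
Markov model (order-0 uniform by default; an order-2 background is
supported), and site bases column-wise from the mode's PWM,
reverse-complemented into place on the minus strand. Planting replaces
background bases, so lengths stay fixed — matching the model's own
likelihood. It emulates the model exactly; it does **not** emulate
several features of real ChIP data: peak-strength variation, positional
enrichment of sites near peak summits, multiple or zero sites per
sequence, repeats, or correlated genomic background. Recovery results
on synthetic data therefore demonstrate correctness of the inference
machinery, not expected field performance.

The recovery experiment shipped in the tests and the acceptance script
uses three planted modes of widths 8/10/12 with ~1.5 bits of
information per column, uniform proportions, $n = 300$ sequences of
100 bp, searched over $m \in 1..6$ with 5 starts — sizes chosen so the
whole experiment is a few minutes' work on one core while leaving the
mode structure genuinely ambiguous at initialisation.

## Known limitations

* **Background absorption on motif-dense input.** The background is
  fitted to the whole input, motifs included. When a strong motif
  occupies a large fraction of all bases (easy to arrange
  synthetically: one 10 bp motif in every 100 bp sequence over an
  otherwise uniform background), an order-2 background learns the
  motif's own trimer statistics, which can cost the motif half a log
  unit per column and — at $m = 1$, where large member counts make the
  collapsed predictive very flat — can leave a single chain unable to
  nucleate within its update cap. The single-mode demonstrations in
  this package therefore fit the background at the generator's own
  order; real 200 bp ChIP windows with thousands of sequences sit far
  from this regime, but very short, very motif-dense inputs are worth
  running at `bg_order = 0` or `1` for comparison.
* **Palindromes.** A PWM whose consensus equals its own reverse
  complement makes phase and strand jointly unidentifiable: shifted,
  strand-flipped solutions score identically, and reported starts can
  legitimately disagree with a planted truth by the shift. This is a
  property of the model class, not of the sampler.
* **One site per sequence.** Regions carrying two sites of one mode, or
  sites of two modes, are forced into a single assignment; data where
  multi-site regions dominate (e.g. open-chromatin catalogues) need a
  richer mode definition.
* **Local optima.** The sampler seeks the MAP; multi-start plus hill
  climbing is a heuristic. More starts buy robustness linearly in
  time; 10 is a common choice for production runs, against a default
  of 5.
* PWMs assume positional independence; dependency-aware motif models
  are out of scope.
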