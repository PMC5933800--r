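# motifmix

De novo partitioning of ChIP-bound DNA sequences into **binding
modes**: disjoint subsets of the input, each explained by its own
position weight matrix (PWM) with its own width. ChIP reports regions a
protein contacts directly *and* regions it reaches through partner
proteins, so one dataset routinely mixes several distinct motifs;
`motifmix` is for regulatory genomicists who want all of them, with the
partition, rather than whichever single motif is most overrepresented.

## The model

Sequences $X_1..X_n$ are modelled as a mixture over $m$ modes. Each
sequence carries exactly one site: with mode $I_i$, start $Z_i$ and
strand $s_i$,

$$P(X_i) = P_{\phi^0}(\text{prefix}) \prod_{a=1}^{w_{I_i}}
\phi^{I_i}_{a, X_{i,Z_i+a-1}} \; P_{\phi^0}(\text{suffix}),$$

with $\phi^0$ an order-2 Markov background fitted once to the whole
input. PWMs $\phi^k$ and mode proportions $\gamma$ carry Dirichlet
priors and are integrated out; a collapsed Gibbs sampler updates
$(Z_i, I_i, s_i)$ and the motif widths (grow/shrink by one column at
either end), stops on a slope-based convergence rule or a $2n^2$
update cap, and hill-climbs to the MAP. The number of modes is chosen
by maximising

$$\log P(X,\hat\theta_m) - \lambda\,|M_m|, \qquad
|M_m| = \textstyle\sum_k 3 w_k + (m-1), \quad \lambda = 5,$$

a MAP plug-in for the model evidence with a prior exponential in the
free-parameter count. See the vignette
(`vignettes/mixture-of-motifs.Rmd`) for the full account.

## Worked example

Plant two motifs (`TGACGTCA`, `GGGATTACAG`) in 120 synthetic 100 bp
sequences, then ask for the best model among 1–4 modes:

```r
library(motifmix)
pwms <- list(consensus_pwm("TGACGTCA"), consensus_pwm("GGGATTACAG"))
dat  <- generate_dataset(plant_spec(120, 100, c(0.5, 0.5), pwms, seed = 42))
fit  <- motif_mix(dat$set, modes = 1:4, n_starts = 3, seed = 1,
                  max_masked = NULL)
fit
#> motif_mix fit: 120 sequences, m searched 1..4
#> best model: 2 mode(s), selection score -15853.53 (lambda = 5)
#>   mode 1: width 10,   59 sequences (gamma_hat 0.492), consensus CTGTAATCCC
#>   mode 2: width  9,   61 sequences (gamma_hat 0.508), consensus TGACGTCAC

summary(fit)
#> model selection over m (selection score = MAP log posterior - lambda * |M|):
#>  m map_log_post n_params selection_score converged sweeps
#>  1    -15769.87       30       -15919.87      TRUE    196
#>  2    -15563.53       58       -15853.53      TRUE    132
#>  3    -15568.07      143       -16283.07      TRUE    191
#>  4    -15570.91      108       -16110.91     FALSE    240
#> best m = 2
```

Two modes win: adding a third buys almost no likelihood
(−15568.07 vs −15563.53) but costs 85 further parameters × λ. Mode 1's
consensus `CTGTAATCCC` is the reverse complement of the planted
`GGGATTACAG` — strands are unidentifiable and either orientation is a
correct answer; mode 2 recovered `TGACGTCA` with one extra column.
Against the planted truth, `score_recovery()` reports label accuracy
0.98 and site accuracy (±1 bp) 0.96 here.

Standard methods work on the fit: `coef(fit)` (the PWMs),
`predict(fit, newdata)` (assign new sequences to modes),
`plot(fit)` (selection-score curve), `simulate(fit)` (parametric
datasets from the fitted model), `logLik(fit)`. `write_results()`
writes per-model assignment tables (1-based coordinates), PWM
probability/count matrices, a per-m score table and an HTML index.
A command-line front end is installed as `motifmix`
(`motifmix -f peaks.fasta -maxMode 20 -r 5 -o out/`); sequences with
more than 150 repeat-masked bases are dropped by default.

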