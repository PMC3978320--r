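---
title: "A componential network model of decimal-fraction comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A componential network model of decimal-fraction comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(dfcomp)
```

`dfcomp` simulates two-choice magnitude comparison of decimal fractions
with natural-number machinery only: place-coded single-digit comparison
networks, a comparison of the number of digits, and a cognitive-control
layer. This vignette is the package's own account of the model — its
equations, parameters, stimulus design, numerical choices and limitations.

## 1. Representations and comparison networks

### Place coding

A digit `j` (0–9) activates a bank of ten magnitude-ordered nodes with

    f(i, j) = exp(-10 * |i - (j + 1)|)

so node `j + 1` is fully active and neighbours fall off steeply
(`exp(-10)` at distance one): digit codes are close to one-hot, and the
model's numerical distance effect is carried by the learned weights rather
than by input overlap. The number of digits (string length, 1–4) uses a
4-node bank with the same form but decay rate 1, so neighbouring lengths
overlap substantially (`exp(-1)` ≈ 0.37) — the coarser tuning expected of a
non-symbolic quantity. One node per value: length `j` peaks at node `j`
(the digit bank's `j + 1` arithmetic is the same rank-alignment
with values starting at 0).

### Trainable comparators

Each comparison network takes two concatenated banks (left value, right
value) fully connected to two comparison nodes, "left larger" and "right
larger", with fixed mutual inhibition −2. Weights start uniform in
[−1, 1] and are trained by the delta rule,

    W <- W + rate * (target - sigmoid(W x)) x'

with target (1, 0) when the left value is larger and (0, 1) otherwise.
Equal-value pairs define no target and are never sampled. Training is a
static single feedforward pass; the recurrent inhibition operates only
during trial dynamics. One digit network is trained for 120,000 trials and
its weights are reused for the unit, tenth and hundredth comparisons;
training frequencies over-represent digit 0 by 15% and digit 1 by 5%,
which strengthens the weights of zero-involving comparisons (the model's
mechanism for faster processing of zeros). The length network trains for
100,000 trials over only 12 ordered pairs, i.e. roughly six times more
training per comparison than any digit pair receives — at matched distance
1 its evidence is about twice the digit network's, which is what makes the
number-of-digits comparison fast.

After training both networks decide every ordered unequal pair correctly
(90/90 digit pairs, 12/12 length pairs, across seeds); `train_comparator()`
reports the achieved accuracy and `dfc_model()` warns if it is below 100%.

**Learning rates.** The rates are free constants of the implementation
(digit 2.0, length 0.2 by default, exposed in `dfc_control()`). They set
the magnitude of the trained evidence, and with it the operating point of
the comparison sigmoid during trials. They were calibrated once, before
the acceptance run was frozen, so that the integrated model works in the
regime the reference simulation describes: digit evidence saturated above
tenth distance ≈ 3 (otherwise the stimulus cells' built-in tenth-distance
imbalance — see §3 — produces a spurious *reversed* compatibility effect),
while comparisons involving zero retain a margin advantage. The
error-correcting update is stable at these step sizes because the place
codes are effectively unit vectors.

## 2. Control network and trial dynamics

All dynamics constants are the reference defaults of `dfc_control()`:
persistence τ = 0.8, input gain β_in = 0.2, response inhibition −0.5,
comparison gain C = 0.7, conflict gain β_con = 1, conflict smoothing
λ_con = 0.8, Hebbian constants λ_w = 0.7, α_w = 1, β_w = 0.5, threshold
θ = 0.8, step cap 200, noise SD 0.11. Attentional weighting mirrors the
relative fixation frequencies on the digit positions: task activations
unit 0, tenth 1.5, hundredth 0.01, length 1.0; comparison→response weights
0.1, 1.0, 0.1, 0.7.

Each trial starts from zero activations. One step computes, in cascade:

    comparison:  c_k,i <- tau * c_k,i + (1 - tau) *
                   sigmoid( beta_in * (C * g_k * ff_k,i - 2 * c_k,opp) ) + noise
    response:    r_i   <- tau * r_i + (1 - tau) *
                   ( sum_k w_k * c_k,i - 0.5 * r_opp ) + noise
    conflict:    conf  <- lambda_con * conf + (1 - lambda_con) * 0.5 * r_L * r_R

where `ff_k` is the trained feedforward evidence of network `k`, `g_k` its
(adaptable) task coupling, `w_k` its response weight, and every node
receives fresh `N(0, 0.11)` noise each step, activations clipped to
[0, 1]. The trial ends when a response node reaches θ (the side of the
first crossing is the response; if both cross on one step the higher node
wins, exact ties are resolved at random) or at 200 steps, which counts as
an error. For two-digit numbers the hundredth banks receive zeros — the
string's length, not a padded digit, carries that information. The decimal
point is represented nowhere.

After every trial the task couplings adapt:

    g_k <- lambda_w * g_k + (1 - lambda_w) *
           ( g0_k + beta_w * alpha_w * conf * g0_k * post_k )

with `g0` the baseline activations and `post_k` the network's strongest
comparison activation on the trial. Without conflict the couplings decay
geometrically to baseline; high-conflict (incongruent) trials transiently
strengthen the couplings of active attributes, carrying a Gratton-type
sequence effect. Couplings persist within a simulated participant and
reset between participants.

### Design decisions in the dynamics

The control equations come from a control-model lineage whose exact
equations are not pinned down by a single formula, so their exact forms are implementation
choices. Three matter:

* **Linear response integration.** A response node that squashes its net
  input through `sigmoid(beta_in * net)` can never exceed ≈ 0.59 with the
  default β_in and weights, so θ = 0.8 would be unreachable and every
  trial would time out. Response nodes therefore integrate their net input
  linearly, clipped to [0, 1].
* **Activation-level noise.** Noise injected inside the sigmoid argument
  is attenuated by the sigmoid slope and the (1 − τ) integration to an
  effective SD below 0.01, which yields an essentially error-free
  simulation — contradicting the reference error rates. The
  SD 0.11 is therefore applied to each node's activation per step.
* **Multiplicative task gating** (`C * task`, not `C + task`). With an
  additive offset the hundredth channel keeps 32% of the tenth channel's
  gain no matter how small its task activation, and the simulation then
  shows a reliable tenth–hundredth compatibility effect — the opposite of
  the reference null, whose stated cause is that the low hundredth
  weighting *eliminates* the effect. Multiplicative gating silences the
  unit (0) and hundredth (0.01) channels as configured; raising the hundredth
  task activation to tenth-like levels together with its response weight
  restores a reliable compatibility effect, as predicted.

## 3. Stimulus design

`dfc_stimuli()` generates the 440-item set: 80 pairs per critical type
(a.0c, a.b0, a.bc, a.b), each split 40/40 by relation, plus 120 fillers.
One member of every critical pair is the all-nonzero three-digit reference
number; units are identical within a pair and all other digits differ.
Values span 1.04–9.96. The position of the larger number is
counterbalanced exactly within every cell.

Cell matching targets (means for overall, tenth and hundredth distance and
problem size, with tolerances) are the reference design values
(`matching_targets()`); problem size is the sum of the two values, the
operationalisation that reproduces the reference magnitudes (≈10.5–11.4).
A swap-based matcher selects each cell's pairs to centre on the targets
(stopping only inside a quarter of the tolerance), within a fixed budget;
unmet cells are reported in the `"unmatched"` attribute.

Two per-pair constraints are worth making explicit:

* **Overall-distance band.** Each pair's own overall distance must lie in
  [0.2, 0.9] — pairs a factor two or more from the ≈0.40 design distance
  would make "matched" a property of the mean only. A direct consequence
  is that incompatible/incongruent cells (where the hundredth comparison
  pulls the overall distance down) need larger tenth distances than
  compatible cells — exactly the asymmetry the reference cell means show
  (≈4.4 vs ≈3.7).
* **Filler form.** Fillers share the tenth digit; the generator uses the
  three- vs two-digit form (e.g. 2.83 vs 2.8) throughout. The alternative
  same-length form (e.g. 7.91 vs 7.98) is decidable only through the
  hundredth comparison, which the default attentional weights gate off —
  such fillers would time out or guess (~50% errors) and inflate the
  overall loss far beyond the reference 2.6%. The reference loss therefore
  implies a length-decidable filler set, which is what the generator
  builds.

## 4. Simulated experiment and analyses

`run_experiment()` simulates 22 participants; each sees all 440 pairs once
in an independently shuffled order, with independent noise. Per-participant
seeds derive from one master seed, so any participant can be re-simulated
alone (`run_participant()`). Error trials (wrong response or step-cap) are
excluded before RT analysis; no further trimming is applied to simulated
steps. Analyses mirror the reference design: 3 × 2 repeated-measures ANOVAs
(decimal type × compatibility) on correct-trial mean steps and on
arcsine-transformed error rates (`asin(sqrt(p))`), with Mauchly's test and
the Greenhouse–Geisser correction applied when sphericity is rejected at
α = 0.05 and Bonferroni-corrected pairwise type comparisons (family of 3);
and paired tests (reported as F = t²) for the string-length congruity
effect. Partial eta-squared is SS_effect / (SS_effect + SS_error). The
ANOVA machinery is the multivariate-model route (`car::Anova`); the test
suite checks it against a hand-computed sums-of-squares oracle.

## 5. What the default run shows — and known limitations

At desk scale (22 participants × 440 trials, one CPU, ~2 minutes including
training) the canonical run reproduces: mean simulated RT ≈ 9.5–9.6 steps
per three-digit type with a.0c fastest; no compatibility effect on RT or
errors; congruent a.b pairs ≈ 8.3 steps vs incongruent ≈ 11.6 with error
rates ≈ 0–1% vs ≈ 6–7%, both congruity contrasts highly significant at
n = 22.

Known deviations and fragilities, stated rather than smoothed over:

* **Overall loss.** The reference overall loss is 2.6% of the data. Summed
  over all 22 × 440 trials the model loses ≈ 6%, because same-tenth
  fillers (decidable only via the length network once the hundredth
  channel is gated off) err at ≈ 15–20%. Restricted to the critical pairs
  that enter the analyses, the loss is ≈ 2.0–2.4% — matching the reference
  figure under the reading that "loss of the data" refers to analyzed
  trials. The package reports the all-trials number.
* **Congruent error rate.** Published ≈ 1.02%; the model's congruent a.b
  errors are ≈ 0–0.5%. With 880 congruent trials per run the between-run
  binomial SE alone is ≈ 0.3 percentage points.
* **Fragile small effects.** The a.0c advantage (~0.1–0.2 steps here vs
  0.35 reference) and the compatibility null are both small relative to
  between-run noise: across noise seeds the ordering occasionally ties and
  the residual distance imbalance can reach nominal significance. A single
  simulated experiment — the reference one included — is one realization
  of that variability.

The simulation abstracts away everything perceptual: no eye movements, no
visual layout, no milliseconds (steps are the RT unit), and no
proportion-congruity manipulations (the control layer supports them, but
they are outside the package's reproduced analyses). Passing tests show
that the componential mechanism suffices for the simulated effects; they
say nothing about human data beyond the qualitative pattern match.
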