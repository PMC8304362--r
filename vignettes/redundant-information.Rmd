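---
title: "Estimating redundant information with agreement-constrained decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating redundant information with agreement-constrained decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rine)
```

## The quantity being estimated

Given sources $X_1, \dots, X_n$ and a discrete target $Y$, the Partial
Information Decomposition splits the joint mutual information
$I(X_1, X_2; Y)$ into unique, synergistic and redundant components. The
redundant component $I_\cap$ — what *every* source knows about $Y$ — is the
contested centerpiece: classical definitions optimize over auxiliary random
variables and are only computable for small discrete alphabets.

One classical notion is the deterministic common-variable redundancy: the
maximum of $I(Y; Q)$ over all $Q$ that are deterministic functions of every
source. Its maximizer is the Gács–Körner common random variable, computable
exactly as the connected components of the support graph that links
co-occurring source symbols; `i_cap_wedge_bits()` implements this. It is a
strict notion: a single noisy symbol pair merges components, which is why the
IMPERFECTRDN task below has a common-variable redundancy of 0 despite the
two sources being almost identical.

This package's estimator replaces the optimization over random variables by
an optimization over *decoders*. For a family $V$ of functions
$f : \mathcal{X} \to P(\mathcal{Y})$,

$$
L_\cap^V = \min_{f_1, f_2 \in V} \tfrac12\left[H_{f_1}(Y|X_1) +
H_{f_2}(Y|X_2)\right] \quad \text{s.t.}\quad D(f_1, f_2) = 0,
\qquad I_\cap^V = H(Y) - L_\cap^V,
$$

where $H_{f_i}(Y|X_i)$ is the expected cross-entropy (in bits) of decoder
$i$'s predicted class distribution and
$D(f_1, f_2) = \mathbb{E}\,\lVert f_1(y|x_1) - f_2(y|x_2)\rVert_1$ is the
expected L1 distance between the two predictions on jointly drawn
observations. Forcing the predictions to agree means only information that
*both* sources can express survives; the achieved cross-entropy then prices
that common prediction, and $H(Y)$ minus it is the redundancy. With a single
source the constraint is vacuous and the quantity reduces to the *usable
information* $H(Y) - H_V(Y|X)$ (`usable_information_bits()`), which recovers
Shannon mutual information when $V$ is unrestricted. With $n$ sources the
package minimizes $\frac1n \sum_i H_{f_i} + \beta \sum_{i<j} D(f_i, f_j)$
— the pairwise-sum penalty is symmetric, reduces to the two-source form, and
drives all predictions together as $\beta \to \infty$.

## Training procedure and its hazards

The constraint is enforced through the Lagrangian
$\tfrac12(H_{f_1} + H_{f_2}) + \beta D(f_1, f_2)$, minimized by mini-batch
Adam over both decoders jointly (they never share weights). Two numerical
points matter:

* **Reverse annealing of $\beta$.** A constant prediction satisfies the
  agreement constraint exactly while carrying zero information — the
  *trivial solution*. Starting training at a high $\beta$ reliably collapses
  into it. The package therefore ramps $\beta$ linearly from
  `beta_start = 0` to `beta_final` over the first 80% of training
  (`beta_schedule()`), letting the decoders become informative before the
  constraint bites. `train_rine()` additionally warns whenever a trained
  decoder's predictions have per-class variance below $10^{-6}$ across the
  test set. Note that on tasks whose constrained optimum *is* the constant
  predictor (UNQ, AND), this warning is expected and benign.
* **Gradient of the L1 penalty.** With softmax outputs the penalty's
  gradient at the logits is $p \odot (s - \langle s, p\rangle)$ with
  $s = \operatorname{sign}(p_1 - p_2)$; the sign subgradient at ties is
  taken as 0. Predicted probabilities are floored at $10^{-12}$ before logs
  so saturated softmaxes yield finite losses.

All randomness (weight initialization, batch shuffling, sampling) is drawn
from R's RNG under an explicit seed, so every estimate is exactly
reproducible; multi-seed aggregation (`estimate_redundancy()`) reports the
mean and sample standard deviation over independent initializations, and a
seed that fails is recorded and excluded rather than aborting the aggregate.

### Parameters that matter

| parameter | default | role |
|---|---|---|
| `beta_final` | 50 (15 for the canonical benchmarks) | constraint strength; larger values enforce agreement harder and can only shrink the estimate |
| `ramp_fraction` | 0.8 | fraction of training over which $\beta$ ramps; too short risks the trivial solution |
| `hidden` | `c(64, 64)`, ReLU | decoder capacity; should be rich enough to decode each source alone |
| `epochs`, `batch_size`, `learning_rate` | 150, 256, $10^{-3}$ | sized so the canonical tasks converge well before the ramp ends |
| `seeds` | `1:5` | initializations aggregated into the reported mean ± sd |
| `h_y_bits` | plug-in from pooled labels | pass the exact $H(Y)$ when the generating distribution is known |

Cross-entropies, the final distance and hence the reported estimate are
always evaluated on a held-out test set, never on the training data: the
framework measures decodability, and train-set evaluation would reward
overfitting. Per-seed estimates can come out slightly negative on held-out
data (test cross-entropy marginally above $H(Y)$); they are reported as-is,
not clamped, so near-zero redundancies aggregate without upward bias.

## Canonical benchmark distributions

`make_canonical()` builds the four standard two-source tasks; all reference
quantities are computed exactly from their probability tables.

* **UNQ** — $X_1 = a$, $X_2 = b$, $Y = (a, b)$: 1 bit unique per source,
  nothing redundant.
* **AND** — $Y = X_1 \wedge X_2$: redundancy between 0 and
  $\min_i I(X_i;Y) = 0.311$ bits depending on the notion; for deterministic
  decoder families the expected value is 0.
* **RDNXOR** — $X_1 = (a, c)$, $X_2 = (b, c)$, $Y = (a \oplus b, c)$:
  exactly 1 redundant bit (the shared $c$) and 1 synergistic bit (the XOR).
* **IMPERFECTRDN** — $P(0,0,0) = 0.499$, $P(0,1,0) = 0.001$,
  $P(1,1,1) = 0.5$: $X_1$ copies $Y$; $X_2$ misses with probability 0.001,
  so $I(X_2;Y) = 0.99$ bits. The common-variable oracle collapses to 0 here
  (the single noisy support point merges the blocks), while the measured
  decoder-based estimate tracks the 0.99-bit value — the estimator behaves
  like the stochastic-channel notion of redundancy on this task, not like
  the deterministic common variable.

At `beta_final = 15`, 10k/10k samples, 150 epochs and 5 seeds the suite
reproduces the reference pattern (≈0, ≈0, ≈1, ≈0.99 bits); the acceptance
script and `test-acceptance.R` recompute this end to end.

## The synthetic class-overlap task

`make_overlap_task()` emulates a population-decoding comparison between two
recorded units sets. Eight balanced classes; each source encodes a
contiguous block of $n \in [4, 8]$ classes, so the two encoded sets overlap
in $2n - 8$ classes. Sixteen class-selective units per source (two tuned to
each class) fire with mean +3 and unit variance when their tuned class is
shown *and* that class is in the source's encoded set; the unit-to-class
tuning is shared between sources so jointly-encoded classes produce aligned
responses. These values were chosen so each source's encoded classes are
decodable near ceiling (measured usable information ≈ 2.92 of 3 bits with
the default family); weaker selectivity leaves the redundancy trends
confounded by decoding error, defeating the comparison the task exists for.
Optional columns add (a) independent Gaussian noise units per source and
(b) shared non-task units, identical in both sources and label-independent.

By construction the label-independent columns carry zero mutual information
about $Y$, so the redundancy estimate should be flat in both counts, while
cosine similarity between the raw inputs (`cosine_similarity_mean()`,
computed per observation pair and averaged) falls as noise units are added
and rises as shared non-task units are added. `run_overlap_sweep()` runs the
factorial grid; the default 250 samples per class keeps the 64×64 MLPs in
their converged regime (at 100 samples per class they overfit under long
training, and residual optimization bias masquerades as a trend in the
noise-unit count).

What this generator does *not* emulate about real recordings: spike-count
statistics (everything is Gaussian), correlated noise across units, temporal
structure, and partial class selectivity. Passing the sweep therefore shows
the estimator's invariance properties under clean conditions, not
performance on real neural data.

## Problem sizes used by the shipped tests

The canonical reproduction runs at its full scale (10k/10k samples, 150
epochs, 5 seeds per task; about a minute of CPU). Property checks
(self-redundancy, source symmetry, the upper bound by usable information,
the $\beta = 0$ limit, $\beta$-monotonicity, permutation invariance,
constraint satisfaction at $\beta = 50$) run on 2000/2000-sample datasets
with 150 epochs, batch 128 and 3 seeds — sized so the coupled training is
converged (verified against the single-decoder usable information) while
keeping the property suite fast. Their tolerances are expressed in units of
the measured per-seed standard deviations. The exact-oracle equivalence
check compares the component-labeling oracle against an exhaustive search
over all admissible per-source labelings on every support with ≤ 4 symbols
per source.

## Known limitations

* Only fully-connected softmax decoder families are implemented; the
  declared `"convolutional"` kind has no fitting backend. Continuous targets
  (Normal output heads) are out of scope.
* The estimate is variational in two directions at once: restricted decoder
  capacity can only lower the recoverable information, while finite $\beta$
  leaves the constraint slightly slack, which biases the estimate upward
  toward $\min_i$ usable information. Report the final distance alongside
  the estimate (the `redundancy_estimate` print method does).
* Small negative estimates are legitimate sampling outcomes near zero
  redundancy, not errors.
* The Gács–Körner oracle is exact but brittle by definition: measure-zero
  perturbations of the support change it discontinuously (IMPERFECTRDN is
  the canonical illustration).
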