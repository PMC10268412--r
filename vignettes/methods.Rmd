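---
title: "Attentive tree and graph encoders for trigger detection: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentive tree and graph encoders for trigger detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatree)
```

## The task and the model family

Biomedical event extraction starts by finding *trigger words*: the tokens
whose presence signals an event (e.g. *binding*, *abolished*) and whose
class fixes the event type. This package treats trigger detection as
per-token classification over a sentence's syntactic structure, with three
encoders of increasing structure-awareness:

1. **Child-Sum Tree-LSTM** over the dependency parse. Each node `j`
   aggregates its children's hidden states by a plain sum
   `h̃_j = Σ_{k∈C(j)} h_k`, computes input/output/update gates from
   `(x_j, h̃_j)`, one forget gate per child from `(x_j, h_k)`, and updates
   `c_j = i_j ⊙ u_j + Σ_k f_jk ⊙ c_k`, `h_j = o_j ⊙ tanh(c_j)`. On a path
   tree this is exactly a sequential LSTM, which the test suite exploits as
   an independent oracle.
2. **Attentive variant**: the plain child sum is replaced by a weighted sum
   whose weights are a softmax over LeakyReLU-activated additive scores
   `a⃗ᵀ[W q ‖ W h_k]` (the GAT scoring form). Children that matter for the
   parent's role receive more mass.
3. **Enhanced variant**: the same gated update, run as `K` synchronous
   attention layers over the sentence's predicate–argument structure (PAS)
   graph — a deep-parse graph that links predicates to arguments
   (roles arg1–arg4) across the sentence, capturing relations the shallow
   dependency tree misses. The final PAS hidden state is concatenated with
   the dependency hidden state, `[h_dep ; h_pas]`, and a single affine +
   softmax layer classifies every token.

Training minimizes the cross-entropy over labeled nodes plus an L2 penalty
`(λ/2)‖θ‖²`, by Adam. All gradients are derived and implemented by hand
(there is no autodiff dependency); the suite checks every parameter group
against central finite differences at 1e-4 relative tolerance.

## Design choices where the design was genuinely open

* **Attention query.** The natural reading of the attentive child
  aggregation is circular: the aggregate both scores the children and is
  their weighted sum. We break the circle with the only quantities
  available at score time in a post-order traversal: the dependency-side
  query is the parent's *projected input embedding* `W_q x_j`; the PAS-side
  query is the node's *previous-layer hidden state*. With the score vector
  `a⃗ = 0` both reduce to uniform weights, a testable limit.
* **PAS execution model.** The gated update is tree-recursive, but a PAS
  graph may be cyclic. We run it as synchronous layer-wise message passing
  (default `K = 2`) with self-loops, the standard GAT execution model: well
  defined on cycles, and at `K = 1` it is one-step neighbor aggregation.
  Layer-0 states are zero, matching the leaf convention on the tree side.
* **Neighborhood direction.** PAS edges are directed (predicate →
  argument), but the encoder uses the undirected neighborhood; role labels
  are carried as metadata and do not condition parameters in this version.
* **The scalar gate ρ.** A learned coefficient weighting the PAS
  contribution is mentioned upstream without a defining equation; we expose
  it as an optional learned scalar multiplying `h_pas` before fusion
  (`rho_gate`), off by default.
* **Classification site.** Every token is classified from its own fused
  hidden state (not only the root), consistent with per-token trigger
  labeling. Multi-token triggers label every token they cover; prediction
  spans are recovered by merging adjacent same-label tokens.
* **Regularization scope.** `‖θ‖²` is taken over the full trainable
  parameter vector, biases included; the LeakyReLU slope (0.2, the GAT
  convention, configurable) is a hyperparameter, not a weight.
* **Optimizer sign and λ.** The upstream update rule as printed ascends
  the gradient and drops λ from the penalty; we use Adam descent
  (β₁ = 0.88, β₂ = 0.90) with λ = 0.003.
* **Scoring convention.** Evaluation is exact-span, exact-type micro-F1
  over merged spans, with NONE never a positive; the shared-task
  approximate-span relaxation is *not* implemented, which makes scores here
  conservative relative to that convention. Macro-F1 is also reported.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `embedding` | 720 | word-vector dimension (corpus scale; synthetic tests use 16) |
| `hidden` | 256 | `d_h`, per-side hidden units; fused width is `2·d_h` |
| `batch_size` | 32 | whole sentences per Adam update |
| `learning_rate` | 0.001 | Adam step size |
| `dropout` | 0.2 | on input embeddings, training only |
| `epochs` | 50 | maximum passes over the data |
| `lambda` | 0.003 | L2 coefficient |
| `beta1`, `beta2` | 0.88, 0.90 | Adam moment decays |
| `K` | 2 | PAS message-passing layers |
| `slope` | 0.2 | LeakyReLU negative slope in both attention modules |

The defaults are the corpus-scale recipe. At synthetic scale (200 training
sentences, 16-dimensional embeddings) 50 epochs of batch-32 updates are
only ~350 optimization steps, far too few for convergence from random
initialization; the test and acceptance harnesses therefore train with
`batch_size` 4–8, `learning_rate` 0.005–0.01 and `dropout = 0` — more and
larger steps, and no noise injection since the planted corpus itself is
noise-free — with hidden sizes 16–24. These are scale adaptations of the
optimizer, not changes to the generated world, which stays at its stated
defaults.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces, under a single seed, byte-reproducible
documents in the three on-disk formats the readers consume (CoNLL
dependencies, a 4-column PAS TSV, BioNLP-style standoff). Its world: random
single-rooted trees by sequential random attachment; a PAS graph that
echoes a random subset of dependency arcs plus long-range
predicate–argument edges; and a planted rule — a token triggers its word's
class iff the word is trigger-vocabulary AND a dependency child is an
entity word OR (for a designated fraction of trigger words) a PAS neighbor
is an entity word. The designated fraction is exactly the part of the
signal a tree-only model cannot see, which is what makes the
dependency-vs-PAS ablation measurable at desk scale. Embeddings are
deterministic hash vectors with additive class-informative components, so
the task is learnable at dimension 16 with no downloads.

It does **not** emulate: realistic biomedical vocabulary or parse
statistics, the 19-type event ontology of corpus-scale datasets, nested
event structure (E-lines are parsed but never scored), or contextual
embeddings. A green synthetic run establishes that the encoders,
gradients, training loop and I/O are correct and that PAS fusion helps
when the data contain PAS-only evidence — not that corpus-scale F1 numbers
are reproduced; those require licensed corpora and pretrained embeddings
and are out of scope by design.

## Numerical notes

* Softmax subtracts the running maximum before exponentiation; probability
  terms are floored at 1e-300 inside the log-loss.
* LeakyReLU's subgradient at 0 takes the negative-side slope; at PAS layer
  1 all scores are exactly 0 (zero initial states), where weights are
  provably uniform and score gradients vanish on both the analytic and
  finite-difference routes.
* Post-order traversal is iterative (explicit stack), so pathologically
  deep parses cannot overflow the recursion limit.
* Malformed CoNLL with several HEAD=0 tokens is accepted as a virtual-root
  forest with a warning, keeping the encoder total on real parser output;
  cycles are an error.
* Character offsets are 0-based end-exclusive throughout (the standoff
  convention).
* Determinism: all randomness (init, shuffling, dropout, generation) flows
  from one seed; hash embeddings never touch R's RNG stream.

## Known limitations

Pure-R execution is the main constraint: training is practical at the
synthetic scale the acceptance suite uses (minutes on one CPU) but not at
corpus scale with `d = 720`/`d_h = 256`. No mini-batch parallelism, no
learning-rate schedule, no approximate-span scoring, no multi-head
attention, and no role-conditioned PAS parameters. Configuration files are
JSON (no YAML reader is assumed to be available).
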