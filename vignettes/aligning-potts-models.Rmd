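---
title: "Aligning Potts models of protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning Potts models of protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsalign)
```

## The problem

Profile and profile-HMM methods compare proteins position by position.
Below roughly 20% sequence identity this positional signal thins out,
while the couplings between positions — residue pairs that co-evolve,
typically because they are in contact — still carry information about
which columns correspond. `pottsalign` represents each sequence (together
with its close homologs) by a Potts model and aligns the *models*, so
both positional composition and direct couplings enter the objective, and
the alignment comes with a certificate of optimality.

## Model and inference

A Potts model over sequences of length $L$ with $q$ states has fields
$v_i \in \mathbb{R}^q$ and couplings $w_{ij} \in \mathbb{R}^{q \times q}$,
with $P(x) \propto \exp\left(\sum_i v_i(x_i) + \sum_{i<j}
w_{ij}(x_i,x_j)\right)$. The normalizer is intractable and never
computed; inference maximizes the *pseudo-likelihood* — for each sequence
and position, the conditional probability of the observed residue given
the rest of the row — which is consistent and tractable. The penalized
objective is

$$\max_{v,w}\ \sum_n \sum_i \log P(x_i^n \mid x_{-i}^n; v, w)
  \;-\; \lambda_v \lVert v - v^* \rVert_2^2
  \;-\; \lambda_w \lVert w \rVert_2^2,$$

where $v^*$ inverts the softmax of the empirical single-site frequencies
($\mathrm{softmax}(v^*_i) = f_i$). Pulling fields towards $v^*$ rather
than towards zero encodes the view that positional composition should
explain as much of the alignment as possible, with couplings added only
where needed — a property that matters here because we want *similar
families to yield similar models*.

Key choices:

* **Regularization defaults.** $\lambda_v = 10$ and $\lambda_w = 0.2(L-1)$,
  the conventional scaling for pseudo-likelihood DCA (coupling shrinkage
  grows with the number of potential partners per position). Any strictly
  positive pair preserves the method's structure; both are exposed in
  `inference_config()`.
* **Optimizer.** Deterministic L-BFGS-B from $v = v^*$, $w = 0$ with an
  analytic gradient; no stochastic initialization, so fits are exactly
  reproducible. Non-convergence within `max_iterations` produces a
  warning and is recorded in the model's provenance, not an error.
* **Gaps.** The alphabet has $q = 20$ amino-acid states; gaps are not a
  state. A position holding a gap contributes no conditional term and
  never conditions its neighbours, and frequency counting likewise
  ignores gap symbols (rows of `f_single` may sum to less than 1). A
  sequence containing gaps has no defined energy and is rejected by
  `sequence_energy()`.
* **Sequence weighting.** None is applied before counting; the
  preprocessing already filters at 80% identity, and introducing a
  weighting scheme would add a free parameter the rest of the pipeline
  never calibrated.
* **Pseudocount.** `pseudocount_epsilon` (default $10^{-6}$) is added to
  single-site frequencies before inverting the softmax for $v^*$, purely
  to avoid $\log 0$ at absent states.
* **Gauge.** Parameters are only identified up to per-pair shifts
  absorbed by the fields; `zero_sum_gauge()` fixes the standard zero-sum
  representative (every $v_i$ and every row and column of every $w_{ij}$
  sums to zero) by double-centering each block and compensating the
  fields. The per-position conditional distributions are invariant under
  this transform on gap-free data, which the tests verify directly.

Preprocessing from a raw MSA of close homologs follows the standard
recipe: greedy filtering at 80% pairwise identity (identity = matches
over the shorter ungapped length, query always kept), first 1000
sequences, and removal of columns with strictly more than 50% gaps.
Trimmed columns are re-inserted into the fitted model with background
fields $v_0(a) = \log f_0(a) - \frac1q \sum_b \log f_0(b)$ and zero
couplings, so model coordinates match the original sequence numbering.
The background table $f_0$ is the Robinson–Robinson amino-acid frequency
set, the standard composition prior of BLAST-family tools.

## Rescaling for comparability

Fields relate to frequencies through a logarithm, so rare states produce
large noisy parameters whose *sign* directly flips similarity scores.
`smooth_fields()` therefore mixes each positional softmax distribution
with the uniform one, $\tilde p_i = (1-\tau_v) p_i + \tau_v / q$, and maps
back through the centered log. `smooth_couplings()` does the analogue for
each coupling block with a sharpened softmax base $\beta_w > 1$ over the
$q^2$ entries, which deliberately skews mass towards large positive
couplings: positive co-occurrence needs few observations to be supported,
whereas apparent anti-correlations are often sampling artifacts.

Numerical conventions: all softmaxes are computed with max-subtraction;
smoothing at $\tau = 0$ is the identity on gauge-fixed input, $\tau = 1$
maps to zero, and round-trips hold to $10^{-10}$. The coupling transform
centers by a single grand mean over the $q^2$ entries — exactly what its
closed form prescribes — so rescaled models intentionally leave the
strict per-row/per-column zero-sum gauge. Rescaling is applied to the
trimmed-length model before background columns are re-inserted, so
re-inserted columns stay exactly at $v_0$ and zero couplings.

## The alignment problem and the solver

Matched pairs score
$s_v(i,k) = \langle v_i^A - v_0,\; v_k^B - v_0\rangle - \gamma$
(log-odds-like background correction; the constant offset $\gamma$
discourages greedy over-alignment and is folded into the positional table
at build time), and coupling pairs score the Frobenius inner product
$s_w = \langle w_{ij}^A, w_{kl}^B\rangle$, weighted by $\alpha_w$. Over
the $L_A \times L_B$ alignment graph — nodes $i.k$, directed edges
$(i.k, j.l)$ for $i<j$, $k<l$ — an alignment is a strictly increasing
node set, and the objective is linear in node variables $x_{ik}$ and edge
variables $y_{ikjl} = x_{ik} x_{jl}$, giving an integer linear program
with the usual activation and increasing-path constraints. The quadratic
interaction makes this NP-hard in general.

`pottsalign` solves it with an exact branch-and-bound written for this
structure. Matches are enumerated in row order; each search node knows
the exact score of its committed prefix, and bounds any completion by an
affine-gap Gotoh dynamic program over the remaining subgrid in which each
cell carries its positional score, its exact coupling to the prefix, and
an optimistic bonus $\alpha_w \sum_{j'>j} \max(0, \max_{l'>l}
s_w(j,l,j',l'))$ — every future coupling counted once at its earlier
endpoint and clipped at zero, hence a valid upper bound. A node is pruned
when its bound cannot improve the incumbent by more than
$\varepsilon\,(s(A,A)+s(B,B))/2$; the largest pruned bound becomes the
final upper bound, so the returned certificate
$2(\mathrm{UB}-\mathrm{LB})/(s(A,A)+s(B,B)) \le \varepsilon$ holds by
construction. With $\varepsilon \to 0$ the solver is exact, which the
test suite verifies against an independent exhaustive-enumeration oracle
on hundreds of small coupled instances, and against a separate
affine-gap dynamic-programming oracle for the independent-site case
($\alpha_w = 0$), where the two optima provably coincide.

Further conventions:

* **Self scores** $s(A,A)$, $s(B,B)$ in the $\varepsilon$ denominator are
  identity-alignment scores under the same $\gamma$, $\alpha_w$ and
  coupling threshold — the only normalization consistent with treating
  them as "model sizes".
* **Gap model.** Affine: a gap segment of $g$ columns costs
  $\text{open} + \text{extend} \cdot g$; with the trained extend of 0
  each segment costs one gap-open. End gaps are free by default
  (reference alignments are structure-trimmed domains; charging terminal
  gaps would be the stronger assumption); `align_config(free_end_gaps =
  FALSE)` switches to charged ends.
* **Ties.** Among equal-score optima the oracles use a canonical rule
  (fewest pairs, then lexicographic); the branch-and-bound applies the
  same rule to incumbents it encounters but epsilon-pruning may hide
  tied optima, so only the score (and its certificate) is canonical.
* **Tractability knobs.** `w_norm_threshold` can drop coupling pairs with
  tiny Frobenius norms from the tables (default 0 keeps all pairs — the
  reference behaviour), and `time_limit_seconds` (default 21600 s) turns
  a long search into a `timeout` result that still reports valid bounds.
* **Offset scope.** Because $\gamma$ lives inside $s_v$, positions
  matched purely to harvest coupling score also pay it.

## Evaluation

`aligned_pairs()` extracts residue–residue pairs from a 2-row reference
FASTA (one pair per column where both rows carry a residue, in ungapped
coordinates), and `precision_recall_f1()` scores a computed alignment by
exact pair identity: $P$ = correct/computed, $R$ = correct/reference,
$F_1 = 2PR/(P+R)$, each 0 when its denominator vanishes. No ±k column
tolerance is applied. Coordinates refer to original (pre-trim) numbering
throughout, so evaluation is independent of preprocessing.

## Synthetic fixtures: what they emulate and what they do not

The generators provide desk-scale ground truth:

* `random_potts_model()` — centered Gaussian fields and a chosen number
  of double-centered dense coupling blocks; `field_scale` around 1
  mimics ordinary positional variation, 2–3 mimics well-conserved
  columns.
* `sample_sequences()` — exact Boltzmann sampling by enumeration (up to
  $10^6$ states), or Gibbs sampling with $100L$ burn-in sweeps and
  thinning $L$, recorded in provenance. Sampled rows are independent:
  real MSAs' phylogenetic correlation is deliberately not modelled.
* `plant_homologous_pair()` — two perturbed copies of a base model with
  inserted background columns and a recorded column correspondence.
  Insertion sites keep at least three base columns from either end and a
  pairwise separation of at least four: a near-terminal insertion lets
  the aligner convert a charged internal gap into a free end gap by
  dropping a terminal match, and two nearby insertions on opposite sides
  let an ungapped alignment "resync" across the short stretch between
  them more cheaply than two gap opens. In either case the planted
  correspondence would no longer be the optimum of the objective — the
  truth would be unidentifiable and recovery tests meaningless — so the
  generator only plants identifiable configurations.
* `coupling_disambiguation_pair()` — blocks in which model A carries two
  columns with *identical* field profiles but only one is coupled to the
  block's anchor (model B couples its single copy identically). Field
  scores and gap costs are exactly symmetric between the two choices;
  only the coupling term breaks the tie. Strong spacer columns between
  blocks and a coupled two-column terminal segment keep each block's
  stray column in its own gap segment (with gap-extend 0, merging gap
  segments would otherwise be free). Independent-site alignment resolves
  each block by tie-break and is wrong whenever the coupled copy is the
  later one (probability 1/2 per block), while coupled alignment prefers
  the truth by a margin of $\alpha_w \lVert \tilde w \rVert_F^2$.

Passing tests on these fixtures show that the machinery — inference,
gauge, rescaling, scoring, exact search, evaluation — does what its
definitions say under controlled conditions. They do not show that real
remote homologs are aligned well: that depends on MSA quality, model
comparability across families, and gap handling, none of which synthetic
independent-row data can probe.

## Problem sizes used in the tests

The suite keeps instances at desk scale by design: solver-vs-oracle
checks use grids up to $5\times5$ (exhaustive enumeration grows as
$\binom{L_A+L_B}{L_A}$) and $8\times8$ for the dynamic-programming cross
check; inference-recovery fits use $L = 5$, $q = 4$, $N = 2000$ sampled
sequences (exact enumeration of $4^5$ states); end-to-end recovery uses
base models of $L = 20$, $q = 20$ with two insertions per side. The full
suite and the acceptance script each run in a few minutes on one CPU.

## Known limitations

* Pseudo-likelihood couplings are noisy at shallow alignment depths; the
  rescaling scheme compensates but is itself a stopgap for the inability
  to put pseudocounts on counts in pseudo-likelihood methods.
* Gaps are not modelled as a Potts state, and gap costs are simple
  affine penalties; very gappy families are handled poorly.
* The solver is exponential in the worst case. Real homologous model
  pairs are far from worst-case, but adversarial instances exist; the
  time limit and `w_norm_threshold` are the escape hatches, both
  reporting honest bounds.
* Dense score tables hold $O(L_A^2 L_B^2)$ coupling entries; models
  beyond a few hundred positions need the sparsification threshold.
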