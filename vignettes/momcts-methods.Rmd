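---
title: "Methods: Pareto Monte Carlo tree search over SMILES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pareto Monte Carlo tree search over SMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momcts)
```

# The model

`momcts` frames de novo molecular design as a search over SMILES strings.
A molecule is a token sequence: the start sentinel `&`, a series of SMILES
tokens (atoms, bonds, branch parentheses, ring digits, bracket atoms such
as `[C@@H]` kept whole), and the terminator `\n`.  The search tree mirrors
this directly — every node is one token, and the path from the root to a
node spells a string prefix.

Three components interact:

1. **A generative rollout policy** $\pi(\text{token} \mid \text{prefix})$,
   a language model over token sequences.  The production policy is a
   recurrent network (embedding, stacked GRU layers, softmax output)
   trained by next-token cross-entropy on a corpus of known molecules.  A
   count-based n-gram policy with the same interface exists for fast,
   fully inspectable experiments.  The policy is frozen during search: it
   proposes, the objectives dispose.
2. **A vector of shaped objective rewards** $r(m) \in [0,1]^d$ for each
   completed molecule $m$ — e.g. docking affinity, drug-likeness (QED) and
   predicted non-toxicity — plus a hard synthetic-accessibility filter.
3. **A Pareto archive** of the nondominated reward vectors found so far,
   which supplies the scalar used to rank tree children.

## Selection: component-wise UCB, scalarized by hypervolume

During selection each visited child $s$ carries a running mean reward
vector $\bar r(s)$ and a visit count $n_s$.  Its upper-confidence reward
vector is the component-wise UCB1 bonus

$$u_i(s) = \bar r_i(s) + c_i \sqrt{\frac{2 \ln n_{parent}}{n_s}},$$

clipped into the unit box $[0,1]^d$ (rewards are shaped into $[0,1]$, so
values above 1 carry no information beyond "optimistic").  To compare
children we need a scalar.  Scalarizing by a fixed weighted sum would bias
the search toward one region of the trade-off surface; instead the scalar
value is defined relative to the current Pareto front $F$ with reference
point $z$ (the origin by default):

$$
W(s) =
\begin{cases}
HV(F \cup \{u\}, z) & u \text{ nondominated w.r.t. } F\\[2pt]
HV(F, z) - \operatorname{dist}(u, F) & u \text{ dominated,}
\end{cases}
$$

where $HV$ is the hypervolume indicator (Lebesgue measure of the region
dominated by the front above $z$) and $\operatorname{dist}(u, F)$ is the
Euclidean distance from $u$ to the nearest front point.  A child whose
optimistic reward vector would *extend* the front is credited with the
extended front's hypervolume; one that falls behind the front is penalized
in proportion to how far behind it falls.  Both cases produce a total
order, so selection is the usual argmax with uniform random tie-breaking.
Unvisited children score $+\infty$ and are visited first.

Hypervolume is computed exactly: one dimension is a maximum, two
dimensions a sorted staircase sweep, three or more a dimension-sweep
recursion that integrates the $(d-1)$-dimensional hypervolume over slabs
of the last coordinate.  Exactness matters because the node value is
compared across children — an approximate indicator would inject noise
into every selection decision.

## Why a constant objective recovers scalar UCB1

Appending a constant objective is the package's single-objective mode, and
the constant must be exactly $1$.  With a second component fixed at 1,
every archived point and every candidate vector has the form $(v, 1)$.
For a clipped UCB vector $u = (u_1, 1)$ and a front $\{(f, 1)\}$:

* if $u_1 \ge f$, $u$ is nondominated and
  $W = HV(\{(f,1),(u_1,1)\}) = u_1 \cdot 1 = u_1$;
* if $u_1 < f$, $u$ is dominated and
  $W = HV(\{(f,1)\}) - \lVert (u_1,1)-(f,1) \rVert = f - (f - u_1) = u_1$.

In both branches $W(s) = \min(1, \text{UCB1}(s))$, so child ranking
coincides with scalar UCB1 — the multiobjective machinery degenerates
cleanly.  Any constant $k < 1$ breaks this: the nondominated branch scales
by $k$ while the penalty branch subtracts an unscaled distance, and the
two branches no longer agree at the front boundary, so the ranking is no
longer order-isomorphic to UCB1.  This degeneration is checked in the test
suite on randomly built trees.

## Expansion, simulation, backpropagation

Expansion adds **one child per visit**.  A node's candidate tokens are the
policy's next-token distribution restricted to probabilities at or above a
floor (default $10^{-3}$, preventing a vocabulary-wide branch at every
node), instantiated in order of decreasing probability.  One step before
the length cap the only candidate is the terminator, which bounds the tree
depth.

Simulation completes the new node's prefix by sampling from the policy
until the terminator (a rollout), then evaluates the completed string:

1. sanitize and canonicalize; an unparsable string scores the zero vector;
2. apply the synthetic-accessibility filter (SAscore $\le 3.5$,
   inclusive); filtered molecules also score zero;
3. otherwise compute the raw objective values, shape each into $[0,1]$,
   and insert the reward vector into the Pareto archive.

Evaluations are cached by canonical SMILES, so a molecule reached twice
(different rollouts, or equivalent SMILES writings) is scored once and the
duplicate costs nothing.  Invalid and filtered completions still *count as
visits* — their zero vectors are backpropagated — so the search learns to
avoid subtrees that mostly produce junk.  Backpropagation updates each
node on the path with the incremental mean
$\bar r \leftarrow \bar r + (r - \bar r)/n$.

## Reward shaping

* **Docking**: with score $ds$ (kcal/mol; lower is better) and a baseline
  $b$ (default 0), the reward is
  $\max\!\left(0, \frac{b - ds}{1 + |b - ds|}\right)$ — a saturating map of
  the improvement over baseline into $[0,1)$.  A score of $-9.4$ against
  baseline 0 maps to $9.4/10.4 \approx 0.904$.
* **QED**: used directly (already in $[0,1]$), clipped.  The QED
  aggregate is computed natively from eight descriptors (molecular
  weight, ALOGP, acceptors, donors, polar surface area, rotatable bonds,
  aromatic rings, structural alerts) via the published asymmetric double
  sigmoid desirability functions and weighted geometric mean; the
  descriptors themselves come from the chemistry backend, and the native
  aggregate matches the backend's own QED to machine precision.
* **Toxicity**: $1 - p$ for a predicted toxicity probability $p$.  No
  pretrained toxicity model ships with the package; the deterministic
  mock (a logistic function of heteroatom fraction and size) stands in,
  and any SMILES-to-probability function can be plugged in.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| embedding dimension | 81 | one dimension per vocabulary token at full scale |
| GRU layers × units | 2 × 256 | full-scale language-model capacity |
| learning rate / batch / epochs | 0.01 / 256 / 100 | Adam, full-scale training schedule |
| exploration constant $c$ | 1 per component | unit-box rewards make 1 a natural scale |
| reference point $z$ | origin | always dominated, since rewards are in $[0,1]^d$ |
| expansion probability floor | $10^{-3}$ | caps branching without hiding plausible tokens |
| SAscore filter | $\le 3.5$ | synthesizability gate before any objective is paid |
| docking baseline | 0 kcal/mol | any binding at all earns positive reward |
| checkpoint schedule | 100, 500, 1000 molecules | front snapshots at fixed generation counts |

Scaled-down values (smaller hidden size, fewer epochs, shorter
`max_length`) are used throughout the tests and examples so everything
runs in seconds on one CPU; they are configuration, not code changes.

# Implementation choices

**Chemistry backend.**  Sanitization, canonicalization, Morgan
fingerprints, SAscore and the QED descriptors are delegated to a
persistent RDKit Python subprocess speaking a line-JSON protocol over
FIFOs (~3 ms per round trip).  An Open Babel-based backend was rejected
after probing: it silently *repairs* malformed SMILES (e.g. `CC(` →
`CC`), which would inflate validity metrics.  Validity here means
"parses and survives sanitization", and invalidity is a result, not an
error.

**Hand-written recurrent network.**  No deep-learning runtime is a
package dependency; the GRU forward pass, backpropagation through time
and Adam are implemented in base R matrix algebra.  The backward pass is
verified against central finite differences in the test suite (relative
error below $10^{-4}$ on every parameter group).  This keeps the package
pure-R-plus-RDKit at the cost of training speed, which is acceptable
because search-time inference, not training, is the hot path.

**Exact hypervolume, incremental archive.**  The archive keeps only
nondominated points, merging exact-duplicate vectors' molecule lists.
Incremental insertion is verified against batch recomputation under
random insertion orders, and the exact hypervolume against
inclusion–exclusion (small $n$) and Monte-Carlo box sampling.

**Enumerable toy space.**  A built-in test double: all strings over a
3-letter alphabet up to length 6, with two anti-correlated objectives
(the fraction of `C` tokens and its complement).  Every achievable
objective point is Pareto-optimal — the 13 Farey fractions with
denominator ≤ 6 — and the exact front is computable by exhaustive
enumeration, giving the full search loop an analytic oracle: 2,000
iterations recover the complete front with no spurious points.

# A minimal run

```{r example, eval = FALSE}
corpus <- generate_fixture_corpus(100, seed = 1)
policy <- ngram_policy(corpus, order = 3, alpha = 0.5)
objectives <- objective_set(
  list(objective_mock_docking(), objective_qed(), objective_mock_toxicity()),
  validity = "chem", sa = "mock")
run <- run_search(search_config(max_iterations = 400, seed = 1),
                  policy, objectives)
run$front
compute_metrics(run, training_corpus = corpus)
```

The same experiment is expressible declaratively — see
`system.file("extdata", "example_run.yaml", package = "momcts")` and
`run_from_config()`, which also writes the generation log, front, metrics
and a manifest.

# Limitations

* **No production toxicity model and no bundled docking engine.**  The
  objective interface is real; the shipped implementations of these two
  are deterministic mocks.  `objective_docking()` drives any
  AutoDock-Vina-compatible binary when one is on the PATH.
* **Training at full scale is slow in base R.**  The recurrent policy
  trains comfortably at fixture scale; a 250k-molecule corpus at the
  full architecture is a multi-day proposition and better served by
  exporting the corpus and importing trained weights.
* **Hypervolume cost grows with front size and dimension.**  The exact
  recursion is fine for $d \le 4$ and the front sizes seen here; large
  $d$ would need an approximate indicator, which would interact with
  selection noise (see above).
* **Single process.**  The search loop is sequential; parallel rollouts
  would change the visit-count semantics and are deliberately out of
  scope.
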