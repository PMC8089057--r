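---
title: "Attention-based contact prediction: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based contact prediction: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A residue-residue contact map records, for a protein of length $L$, which
pairs of residues lie within 8.0 Å of each other (C$\beta$–C$\beta$; C$\alpha$
for glycine) in the native structure. Predicted contact maps are a standard
intermediate for template-free structure prediction, and are assessed by the
precision of the top $\lfloor L/n \rfloor$ predicted pairs ($n = 1, 2, 5$)
within sequence-separation classes: short (6–11), medium (12–23) and long
($\ge 24$) range.

`contattn` implements a two-branch attention architecture over the two
canonical input feature types:

* a **sequence profile** (PSSM, $L \times 20$), processed by the *sequence
  attention module*: instance normalization, a 1D convolution, a
  bidirectional LSTM encoder (forward and backward hidden states
  concatenated), and multi-head scaled dot-product attention
  $$Z = \mathrm{Softmax}\!\left(\frac{QK^\top}{\sqrt{d_{att}}}\right) V,$$
  with per-head trainable $d_{att} \times d_{att}$ maps producing $Q, K, V$
  from per-head slices of a linear projection of the encoder output. The
  attended encoding is tiled to 2D (cell $(i,j)$ receives residue $i$'s
  vector in its first half and residue $j$'s in the second) and concatenated
  with a reduced form of the coupling tensor.

* a **coevolution coupling tensor** (PLM, $L \times L \times C$), processed
  by the *regional attention module*: the tiled profile and the couplings
  are concatenated, reduced (instance norm, ReLU, 1×1 convolution to 2×trunk
  channels, Maxout down to trunk width), passed through the residual trunk,
  projected to 32 channels, and fed to *windowed regional attention*: a
  fixed-filter "region stretching" gather rewrites every cell as its
  flattened $n \times n$ window (row-major offsets, zero padding), the
  center cell provides a query, each window cell a key and value, logits are
  scaled by $1/\sqrt{d}$, and a masked softmax over the in-bounds window
  cells yields the weights.

Both branches share a residual trunk of four blocks with 3-4-6-3 repetitions
of (instance norm → ReLU → 3×3 convolution), a 1×1-convolution shortcut per
block, and a squeeze-and-excitation gate; a 1×1 convolution with sigmoid
produces the $L \times L$ probability map. The final prediction is the
elementwise mean of the two modules' maps; a baseline variant removes the
attention layer from each branch.

## Tunable parameters

| parameter | default (paper preset) | tiny preset | role |
|---|---|---|---|
| `plm_channels` | 441 | 16 | coupling channels C |
| `n_heads` | 4 | 2 | attention heads (both modules) |
| `d_att` | 32 | 8 | per-head width, sequence attention |
| `region_n` | 5 | 5 | regional attention window (odd) |
| `trunk_width` | 64 | 16 | residual trunk channels |
| `reduce_width` | 128 | 32 | pre-Maxout channels (halved by Maxout) |
| `repeats` | 3,4,6,3 | 1,1,1,1 | convolutions per residual block |
| `se_ratio` | 16 | 4 | squeeze-and-excitation bottleneck |
| `lstm_hidden` | 64 | 16 | per-direction encoder width |

Four heads and a 5×5 region are the defaults because that configuration
performed best in the original benchmark. The 1D convolution kernel (5), the
ReLU placement after each instance norm, the per-head width of the regional
attention, and the SE ratio are not specified by the source architecture;
they are package defaults, configurable through `model_config()`.

The **training schedule** is: batch size 1 (one protein per step), Adam at
learning rate 0.001 for epochs 0–29, SGD with learning rate 0.01 and
momentum 0.9 from epoch 30, stop at epoch 60. After every epoch the weights
are checkpointed and the top-$L/2$ long-range precision on the validation
set is computed; the checkpoint with the best validation score is selected
(ties → earliest epoch). The optimizer state is re-initialized at the phase
switch. The loss is mean binary cross-entropy over pairs with separation
$\ge 6$ (the architecture's source does not state its loss; near-diagonal
pairs are trivially non-informative for structure and are excluded).
Weights are initialized from a truncated normal (resampled beyond 2 sd)
with He fan-in scaling; the output bias starts at −2, a prior log-odds
reflecting the rarity of contacts.

## The synthetic-data generator

Training the published architecture requires thousands of proteins with
MSA-derived features; at desk scale the package instead generates fully
self-contained fixtures that preserve the *structure* of the problem:

* **Chains**: a self-avoiding-biased random walk with fixed 3.8 Å steps, a
  4 Å clash distance, and a centroid-pull (compactness 0.9) that yields
  globule-like conformations. Over 200 seeds at $L = 60$ the long-range
  contact density of the resulting 8 Å maps spans roughly 1–20 % (median
  7 %), the band frozen into the test suite.
* **Couplings**: `signal_channels` of the C channels equal
  `contacts + noise` with symmetric Gaussian noise of sd
  `1/signal_to_noise`; the rest are symmetric unit noise. Real coupling
  matrices carry phylogenetic and entropic structure that this deliberately
  omits — passing tests show the pipeline can recover a planted signal, not
  that it reaches benchmark accuracy on real proteins.
* **Profiles**: rows are random probability profiles, with extra mass on
  hydrophobic columns for residues that have at least one long-range
  contact. This is a composition bias, not a realistic profile model; it is
  just enough for the 1D branch to carry predictive information.
* Sequences are drawn residue-wise from the profile rows, so FASTA and
  PSSM agree.

Everything is deterministic given the master seed, at every granularity
(chains, features, sequence draws, training order, ablation shuffles), via
scoped RNG so library code never disturbs the caller's stream.

## Numerical and design choices

* **Out-of-bounds window cells** in regional attention are masked to
  $-\infty$ before the softmax, so padded cells receive exactly zero weight
  and every center distributes exactly one unit of attention. (The
  alternative — letting zero-padded features receive bias-driven weight —
  breaks the conservation properties the interpretation pipeline relies
  on.) Predictions near map borders could differ from an implementation
  that does not mask.
* **Regional attention queries** come from the center cell only, matching
  "each position is a weighted sum of its surrounding region"; full
  window-to-window self-attention would leave the per-position output
  reduction undefined.
* **Tiling layout** is fixed: row-source block first, column-source block
  second.
* **Ranking**: only upper-triangle pairs of the symmetrized map are ranked;
  ties break by (i, j) ascending; the top count is $\lfloor L/n \rfloor$
  with a minimum of 1; pairs with probability exactly 0 are treated as
  unlisted (the RR-file convention) and never selected. Targets whose
  length admits no pair in a range score `NA` and are excluded from
  dataset means rather than scored 0.
* **Received attention**: the $(L, L, heads, n^2)$ regional weight tensor
  is folded back onto the map by accumulating, for every center, the
  weight it assigns to each covered cell (head-averaged). This conserves
  total mass at $L^2$ and is the package's definition of the "2D attention
  score matrix"; the per-residue form adds the normalized row and column
  sums and rescales to sum 1.
* **Permutation ablation** shuffles the channel axis of every coupling
  cell in the $m \times m$ window around a center (mirrored at $(j, i)$ to
  preserve pair symmetry). A spatial shuffle of a 1×1 region would be a
  no-op, yet 1×1 regions are part of the published protocol, so the
  channel axis is the only reading under which all three region sizes act.
* **Phi-value peak region**: a contiguous window of half-width 3 around
  the argmax of the profile; experimental peaks are broader than a single
  residue but the source does not define the extent.
* **Checkpoint format**: R native serialization with the configuration
  embedded; `load_checkpoint()` restores a model whose validation score
  reproduces the logged value exactly.

## Problem sizes used by the shipped analyses

The package's own study (tests and `scripts/acceptance.R`) trains the tiny
preset for 10 epochs on 30 synthetic proteins with $L \in [24, 48]$ and
signal-to-noise 5, validates on 6, and holds out 10 for evaluation; the
ablation analysis aggregates 20+ seeded shuffles on the held-out proteins.
These sizes were chosen so that the whole study runs on a single CPU in
minutes while the planted signal remains comfortably learnable; the paper-
scale preset instantiates the full published architecture and trains with
the same code path.

## Known limitations

* The engine is a dense, single-threaded autodiff tape; it is sized for
  desk-scale experiments, not for 441-channel features on 500-residue
  proteins.
* The synthetic generator does not emulate MSA statistics, phylogenetic
  correlations, alignment depth effects, or real DCA inference; results on
  it bound nothing about CASP-level accuracy.
* The no-attention baseline is this package's construction (both branches
  minus their attention layers); the original baseline is named but not
  specified.
* Whether the original implementation masks padded window cells, and how
  it collapses the regional weight tensor to an $L \times L$ score matrix,
  are not stated in the source; both choices here are documented above and
  configurable.
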