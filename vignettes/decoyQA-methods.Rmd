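---
title: "decoyQA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{decoyQA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-prediction pipelines emit many candidate 3D models ("decoys") for
a target protein. Estimation of model accuracy (EMA) asks: given only a
decoy — no native structure — how good is it? decoyQA treats this as
regression onto the two standard CASP quality scores, GDT-TS and lDDT, both
on the $[0,1]$ scale, and predicts them with a graph convolutional network
that uses only the decoy's geometry and sequence; no engineered energy,
accessibility or evolutionary features.

## Quality scores

**GDT-TS** is the mean over distance cutoffs $\{1, 2, 4, 8\}$ Å of the
maximal fraction of alpha-carbons that a rigid superposition can place
within the cutoff of their native positions. The exact maximisation is
NP-hard; `compute_gdtts()` uses the standard seed-and-extend approximation:
every contiguous window of length 3, 5, 7 and the whole chain seeds a
least-squares (Kabsch) superposition, which is refitted on the under-cutoff
atom set until that set stabilises; the best fraction per cutoff is kept.
The procedure is exact for the identity and any rigid motion, and the test
suite pins it against an independently written implementation of the same
search.

**lDDT** is superposition-free. The native defines the reference pair set:
all heavy-atom pairs in *different* residues closer than the 15 Å inclusion
radius. A pair is preserved at tolerance $t \in \{0.5, 1, 2, 4\}$ Å when
the decoy reproduces the native distance within $t$; a residue's score is
the mean preserved fraction over the four tolerances across its pairs, and
the global score is the mean over residues with at least one pair. Pairs
with atoms absent from the decoy count as not preserved; decoy atoms are
matched by (residue index, atom name). We use the plain distance-difference
variant, without stereochemistry penalties, because the score serves purely
as a regression label. Inclusion and preservation use strict inequalities;
both choices only matter on measure-zero boundaries.

## Dual graph representation

A decoy is represented by two directed nearest-neighbour graphs:

* **Atom graph** — nodes are heavy atoms; each atom keeps up to 20 nearest
  same-residue neighbours and up to 20 nearest cross-residue neighbours
  whose distance is strictly below 6 Å. The same/cross partition lets the
  network treat intra-residue covalent context separately from packing
  contacts.
* **Residue graph** — nodes are residues; residue–residue distance is the
  minimum over their heavy-atom pairs, with the same 6 Å threshold and a
  20-neighbour cap.

The caps and threshold are exposed in `graph_config()`; 6 Å / 20 are the
defaults because they were the selected values in the hyperparameter search
the architecture comes from. Neighbour lists are per-source (reciprocity is
not enforced), and ties at the cap break by (distance, index) so graphs are
bit-for-bit reproducible. Construction is brute-force $O(n^2)$ in
distances — at single-chain sizes this is milliseconds, and the tests pin
it against an independent exhaustive sort.

## Features

Atoms carry a one-hot encoding over 11 context-refined element classes:
alpha-carbon; sp2 carbon (backbone carbonyl, carboxylate, amide and
guanidinium carbons); aromatic-ring carbon; other sp3 carbon; amide
nitrogen (backbone and side-chain); aromatic-ring nitrogen; positively
charged nitrogen (guanidinium and lysine ammonium); carbonyl oxygen;
hydroxyl oxygen; carboxylate oxygen (including terminal OXT); sulfur. The
class system refines element identity (C/N/O/S) by residue context, keeping
the alpha-carbon — the one atom shared by every residue with a fixed
structural role — as its own class.

Residues carry an embedding from a pluggable, purely sequence-determined
provider: `onehot` (20-dim identity), `random` (fixed-seed Gaussian lookup
table, arbitrary dimension, for tests), or `plm`, an adapter for an
external protein language model whose per-residue output is 1024-dim. The
language model is deliberately not a dependency: the architecture only
needs *a* residue feature matrix of declared width, and everything in this
package is testable without multi-gigabyte downloads. All features are
functions of sequence and atom identity only, so the network is
rigid-motion invariant by construction.

## Network

Four atom-level convolution layers update atom $i$ as

$$v_i \leftarrow \mathrm{ReLU}\Big(W^{(c)} v_i
 + \tfrac{1}{|N_s(i)|} W^{(s)} \sum_{j \in N_s(i)} v_j
 + \tfrac{1}{|N_o(i)|} W^{(o)} \sum_{j \in N_o(i)} v_j + b\Big),$$

with $N_s$, $N_o$ the same-/cross-residue neighbour sets (an empty set
contributes zero). Four residue-level layers do the same with a single
neighbour set. Each activation is followed by batch normalisation and then
dropout (0.1 on convolution layers only). The final atom representations
are max-pooled within each residue, concatenated with the residue stream,
and an MLP (two hidden layers, ReLU) emits one scalar per residue; a
sigmoid squashes it into $[0,1]$ and the **global score is exactly the mean
of the per-residue scores**. That averaging is what makes the per-residue
outputs interpretable as local quality even though training uses only
global labels.

Choices the published architecture leaves open, fixed here:

* *Output squashing*: sigmoid (bounded outputs keep the loss bins
  well-defined); `clamp` and `none` are available in `model_config()`.
* *Hidden widths*: 128 per stream and MLP (128, 64) by default; the desk
  protocol below uses 64 and (128, 64) for runtime.
* *Batch normalisation scope*: statistics are taken over the nodes of the
  decoy's own graph (training mode), with running statistics used in
  evaluation mode so prediction is deterministic. Normalising per graph
  rather than across a stacked batch makes decoys independent, which keeps
  gradient accumulation exact and predictions independent of batch
  composition.
* *Dropout location*: convolution layers only, not the MLP.
* *Concatenation*: final layers of each stream only.
* *Initialisation*: uniform fan-in with a recorded seed.

The backward pass is written by hand (there is no autodiff here) and is
verified against central finite differences in the test suite; max-pool
gradients route to the argmax atom (first on ties), and the loss
subgradient at the tube boundary uses the inside-tube convention (zero).

## The score-dependent ε-insensitive loss

The training loss is
$$L(y, y') = \max\big(0,\, |y - y'| - \varepsilon(y)\big),$$
an ε-insensitive (SVM-regression) loss whose tube half-width depends on the
*true* score $y$ through a 9-bin step function on $[0, 1]$ (bins of width
0.1 up to 0.8, then one bin for $y > 0.8$; bins are half-open on the left,
the last closed at 1). The default (`mid`) widths fall from 0.45 in the
worst bin to 0.01 above 0.8, with `low`/`high` presets shifting all nine
values down/up by 0.05 (0.005 in the last bin). The intent: poor decoys
only need to be *recognised* as poor, so they sit in a wide tube the model
is free to ignore; near-native decoys — the ones that matter for model
selection — must be fitted to within a few hundredths. Because
$\varepsilon$ depends on $y$ only, the gradient in $y'$ is simply the L1
sign masked by tube membership. Ablation baselines (plain L1, L2, and a
constant-width tube, default 0.2) share the `loss_config()` interface.

## Training schedule

The recipe is two-phase: pre-train with the L1-loss (default 50 epochs),
then fine-tune with the variable-width ε-loss (default 10 epochs),
optimised with Adam (defaults except learning rate $10^{-3}$), batch size
70. Pre-training matters because early in training everything is far
outside the tube and the ε-loss is then just L1 with a dead zone; L1 first
bootstraps the fit. For lDDT prediction the best GDT-TS checkpoint can be
passed as a warm start (`init_params_warm`) and fine-tuned further.

Score distributions in real decoy pools are heavily skewed toward poor
decoys, so the sampler draws decoys with probability inverse to the
population of their score bin (10 equal-width bins), equalising bin draw
rates. Validation loss is logged per epoch under the active phase's loss,
the phase-2 loss is recomputed on every checkpoint, and the selected model
is the argmin of that recomputed loss across all epochs, so the selection
criterion is consistent across phases. Splits are always by target — decoys
of one target never straddle train/validation — and training is
deterministic given the seed.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` stands in for CASP-style training pools. Natives are
idealised single chains (alternating helical segments and extended linkers
built from ideal bond geometry with small dihedral jitter; N, CA, C, O and
a virtual CB), with random sequences, and are rejected and resampled until
free of inter-residue clashes below 2 Å — the covalent peptide-bond pair
C(i)–N(i+1), which sits at 1.33 Å by construction, is the one excluded
pair. Decoys perturb a native by i.i.d. Gaussian coordinate noise
(`global_noise`), by rigidly displacing a contiguous segment
(`segment_shift`, which decouples GDT-TS from lDDT the way domain
misplacement does), or both (`mixed`). Noise grades span 0.1–4 Å, and only
a `high_quality_fraction` (default 0.1) of decoys draw from the grades at
or below 0.5 Å, reproducing the sparse high-quality tail of real pools.
Labels are always recomputed with the scoring functions, never trusted from
the generator, so the scoring module is on every test path.

These sets share with real data exactly the statistics the method consumes:
full-range, imbalanced labels; local packing that degrades monotonically
with noise; sequence/structure consistency. They do *not* contain realistic
folds, side chains beyond CB, systematic modelling errors (register shifts,
mirrored topologies) or inter-decoy correlation structure, so passing the
desk-scale tests demonstrates that the implementation learns and ranks as
designed — not that it reaches published CASP correlations, which require
the real decoy sets and GPU-scale training and are out of scope here.

## Desk-scale protocol and problem sizes

The end-to-end learning check trains on 30 targets × 25 decoys (chains of
30–60 residues, one-hot residue features, hidden width 64, schedule 10 L1
+ 5 ε epochs, batch 70, 20% of targets held out) and requires held-out
pooled Pearson $R \ge 0.8$ plus an improvement over the untrained network.
The ablation-direction check uses 10 targets × 12 decoys (25–40 residues,
hidden 48) across five seeds, comparing the two-phase model's selected
validation ε-loss against the pure-L1 model obtained from the phase-1
prefix of the same deterministic trajectory. Numerical tolerances
elsewhere: graph and scoring oracles are exact or $10^{-12}$; network
invariances $10^{-5}$ (float accumulation order); finite-difference
gradient checks $10^{-4}$ relative.

## Known limitations

Single chains only (first MODEL, one chain per run); no structure repair;
residues missing from a decoy are tolerated but entire-residue gaps are
re-indexed contiguously with a warning; non-standard residues are accepted
only where a canonical parent exists (MSE→MET, SEC→CYS, PYL→LYS). The
GDT-TS search is an approximation with the usual seed-and-extend blind
spots on adversarial geometries. Training at the published scale (tens of
thousands of decoys, 1024-dim language-model embeddings) is supported by
the code paths but not by the bundled protocols.
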