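---
title: "Sparse adjusted motif models of the splicing code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse adjusted motif models of the splicing code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samsplice)
```

## The model

`samsplice` implements an interpretable, modular neural model of RNA
splice-site choice.  Instead of learning splice sites from raw sequence as
a black box, the model is forced to route all sequence information through
two biologically anchored bottlenecks:

1. **LSSI** — two small feedforward networks score every position as a
   candidate 3′ splice site (23-nt window: the last 20 intron bases and
   first 3 exon bases) or 5′ splice site (9-nt window: last 3 exon bases,
   first 6 intron bases).  Scores are natural-log probabilities clamped at
   a floor of −10; positions at the floor for both site types can never be
   predicted as splice sites.  The clamp makes the LSSI a high-recall mask
   that passes only 1–2% of positions while discarding almost no true
   sites.

2. **Motif layer** — each RNA-binding protein (RBP) channel scores the
   sequence with its position-specific affinity matrices (PSAMs): the
   affinity of a window is the product of per-position relative affinities
   times an absolute affinity, summed over the RBP's 1–5 PSAMs and
   assigned to the window's *center* position.  A sparsity layer then
   zeroes everything below a per-channel threshold, keeping at most a
   fraction δ of positions per channel (hard-mask semantics: surviving
   values pass unchanged, so the track stays in affinity units).

An **aggregator** (convolution of width 49 → windowed attention of width
401 → elementwise multiplication with the sparse motif track, which makes
the sparsity propagate → two more convolutions → BiLSTM → per-position
3-way softmax gated by the LSSI scores in log space) turns the two tracks
into per-position probabilities over {null, acceptor, donor}.

The **adjusted motif (AM)** layer lets the motif scores change during
end-to-end training without losing their identity: with
`u ⊕ v = 1(u ≠ 0)(u + v)`,

```
AM(x) = Sparse( Sparse(FM(x), k·δ) ⊕ Adj(x), δ ),
```

where `Adj` is a residual CNN (5 units × two width-3 convolutions,
receptive field 21 nt) and `k = 2`.  Every AM site is therefore one of the
top-`k·δ` FM sites of its channel — the AM can rescore and reselect among
plausible PSAM sites, but cannot invent new motifs.

## The information bottleneck

With `M` channels at mean density δ and at most η bits per nonzero
activation, the motif layer transmits at most

```
H/L ≤ M [ H(B(δ)) + δ·η ]        (bits per base)
```

(`H(B(·))` is binary entropy).  At the operating point `M = 79`,
`δ = 0.18%`, `η = 2.8` bits this evaluates just below the 1.91 bits/nt
compression requirement:

```{r}
entropy_bound(M = 79, delta = 0.0018, eta = 2.8)
solve_eta(1.91, M = 79, delta = 0.0018)
```

Density is annealed during training: δ starts at 0.75 and is multiplied
by 0.75, 20 checks per epoch, whenever validation accuracy `V(t)` reaches
a target `VT(t)` — either a constant tuned externally ("standard"
training) or the dynamic quick schedule (starts at 0.85, decays 1% per
epoch, bumps to the accuracy achieved at each reduction).  Thresholds
track the `(1−δ)` batch quantile by EMA (momentum 0.9) during training and
are recalibrated to the exact top-δ cut over the training set afterwards.
`empirical_channel_entropy()` estimates (δ̂, η̂) from a sparse track, and
`reconstruction_probe()` trains a decoder from track windows back to base
identity as an empirical check that the bound is sound (the information
estimate `2 − H(base | prediction)` must stay below the bound — it does,
loosely, matching the bound's character as sound but not tight).

## Synthetic study system

Everything is validated on a ground-truthed synthetic genome
(`gen_genome()`).  Genes carry 3–4 real exons with consensus splice sites
(polypyrimidine tract + AG; AG|GTAAGT) planted at strength 0.9 per base,
plus 1–2 *decoy* exons per gene with the same consensus strength inside
introns.  Five splicing regulatory factors (two exonic enhancers, one
exonic silencer, one intronic enhancer, one intronic silencer) are planted
preferentially near the candidate type they favour; a candidate internal
exon is then included with probability

```
plogis( gain · (core + Σ signed activities within the effect window) + bias )
```

with gain 1, bias −2, a latent core-strength term of SD 0.5, and an
effect window of 50 nt.  Under these settings real internal exons are
included ~80% of the time and decoys ~8%, and — by construction — splice-
site sequence alone cannot separate the two: only motif context can.
That is the property the recovery experiments rely on, and it is why a
trained model must beat the LSSI-only baseline to demonstrate that the
motif pathway carries signal.

The window is 50 nt rather than something larger because introns are
90–160 nt here: a larger window would let enhancers planted for a real
exon bleed into a neighbouring decoy's window and blur the planted ground
truth.  For the in-vitro-vs-in-vivo experiments, `gen_psams()` can
mis-specify one consensus position per motif; the off-consensus relative
affinity (0.2) keeps true occurrences scorable so they remain inside the
AM's support constraint.

What the generator does *not* emulate: real base composition and isochore
structure, overlapping genes, alternative 5′/3′ site pairs, motif
families with correlated specificities, and expression-level effects.
Passing recovery tests therefore show that the machinery can extract a
planted regulatory code at this signal-to-noise level, not that it
attains the published genome-scale accuracies.

## Problem sizes and training protocol

The package's validation experiments run at fixture scale: 110 genes of
~600 nt (40 training, 10 validation, 48 test with a short gap), 5 motif
channels, a target density of 0.5% (the planted per-channel occurrence
density is ~0.3%, so 0.18% would truncate true sites), aggregator
channels 16, BiLSTM hidden 16, attention 2 heads — the architectural
constants 49/401/21/k=2 are kept.  End-to-end training uses Adam at 1e-3
for 10 epochs with standard-mode annealing at `VT = 0.55`; the VT grid
search the full-scale protocol calls for is replaced by its own
criterion — the largest VT at which this fixture's model still anneals
all the way to the density target (a higher VT stalls the anneal once
early training dips below it, leaving the motif layer dense).  The LSSI
trains separately (10 epochs, batch 150, lr 1e-3 at full scale; 4 epochs
suffice on fixtures).

## Numerical and design choices

* **Window-center assignment** of PSAM scores (offset `floor(w/2)`); the
  alternative left-anchor convention only shifts tracks.
* **N bases** become uniform 0.25 one-hot rows; a PSAM row contributes its
  mean; positions containing N are excluded from top-k ranking.
* **Labels** sit on exonic bases (acceptor = first, donor = last exonic
  base).  Recovery results are insensitive to any consistent shift.
* **Hard-mask sparsity** (no shrinkage), density enforced per channel at
  δ so the mean density equals the δ used in the bound; thresholds are
  EMA-tracked over all values of the pre-sparse track, with an exact
  deterministic recalibration pass for evaluation.
* **Ties** at the top-k cutoff break by (score descending, position
  ascending).
* **⊕ and clipping**: negative post-⊕ values are clipped to 0 by default
  (exposed as `clip_negative`) so AM tracks stay in nonnegative
  relative-affinity units for display and interpretation.
* **Zero-initialised heads**: both the AM adjustment network's output
  convolution and the aggregator's output layer start at zero.  The AM
  then begins exactly as the resparsified FM (a random head's adjustment
  noise reshuffles site selection, which the support gate makes hard to
  undo), and the aggregator begins exactly at the LSSI-gated baseline, so
  training can only build on signal it actually finds.
* **Input conditioning**: the aggregator's concat uses exponentiated
  LSSI scores (probabilities in `[0, 1]`) next to the affinity-scale
  motif channels; feeding the raw −10-floored log scores makes the
  convolution features an order of magnitude more sensitive to the LSSI
  columns than to the motifs and destabilises the annealing phase.  The
  final log-space gating still uses the raw clamped scores.
* **Optimization safeguards**: global gradient-norm clipping (BiLSTM
  backpropagation occasionally explodes), optional gradient accumulation
  across genes, and validation-selected parameter snapshots (the model
  returned is the epoch with the best validation top-k once the density
  target is reached).
* **Read pooling** for RBNS classification is log-sum-exp over positions
  of the per-position track, with the PSAM signal entering on the
  log-affinity scale — a smooth "best site" score matching at-least-one-
  site semantics.
* **ψ of an exon** is the mean of the acceptor probability at its 3′SS
  and donor probability at its 5′SS.
* **RII direction** follows SD1−SD2 / SA2−SA1 (positive = favours intron
  recognition); a `flip` flag exists because caption and text phrasings
  of such subtractions commonly disagree.
* **eCLIP regions**: a site is exonic iff its (center) base is exonic;
  enrichment is computed from site counts, not region lengths; rows with
  zero control overlap or zero enrichment for either model are excluded.
* **RNA-map aggregation** uses 150 nt of intron and 75 nt of exon around
  each splice site, mean effect per meta-position, normalised to the 99th
  percentile of |effect| and clipped to [−1, 1].
* **Landscape normalisation**: site scores are `log p − log p_topk − 1`
  (natural log), so the model's top-k threshold sits at −1 and only
  sites above −5 are displayed; knockout arrows use the 1.5× / 2⁄3 fold
  thresholds with the top-5 effects always listed (dashed below cutoff).
* **MPRA significance** is a 10⁴-draw permutation test on BMA/AFD sign
  agreement across RBPs.

* **Sparsity-propagating multiply**: the default wiring multiplies the
  first M attention channels elementwise with the motif track and passes
  the remaining channels through; an alternative (`all_channels`) scales
  every channel by the summed site strength, making the entire
  post-attention pathway sparse.  Both are exposed on the aggregator
  configuration; the default trains more stably here.

## Limitations

The neural core is written in R with hand-derived gradients (verified
against finite differences in the test-suite); it is adequate for
fixture-scale experiments but not for genome-scale training.  Quick-mode
annealing needs many epochs to reach low densities and is exercised here
mainly through its schedule contract; fixture training uses standard mode.

At fixture scale the end-to-end model's pooled top-k accuracy tracks the
LSSI-only baseline closely rather than exceeding it by a wide margin: the
baseline is strong on short genes whose true sites are mostly
constitutive, per-position cross-entropy optimises calibration rather
than cross-gene ranking, and a few hundred optimizer steps at batch size
one extract only part of the planted regulatory signal (within single
genes the trained model separates regulated candidates better than the
LSSI alone).  The motif pathway's value at this scale therefore shows
most clearly in site-level measures — the purity of adjusted-motif sites
and the assay analyses — rather than in the headline ranking metric.
Accuracies quoted anywhere in this package refer to the synthetic study
system only.
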