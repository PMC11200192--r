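---
title: "Models and methods in mhc2epi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mhc2epi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2epi)
```

# The problem

HLA class II molecules present peptides of variable length (roughly 11–19
residues) to CD4+ T cells. Predicting which peptides are *presented* (the
eluted-ligand, "EL" problem) is necessary but not sufficient for vaccine
design: only a fraction of presented ligands are *immunogenic* (the "IM"
problem). mhc2epi implements a two-stage pipeline: a presentation model
trained on ligandome-style data, followed by a conditional domain-adversarial
transfer stage that adapts the learned features to the immunogenicity domain,
where labelled data are scarcer and differently distributed.

# The presentation model

Each peptide and each allele pseudosequence (the 34 groove-lining residues)
is encoded residue-wise by stacked one-hot and BLOSUM62 channels (42 channels
per position; BLOSUM62 scores are divided by 11, their maximum magnitude, so
both blocks are on comparable scale). Each branch applies a learned input
projection plus positional embedding and a stack of pre-norm transformer
encoder blocks (default 3 per branch, 12 attention heads, model width 96).
The two branches are coupled by low-rank bilinear attention pooling: with
peptide states $H_p$ and allele states $H_a$, factors $U, V$ of rank $r$
(default 32),

$$A = \mathrm{softmax}_{\text{rows}}\!\left(\frac{(H_p U)(H_a V)^\top}{\sqrt r}\right),
\qquad
f_r = \frac{1}{L_p}\sum_{i,j} A_{ij}\,(H_p U)_{ir}\,(H_a V)_{jr}.$$

The attention map $A$ is exported directly for interpretation
(`attention_export()`, `plot_attention()`); the joint vector $f$ feeds a
dense head of 128–64–32 units with a 2-unit softmax output. Training uses
AdamW on cross-entropy, with the learning rate restricted to
$[10^{-5}, 10^{-2}]$; validation loss selects the reported epoch. Training
is deterministic given the seed, and records are canonically ordered first
so that results never depend on input row order.

Positions beyond a sequence's true length are one-hot on the padding symbol
`X` and participate in attention; the learned positional and padding
embeddings let the model use or ignore them. This means sequence length is
visible to the model — intentional, since ligand length is informative in
this problem.

# Branch features and score fusion

Three scalar features complement the sequence branch, fused with fixed
contribution weights: peptide sequence 60%, gene expression 12%,
cleavability 12%, binding-core offset 16% (`fusion_weights()`, `fuse()`).
Fusion happens on the probability scale; a record with no expression value
has the remaining weights renormalized.

* **Expression.** TPM values are mapped as $\log_{10}(X + 10^6)$
  (`expression_feature()`); a fixed override (conventionally TPM = 50) serves
  vaccine-candidate scanning where per-sample RNA-seq is unavailable. This
  transform compresses all biological TPM values into roughly $[6, 6.3]$; it
  is implemented exactly as stated, and `expression_score()` rescales that
  interval onto $[0, 1]$ for fusion (TPM cannot exceed $10^6$, which fixes
  the upper bound).
* **Cleavage.** Each terminus contributes a 6-residue window (3 residues
  either side of the cut). The two windows, one-hot encoded (12 × 21,
  flattened), pass through two 32-unit dense layers and a logistic output
  (`train_cleavage_model()`). Decoy windows define the background
  composition (`cleavage_background()`).
* **Binding-core offset.** Motif deconvolution (below) yields a per-motif
  prior over core offsets; the feature is the prior probability of the
  assigned offset normalized by the motif's modal offset
  (`offset_feature()`). Background-assigned peptides carry no offset
  information and receive the neutral value 0.5.

# Motif deconvolution

Ligands are extended by three residues of flanking context per side and
modelled as a mixture of $K$ motifs plus a flat background. A motif is a
9 × 20 PWM with a global prior over core offsets; the background emission is
the empirical residue composition, held fixed. EM alternates posterior
responsibilities over (motif, offset, background) with re-estimation of
PWMs, offset priors and mixture weights.

Numerical choices: PWM pseudocount 0.1 per cell and offset-prior floor
$10^{-3}$ prevent zero-likelihood lock-in; convergence is declared when the
objective changes by less than $10^{-6} n$, with a 500-iteration cap;
restarts default to 10 at desk scale (configurable to the hundreds for
production deconvolution). The offset prior is *global*: offsets
inadmissible for a short sequence contribute zero likelihood rather than
being renormalized per length. This keeps the M-step exact, so the EM
objective — the log-likelihood plus the Dirichlet pseudocount/floor penalty,
stored per iteration in `trace` — is provably non-decreasing. The plain
data log-likelihood is reported separately as `loglik`; for $K = 0$ it is
the exact closed-form background log-likelihood. Padding symbols emit
probability 1 under every component, so flank padding never biases
responsibilities. Ties and model choice across $K$ are left to `glance()`'s
AIC. Offsets are 0-based from the start of the extended sequence; the
offset feature is per-motif (not per-allele), with allele attribution left
to caller metadata.

# Domain-adversarial transfer

The immunogenicity stage transfers the presentation feature extractor $F$
(encoders + bilinear attention) and attaches a decoder $G$ (two dense
layers + softmax) and a domain discriminator $D$ (three dense layers) fed by
the multilinear map $h = f \otimes g$ of features and class probabilities
(`multilinear_map()`; a seed-fixed randomized projection of width 1024 caps
the dimension). Training solves a minimax problem: $D$ minimizes the domain
cross-entropy $\mathcal{L}_{adv}$, while $F$ and $G$ minimize their
classification losses *minus* $\omega\,\mathcal{L}_{adv}$ — implemented by
gradient reversal, i.e. the adversarial gradient reaching $F, G$ is
$-\omega\,\partial\mathcal{L}_{adv}$. The reversal is verified against
finite differences in the test suite. With $\omega = 0$ the procedure
reduces exactly to supervised fine-tuning.

Because the immunogenic set is labelled and the model is evaluated on
immunogenicity, a target-supervised cross-entropy term on the immunogenic
records is included by default (`target_supervised = TRUE`); switching it
off together with $\omega = 0$ gives the source-only baseline. $\omega$
defaults to 1 with a linear warm-up over the first 10% of steps; batch
size 32 per domain and 30 epochs are the training defaults. Divergence
(NaN loss) aborts with diagnostics rather than returning a corrupt model.

Two stabilizations, both on by default and both switchable, address the
failure modes of the minimax game at small sample sizes:

* `detach_conditioning` treats the classifier predictions $g$ as constant
  inside the conditioning map $h$ (as the reference conditional-adversarial
  implementations do), so the reversed adversarial gradient reaches the
  feature extractor only and cannot corrupt the decoder directly;
* `balance_adversarial` rescales the reversed adversarial gradient, when
  necessary, so its per-batch norm never exceeds the supervised gradient
  norm. Without the cap, the alignment pressure on a few hundred records
  either dominates (the decoder collapses to chance) or must be made so
  weak that no alignment happens; with it, alignment proceeds exactly as
  fast as the classification signal can tolerate.

Two diagnostics quantify alignment: `domain_discriminator_accuracy()` (the
trained $D$'s own accuracy — near chance after successful alignment, high
when trained with $\omega = 0$ on genuinely shifted domains) and
`probe_domain_accuracy()` (a fresh discriminator trained to convergence on
frozen features; its training accuracy is the separability measure — its
held-out accuracy mostly reflects probe overfitting at these sample sizes
and is not used).

`cdan_benchmark()` packages the full protocol at desk scale — maximally
shifted two-domain simulation, reduced-width presentation model,
adversarial ($\omega = 1.5$, chosen with the stabilizers so that alignment
succeeds without collapse) and source-only transfer — and returns the
alignment and transfer diagnostics for one seed.

# Evaluation protocol

`auc()` uses the Mann–Whitney rank formulation with tie correction;
`aupr()` is average precision with tied scores grouped; `f1_score()` and
`balanced_accuracy()` threshold at 0.5 on the probability scale (the
threshold is a package choice, stated here because it is not dictated by
the method). `ppvn()` ranks all records and takes the top
$k = \lceil \text{fraction} \times n\rceil$ with stable ties: the
*precision* variant (fraction of the top $k$ that are true binders) is the
default, because in a decoy-dominated design it is the reading under which
performance necessarily degrades as the fraction grows; the *recall*
variant (fraction of binders captured) is available and labelled
explicitly. Decoy generation (`make_decoys()`) draws length-matched random
proteome substrings, excludes any sequence in the hit set, skips windows
with non-standard residues, and is deterministic per seed; the canonical
benchmark design pairs each binder with 98 decoys. `core_scan()` evaluates
every 9-mer window of an oligomer (10 windows for the canonical 18-mer)
and returns the argmax with ties to the smallest offset.
`percentile_rank()` converts scores to the percentage of a length-matched
background scoring strictly higher (lower = stronger).

# The synthetic-data generator

`simulate_dataset()` provides the controlled test bed. Per allele it plants
a sharp 9-mer PWM (Dirichlet concentration 0.05 per column — near-consensus
cores, the regime where motif recovery is well-posed); core offsets follow
a geometrically decaying prior (rate 0.7, mimicking the N-terminal offset
preference of natural ligands); lengths are uniform on 12–19; positives
embed a PWM-sampled core in background flanks, negatives are background
only; labels flip at 5% to emulate assay noise. Hit flanks are enriched for
proline/alanine within two residues of the termini (probability 0.4 per
position), reproducing the cleavage signature the cleavage branch is meant
to detect. TPM values are log-normal (meanlog 2, sdlog 1.5, a realistic
bulk RNA-seq spread).

The immunogenic domain shifts relative to the antigenic one under a single
control, `domain_shift_strength` $s \in [0,1]$, with two components chosen
to satisfy the assumptions under which domain-adversarial alignment is
meaningful. First, a covariate shift that is *feature-visible yet
label-orthogonal*: the background frequencies of the aliphatic residues
I/L/M/V scale by $1 + 3s$. Aromatics are deliberately excluded from the
skew because the label signal (below) is aromatic, and a shift entangled
with label-relevant information cannot be aligned away without destroying
the classifier — a failure mode we observed directly with a
length-distribution shift, since length is entangled with the core-offset
information classification needs. Second, a labelling-rule shift engaged
per record with probability $s$: immunogenicity requires an aromatic
TCR-facing stretch at core positions 4–6, shifted positives carry it, and
shifted negatives are *presented-but-non-immunogenic* ligands — a planted
binding core whose central stretch is forced non-aromatic. These negatives
are the crux of real immunogenicity data (presentation is necessary but
not sufficient) and are what makes a presentation-only model genuinely
degrade on the immunogenic domain. At $s = 0$ the two domains are
identical in law — a tested invariant. Ground truth (planted PWMs,
offsets, generative scores) is returned for recovery tests.

What the generator does *not* emulate: mass-spectrometry acquisition bias,
multi-allele deconvolution ambiguity within a sample, real pseudosequence
structure (bundled pseudosequences are synthetic random 34/269-mers,
labelled as such), and correlations between expression and presentation.
Passing tests on simulated data therefore demonstrate algorithmic
correctness and the intended qualitative behaviors, not clinical-grade
accuracy on real ligandomes.

# Problem sizes and numerical scale

The packaged tests and the acceptance script run the full pipeline at desk
scale, chosen so every stage remains informative: presentation smoke
training uses 2 000 records at reduced encoder width (model width 48,
4 heads, rank 16), motif recovery uses 500 peptides with one planted motif,
and the adversarial benchmark uses 300 records per domain at width 16
across 10 seeds. The architecture defaults above (96/12/32) are the
production configuration; all sizes are arguments, and the behaviors tested
are size-stable. The numeric core is hand-written dense linear algebra with
manual backpropagation — every backward pass is checked against central
finite differences in the test suite — with AdamW and decoupled weight
decay (decay skipped for biases and layer-norm gains). Training batches
sequences of a branch into stacked matrices so projections and
feed-forward layers are single BLAS calls; the per-sample attention cores
and layer norms run as compiled kernels, records sharing an allele
pseudosequence run the allele branch once per batch, and the compiled path
is verified element-wise against the plain per-sample reference
implementation in the tests.

# Known limitations

* The distance-profile allele encoding is defined against a pluggable
  residue-distance table; no curated structural table ships with the
  package, only a synthetic one for tests.
* Percentile-rank backgrounds default to a few hundred random peptides per
  allele at the CLI for speed; production use should raise
  `n_background` to the canonical 10 000.
* The EM deconvolution does not model reverse binders or per-sample
  multi-allele mixtures; motif-to-allele attribution is the caller's
  responsibility.
* Training the transformer stages in plain R is CPU-bound; the defaults are
  sized for tens of thousands of records, not millions.
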