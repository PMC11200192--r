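# mhc2epi

HLA class II epitope presentation and immunogenicity modelling in R.

CD4+ T cell responses require two things of a peptide: that an HLA class II
molecule presents it, and that the presented complex is immunogenic. mhc2epi
implements a two-stage pipeline for both questions, aimed at computational
immunologists building neoantigen or vaccine-candidate prioritization
workflows:

1. **Presentation (EL) model** — transformer encoders over the peptide and
   the 34-residue allele pseudosequence, coupled by low-rank bilinear
   attention whose joint representation feeds a 128–64–32 dense head. The
   sequence score is fused with three biological features at fixed
   contribution weights

   *score* = 0.60 · sequence + 0.12 · expression + 0.12 · cleavage + 0.16 · core-offset,

   where expression is log10(TPM + 10⁶) rescaled, cleavage comes from a
   two-layer classifier over the 3+3-residue windows flanking each terminus,
   and the core-offset feature comes from motif deconvolution: an EM mixture
   of 9-mer position weight matrices with binding-core offset priors over
   flank-extended ligands.

2. **Immunogenicity (IM) model** — a conditional domain-adversarial network
   (CDAN) transfers the presentation features to the immunogenicity domain:
   a domain discriminator D is trained on the multilinear map h = f ⊗ g of
   features and class probabilities, while the feature extractor and decoder
   minimize their classification losses and confuse D via gradient reversal
   (min_D max_{F,G} objective with adversarial weight ω).

Evaluation utilities implement the field's protocol: AUC/AUPR/F1/balanced
accuracy, PPVn on a 98-decoys-per-binder design, length- and locus-stratified
reports, percentile ranks against proteome backgrounds, and the 18-mer /
9-mer binding-core scan for neoantigen candidates. A synthetic-data generator
with planted motifs, cleavage signatures, log-normal expression and a
controlled domain shift makes every stage testable end-to-end without
external downloads.

All neural components run on a small, hand-written dense/attention numeric
core with manual backpropagation (gradients are finite-difference-verified in
the test suite), so the package has no deep-learning framework dependency.

## Worked example

```r
library(mhc2epi)

# a synthetic two-domain study: planted motifs, flanks, expression, shift
sim <- simulate_dataset(sim_config(n_alleles = 1, n_pos = 300, n_neg = 300,
                                   label_noise = 0, seed = 7))

# motif deconvolution on the presented ligands
hits <- dplyr::filter(sim$antigenic, label == 1)
mm <- fit_motifs(extend_peptides(hits), K = 1, seed = 7)
mm
#> <motif_mixture> K = 1 motif(s) + background, fit on 300 sequences
#>   loglik -14412.97 after 6 EM iteration(s) (converged)
#>   consensus: WARLWETRW
pwm_consensus(sim$truth$pwms[[1]][[1]])   # the planted motif
#> [1] "WARLWEHRW"

# presentation model (reduced width for a quick run)
cfg <- el_config(d_model = 16, n_heads = 4, d_ban = 16, epochs = 5,
                 lr = 3e-3, seed = 7)
el <- train_el(build_el_model(cfg), sim$antigenic, sim$pseudo)
glance(el)
#> # A tibble: 1 × 4
#>   n_parameters epochs_trained best_val_loss best_val_auc
#>          <int>          <int>         <dbl>        <dbl>
#> 1        28274              5         0.459        0.915

# domain-adversarial transfer to the immunogenicity domain
im <- train_im(el, sim$antigenic, sim$immunogenic, sim$pseudo,
               cdan_config(omega = 1, epochs = 10, seed = 7))
preds <- predict_im(im, sim$immunogenic, sim$pseudo)
auc(preds$s_im, preds$label)
#> [1] 0.9238
```

The deconvolution recovers the planted binding core at 8/9 consensus
positions from 300 ligands. `best_val_auc` is the validation AUC of the
presentation model on held-out peptides (1.0 = perfect ranking); the final call scores the immunogenic
domain with the adapted decoder. `autoplot()` methods draw training curves
and motif logos; `attention_export()`/`plot_attention()` expose the bilinear
attention map over (peptide position × HLA residue) for interpretation.

A thin command-line front-end mirrors the pipeline
(`inst/scripts/mhc2epi`): subcommands `simulate`, `deconvolve`, `train-el`,
`train-im`, `predict`, `evaluate`, `attention`, each writing its artifacts
with a reproducibility manifest.

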