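# The packaged domain-shift benchmark: a fixed, seed-indexed protocol that
# exercises the adversarial transfer stage end-to-end on the synthetic
# two-domain test bed and reports the alignment and transfer diagnostics.

#' Run one replicate of the domain-adversarial benchmark
#'
#' A fixed protocol at desk scale: simulate a maximally shifted two-domain
#' study (150 positives and negatives per domain, one allele), train a
#' reduced-width presentation model (width 16, 4 heads, rank 16, 8 epochs),
#' then adapt it to the immunogenic domain twice — adversarially
#' (omega = 1.5, 30 epochs) and source-only (omega = 0, no target labels) —
#' and measure: the trained discriminator's domain accuracy after
#' adversarial training, the accuracy of a fresh probe discriminator on the
#' source-only model's features (domain separability without adversarial
#' coupling), and the target-domain balanced accuracy of both models on
#' held-out immunogenic records.
#'
#' @param seed Integer seed driving every stochastic stage of the
#'   replicate.
#' @return One-row tibble: `seed`, `disc_acc_adversarial`,
#'   `disc_acc_no_adversarial`, `bacc_cdan`, `bacc_source_only`.
#' @export
cdan_benchmark <- function(seed) {
  sim <- simulate_dataset(sim_config(n_alleles = 1L, n_pos = 150L, n_neg = 150L,
                                     domain_shift_strength = 1, seed = seed))
  cfg <- el_config(d_model = 16L, n_heads = 4L, d_ban = 16L, epochs = 8L,
                   lr = 3e-3, seed = seed)
  el <- train_el(build_el_model(cfg), sim$antigenic, sim$pseudo)
  imm <- split_train_val(sim$immunogenic, 0.3, seed = seed + 100L)
  m_adv <- train_im(el, sim$antigenic, imm$train, sim$pseudo,
                    cdan_config(omega = 1.5, epochs = 30L, seed = seed,
                                lr_d = 3e-3, warmup_frac = 0.3))
  m_src <- train_im(el, sim$antigenic, imm$train, sim$pseudo,
                    cdan_config(omega = 0, epochs = 30L, seed = seed,
                                lr_d = 3e-3, target_supervised = FALSE))
  tibble::tibble(
    seed = seed,
    disc_acc_adversarial =
      domain_discriminator_accuracy(m_adv, sim$antigenic, imm$train, sim$pseudo),
    disc_acc_no_adversarial =
      probe_domain_accuracy(m_src, sim$antigenic, imm$train, sim$pseudo,
                            epochs = 400L, seed = seed),
    bacc_cdan =
      balanced_accuracy(predict_im(m_adv, imm$val, sim$pseudo)$s_im, imm$val$label),
    bacc_source_only =
      balanced_accuracy(predict_im(m_src, imm$val, sim$pseudo)$s_im, imm$val$label))
}
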