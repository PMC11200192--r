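# Synthetic-data generator.
#
# Emulates the structure of class II immunopeptidomics studies: per-allele
# 9-mer binding motifs planted as PWMs, binding-core offsets drawn from a
# decaying prior, 3-residue flanking context, proline/alanine-enriched
# cleavage signatures near hit termini, log-normal gene expression, and a
# controlled shift between the presentation ("antigenic") and
# immunogenicity ("immunogenic") domains. Ground truth (PWMs, offsets,
# generative scores) is returned so recovery can be tested.

#' Configuration for the synthetic-data generator
#'
#' @param n_alleles Number of alleles (default 2).
#' @param motifs_per_allele Planted motifs per allele (default 1).
#' @param pwm_sharpness Dirichlet concentration of each PWM column; smaller
#'   is sharper (default 0.05, near-consensus cores).
#' @param offset_prior_decay Geometric decay of the binding-core offset
#'   prior, `prior(o) ~ decay^o` (default 0.7).
#' @param n_pos,n_neg Positives and negatives per domain (default 250
#'   each).
#' @param domain_shift_strength Shift between domains in [0, 1]: 0 makes
#'   the immunogenic domain identical in law to the antigenic domain. At
#'   positive strength the immunogenic domain shifts (i) its residue
#'   composition — the background aliphatic (I/L/M/V) frequencies scale by
#'   `1 + 3 * strength` — and (ii) its labelling rule, engaged per record
#'   with probability equal to the strength: immunogenicity then depends on
#'   an aromatic TCR-facing stretch at core positions 4-6, with shifted
#'   positives carrying it and shifted negatives being
#'   *presented-but-non-immunogenic* ligands (a planted core with that
#'   stretch forced non-aromatic), so presentation evidence alone cannot
#'   separate the immunogenic classes. Default 0.5.
#' @param cleavage_enrichment Probability that each flank residue within
#'   two positions of a hit terminus is replaced by proline or alanine
#'   (default 0.4).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters (defaults 2 and
#'   1.5, a realistic bulk RNA-seq spread).
#' @param length_range Inclusive peptide length bounds (default 12-19).
#' @param label_noise Label flip rate (default 0.05).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_alleles = 2L, motifs_per_allele = 1L,
                       pwm_sharpness = 0.05, offset_prior_decay = 0.7,
                       n_pos = 250L, n_neg = 250L, domain_shift_strength = 0.5,
                       cleavage_enrichment = 0.4, tpm_meanlog = 2,
                       tpm_sdlog = 1.5, length_range = c(12L, 19L),
                       label_noise = 0.05, seed = 1L) {
  if (domain_shift_strength < 0 || domain_shift_strength > 1)
    stopf("domain_shift_strength must be in [0, 1]")
  if (any(c(n_alleles, motifs_per_allele, n_pos, n_neg) < 0))
    stopf("counts must be >= 0")
  if (length_range[1] + 6L < MOTIF_LEN)
    stopf("length_range too short to place a %d-mer core", MOTIF_LEN)
  structure(as.list(environment()), class = "sim_config")
}

BG_FREQS <- local({
  # Uniprot-like average amino-acid composition, ordered as AA_ALPHABET.
  f <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
         I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
         R = 5.5, S = 6.6, T = 5.3, V = 6.9, W = 1.1, Y = 2.9)
  f / sum(f)
})

sample_aa <- function(n, freqs = BG_FREQS) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = freqs)
}
# sample() treats a length-1 vector as 1:x; guard against collapsed ranges
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
sample_seq <- function(len, freqs = BG_FREQS) {
  paste(sample_aa(len, freqs), collapse = "")
}

#' Simulate a toy proteome
#'
#' Random proteins drawn from average amino-acid composition, for decoy
#' generation and flank lookup in tests and examples.
#'
#' @param n_proteins Number of proteins (default 40).
#' @param mean_len Mean protein length (default 350; lengths vary +/-50%).
#' @param seed Integer seed.
#' @return Named character vector of protein sequences.
#' @export
simulate_proteome <- function(n_proteins = 40L, mean_len = 350L, seed = 1L) {
  with_seed(seed, {
    lens <- pmax(60L, round(stats::runif(n_proteins, 0.5, 1.5) * mean_len))
    stats::setNames(vapply(lens, sample_seq, character(1)),
                    sprintf("SYNP%04d", seq_len(n_proteins)))
  })
}

sim_allele_names <- function(n) {
  stock <- c("DRB1*07:01", "DRB1*04:04", "DQA1*05:01/DQB1*02:01",
             "DRB1*15:01", "DPA1*01:03/DPB1*04:01", "DRB1*03:01")
  if (n <= length(stock)) return(stock[seq_len(n)])
  c(stock, sprintf("DRB1*%02d:01", 20L + seq_len(n - length(stock))))
}

sample_pwm <- function(sharpness) {
  t(vapply(seq_len(MOTIF_LEN), function(j) {
    g <- stats::rgamma(20L, shape = sharpness)
    if (sum(g) == 0) g[sample.int(20L, 1L)] <- 1
    g / sum(g)
  }, numeric(20L)))
}

#' Simulate paired presentation and immunogenicity datasets
#'
#' Builds the two-domain test bed: positive peptides embed a PWM-sampled
#' 9-mer core at a prior-sampled offset within background flanks;
#' negatives are background-only. Hit flanks are proline/alanine-enriched
#' within two residues of the termini. The immunogenic domain shifts both
#' the residue composition and the labelling rule by
#' `domain_shift_strength`: its positives additionally carry an aromatic
#' TCR-facing stretch at core positions 4-6, its negatives include
#' presented-but-non-immunogenic ligands, and its background mixes toward a
#' hydrophobic-skewed composition. TPM values are log-normal per gene.
#'
#' @param cfg A [sim_config()].
#' @return List with tibbles `antigenic` and `immunogenic`, the allele
#'   `pseudo` table, the `expression` table, a toy `proteome`, and `truth`
#'   (planted PWMs, offset priors, per-record generative scores).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    alleles <- sim_allele_names(cfg$n_alleles)
    pseudo <- tibble::tibble(
      allele = alleles,
      short_seq = vapply(alleles, function(a) sample_seq(34L), character(1)),
      full_seq = vapply(alleles, function(a) sample_seq(269L), character(1)))

    pwms <- lapply(alleles, function(a)
      lapply(seq_len(cfg$motifs_per_allele), function(m) sample_pwm(cfg$pwm_sharpness)))
    names(pwms) <- alleles
    max_off <- cfg$length_range[2] + 6L - MOTIF_LEN
    offset_prior <- cfg$offset_prior_decay^(0:max_off)
    offset_prior <- offset_prior / sum(offset_prior)

    n_genes <- max(20L, (cfg$n_pos + cfg$n_neg) %/% 5L)
    genes <- sprintf("SYNG%04d", seq_len(n_genes))
    expression <- tibble::tibble(
      gene = genes,
      tpm = stats::rlnorm(n_genes, cfg$tpm_meanlog, cfg$tpm_sdlog))

    # aliphatic skew only: keeps the domain cue orthogonal to the aromatic
    # immunogenicity signal
    hydro <- c("I", "L", "M", "V")

    make_domain <- function(domain) {
      s <- if (domain == "immunogenic") cfg$domain_shift_strength else 0
      # composition shift: hydrophobic skew grows with strength (x4 at s = 1)
      bg <- BG_FREQS
      bg[hydro] <- bg[hydro] * (1 + 3 * s)
      bg <- bg / sum(bg)
      rows <- vector("list", cfg$n_pos + cfg$n_neg)
      truth <- vector("list", cfg$n_pos + cfg$n_neg)
      for (i in seq_len(cfg$n_pos + cfg$n_neg)) {
        is_pos <- i <= cfg$n_pos
        allele <- alleles[((i - 1L) %% cfg$n_alleles) + 1L]
        L <- sample1(cfg$length_range[1]:cfg$length_range[2])
        ext_len <- L + 6L
        ext <- sample_aa(ext_len, bg)
        core_off <- NA_integer_; gen_score <- NA_real_
        # at positive shift the immunogenic domain's negatives include
        # presented-but-non-immunogenic ligands: a planted core whose anchor
        # position is forced non-aromatic, so presentation alone cannot
        # separate the immunogenic classes
        if (!is_pos && s > 0 && stats::runif(1) < s) {
          adm <- seq_len(ext_len - MOTIF_LEN + 1L)
          pri <- offset_prior[adm] / sum(offset_prior[adm])
          core_off <- if (length(adm) == 1L) adm - 1L else sample(adm, 1L, prob = pri) - 1L
          pwm <- pwms[[allele]][[sample.int(cfg$motifs_per_allele, 1L)]]
          core <- vapply(seq_len(MOTIF_LEN), function(j)
            sample(AA_ALPHABET, 1L, prob = pwm[j, ]), character(1))
          non_arom <- setdiff(AA_ALPHABET, c("F", "W", "Y"))
          for (j in 4:6) if (core[j] %in% c("F", "W", "Y"))
            core[j] <- sample(non_arom, 1L)
          ext[(core_off + 1L):(core_off + MOTIF_LEN)] <- core
        }
        if (is_pos) {
          adm <- seq_len(ext_len - MOTIF_LEN + 1L)   # offsets 0..ext_len-9
          pri <- offset_prior[adm] / sum(offset_prior[adm])
          core_off <- if (length(adm) == 1L) adm - 1L else sample(adm, 1L, prob = pri) - 1L
          pwm <- pwms[[allele]][[sample.int(cfg$motifs_per_allele, 1L)]]
          core <- vapply(seq_len(MOTIF_LEN), function(j)
            sample(AA_ALPHABET, 1L, prob = pwm[j, ]), character(1))
          if (s > 0 && stats::runif(1) < s) {
            # shifted labelling rule: aromatic TCR-facing stretch at the
            # core centre
            core[4:6] <- sample(c("F", "W", "Y"), 3L, replace = TRUE)
          }
          ext[(core_off + 1L):(core_off + MOTIF_LEN)] <- core
          gen_score <- sum(log(pwm[cbind(seq_len(MOTIF_LEN), aa_index[core])] /
                                 BG_FREQS[core]))
          # cleavage signature: P/A enrichment within two residues of termini
          for (pos in c(2L, 3L, ext_len - 2L, ext_len - 1L)) {
            in_core <- pos > core_off & pos <= core_off + MOTIF_LEN
            if (!in_core && stats::runif(1) < cfg$cleavage_enrichment)
              ext[pos] <- sample(c("P", "A"), 1L)
          }
        }
        label <- as.integer(is_pos)
        if (stats::runif(1) < cfg$label_noise) label <- 1L - label
        rows[[i]] <- tibble::tibble(
          peptide = paste(ext[4:(3 + L)], collapse = ""),
          allele = allele, label = label,
          gene = genes[((i - 1L) %% n_genes) + 1L],
          n_flank = paste(ext[1:3], collapse = ""),
          c_flank = paste(ext[(ext_len - 2L):ext_len], collapse = ""),
          domain = domain, source = "simulated")
        truth[[i]] <- tibble::tibble(true_label = as.integer(is_pos),
                                     core_offset = core_off, gen_score = gen_score)
      }
      list(records = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
    }

    ant <- make_domain("antigenic")
    imm <- make_domain("immunogenic")
    list(antigenic = ant$records, immunogenic = imm$records,
         pseudo = pseudo, expression = expression,
         proteome = simulate_proteome(seed = cfg$seed + 1L),
         truth = list(pwms = pwms, offset_prior = offset_prior,
                      antigenic = ant$truth, immunogenic = imm$truth,
                      config = cfg))
  })
}
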