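# Probabilistic motif deconvolution.
#
# Class II ligands of mixed length and allele origin are modelled as a
# mixture of K motifs plus a flat background. Each motif is a 9 x 20
# position weight matrix (PWM) paired with a prior over binding-core offsets
# within the flank-extended peptide; EM estimates PWMs, offset priors and
# mixture weights jointly. The background emission is the empirical
# amino-acid composition and stays fixed during EM.
#
# Peptides are extended by 3 residues of flanking context on each side
# before fitting, so a core can sit partly in the flank region, as observed
# for natural ligands.

MOTIF_LEN <- 9L

#' Extend peptides with 3-residue flanking context
#'
#' Each peptide becomes `n_flank (3) + peptide + c_flank (3)`. Flanks come
#' from the record fields when present, else from a proteome lookup, and are
#' X-padded to exactly 3 residues when shorter or unknown.
#'
#' @param records Peptide record tibble.
#' @param proteome Optional named protein vector for flank lookup.
#' @return Character vector of extended sequences (length = peptide + 6).
#' @export
extend_peptides <- function(records, proteome = NULL) {
  n <- nrow(records)
  nf <- if ("n_flank" %in% names(records)) records$n_flank else rep("", n)
  cf <- if ("c_flank" %in% names(records)) records$c_flank else rep("", n)
  out <- character(n)
  for (i in seq_len(n)) {
    nfi <- nf[i]; cfi <- cf[i]
    if (!nzchar(nfi) && !nzchar(cfi) && !is.null(proteome)) {
      w <- lookup_windows(records$peptide[i], proteome)
      if (!is.null(w)) {
        nfi <- substr(w$n_window, 1L, 3L)
        cfi <- substr(w$c_window, 4L, 6L)
      }
    }
    out[i] <- paste0(pad_flank(nfi, "left"), records$peptide[i], pad_flank(cfi, "right"))
  }
  out
}

# Integer-code sequences: residues 1..20, padding/unknown -> 21 (emits
# probability 1, i.e. log-weight 0, under every component).
code_seq <- function(seq) {
  chars <- split_chars(seq)
  idx <- aa_index[chars]
  idx[is.na(idx)] <- 21L
  unname(idx)
}

# Per-sequence core index matrix: row o+1 lists the coded residues of the
# 9-mer starting at 0-based offset o.
core_matrix <- function(v) {
  n_off <- length(v) - MOTIF_LEN + 1L
  if (n_off < 1L) stopf("sequence shorter than the %d-mer core", MOTIF_LEN)
  m <- matrix(0L, n_off, MOTIF_LEN)
  for (o in seq_len(n_off)) m[o, ] <- v[o:(o + MOTIF_LEN - 1L)]
  m
}

empirical_background <- function(coded) {
  counts <- tabulate(unlist(coded), nbins = 21L)[1:20]
  if (sum(counts) == 0L) return(rep(1 / 20, 20L))
  freq <- counts / sum(counts)
  # floor to keep log-ratios finite for residues absent from the sample
  freq <- pmax(freq, 1e-6)
  stats::setNames(freq / sum(freq), AA_ALPHABET)
}

# E-step for one sequence: log relative likelihood of each (motif, offset)
# against background, via the padded log-weight matrices lw[[k]] (9 x 21).
# The offset prior is global: offsets inadmissible for a short sequence
# simply contribute zero likelihood, which keeps the M-step exact and the
# EM objective monotone.
seq_log_ratios <- function(cm, lw, log_prior, n_off) {
  K <- length(lw)
  out <- matrix(-Inf, K, nrow(cm))
  jcol <- col(cm)
  for (k in seq_len(K)) {
    out[k, ] <- rowSums(matrix(lw[[k]][cbind(as.vector(jcol), as.vector(cm))],
                               nrow = nrow(cm)))
  }
  out + log_prior[, seq_len(nrow(cm)), drop = FALSE]
}

#' Fit a motif mixture model by EM
#'
#' Decomposes a set of flank-extended ligands into `K` 9-mer PWMs with
#' offset-preference priors plus a flat background class. Each EM restart
#' runs to convergence (absolute log-likelihood change below `tol_factor *
#' n` or `max_iter` iterations); the restart with the best log-likelihood is
#' returned. `K = 0` gives the closed-form background-only model.
#'
#' @param extended Character vector of flank-extended sequences (each length
#'   >= 9; see [extend_peptides()]).
#' @param K Number of motifs (>= 0).
#' @param restarts Number of EM restarts (default 10; raise towards a few
#'   hundred for production-scale deconvolution).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol_factor Convergence tolerance per sequence (default 1e-6).
#' @param pseudocount PWM pseudocount per cell (default 0.1).
#' @param offset_floor Offset-prior floor (default 1e-3) preventing
#'   zero-likelihood lock-in.
#' @return Object of class `motif_mixture`: PWMs, offset priors, mixture
#'   weights (last element = background), background composition, the data
#'   log-likelihood (`loglik`) and the per-iteration `trace` of the EM
#'   objective (log-likelihood plus the Dirichlet pseudocount/floor
#'   penalty; non-decreasing by construction).
#' @export
fit_motifs <- function(extended, K, restarts = 10L, seed = 1L, max_iter = 500L,
                       tol_factor = 1e-6, pseudocount = 0.1, offset_floor = 1e-3) {
  if (length(extended) == 0L) stopf("no sequences to deconvolve")
  if (K < 0L) stopf("K must be >= 0")
  coded <- lapply(extended, code_seq)
  lens <- lengths(coded)
  if (any(lens < MOTIF_LEN))
    stopf("all sequences must be >= %d residues after extension", MOTIF_LEN)
  background <- empirical_background(coded)
  n <- length(coded)

  if (K == 0L) {
    lbg <- c(log(background), 0)
    loglik <- sum(vapply(coded, function(v) sum(lbg[v]), numeric(1)))
    return(new_motif_mixture(K = 0L, pwms = list(),
                             offset_priors = matrix(0, 0, 0),
                             mixture_weights = 1, background = background,
                             loglik = loglik, trace = loglik, n = n,
                             converged = TRUE, seed = seed))
  }

  n_off_max <- max(lens) - MOTIF_LEN + 1L
  if (K > n) rlang::warn(sprintf("K = %d exceeds the %d distinct sequences; fit proceeds", K, n))
  cms <- lapply(coded, core_matrix)
  n_offs <- vapply(cms, nrow, integer(1))
  lbg_const <- sum(vapply(coded, function(v) sum(c(log(background), 0)[v]), numeric(1)))

  best <- NULL
  with_seed(seed, {
    for (rs in seq_len(restarts)) {
      fit <- em_one_restart(cms, n_offs, background, K, n_off_max, max_iter,
                            tol_factor * n, pseudocount, offset_floor, lbg_const)
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
  })
  new_motif_mixture(K = K, pwms = best$pwms, offset_priors = best$offset_priors,
                    mixture_weights = best$weights, background = background,
                    loglik = best$loglik, objective = best$objective,
                    trace = best$trace, n = n,
                    converged = best$converged, seed = seed)
}

em_one_restart <- function(cms, n_offs, background, K, n_off_max, max_iter,
                           tol, pseudocount, offset_floor, lbg_const) {
  # random init: PWMs near-background with Dirichlet noise, priors near-flat
  pwms <- lapply(seq_len(K), function(k) {
    g <- matrix(stats::rgamma(MOTIF_LEN * 20L, shape = 5), MOTIF_LEN, 20L)
    p <- g * rep(background, each = MOTIF_LEN)
    p / rowSums(p)
  })
  offset_priors <- matrix(stats::rgamma(K * n_off_max, shape = 20), K, n_off_max)
  offset_priors <- offset_priors / rowSums(offset_priors)
  weights <- rep(1 / (K + 1), K + 1)

  n <- length(cms)
  trace <- numeric(0)
  prev_obj <- -Inf
  ll <- NA_real_
  converged <- FALSE
  resp_list <- vector("list", n)
  for (iter in seq_len(max_iter)) {
    lw <- lapply(pwms, function(p) cbind(log(p) - rep(log(background), each = MOTIF_LEN), 0))
    log_prior <- log(offset_priors)
    lwk <- log(weights[seq_len(K)])
    lbgw <- log(weights[K + 1L])
    ll <- lbg_const
    for (i in seq_len(n)) {
      lr <- seq_log_ratios(cms[[i]], lw, log_prior, n_offs[i]) + lwk
      mx <- max(lr, lbgw)
      num <- exp(lr - mx)
      den <- sum(num) + exp(lbgw - mx)
      ll <- ll + mx + log(den)
      resp_list[[i]] <- list(motif = num / den, bg = exp(lbgw - mx) / den)
    }
    # EM objective: data loglik + Dirichlet regularization terms (the
    # quantity the pseudocounted M-step provably never decreases)
    obj <- ll + pseudocount * sum(vapply(pwms, function(p) sum(log(p)), numeric(1))) +
      offset_floor * sum(log_prior)
    trace <- c(trace, obj)
    if (abs(obj - prev_obj) < tol) { converged <- TRUE; break }
    prev_obj <- obj

    # M-step
    counts <- lapply(seq_len(K), function(k) matrix(pseudocount, MOTIF_LEN, 20L))
    off_counts <- matrix(offset_floor, K, n_off_max)
    w_counts <- rep(0, K + 1L)
    for (i in seq_len(n)) {
      r <- resp_list[[i]]$motif         # K x n_off
      cm <- cms[[i]]
      w_counts[seq_len(K)] <- w_counts[seq_len(K)] + rowSums(r)
      w_counts[K + 1L] <- w_counts[K + 1L] + resp_list[[i]]$bg
      for (k in seq_len(K)) {
        rk <- r[k, ]
        keep <- rk > 1e-12
        if (!any(keep)) next
        for (o in which(keep)) {
          res <- cm[o, ]
          real <- res <= 20L
          if (any(real)) {
            idx <- cbind(which(real), res[real])
            counts[[k]][idx] <- counts[[k]][idx] + rk[o]
          }
        }
        off_counts[k, seq_len(nrow(cm))] <- off_counts[k, seq_len(nrow(cm))] + rk
      }
    }
    pwms <- lapply(counts, function(cc) cc / rowSums(cc))
    offset_priors <- off_counts / rowSums(off_counts)
    weights <- (w_counts + 1e-8) / sum(w_counts + 1e-8)
  }
  list(pwms = pwms, offset_priors = offset_priors, weights = weights,
       loglik = ll, objective = trace[length(trace)], trace = trace,
       converged = converged)
}

new_motif_mixture <- function(K, pwms, offset_priors, mixture_weights,
                              background, loglik, trace, n, converged, seed,
                              objective = loglik) {
  pwms <- lapply(pwms, function(p) {
    dimnames(p) <- list(paste0("P", seq_len(MOTIF_LEN)), AA_ALPHABET); p
  })
  structure(list(K = K, pwms = pwms, offset_priors = offset_priors,
                 mixture_weights = mixture_weights, background = background,
                 loglik = loglik, objective = objective, trace = trace, n = n,
                 converged = converged, seed = seed),
            class = "motif_mixture")
}

#' @export
print.motif_mixture <- function(x, ...) {
  cat(sprintf("<motif_mixture> K = %d motif(s) + background, fit on %d sequences\n",
              x$K, x$n))
  cat(sprintf("  loglik %.2f after %d EM iteration(s)%s\n", x$loglik,
              length(x$trace), if (x$converged) " (converged)" else ""))
  if (x$K > 0L) {
    cons <- vapply(x$pwms, pwm_consensus, character(1))
    cat("  consensus:", paste(cons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm 9 x 20 probability matrix.
#' @return 9-character consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(AA_ALPHABET[apply(pwm, 1L, which.max)], collapse = "")
}

#' Assign binding cores to peptides under a fitted motif mixture
#'
#' Computes the E-step responsibilities of every (motif, offset) pair and
#' the background class for each sequence, and reports the maximum-
#' responsibility assignment. The full responsibility table is retained as
#' attribute `"responsibilities"` (per sequence: a `K x n_offsets` matrix
#' plus the background mass); responsibilities sum to 1 per sequence.
#'
#' @param model Fitted `motif_mixture`.
#' @param extended Character vector of flank-extended sequences.
#' @return Tibble with `extended`, `motif` (0 = background), `offset`
#'   (0-based core start within the extended sequence; `NA` for
#'   background) and `responsibility`.
#' @export
assign_cores <- function(model, extended) {
  coded <- lapply(extended, code_seq)
  if (any(lengths(coded) < MOTIF_LEN))
    stopf("all sequences must be >= %d residues", MOTIF_LEN)
  n <- length(coded)
  if (model$K == 0L) {
    out <- tibble::tibble(extended = extended, motif = 0L,
                          offset = NA_integer_, responsibility = 1)
    attr(out, "responsibilities") <- replicate(n, list(motif = matrix(0, 0, 0), bg = 1),
                                               simplify = FALSE)
    return(out)
  }
  lw <- lapply(model$pwms, function(p)
    cbind(log(p) - rep(log(model$background), each = MOTIF_LEN), 0))
  log_prior <- log(model$offset_priors)
  lwk <- log(model$mixture_weights[seq_len(model$K)])
  lbgw <- log(model$mixture_weights[model$K + 1L])
  resp_all <- vector("list", n)
  motif <- integer(n); offset <- integer(n); responsibility <- numeric(n)
  for (i in seq_len(n)) {
    cm <- core_matrix(coded[[i]])
    lr <- seq_log_ratios(cm, lw, log_prior, nrow(cm)) + lwk
    mx <- max(lr, lbgw)
    num <- exp(lr - mx)
    bg <- exp(lbgw - mx)
    den <- sum(num) + bg
    r <- num / den; rbg <- bg / den
    resp_all[[i]] <- list(motif = r, bg = rbg)
    if (rbg >= max(r)) {
      motif[i] <- 0L; offset[i] <- NA_integer_; responsibility[i] <- rbg
    } else {
      am <- arrayInd(which.max(r), dim(r))
      motif[i] <- am[1]; offset[i] <- am[2] - 1L; responsibility[i] <- max(r)
    }
  }
  out <- tibble::tibble(extended = extended, motif = motif, offset = offset,
                        responsibility = responsibility)
  attr(out, "responsibilities") <- resp_all
  out
}

#' Binding-core offset feature
#'
#' Converts an assigned core offset into a [0, 1] feature: the motif's
#' offset-prior probability at the assigned offset, normalized by that
#' motif's maximum prior, so the modal offset scores 1. Background
#' assignments carry no offset information and receive the neutral value
#' 0.5.
#'
#' @param assignments Tibble from [assign_cores()].
#' @param model The `motif_mixture` used for assignment.
#' @return Numeric vector of offset features in [0, 1].
#' @export
offset_feature <- function(assignments, model) {
  vapply(seq_len(nrow(assignments)), function(i) {
    k <- assignments$motif[i]
    if (k == 0L) return(0.5)
    pri <- model$offset_priors[k, ]
    pri[assignments$offset[i] + 1L] / max(pri)
  }, numeric(1))
}

#' Export motif logos and PWM tables
#'
#' Writes, per motif, the PWM as TSV and an information-content sequence
#' logo as PNG. For a background-only model (`K = 0`) a background
#' composition bar chart is written instead.
#'
#' @param model Fitted `motif_mixture`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
export_logos <- function(model, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create output directory: %s", out_dir)
  files <- character(0)
  if (model$K == 0L) {
    df <- tibble::tibble(aa = factor(AA_ALPHABET, AA_ALPHABET), freq = model$background)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$freq)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(x = NULL, y = "background frequency") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "background_composition.png")
    ggplot2::ggsave(f, p, width = 6, height = 3, dpi = 120)
    return(invisible(f))
  }
  for (k in seq_len(model$K)) {
    tsv <- file.path(out_dir, sprintf("motif_%d_pwm.tsv", k))
    readr::write_tsv(tibble::as_tibble(model$pwms[[k]], rownames = "position"), tsv)
    png <- file.path(out_dir, sprintf("motif_%d_logo.png", k))
    ggplot2::ggsave(png, plot_logo(model$pwms[[k]]), width = 6, height = 3, dpi = 120)
    files <- c(files, tsv, png)
  }
  invisible(files)
}

# Information-content sequence logo: letters at each position scaled by
# p * IC, IC = log2(20) + sum p log2 p.
plot_logo <- function(pwm) {
  df <- purrr::map_dfr(seq_len(nrow(pwm)), function(j) {
    p <- pwm[j, ]
    ic <- log2(20) + sum(ifelse(p > 0, p * log2(p), 0))
    ord <- order(p)
    tibble::tibble(position = j, aa = AA_ALPHABET[ord], height = p[ord] * ic,
                   ymin = cumsum(c(0, (p * ic)[ord]))[seq_along(p)])
  })
  df$ymax <- df$ymin + df$height
  df$mid <- (df$ymin + df$ymax) / 2
  big <- df[df$height > 0.08, , drop = FALSE]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$aa), show.legend = FALSE) +
    ggplot2::geom_text(data = big,
                       ggplot2::aes(x = .data$position, y = .data$mid, label = .data$aa),
                       size = 3, color = "white") +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(pwm))) +
    ggplot2::labs(x = "core position", y = "bits") +
    ggplot2::theme_minimal()
}
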