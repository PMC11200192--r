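# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a motif mixture model
#'
#' @param x A `motif_mixture`.
#' @param ... Unused.
#' @return Long tibble: `motif`, `position`, `aa`, `prob`.
#' @export
tidy.motif_mixture <- function(x, ...) {
  if (x$K == 0L)
    return(tibble::tibble(motif = integer(), position = integer(),
                          aa = character(), prob = numeric()))
  purrr::map_dfr(seq_len(x$K), function(k) {
    tibble::as_tibble(x$pwms[[k]], rownames = "position") |>
      dplyr::mutate(motif = k, position = match(.data$position, rownames(x$pwms[[k]]))) |>
      tidyr::pivot_longer(dplyr::all_of(AA_ALPHABET), names_to = "aa",
                          values_to = "prob")
  }) |>
    dplyr::select("motif", "position", "aa", "prob")
}

#' @rdname tidy.motif_mixture
#' @export
glance.motif_mixture <- function(x, ...) {
  n_par <- x$K * (MOTIF_LEN * 19L + ncol(x$offset_priors) - 1L) + x$K
  tibble::tibble(K = x$K, n = x$n, loglik = x$loglik,
                 aic = -2 * x$loglik + 2 * n_par,
                 iterations = length(x$trace), converged = x$converged)
}

#' Sequence logos of a fitted motif mixture
#'
#' @param object A `motif_mixture`.
#' @param ... Unused.
#' @return A patchworked ggplot (one logo per motif) or a single logo.
#' @export
autoplot.motif_mixture <- function(object, ...) {
  if (object$K == 0L) {
    df <- tibble::tibble(aa = factor(AA_ALPHABET, AA_ALPHABET),
                         freq = object$background)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$aa, .data$freq)) +
             ggplot2::geom_col() + ggplot2::theme_minimal() +
             ggplot2::labs(x = NULL, y = "background frequency"))
  }
  plots <- lapply(seq_len(object$K), function(k)
    plot_logo(object$pwms[[k]]) +
      ggplot2::ggtitle(sprintf("motif %d (%s)", k, pwm_consensus(object$pwms[[k]]))))
  patchwork::wrap_plots(plots, ncol = 1L)
}

#' Tidy a trained presentation model
#'
#' @param x An `el_model`.
#' @param ... Unused.
#' @return The per-epoch training history tibble.
#' @export
tidy.el_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric(), val_auc = numeric())
}

#' @rdname tidy.el_model
#' @export
glance.el_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    best_val_loss = if (is.null(h)) NA_real_ else min(h$val_loss, na.rm = TRUE),
    best_val_auc = if (is.null(h)) NA_real_ else max(h$val_auc, na.rm = TRUE))
}

#' Training curves of a presentation model
#'
#' @param object A trained `el_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @export
autoplot.el_model <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, color = .data$series)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", color = NULL)
}

#' Tidy a domain-adapted immunogenicity model
#'
#' @param x A `cdan_model`.
#' @param ... Unused.
#' @return Long tibble of per-epoch losses (`L_a`, `L_i`, `L_adv`).
#' @export
tidy.cdan_model <- function(x, ...) {
  h <- x$history %||% tibble::tibble(epoch = integer(), L_a = numeric(),
                                     L_i = numeric(), L_adv = numeric())
  tidyr::pivot_longer(h, -"epoch", names_to = "loss", values_to = "value")
}

#' @rdname tidy.cdan_model
#' @export
glance.cdan_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    omega = x$cdan$omega,
    target_supervised = x$cdan$target_supervised,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_L_a = if (is.null(h)) NA_real_ else h$L_a[nrow(h)],
    final_L_adv = if (is.null(h)) NA_real_ else h$L_adv[nrow(h)])
}

#' Adversarial training curves
#'
#' @param object A trained `cdan_model`.
#' @param ... Unused.
#' @return A ggplot of the three loss components by epoch.
#' @export
autoplot.cdan_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$epoch, .data$value, color = .data$loss)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL)
}

#' Heatmap of a bilinear attention map
#'
#' @param attention Result of [attention_export()].
#' @return A ggplot heatmap of attention over (peptide position,
#'   pseudosequence residue) with the per-residue marginal implicit in the
#'   column sums.
#' @export
plot_attention <- function(attention) {
  A <- attention$map
  df <- tibble::as_tibble(A, rownames = "peptide_pos") |>
    tidyr::pivot_longer(-"peptide_pos", names_to = "hla_residue",
                        values_to = "weight")
  df$peptide_pos <- factor(df$peptide_pos, rownames(A))
  df$hla_residue <- factor(df$hla_residue, colnames(A))
  ggplot2::ggplot(df, ggplot2::aes(.data$hla_residue, .data$peptide_pos,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6)) +
    ggplot2::labs(x = "pseudosequence residue", y = "peptide position")
}
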