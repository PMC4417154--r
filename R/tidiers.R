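# broom-style tidiers and ggplot2 autoplot methods for result types.

#' Tidy an enhancer model into a term/estimate table
#' @param x an `enhancer_model`.
#' @param ... unused.
#' @return tibble with `term`, `type` (intercept/motif/stage), `estimate`.
#' @export
tidy.enhancer_model <- function(x, ...) {
  terms <- names(x$coef)
  stages <- x$metadata$stages %||% character(0)
  tibble(term = terms,
         type = dplyr::case_when(terms == "(intercept)" ~ "intercept",
                                 terms %in% stages ~ "stage",
                                 TRUE ~ "motif"),
         estimate = unname(x$coef))
}

#' One-row summary of an enhancer model
#' @param x an `enhancer_model`.
#' @param ... unused.
#' @return tibble with `domain`, `n_train`, `lambda`, `n_terms`.
#' @export
glance.enhancer_model <- function(x, ...) {
  tibble(domain = x$domain, n_train = x$n_train, lambda = x$lambda,
         n_terms = length(x$coef))
}

#' Tidy a window-HMM fit
#' @param x a `stubb_fit`.
#' @param ... unused.
#' @return one-row tibble with `p_hat`, `loglik`, `loglik0`, `iters`,
#'   `n_flagged`.
#' @export
tidy.stubb_fit <- function(x, ...) {
  tibble(p_hat = x$p_hat, loglik = x$loglik, loglik0 = x$loglik0,
         iters = x$iters, n_flagged = x$n_flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a ROC curve
#' @param object a [roc_auc()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Plot a window track along the genome
#' @param object a `window_track`.
#' @param chrom optional chromosome to restrict to.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.window_track <- function(object, chrom = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(chrom)) df <- filter(df, .data$chrom == .env$chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "Window value") +
    ggplot2::theme_minimal()
}

#' Heatmap of a motif-vs-target correlation matrix
#' @param x the `matrix` element of [cross_correlation_matrix()].
#' @return a ggplot.
#' @export
plot_correlation_matrix <- function(x) {
  df <- as_tibble(as.table(x), .name_repair = "minimal")
  names(df) <- c("motif", "target", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$motif,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano-style overview of TF-domain associations
#' @param x an association tibble (with `S` and `support`).
#' @param alpha significance threshold drawn as a line.
#' @return a ggplot.
#' @export
plot_associations <- function(x, alpha = 1e-7) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$domain, y = .data$S,
                                  colour = .data$support)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "Expression domain", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
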