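#' @export
autoplot.ref_screen <- function(object, ...) {
  stats <- dplyr::filter(object$stats, !is.na(.data$cv))
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$mean_log2tpm, y = .data$cv,
                                      colour = .data$excluded_reason == "none")) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$thresholds["max_cv"], linetype = 2) +
    ggplot2::geom_vline(xintercept = object$thresholds["min_mean"], linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
                                 labels = c(`TRUE` = "candidate", `FALSE` = "excluded"),
                                 name = NULL) +
    ggplot2::labs(x = "mean log2(TPM)", y = "CV of log2(TPM)",
                  title = "Candidate reference-gene screen")
}

#' @export
autoplot.ref_genorm <- function(object, ...) {
  rk <- dplyr::arrange(object$ranking, dplyr::desc(.data$rank))
  rk$gene_id <- factor(rk$gene_id, levels = rk$gene_id)
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$gene_id, y = .data$m_value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "geNorm M value (first round)",
                  title = "geNorm expression stability")
}

#' @export
autoplot.ref_ctfit <- function(object, ...) {
  df <- stats::model.frame(object$lm_fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2tpm, y = .data$ct)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#b2182b") +
    ggplot2::labs(x = "log2(TPM)", y = "Ct",
                  title = sprintf("Ct = %.4f log2(TPM) + %.2f  (R² = %.3f)",
                                  object$slope, object$intercept, object$r_squared))
}

#' Plot a comprehensive stability ranking
#'
#' Bar chart of the geometric-mean rank per gene, most stable first.
#'
#' @param ranking Tibble from [comprehensive_ranking()].
#' @return A ggplot object.
#' @export
plot_comprehensive_ranking <- function(ranking) {
  rk <- dplyr::arrange(ranking, dplyr::desc(.data$final_rank))
  rk$gene_id <- factor(rk$gene_id, levels = rk$gene_id)
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$gene_id, y = .data$geomean)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "geometric mean of method ranks",
                  title = "Comprehensive stability ranking")
}
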