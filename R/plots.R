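#' Plot the significant profiles of a fit
#'
#' Bar chart of gene counts per significant stage-state profile, filled by
#' profile class (oncogene/TSG family, two-transition, ...), the visual
#' analogue of the significant-profile table.
#'
#' @param object A `bsm_fit`.
#' @param q_cutoff Significance threshold; defaults to the fit's own.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsm_fit <- function(object, q_cutoff = NULL, ...) {
  q_cutoff <- q_cutoff %||% object$q_cutoff
  sel <- dplyr::filter(object$results, .data$q <= q_cutoff)
  if (nrow(sel) == 0) {
    stop("no significant genes at q <= ", q_cutoff, call. = FALSE)
  }
  counts <- dplyr::count(sel, .data$profile, .data$class, name = "genes")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$profile, -.data$genes),
                               y = .data$genes, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "stage-state profile", y = "genes",
                  fill = "profile class",
                  title = sprintf("Significant profiles (q <= %g)",
                                  q_cutoff)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot recovery across a simulation study
#'
#' One point per dataset (recovery of the positive genes in the method's
#' top N), split by stage count, with pooled per-group recovery overlaid.
#'
#' @param object A `bsm_simstudy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsm_simstudy <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  pooled <- recovery_summary(object)
  pooled <- dplyr::filter(pooled, .data$stages != "overall")
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$Z), y = .data$recovery,
                                    colour = .data$method)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = pooled,
                        ggplot2::aes(x = .data$stages, y = .data$recovery),
                        shape = 95, size = 10) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "progression stages", y = "top-N recovery",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot one gene's expression along the progression stages
#'
#' Per-sample expression by stage with the discretization cutoff and
#' uncertainty band overlaid -- the per-gene view of the binarization rule.
#'
#' @inheritParams uniformize
#' @inheritParams gene_profiles
#' @param gene Gene id to plot.
#' @param params [bsm_params()] used for the cutoff/band annotation.
#' @return A ggplot object.
#' @export
plot_gene <- function(data, design, gene, params = bsm_params()) {
  m <- as_expr_matrix(data)
  if (!gene %in% rownames(m)) stop("gene '", gene, "' not found",
                                   call. = FALSE)
  al <- align_design(colnames(m), design)
  h <- half_widths(m, params$u, params$sd_mode)
  h <- rep(h, length.out = nrow(m))[match(gene, rownames(m))]
  df <- tibble::tibble(
    stage = factor(al$levels[al$idx], levels = al$levels),
    value = m[gene, ]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = params$t - h, ymax = params$t + h,
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = params$t, linetype = 2) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(title = gene, y = "uniformized expression") +
    ggplot2::theme_minimal()
}
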