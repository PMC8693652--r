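#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' Tidy and summarise pipeline objects
#'
#' `tidy()` returns the per-unit table (genes, TFs, modules); `glance()` a
#' one-row summary.
#'
#' @param x A `de_result`, `mra_result` or `module_set`.
#' @param ... Unused.
#' @name tidiers
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_tested = sum(!is.na(x$p)),
         n_sig_padj05 = sum(x$padj < 0.05, na.rm = TRUE))
}

#' @rdname tidiers
#' @method tidy mra_result
#' @export
tidy.mra_result <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @method glance mra_result
#' @export
glance.mra_result <- function(x, ...) {
  tibble(n_tfs = nrow(x),
         n_activated = sum(x$call == "activated"),
         n_inhibited = sum(x$call == "inhibited"),
         n_core = if ("passes_core_filter" %in% names(x))
           sum(x$passes_core_filter) else NA_integer_)
}

#' @rdname tidiers
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$stability)) {
    out$stability <- unname(x$stability[out$module])
  }
  out
}

#' @rdname tidiers
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = length(x$sizes),
         min_size = if (length(x$sizes)) min(x$sizes) else NA_integer_,
         max_size = if (length(x$sizes)) max(x$sizes) else NA_integer_,
         median_size = if (length(x$sizes)) stats::median(x$sizes) else NA_real_,
         n_unassigned = sum(x$assignment$module == "unassigned"))
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param alpha,min_abs_lfc Thresholds drawn and used for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, alpha = 0.01, min_abs_lfc = 1, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$padj)) %>%
    mutate(status = case_when(
      .data$padj < alpha & .data$log2fc > min_abs_lfc ~ "up",
      .data$padj < alpha & .data$log2fc < -min_abs_lfc ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-min_abs_lfc, min_abs_lfc),
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::labs(x = "log2 fold change (disease vs control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param object A tibble from [module_trait_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_trait
#' @export
autoplot.module_trait <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$contrast, .data$module,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Cell embedding coloured by cluster or class
#'
#' @param cell_table The `cell_table` of a `scregnet_result`.
#' @param colour Column to colour by (default `class_label`).
#' @return A ggplot.
#' @export
plot_cells <- function(cell_table, colour = "class_label") {
  ggplot2::ggplot(cell_table,
                  ggplot2::aes(.data$pc1, .data$pc2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = colour) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
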