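#' Plot a Young's modulus distribution
#'
#' Histogram of fitted moduli with the fitted Gaussian overlaid; the
#' dashed line marks the modal modulus.
#'
#' @param object A `modulus_distribution` from [modal_modulus()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.modulus_distribution <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(
      width = h$upper - h$lower, fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_vline(
      xintercept = object$mode_kPa, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Young's modulus (kPa)", y = "curves",
      title = sprintf("Modal modulus %.0f +/- %.0f kPa",
                      object$mode_kPa, object$sigma_kPa)
    )
  if (object$method == "gaussian" && is.finite(object$sigma_kPa) &&
      object$sigma_kPa > 0) {
    amp <- max(h$count)
    grid <- tibble(
      x = seq(min(h$lower), max(h$upper), length.out = 200)
    )
    grid$y <- amp * exp(-(grid$x - object$mode_kPa)^2 /
                          (2 * object$sigma_kPa^2))
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick"
    )
  }
  p
}

#' Plot a contour-length distribution
#'
#' @param object A `contour_length_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contour_length_distribution <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(
      width = h$upper - h$lower, fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_vline(xintercept = object$mean_nm, linetype = "dashed") +
    ggplot2::labs(
      x = "contour length (nm)", y = "events",
      title = sprintf("Mean contour length %.1f +/- %.1f nm",
                      object$mean_nm, object$sd_nm)
    )
}

#' Correlation-circle plot of an sPLS model
#'
#' Variables plotted at their correlations with the first two latent
#' components; the reference circle (default radius 0.5) separates
#' well-represented variables from poorly represented ones.
#'
#' @param object An `spls_model`.
#' @param radius Reference radius (default 0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spls_model <- function(object, radius = 0.5, ...) {
  cc <- correlation_circle(object, radius = radius)
  cc_genes <- cc[cc$block == "gene" &
                   cc$variable %in% spls_selected(object, block = "x"), ]
  cc_pheno <- cc[cc$block == "phenotype", ]
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = dplyr::mutate(circ, x = cos(.data$theta), y = sin(.data$theta)),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "grey60"
    ) +
    ggplot2::geom_path(
      data = dplyr::mutate(circ, x = radius * cos(.data$theta),
                           y = radius * sin(.data$theta)),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey60", linetype = "dotted"
    ) +
    ggplot2::geom_point(
      data = cc_genes, ggplot2::aes(x = .data$r1, y = .data$r2),
      colour = "steelblue", size = 1
    ) +
    ggplot2::geom_text(
      data = cc_pheno,
      ggplot2::aes(x = .data$r1, y = .data$r2, label = .data$variable),
      colour = "firebrick", size = 3
    ) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "correlation with component 1",
                  y = "correlation with component 2")
}

#' Clustered heat-map of a similarity map
#'
#' Tile plot of phenotype-gene similarities with rows and columns in
#' dendrogram order; red marks positive and blue negative association.
#'
#' @param object A `similarity_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_map <- function(object, ...) {
  long <- tidy(object)
  long$phenotype <- factor(
    long$phenotype,
    levels = rownames(object$matrix)[object$row_tree$order]
  )
  long$gene <- factor(
    long$gene,
    levels = colnames(object$matrix)[object$col_tree$order]
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$gene, y = .data$phenotype,
                 fill = .data$similarity)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "royalblue", mid = "white", high = "firebrick", midpoint = 0
    ) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.ticks.x = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = "genes (clustered)", y = NULL, fill = "similarity")
}
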