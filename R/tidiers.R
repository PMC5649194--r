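#' Tidy an sPLS model
#'
#' One row per variable and component with its loading; zero loadings
#' (variables not selected on a component) are kept so selection can be
#' audited.
#'
#' @param x An `spls_model`.
#' @param ... Unused.
#' @return Tibble: `variable`, `block`, `component`, `loading`,
#'   `selected`.
#' @export
tidy.spls_model <- function(x, ...) {
  one <- function(L, block) {
    as_tibble(L, rownames = "variable") |>
      tidyr::pivot_longer(
        -"variable", names_to = "component", values_to = "loading",
        names_transform = function(nm) as.integer(sub("^comp", "", nm))
      ) |>
      dplyr::mutate(block = block, selected = .data$loading != 0)
  }
  dplyr::bind_rows(
    one(x$loadings_x, "gene"),
    one(x$loadings_y, "phenotype")
  )[, c("variable", "block", "component", "loading", "selected")]
}

#' Summarize an sPLS model fit
#'
#' @param x An `spls_model`.
#' @param ... Unused.
#' @return One-row tibble: `ncomp`, `n_genes`, `n_phenotypes`,
#'   `n_selected_genes`, `iterations` (total), `converged`.
#' @export
glance.spls_model <- function(x, ...) {
  tibble(
    ncomp = x$ncomp,
    n_genes = nrow(x$loadings_x),
    n_phenotypes = nrow(x$loadings_y),
    n_selected_genes = length(spls_selected(x, block = "x")),
    iterations = sum(x$iterations),
    converged = all(x$converged)
  )
}

#' Tidy a modulus distribution
#'
#' @param x A `modulus_distribution` from [modal_modulus()].
#' @param ... Unused.
#' @return Histogram tibble (`mid`, `lower`, `upper`, `count`).
#' @export
tidy.modulus_distribution <- function(x, ...) x$histogram

#' @rdname tidy.modulus_distribution
#' @export
glance.modulus_distribution <- function(x, ...) {
  tibble(
    mode_kPa = x$mode_kPa, sigma_kPa = x$sigma_kPa,
    n_fits = x$n_fits, method = x$method
  )
}

#' Tidy a contour-length distribution
#'
#' @param x A `contour_length_distribution`.
#' @param ... Unused.
#' @return Histogram tibble (`mid`, `lower`, `upper`, `count`).
#' @export
tidy.contour_length_distribution <- function(x, ...) x$histogram

#' @rdname tidy.contour_length_distribution
#' @export
glance.contour_length_distribution <- function(x, ...) {
  tibble(mean_nm = x$mean_nm, sd_nm = x$sd_nm, n_fits = x$n_fits)
}

#' Tidy a similarity map
#'
#' @param x A `similarity_map`.
#' @param ... Unused.
#' @return Long tibble: `phenotype`, `gene`, `similarity`,
#'   `phenotype_group`, `gene_group`.
#' @export
tidy.similarity_map <- function(x, ...) {
  as_tibble(x$matrix, rownames = "phenotype") |>
    tidyr::pivot_longer(
      -"phenotype", names_to = "gene", values_to = "similarity"
    ) |>
    dplyr::mutate(
      phenotype_group = unname(x$row_groups[.data$phenotype]),
      gene_group = unname(x$col_groups[.data$gene])
    )
}
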