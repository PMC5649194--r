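#' Preprocess probe-level microarray intensities
#'
#' Full probe-to-gene preprocessing chain for one-colour arrays:
#' \enumerate{
#'   \item log2 transform of raw intensities;
#'   \item within-array centring on the weighted global median (spots
#'     with weight 0 are excluded from the median);
#'   \item imputation of weight-0 spots by the per-array median of the
#'     retained spots (quantile normalization needs complete columns);
#'   \item quantile normalization across arrays, by default within each
#'     strain group (`scope = "per_strain"`), optionally across all
#'     arrays;
#'   \item per-gene summary as the median of replicate probes, using
#'     good (weight-1) spots only.
#' }
#'
#' @param raw Probes x arrays matrix of raw intensities (> 0 where the
#'   weight is 1); rownames are probe ids.
#' @param weights Same-shape 0/1 spot-quality matrix.
#' @param probe_map Tibble with columns `probe_id`, `gene` mapping every
#'   probe (row of `raw`) to exactly one gene.
#' @param array_groups Character vector (one entry per column of `raw`)
#'   giving each array's strain; required for `scope = "per_strain"`.
#' @param scope `"per_strain"` (default) or `"all_arrays"` quantile
#'   normalization scope.
#' @return Genes x arrays matrix of normalized log2 expression values.
#' @export
preprocess_expression <- function(raw, weights, probe_map,
                                  array_groups = NULL,
                                  scope = c("per_strain", "all_arrays")) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(raw), all(dim(raw) == dim(weights)))
  if (!all(weights %in% c(0, 1))) abort("`weights` must be 0/1.")
  if (any(colSums(weights) == 0)) {
    abort("An array has all-zero spot weights; cannot normalize it.")
  }
  if (any(raw[weights == 1] <= 0)) {
    abort("Raw intensities must be > 0 where the spot weight is 1.")
  }
  lg <- log2(ifelse(weights == 1, raw, NA))
  # within-array weighted global median
  med <- apply(lg, 2, median, na.rm = TRUE)
  lg <- sweep(lg, 2, med)
  # impute excluded spots with the per-array median of retained spots (0)
  for (j in seq_len(ncol(lg))) {
    lg[is.na(lg[, j]), j] <- median(lg[, j], na.rm = TRUE)
  }
  if (scope == "per_strain") {
    if (is.null(array_groups)) {
      abort("`array_groups` is required for per-strain normalization.")
    }
    for (g in unique(array_groups)) {
      idx <- which(array_groups == g)
      lg[, idx] <- quantile_normalize(lg[, idx, drop = FALSE])
    }
  } else {
    lg <- quantile_normalize(lg)
  }
  # per-gene median over replicate probes
  probes <- rownames(raw) %||% as.character(seq_len(nrow(raw)))
  gene <- probe_map$gene[match(probes, probe_map$probe_id)]
  if (anyNA(gene)) abort("Every probe must map to a gene in `probe_map`.")
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, length(genes), ncol(lg),
                dimnames = list(genes, colnames(lg)))
  # gene summaries use only good (weight-1) spots; imputed values exist
  # solely to complete the columns for quantile normalization
  for (g in genes) {
    rows <- which(gene == g)
    for (j in seq_len(ncol(lg))) {
      good <- rows[weights[rows, j] == 1]
      out[g, j] <- if (length(good) > 0) {
        median(lg[good, j])
      } else {
        median(lg[rows, j])
      }
    }
  }
  out
}

#' Quantile normalization across arrays
#'
#' Forces every column (array) to share the same empirical distribution:
#' each column's sorted values are replaced by the mean of the
#' column-sorted input, with tied ranks averaged. Delegates to the
#' standard limma implementation.
#'
#' @param m Numeric matrix with no missing values.
#' @return Matrix of the same shape.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) == 1) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-gene two-sample t-test whose residual variance is shrunk toward a
#' prior: the posterior variance is
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' and the moderated statistic
#' \eqn{t_g = \bar x_A - \bar x_B \,/\, (\tilde s_g \sqrt{1/n_A + 1/n_B})}
#' is referred to a t distribution on \eqn{d_0 + d_g} degrees of freedom.
#' When not supplied, the prior degrees of freedom `d0` and prior
#' variance `s0sq` are estimated from the data by the method of moments
#' on the log sample variances: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, `d0` solves
#' \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)} and
#' \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}
#' (\eqn{\psi}, \eqn{\psi'}: digamma, trigamma). `d0 = 0` recovers the
#' ordinary pooled t-test.
#'
#' @param groupA,groupB Genes x arrays matrices with identical rownames;
#'   at least 2 arrays each.
#' @param d0 Prior degrees of freedom (`NULL` = estimate; may be `Inf`).
#' @param s0sq Prior variance (`NULL` = estimate).
#' @return Tibble: `gene`, `log2_fc` (mean A - mean B), `t_mod`, `p`
#'   (two-sided), `df_total`, `s2_post`, plus attributes `d0`, `s0sq`.
#' @export
moderated_ttest <- function(groupA, groupB, d0 = NULL, s0sq = NULL) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            nrow(groupA) == nrow(groupB))
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2 || nB < 2) abort("Need at least 2 arrays per group.")
  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  dg <- nA + nB - 2
  sg2 <- (rowSums((groupA - mA)^2) + rowSums((groupB - mB)^2)) / dg

  if (is.null(d0) || is.null(s0sq)) {
    pos <- sg2 > 0
    if (!any(pos)) abort("All genes have zero variance; cannot moderate.")
    e <- log(sg2[pos]) - digamma(dg / 2) + log(dg / 2)
    rhs <- var(e) - trigamma(dg / 2)
    if (is.null(d0)) {
      d0 <- if (is.na(rhs) || rhs <= 0) Inf else 2 * .trigamma_inverse(rhs)
    }
    if (is.null(s0sq)) {
      s0sq <- if (is.infinite(d0)) {
        exp(mean(e))
      } else {
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0sq, length(sg2))
  } else if (d0 == 0) {
    sg2
  } else {
    (d0 * s0sq + dg * sg2) / (d0 + dg)
  }
  df_total <- d0 + dg
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t_mod <- ifelse(se > 0, (mA - mB) / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(t_mod), df = df_total), 1)
  out <- tibble(
    gene = rownames(groupA) %||% as.character(seq_along(t_mod)),
    log2_fc = unname(mA - mB),
    t_mod = unname(t_mod),
    p = unname(p),
    df_total = unname(rep_len(df_total, length(t_mod))),
    s2_post = unname(s2_post)
  )
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  out
}

# solve trigamma(x) = y for x > 0
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  exp(uniroot(
    function(lx) trigamma(exp(lx)) - y,
    lower = log(1e-8), upper = log(1e8), tol = 1e-12
  )$root)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate:
#' on p-values sorted ascending, \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)}/j}
#' capped at 1, mapped back to input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("`pvals` must be in [0, 1] with no missing values.")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Filter differential-expression results on fold change and p-value
#'
#' @param results Tibble with columns `gene`, `log2_fc` and the p-value
#'   column named by `use`.
#' @param fc_threshold Minimum fold change (linear scale, default 2:
#'   |log2 FC| >= 1).
#' @param p_threshold Strict upper bound on the p-value (default 0.01).
#' @param use P-value column to threshold: `"p"` (default) or `"q"`.
#' @return Character vector of genes passing both cuts.
#' @export
de_filter <- function(results, fc_threshold = 2, p_threshold = 0.01,
                      use = c("p", "q")) {
  use <- match.arg(use)
  if (nrow(results) == 0) return(character())
  keep <- abs(results$log2_fc) >= log2(fc_threshold) &
    results[[use]] < p_threshold
  results$gene[keep]
}

#' Intersection and Venn partition of gene sets
#'
#' @param sets Named list of at least two character vectors (gene sets).
#' @return List with `intersection` (genes in every set), `exclusive`
#'   (named list of genes unique to each set) and `venn_counts` (tibble
#'   of membership patterns and their sizes).
#' @export
common_set <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    abort("`sets` must be a list of at least 2 gene sets.")
  }
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(m) paste(as.integer(m), collapse = ""))
  venn_counts <- tibble(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$pattern))
  inter <- universe[rowSums(membership) == length(sets)]
  exclusive <- lapply(seq_along(sets), function(k) {
    universe[membership[, k] & rowSums(membership) == 1]
  })
  names(exclusive) <- names(sets)
  list(
    intersection = sort(inter),
    exclusive = lapply(exclusive, sort),
    venn_counts = venn_counts
  )
}

#' Hypergeometric (upper-tail) gene-category enrichment
#'
#' Probability of observing at least `k` category members in a cluster of
#' `n` genes drawn from a universe of `N` genes of which `f` belong to
#' the category: \eqn{p = P(X \ge k)}, \eqn{X \sim}
#' Hypergeometric(N, f, n).
#'
#' @param cluster Character vector of cluster genes.
#' @param category Character vector of category (annotation) genes.
#' @param universe_size Number of genes in the annotation universe
#'   (>= both set sizes).
#' @param category_id Optional label carried into the result.
#' @return One-row tibble: `category`, `k`, `n`, `f`, `N`, `p`.
#' @export
hypergeometric_enrichment <- function(cluster, category, universe_size,
                                      category_id = NA_character_) {
  cluster <- unique(cluster)
  category <- unique(category)
  n <- length(cluster)
  f <- length(category)
  if (universe_size < n || universe_size < f) {
    abort("`universe_size` must be at least as large as each gene set.")
  }
  k <- length(intersect(cluster, category))
  tibble(
    category = category_id,
    k = k, n = n, f = f, N = universe_size,
    p = phyper(k - 1, f, universe_size - f, n, lower.tail = FALSE)
  )
}
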