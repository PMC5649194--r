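#' Centre and unit-scale the columns of a block
#'
#' Standardizes each column to mean 0 and unit scale, dividing by the
#' population (1/n) standard deviation so that a column's squared norm
#' equals the number of rows. Constant columns cannot be scaled; they
#' are dropped with a warning and recorded in the `"dropped"` attribute.
#'
#' @param block Numeric matrix or data frame, >= 2 rows.
#' @return Standardized matrix (attribute `dropped`: names of removed
#'   constant columns).
#' @export
center_unit_scale <- function(block) {
  m <- as.matrix(block)
  if (nrow(m) < 2) abort("Need at least 2 rows to standardize.")
  ctr <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2, ctr)^2))
  dropped <- colnames(m)[sds == 0] %||% character()
  if (any(sds == 0)) {
    warn(paste(
      "Dropping constant column(s):",
      paste(colnames(m)[sds == 0], collapse = ", ")
    ))
    m <- m[, sds > 0, drop = FALSE]
    ctr <- ctr[sds > 0]
    sds <- sds[sds > 0]
  }
  out <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  attr(out, "dropped") <- dropped
  out
}

# keep the `keep` largest-|entry| coefficients, soft-thresholding the rest
.soft_select <- function(v, keep) {
  if (keep >= length(v)) return(v)
  lambda <- sort(abs(v), decreasing = TRUE)[keep + 1]
  sign(v) * pmax(abs(v) - lambda, 0)
}

#' Sparse partial least squares (regression mode)
#'
#' Two-block sPLS relating a gene-expression block `X` to a phenotype
#' block `Y`. Each component maximizes the covariance between block
#' scores under cardinality constraints on the loadings: with
#' \eqn{M = X^\top Y}, the loading pair is found by alternating
#' \eqn{u \leftarrow \mathrm{soft}(M v)} (keep the `keepX` largest
#' entries), \eqn{v \leftarrow \mathrm{soft}(M^\top u)} (keep `keepY`),
#' normalizing each to unit length, until the change is below `tol`.
#' Blocks are then deflated in regression mode
#' (\eqn{X \leftarrow X - t p^\top}, \eqn{Y \leftarrow Y - t c^\top}
#' with `t = X u` and `p`, `c` the regressions of X, Y on t). With
#' sparsity disabled the first component equals the leading singular
#' pair of \eqn{X^\top Y}. Loadings are oriented so the
#' largest-magnitude entry of each `u` is positive; the fit contains no
#' randomness, so identical input gives identical selections.
#'
#' @param X Samples x genes matrix, standardized ([center_unit_scale()]).
#' @param Y Samples x phenotypes matrix, standardized; same rows as `X`.
#' @param ncomp Number of components (default 2).
#' @param keepX Genes retained per component (scalar or vector of length
#'   `ncomp`; default 50).
#' @param keepY Phenotypes retained per component (default: all).
#' @param tol Convergence tolerance on the loadings (default 1e-9).
#' @param max_iter Maximum alternations per component (default 500).
#' @return An `spls_model`: loading matrices `loadings_x` (genes x
#'   ncomp), `loadings_y`, score matrix `scores` (samples x ncomp),
#'   `keepX`, `keepY`, per-component `iterations` and `converged`, and
#'   the standardized input blocks (`X0`, `Y0`) used for correlation
#'   displays.
#' @export
spls_fit <- function(X, Y, ncomp = 2, keepX = 50, keepY = ncol(Y),
                     tol = 1e-9, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("`X` and `Y` must have the same rows.")
  if (ncomp < 1 || ncomp > min(dim(X), nrow(X) - 1)) {
    abort("`ncomp` out of range for these blocks.")
  }
  keepX <- rep_len(keepX, ncomp)
  keepY <- rep_len(keepY, ncomp)
  if (any(keepX < 1) || any(keepX > ncol(X)) ||
      any(keepY < 1) || any(keepY > ncol(Y))) {
    abort("`keepX`/`keepY` must lie in [1, #variables].")
  }
  p <- ncol(X); q <- ncol(Y)
  gene_names <- colnames(X) %||% paste0("gene", seq_len(p))
  pheno_names <- colnames(Y) %||% paste0("pheno", seq_len(q))
  X0 <- X; Y0 <- Y
  comp_names <- paste0("comp", seq_len(ncomp))
  U <- matrix(0, p, ncomp, dimnames = list(gene_names, comp_names))
  V <- matrix(0, q, ncomp, dimnames = list(pheno_names, comp_names))
  Tm <- matrix(0, nrow(X), ncomp, dimnames = list(rownames(X), comp_names))
  iters <- integer(ncomp)
  conv <- logical(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(X, Y)
    v <- svd(M, nu = 0, nv = 1)$v[, 1]
    u <- rep(0, p)
    for (it in seq_len(max_iter)) {
      u_new <- .soft_select(drop(M %*% v), keepX[h])
      u_new <- u_new / sqrt(sum(u_new^2))
      v_new <- .soft_select(drop(crossprod(M, u_new)), keepY[h])
      v_new <- v_new / sqrt(sum(v_new^2))
      delta <- max(abs(u_new - u), abs(v_new - v))
      u <- u_new; v <- v_new
      if (delta < tol) break
    }
    iters[h] <- it
    conv[h] <- it < max_iter || delta < tol
    # orient: largest |u| entry positive
    flip <- sign(u[which.max(abs(u))])
    u <- flip * u; v <- flip * v
    t_h <- drop(X %*% u)
    tt <- sum(t_h^2)
    p_load <- drop(crossprod(X, t_h)) / tt
    c_load <- drop(crossprod(Y, t_h)) / tt
    X <- X - tcrossprod(t_h, p_load)
    Y <- Y - tcrossprod(t_h, c_load)
    U[, h] <- u; V[, h] <- v; Tm[, h] <- t_h
  }

  structure(
    list(
      loadings_x = U, loadings_y = V, scores = Tm,
      ncomp = ncomp, keepX = keepX, keepY = keepY,
      iterations = iters, converged = conv,
      X0 = X0, Y0 = Y0
    ),
    class = "spls_model"
  )
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf(
    "<spls_model> %d component(s), %d genes x %d phenotypes, keepX = %s\n",
    x$ncomp, nrow(x$loadings_x), nrow(x$loadings_y),
    paste(x$keepX, collapse = "/")
  ))
  invisible(x)
}

#' Selected variables of an sPLS model
#'
#' @param model An `spls_model`.
#' @param comp Component(s) to inspect (default: all).
#' @param block `"x"` or `"y"`.
#' @return Character vector of variables with a nonzero loading on any
#'   of the requested components.
#' @export
spls_selected <- function(model, comp = seq_len(model$ncomp),
                          block = c("x", "y")) {
  block <- match.arg(block)
  L <- if (block == "x") model$loadings_x else model$loadings_y
  rownames(L)[rowSums(abs(L[, comp, drop = FALSE])) > 0]
}

#' Correlation-circle coordinates
#'
#' Correlation of every (standardized) gene and phenotype variable with
#' the first two latent scores. Variables with radius
#' \eqn{\sqrt{r_1^2 + r_2^2}} above `radius` are well represented by the
#' two components and can be read as positively/negatively correlated
#' with each other by their angular proximity.
#'
#' @param model An `spls_model` with `ncomp >= 2`.
#' @param comps Pair of components to project on (default `c(1, 2)`).
#' @param radius Reference radius for the `outside` flag (default 0.5).
#' @return Tibble: `variable`, `block` ("gene"/"phenotype"), `r1`, `r2`,
#'   `radius`, `outside`.
#' @export
correlation_circle <- function(model, comps = c(1, 2), radius = 0.5) {
  if (model$ncomp < 2) abort("Need at least 2 components.")
  t1 <- model$scores[, comps[1]]
  t2 <- model$scores[, comps[2]]
  corr_block <- function(B, label) {
    keep <- apply(B, 2, sd) > 0
    B <- B[, keep, drop = FALSE]
    tibble(
      variable = colnames(B),
      block = label,
      r1 = drop(cor(B, t1)),
      r2 = drop(cor(B, t2))
    )
  }
  out <- dplyr::bind_rows(
    corr_block(model$X0, "gene"),
    corr_block(model$Y0, "phenotype")
  )
  out$radius <- sqrt(out$r1^2 + out$r2^2)
  out$outside <- out$radius > radius
  out
}

#' Clustered similarity map between phenotypes and genes
#'
#' The clustered-image-map construction: each variable is represented by
#' its correlations with the latent scores, and the similarity between
#' phenotype j and gene i is the sum over components of the products of
#' their score correlations,
#' \eqn{\mathrm{sim}_{ji} = \sum_h r_h(\mathrm{pheno}_j)
#' r_h(\mathrm{gene}_i)} — an approximation of the cross-block
#' correlation restricted to the modelled components. Rows (phenotypes)
#' and columns (genes, restricted to variables selected by the model)
#' are ordered by complete-linkage hierarchical clustering of Euclidean
#' distances on the similarity profiles and cut into `k_pheno` and
#' `k_gene` groups.
#'
#' @param model An `spls_model`.
#' @param k_pheno Number of phenotype groups (default 4).
#' @param k_gene Number of gene groups (default 6).
#' @return A `similarity_map`: `matrix` (phenotypes x selected genes),
#'   `row_groups`, `col_groups` (named integer partitions),
#'   `row_tree`, `col_tree` (hclust objects).
#' @export
similarity_map <- function(model, k_pheno = 4, k_gene = 6) {
  # variable-score correlations for every retained component
  Rx <- sapply(seq_len(model$ncomp), function(h) {
    drop(cor(model$X0, model$scores[, h]))
  })
  Ry <- sapply(seq_len(model$ncomp), function(h) {
    drop(cor(model$Y0, model$scores[, h]))
  })
  Rx <- matrix(Rx, ncol = model$ncomp,
               dimnames = list(colnames(model$X0), NULL))
  Ry <- matrix(Ry, ncol = model$ncomp,
               dimnames = list(colnames(model$Y0), NULL))
  sel <- spls_selected(model, block = "x")
  Rx <- Rx[sel, , drop = FALSE]
  sim <- tcrossprod(Ry, Rx) # phenotypes x genes
  if (k_pheno > nrow(sim)) abort("`k_pheno` exceeds the number of phenotypes.")
  if (k_gene > ncol(sim)) abort("`k_gene` exceeds the number of genes.")
  row_tree <- hclust(dist(sim), method = "complete")
  col_tree <- hclust(dist(t(sim)), method = "complete")
  structure(
    list(
      matrix = sim,
      row_groups = cutree(row_tree, k = k_pheno),
      col_groups = cutree(col_tree, k = k_gene),
      row_tree = row_tree,
      col_tree = col_tree
    ),
    class = "similarity_map"
  )
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf(
    "<similarity_map> %d phenotypes x %d genes; %d row / %d column groups\n",
    nrow(x$matrix), ncol(x$matrix),
    length(unique(x$row_groups)), length(unique(x$col_groups))
  ))
  invisible(x)
}
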