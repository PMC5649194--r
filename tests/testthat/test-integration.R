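test_that("center_unit_scale standardizes and drops constant columns", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  expect_warning(out <- center_unit_scale(m), "constant")
  expect_equal(colnames(out), c("a", "c"))
  expect_equal(attr(out, "dropped"), "b")
  expect_equal(unname(out[, "a"]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(unname(colMeans(out)), c(0, 0))
  # population (1/n) scaling: squared column norm equals the row count
  expect_equal(unname(colSums(out^2)), c(3, 3))
  # idempotence
  expect_equal(unclass(center_unit_scale(out))[, ], out[, ],
               tolerance = 1e-12)
  expect_error(center_unit_scale(m[1, , drop = FALSE]), "2 rows")
})

test_that("dense sPLS component 1 equals the leading singular pair", {
  fx <- make_spls_fixture()
  X <- center_unit_scale(fx$X)
  Y <- center_unit_scale(fx$Y)
  m <- spls_fit(X, Y, ncomp = 2, keepX = ncol(X), keepY = ncol(Y))
  sv <- svd(crossprod(X, Y))
  expect_lt(max(abs(abs(m$loadings_x[, 1]) - abs(sv$u[, 1]))), 1e-8)
  expect_lt(max(abs(abs(m$loadings_y[, 1]) - abs(sv$v[, 1]))), 1e-8)
  cov1 <- abs(drop(
    crossprod(X %*% m$loadings_x[, 1], Y %*% m$loadings_y[, 1])
  ))
  expect_lt(abs(cov1 - sv$d[1]), 1e-8)
})

test_that("sPLS scores are orthogonal and loadings unit-norm", {
  fx <- make_spls_fixture()
  m <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                ncomp = 2, keepX = 20)
  G <- crossprod(m$scores)
  expect_lt(abs(G[1, 2]) / sqrt(G[1, 1] * G[2, 2]), 1e-8)
  expect_equal(unname(colSums(m$loadings_x^2)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(colSums(m$loadings_y^2)), c(1, 1), tolerance = 1e-9)
  # cardinality constraint honoured
  expect_lte(sum(m$loadings_x[, 1] != 0), 20)
  # sign convention: largest |u| entry positive; rerun identical
  expect_gt(m$loadings_x[which.max(abs(m$loadings_x[, 1])), 1], 0)
  m2 <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                 ncomp = 2, keepX = 20)
  expect_identical(m$loadings_x, m2$loadings_x)
})

test_that("sPLS recovers planted genes tied to phenotypes", {
  fx <- make_spls_fixture(snr = 3)
  m <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                ncomp = 2, keepX = 20)
  sel <- rownames(m$loadings_x)[m$loadings_x[, 1] != 0]
  expect_gte(sum(sel %in% fx$planted), 18)
})

test_that("dense fit agrees with the reference mixOmics implementation", {
  fx <- make_spls_fixture()
  X <- center_unit_scale(fx$X)
  Y <- center_unit_scale(fx$Y)
  m <- spls_fit(X, Y, ncomp = 2, keepX = ncol(X), keepY = ncol(Y))
  ref <- mixOmics::spls(X, Y, ncomp = 2, mode = "regression",
                        keepX = rep(ncol(X), 2), keepY = rep(ncol(Y), 2),
                        scale = FALSE)
  for (h in 1:2) {
    expect_gt(abs(cor(m$scores[, h], ref$variates$X[, h])), 1 - 1e-6)
  }
})

test_that("correlation circle flags represented variables", {
  fx <- make_spls_fixture(n = 60, snr = 5, n_planted2 = 15, n_linked2 = 2,
                          seed = 77)
  m <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                ncomp = 2, keepX = 20)
  cc <- correlation_circle(m)
  expect_true(all(cc$radius <= 1 + 1e-8)) # Cauchy-Schwarz bound
  ph <- cc[cc$block == "phenotype", ]
  # linked phenotypes sit outside the 0.5 circle, zero-SNR decoys inside
  linked <- paste0("ph", seq_len(fx$n_linked + fx$n_linked2))
  decoys <- setdiff(ph$variable, linked)
  expect_true(all(ph$outside[match(linked, ph$variable)]))
  expect_true(all(!ph$outside[match(decoys, ph$variable)]))
  # the planted genes are strongly represented on component 1
  cg <- cc[cc$block == "gene", ]
  top <- cg[which.max(abs(cg$r1)), ]
  expect_gt(abs(top$r1), 0.8)
  expect_lt(abs(top$r2), 0.4)
})

test_that("similarity map stays on the correlation scale and clusters", {
  fx <- make_block_fixture()
  m <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                ncomp = 6, keepX = ncol(fx$X), keepY = ncol(fx$Y))
  sm <- similarity_map(m, k_pheno = 4, k_gene = 6)
  expect_true(all(sm$matrix >= -1 - 1e-6 & sm$matrix <= 1 + 1e-6))
  expect_equal(length(unique(sm$col_groups)), 6)
  expect_equal(length(unique(sm$row_groups)), 4)
  ari <- mclust::adjustedRandIndex(sm$col_groups, fx$block)
  expect_gte(ari, 0.9)
  expect_error(similarity_map(m, k_pheno = 50), "exceeds")
})

test_that("duplicated gene columns always co-cluster", {
  fx <- make_block_fixture()
  X <- fx$X
  X[, 2] <- X[, 1] # exact duplicate
  m <- spls_fit(center_unit_scale(X), center_unit_scale(fx$Y),
                ncomp = 3, keepX = ncol(X), keepY = ncol(fx$Y))
  sm <- similarity_map(m, k_pheno = 3, k_gene = 6)
  expect_equal(sm$matrix[, colnames(X)[1]], sm$matrix[, colnames(X)[2]])
  expect_equal(
    unname(sm$col_groups[colnames(X)[1]]),
    unname(sm$col_groups[colnames(X)[2]])
  )
})

test_that("tidy and glance expose the model tables", {
  fx <- make_spls_fixture()
  m <- spls_fit(center_unit_scale(fx$X), center_unit_scale(fx$Y),
                ncomp = 2, keepX = 20)
  td <- tidy(m)
  expect_true(all(c("variable", "block", "component", "loading",
                    "selected") %in% names(td)))
  expect_equal(sum(td$block == "gene"), 2 * 200)
  gl <- glance(m)
  expect_equal(gl$ncomp, 2)
  expect_lte(gl$n_selected_genes, 40)
  sm <- similarity_map(
    spls_fit(center_unit_scale(make_block_fixture()$X),
             center_unit_scale(make_block_fixture()$Y),
             ncomp = 4, keepX = 60, keepY = 8),
    k_pheno = 4, k_gene = 6
  )
  expect_s3_class(autoplot(sm), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
})
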