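test_that("quantile normalization matches the hand-computed oracle", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # single column unchanged; identical columns unchanged
  one <- cbind(x = c(3, 1, 2))
  expect_equal(quantile_normalize(one), one)
  same <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(quantile_normalize(same), same)
  # invariant: all columns share the same sorted values
  withr::with_seed(3, {
    r <- matrix(rexp(60), 20, 3)
    q <- quantile_normalize(r)
    expect_equal(sort(q[, 1]), sort(q[, 2]))
    expect_equal(sort(q[, 2]), sort(q[, 3]))
  })
})

test_that("preprocessing collapses correctly for a single array", {
  raw <- matrix(c(4, 16, 64), ncol = 1,
                dimnames = list(c("p1", "p2", "p3"), "A_1"))
  w <- matrix(1, 3, 1, dimnames = dimnames(raw))
  pm <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       gene = c("g1", "g2", "g3"))
  out <- preprocess_expression(raw, w, pm, array_groups = "A")
  expect_equal(unname(out[, 1]), log2(c(4, 16, 64)) - 4) # median log2 = 4
})

test_that("zero-weight spots are excluded from medians and summaries", {
  # gene g1 has two spots; the corrupted one carries weight 0
  raw <- matrix(
    c(8, 8, 2^20, 8,
      8, 8, 8, 8),
    nrow = 4,
    dimnames = list(c("g1_a", "g2_a", "g1_b", "g2_b"), c("A_1", "A_2"))
  )
  w <- matrix(1, 4, 2, dimnames = dimnames(raw))
  w["g1_b", "A_1"] <- 0
  pm <- tibble::tibble(
    probe_id = c("g1_a", "g2_a", "g1_b", "g2_b"),
    gene = c("g1", "g2", "g1", "g2")
  )
  out <- preprocess_expression(raw, w, pm, array_groups = c("A", "A"))
  # the 2^20 outlier must not leak into g1's summary on array 1
  expect_equal(out["g1", "A_1"], out["g2", "A_1"])
  expect_error(
    preprocess_expression(raw, w * 0, pm, array_groups = c("A", "A")),
    "all-zero"
  )
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t-test", {
  withr::with_seed(10, {
    A <- matrix(rnorm(30, 5), 10, 3,
                dimnames = list(paste0("g", 1:10), NULL))
    B <- matrix(rnorm(30, 5), 10, 3, dimnames = dimnames(A))
    res <- moderated_ttest(A, B, d0 = 0, s0sq = 1)
    # textbook pooled two-sample t, computed independently
    for (g in 1:10) {
      sp2 <- (2 * var(A[g, ]) + 2 * var(B[g, ])) / 4
      t_ref <- (mean(A[g, ]) - mean(B[g, ])) / sqrt(sp2 * (2 / 3))
      expect_equal(res$t_mod[g], t_ref, tolerance = 1e-10)
      expect_equal(res$p[g], 2 * pt(-abs(t_ref), 4), tolerance = 1e-10)
    }
  })
})

test_that("moderated t degenerates sensibly at the extremes", {
  A <- matrix(rep(c(1, 2, 3), each = 3), 3, 3, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), NULL))
  res_same <- moderated_ttest(A, A, d0 = 4, s0sq = 0.1)
  expect_true(all(res_same$t_mod == 0))
  expect_true(all(res_same$p == 1))
  withr::with_seed(11, {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
    Y <- matrix(rnorm(60), 20, 3, dimnames = dimnames(X))
    res_inf <- moderated_ttest(X, Y, d0 = 1e9, s0sq = 0.5)
    # with an overwhelming prior, t ordering equals mean-difference ordering
    expect_equal(order(res_inf$t_mod), order(res_inf$log2_fc))
  })
})

test_that("prior moment estimates agree with limma's squeezeVar", {
  withr::with_seed(12, {
    ng <- 500
    # heteroscedastic truth: per-gene variances from an inverse-chisquare
    s2_true <- 0.04 * 8 / rchisq(ng, df = 8)
    A <- matrix(rnorm(ng * 3, 0, sqrt(s2_true)), ng, 3,
                dimnames = list(paste0("g", 1:ng), NULL))
    B <- matrix(rnorm(ng * 3, 0, sqrt(s2_true)), ng, 3,
                dimnames = dimnames(A))
    res <- moderated_ttest(A, B)
    sg2 <- (rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)) / 4
    sq <- limma::squeezeVar(sg2, df = 4)
    expect_equal(attr(res, "d0"), sq$df.prior, tolerance = 0.15)
    expect_equal(attr(res, "s0sq"), sq$var.prior, tolerance = 0.15)
    expect_equal(res$s2_post, unname(sq$var.post), tolerance = 0.05)
  })
})

test_that("BH adjustment matches hand and brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(13, {
    for (i in seq_len(200)) {
      p <- runif(sample(2:40, 1))
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  })
})

test_that("DE filter applies both the fold-change and p cuts", {
  tab <- tibble::tibble(
    gene = paste0("g", 1:5),
    log2_fc = c(2, 0.5, -1.5, 1.2, -0.2),
    p = c(0.001, 0.001, 0.005, 0.5, 0.0001)
  )
  expect_equal(de_filter(tab), c("g1", "g3"))
  expect_equal(
    sort(de_filter(tab, fc_threshold = 1)),
    sort(c("g1", "g2", "g3", "g5"))
  )
  expect_equal(de_filter(tab[0, ]), character())
})

test_that("common_set partitions gene sets correctly", {
  s <- list(a = c("x", "y", "z"), b = c("x", "y", "z"))
  cs <- common_set(s)
  expect_equal(cs$intersection, c("x", "y", "z"))
  expect_equal(lengths(cs$exclusive), c(a = 0L, b = 0L))
  disj <- common_set(list(a = "x", b = "y"))
  expect_equal(disj$intersection, character())
  expect_error(common_set(list(a = "x")), "at least 2")
})

test_that("hypergeometric enrichment equals the summation oracle", {
  universe <- sprintf("g%04d", 1:6000)
  cluster <- universe[1:23]
  category <- universe[c(1:5, 30:35)] # k = 5, f = 11
  res <- hypergeometric_enrichment(cluster, category, 6000)
  expect_equal(res$k, 5)
  expect_equal(res$p, hyper_brute(5, 23, 11, 6000), tolerance = 1e-12)
  # k = 0 and f = N certainties
  res0 <- hypergeometric_enrichment(universe[100:110], universe[1:20], 6000)
  expect_equal(res0$p, 1)
  resN <- hypergeometric_enrichment(universe[1:23], universe, 6000)
  expect_equal(resN$p, 1)
  expect_error(hypergeometric_enrichment(universe[1:30], universe[1:5], 10))
})

test_that("planted two-fold effects are recovered with few false calls", {
  cfg <- expr_sim_config(
    n_genes = 1500, strains = c("REF", "S1"), n_de_per_strain = 100,
    n_core = 40, seed = 23
  )
  sim <- gen_expression(cfg)
  expr <- preprocess_expression(sim$raw, sim$weights, sim$probe_map,
                                sim$array_groups)
  res <- moderated_ttest(
    expr[, sim$array_groups == "S1", drop = FALSE],
    expr[, sim$array_groups == "REF", drop = FALSE]
  )
  hits <- de_filter(res)
  planted <- sim$truth$de_sets[["S1"]]
  expect_gte(mean(planted %in% hits), 0.9)
  fp <- length(setdiff(hits, planted)) /
    (cfg$n_genes - length(planted))
  expect_lte(fp, 0.01)
})
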