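# shared fixture builders and independent oracles

# noise-free approach trace: baseline then conical-Hertz ramp
make_hertz_trace <- function(E_kPa = 300, contact_nm = 120, step = 1,
                             noise_sd = 0, tip = tip_geometry()) {
  sep <- seq(contact_nm + 130, contact_nm - 70, by = -step)
  delta <- pmax(contact_nm - sep, 0)
  tibble::tibble(
    separation_nm = sep,
    force_pN = hertz_force(delta, E_kPa, tip) +
      rnorm(length(sep), 0, noise_sd)
  )
}

# retract trace with planted polymer fingerprints (negative force dips)
make_retract_trace <- function(Lc = 96.9, stiffness = 0.5, model = "WLC",
                               rupture_force = 60, max_sep = 400,
                               step = 1, noise_sd = 0) {
  sep <- seq(0, max_sep, by = step)
  force <- rnorm(length(sep), 0, noise_sd)
  x_rupt <- if (model == "FJC") {
    fjc_extension(rupture_force, stiffness, Lc)
  } else {
    stats::uniroot(
      function(x) wlc_force(x, stiffness, Lc) - rupture_force,
      lower = 1e-9, upper = Lc * (1 - 1e-9)
    )$root
  }
  act <- sep > 0 & sep <= x_rupt
  fmodel <- if (model == "FJC") {
    fjc_force(sep[act], stiffness, Lc)
  } else {
    wlc_force(sep[act], stiffness, Lc)
  }
  force[act] <- force[act] - fmodel
  list(
    trace = tibble::tibble(separation_nm = sep, force_pN = force),
    rupture_x = x_rupt
  )
}

# brute-force BH step-up, independent of stats::p.adjust
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# brute-force upper-tail hypergeometric by explicit summation
hyper_brute <- function(k, n, f, N) {
  i <- k:min(n, f)
  sum(choose(f, i) * choose(N - f, n - i)) / choose(N, n)
}

# latent-factor two-block fixture: `n_planted` genes share a factor that
# drives the linked phenotypes; optionally a second, weaker factor block
# (`n_planted2` genes, `n_linked2` phenotypes) gives component 2 real
# signal to capture
make_spls_fixture <- function(n = 15, p = 200, n_planted = 20,
                              n_linked = 3, n_decoy = 6, snr = 3,
                              n_planted2 = 0, n_linked2 = 0,
                              seed = 42) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    f2 <- rnorm(n)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%03d", seq_len(p))))
    planted <- sprintf("g%03d", seq_len(n_planted))
    X[, planted] <- sqrt(0.7) * f + sqrt(0.3) * X[, planted]
    planted2 <- character()
    if (n_planted2 > 0) {
      planted2 <- sprintf("g%03d", n_planted + seq_len(n_planted2))
      X[, planted2] <- sqrt(0.7) * f2 + sqrt(0.3) * X[, planted2]
    }
    links <- c(
      lapply(seq_len(n_linked), function(i) planted),
      if (n_linked2 > 0) lapply(seq_len(n_linked2), function(i) planted2),
      lapply(seq_len(n_decoy), function(i) NULL)
    )
    names(links) <- paste0("ph", seq_along(links))
    lp <- gen_linked_phenotypes(t(X), links, snr = snr, seed = seed + 1)
    list(X = X, Y = lp$Y, planted = planted, planted2 = planted2,
         n_linked = n_linked, n_linked2 = n_linked2)
  })
}

# six co-expressed gene blocks driven by six factors, phenotypes mixing
# the factors with distinct signatures
make_block_fixture <- function(n = 45, genes_per_block = 10, seed = 11) {
  withr::with_seed(seed, {
    F6 <- matrix(rnorm(n * 6), n, 6)
    p <- 6 * genes_per_block
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
    block <- rep(seq_len(6), each = genes_per_block)
    for (i in seq_len(p)) {
      X[, i] <- sqrt(0.85) * F6[, block[i]] + sqrt(0.15) * X[, i]
    }
    W <- rbind(
      c(1, 0, 0, 0, 0, 0), c(-1, 1, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0),
      c(0, 0, 1, -1, 0, 0), c(0, 0, 1, 0, 0, 0), c(0, 0, 0, 1, 0, 0),
      c(0, 0, 0, 0, 1, 0), c(0, 0, 0, 0, -1, 1)
    )
    Y <- F6 %*% t(W) + matrix(rnorm(n * 8, 0, 1 / 3), n, 8)
    colnames(Y) <- paste0("ph", seq_len(8))
    list(X = X, Y = Y, block = block)
  })
}
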