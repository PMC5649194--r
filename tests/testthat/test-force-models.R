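test_that("thermal context derives kBT from temperature", {
  expect_equal(thermal_context(298)$kBT_pN_nm, 4.11, tolerance = 0.01 / 4.11)
  expect_error(thermal_context(-1), "positive")
})

test_that("Hertz force matches the closed-form cone model", {
  # direct arithmetic oracle: 2 tan(0.31)/(pi * 0.75) * E * delta^2
  pref <- 2 * tan(0.31) / (pi * (1 - 0.5^2))
  expect_equal(hertz_force(50, 483), pref * 0.483 * 2500, tolerance = 1e-12)
  expect_equal(hertz_force(50, 483), 330, tolerance = 0.01) # ~3.3e2 pN
  expect_identical(hertz_force(0, 123), 0)
  # quadratic scaling
  for (d in c(3, 17, 42)) {
    expect_equal(hertz_force(2 * d, 100) / hertz_force(d, 100), 4)
  }
  expect_error(hertz_force(-1, 100), "0")
  expect_error(hertz_force(10, -5))
})

test_that("WLC force is zero at rest, matches arithmetic, and diverges", {
  expect_equal(wlc_force(0, 0.4, 100), 0)
  # x = Lc/2: (kBT / lp) * (0.25 * 4 + 0.5 - 0.25) = (kBT/0.4) * 1.25
  kBT <- thermal_context()$kBT_pN_nm
  expect_equal(wlc_force(50, 0.4, 100), kBT / 0.4 * 1.25, tolerance = 1e-12)
  f1 <- wlc_force(0.999 * 100, 0.4, 100)
  f2 <- wlc_force(0.99 * 100, 0.4, 100)
  f3 <- wlc_force(50, 0.4, 100)
  expect_gt(f1, f2)
  expect_gt(f2, 10 * f3)
  expect_error(wlc_force(100, 0.4, 100), "Lc")
  expect_error(wlc_force(150, 0.4, 100), "Lc")
})

test_that("FJC extension has the Langevin form with correct limits", {
  kBT <- thermal_context()$kBT_pN_nm
  # F lk / kBT = 1: x = Lc (coth(1) - 1)
  expect_equal(
    fjc_extension(kBT / 0.3, 0.3, 100),
    100 * (1 / tanh(1) - 1),
    tolerance = 1e-12
  )
  expect_equal(fjc_extension(0, 0.3, 100), 0)
  expect_lt(fjc_extension(1e-6, 0.3, 100), 1e-4) # F -> 0 => x -> 0
  expect_gte(fjc_extension(100 * kBT / 0.3, 0.3, 100), 99) # saturation
  expect_error(fjc_extension(-1, 0.3, 100))
})

test_that("FJC force inverts FJC extension to relative 1e-6", {
  x <- c(5, 20, 45, 58)
  f <- fjc_force(x, 0.3, 60)
  expect_equal(fjc_extension(f, 0.3, 60), x, tolerance = 1e-5)
  expect_identical(fjc_force(0, 0.3, 60), 0)
})

test_that("mechanical force laws are strictly monotone (property)", {
  withr::with_seed(7, {
    for (rep in seq_len(20)) {
      Lc <- runif(1, 20, 300)
      s <- runif(1, 0.05, 5)
      x <- sort(runif(50, 0, 0.999 * Lc))
      expect_true(all(diff(wlc_force(x, s, Lc)) > 0))
      expect_true(all(diff(fjc_force(x, s, Lc)) >= 0))
      d <- sort(runif(50, 0, 80))
      expect_true(all(diff(hertz_force(d, runif(1, 50, 900))) >= 0))
    }
  })
})

test_that("fit_hertz recovers the modulus from a noise-free curve", {
  tr <- make_hertz_trace(E_kPa = 300)
  fit <- fit_hertz(tr)
  expect_true(fit$converged)
  expect_equal(fit$youngs_modulus_kPa, 300, tolerance = 1e-3)
  expect_gte(fit$n_points, 5)
})

test_that("fit_hertz flags a flat no-contact curve as non-converged", {
  flat <- tibble::tibble(
    separation_nm = seq(250, 50, by = -1),
    force_pN = 0
  )
  fit <- fit_hertz(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$youngs_modulus_kPa))
})

test_that("polymer fits round-trip noise-free WLC and FJC segments", {
  withr::with_seed(5, {
    x <- seq(2, 78, length.out = 30)
    wseg <- tibble::tibble(
      extension_nm = x, force_pN = wlc_force(x, 0.5, 96.9)
    )
    wfit <- fit_polymer(wseg, "WLC")
    expect_true(wfit$converged)
    expect_equal(wfit$contour_length_nm, 96.9, tolerance = 0.01)
    expect_equal(wfit$stiffness_length_nm, 0.5, tolerance = 0.01)

    x2 <- seq(2, 50, length.out = 30)
    fseg <- tibble::tibble(
      extension_nm = x2, force_pN = fjc_force(x2, 0.3, 60)
    )
    ffit <- fit_polymer(fseg, "FJC")
    expect_true(ffit$converged)
    expect_equal(ffit$contour_length_nm, 60, tolerance = 0.01)
    expect_equal(ffit$stiffness_length_nm, 0.3, tolerance = 0.01)
  })
})

test_that("polymer fit refuses segments with fewer than 5 points", {
  seg <- tibble::tibble(extension_nm = 1:4, force_pN = c(1, 2, 4, 9))
  expect_error(fit_polymer(seg, "WLC"), "5 points")
})

test_that("polymer fit matches or beats a dense grid search", {
  withr::with_seed(33, {
    for (model in c("WLC", "FJC")) {
      x <- seq(3, 75, length.out = 20)
      ftrue <- if (model == "WLC") {
        wlc_force(x, 0.4, 95)
      } else {
        fjc_force(x, 0.4, 95)
      }
      f <- ftrue + rnorm(20, 0, 3)
      fit <- fit_polymer(tibble::tibble(extension_nm = x, force_pN = f),
                         model)
      xmax <- max(x)
      Lcs <- seq(xmax * 1.001, 10 * xmax, length.out = 200)
      ss <- seq(0.01, 10, length.out = 200)
      best <- Inf
      for (Lc in Lcs) {
        for (s in ss) {
          pred <- if (model == "WLC") {
            wlc_force(x, s, Lc)
          } else {
            fjc_force(x, s, Lc)
          }
          v <- sum((pred - f)^2)
          if (v < best) best <- v
        }
      }
      expect_lte(fit$residual_ss, best + 1e-9)
    }
  })
})

test_that("sub-physical stiffness lengths are flagged, not clamped", {
  withr::with_seed(8, {
    x <- seq(2, 60, length.out = 25)
    seg <- tibble::tibble(
      extension_nm = x, force_pN = wlc_force(x, 0.05, 80)
    )
    fit <- fit_polymer(seg, "WLC")
    expect_true(fit$subphysical)
    expect_lt(fit$stiffness_length_nm, 0.1)
    expect_gt(fit$stiffness_length_nm, 0)
  })
})
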