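test_that("baseline correction removes a planted tilt", {
  withr::with_seed(1, {
    sep <- seq(250, 50, by = -1)
    tilt <- 0.1 * sep + 5
    tr <- tibble::tibble(
      separation_nm = sep,
      force_pN = tilt + rnorm(length(sep), 0, 0.5)
    )
    out <- correct_baseline(tr)
    far <- sep >= 190
    slope <- coef(lm(out$force_pN[far] ~ sep[far]))[2]
    expect_lt(abs(slope), 0.005)
    expect_lt(abs(mean(out$force_pN[far])), 0.2)
    # idempotence: already-flat trace unchanged within noise
    again <- correct_baseline(out)
    expect_equal(again$force_pN, out$force_pN, tolerance = 0.1)
  })
})

test_that("baseline correction rejects degenerate traces", {
  bad <- tibble::tibble(separation_nm = rep(5, 10), force_pN = rnorm(10))
  expect_error(correct_baseline(bad), "zero span")
})

test_that("contact point is located at the planted position", {
  tr <- make_hertz_trace(E_kPa = 400, contact_nm = 120)
  expect_equal(find_contact_point(tr), 120, tolerance = 1.5 / 120)
  zero <- tibble::tibble(
    separation_nm = seq(250, 50, by = -1), force_pN = 0
  )
  expect_true(is.na(find_contact_point(zero)))
})

test_that("noise-only curves rarely trigger the contact detector", {
  withr::with_seed(21, {
    hits <- 0
    for (i in seq_len(1000)) {
      tr <- tibble::tibble(
        separation_nm = seq(250, 50, by = -1),
        force_pN = rnorm(201, 0, 5)
      )
      if (!is.na(find_contact_point(tr))) hits <- hits + 1
    }
    expect_lt(hits / 1000, 0.01)
  })
})

test_that("a single planted fingerprint yields one specific event", {
  withr::with_seed(3, {
    # FJC fingerprint rupturing at ~60 pN; noise sigma 3 pN
    mk <- make_retract_trace(
      Lc = 40, stiffness = 0.3, model = "FJC",
      rupture_force = 60, noise_sd = 3
    )
    ev <- detect_adhesion_events(correct_baseline(mk$trace))
    sp <- ev[ev$specific, ]
    expect_equal(nrow(sp), 1)
    expect_lt(abs(sp$rupture_force_pN - 60), 5 + 3 * 3)
    expect_lt(abs(sp$rupture_distance_nm - mk$rupture_x), 4)
  })
})

test_that("three planted ruptures are reported in distance order", {
  sep <- seq(0, 400, by = 1)
  force <- rep(0, length(sep))
  for (xr in c(20, 60, 150)) {
    act <- sep > xr - 15 & sep <= xr
    force[act] <- force[act] - seq(10, 60, length.out = sum(act))
  }
  ev <- detect_adhesion_events(
    tibble::tibble(separation_nm = sep, force_pN = force)
  )
  sp <- ev[ev$specific, ]
  expect_equal(nrow(sp), 3)
  expect_equal(sp$rupture_distance_nm, c(21, 61, 151), tolerance = 0.1)
  expect_true(!is.unsorted(sp$rupture_distance_nm))
})

test_that("featureless retract traces produce no events", {
  flat <- tibble::tibble(separation_nm = 0:400, force_pN = 0)
  expect_equal(nrow(detect_adhesion_events(flat)), 0)
})

test_that("curve classification routes by specific event count", {
  none <- detect_adhesion_events(
    tibble::tibble(separation_nm = 0:400, force_pN = 0)
  )
  expect_identical(classify_curve(none), "none")
  one <- tibble::tibble(
    rupture_force_pN = 60, rupture_distance_nm = 30,
    i_start = 10L, i_end = 30L, specific = TRUE
  )
  expect_identical(classify_curve(one), "single")
  expect_identical(classify_curve(dplyr::bind_rows(one, one)), "multiple")
  # nonspecific events do not count
  ns <- one
  ns$specific <- FALSE
  expect_identical(classify_curve(ns), "none")
})

test_that("every curve is classified exactly once (conservation)", {
  cfg <- force_sim_preset("L62", force_noise_sd_pN = 3, seed = 19)
  ret <- gen_retract_curves(cfg, 60)
  classes <- vapply(ret$curves, function(cv) {
    classify_curve(detect_adhesion_events(correct_baseline(cv)))
  }, character(1))
  expect_length(classes, 60)
  expect_true(all(classes %in% c("none", "single", "multiple")))
  counts <- table(factor(classes, levels = c("none", "single", "multiple")))
  expect_equal(sum(counts), 60)
})

test_that("modal modulus recovers the Gaussian location and spread", {
  withr::with_seed(14, {
    fits <- tibble::tibble(
      youngs_modulus_kPa = rnorm(1024, 483, 61), converged = TRUE
    )
    mm <- modal_modulus(fits)
    expect_lt(abs(mm$mode_kPa - 483), 10)
    expect_lt(abs(mm$sigma_kPa - 61), 10)
    expect_identical(mm$method, "gaussian")
  })
})

test_that("modal modulus handles degenerate and mixture inputs", {
  same <- tibble::tibble(youngs_modulus_kPa = rep(250, 40), converged = TRUE)
  mm <- modal_modulus(same)
  expect_equal(mm$mode_kPa, 250)
  expect_equal(mm$sigma_kPa, 0)
  expect_error(
    modal_modulus(tibble::tibble(
      youngs_modulus_kPa = rnorm(10, 400, 10), converged = TRUE
    )),
    "30"
  )
  withr::with_seed(2, {
    mix <- tibble::tibble(
      youngs_modulus_kPa = c(rnorm(800, 230, 40), rnorm(200, 600, 40)),
      converged = TRUE
    )
    mmix <- modal_modulus(mix)
    expect_lt(abs(mmix$mode_kPa - 230), 20)
  })
})

test_that("Gaussian-mode error shrinks with sample size", {
  withr::with_seed(9, {
    err_at <- function(n) {
      errs <- vapply(1:5, function(i) {
        fits <- tibble::tibble(
          youngs_modulus_kPa = rnorm(n, 483, 61), converged = TRUE
        )
        abs(modal_modulus(fits)$mode_kPa - 483)
      }, numeric(1))
      mean(errs)
    }
    expect_lt(err_at(10000), err_at(100))
  })
})

test_that("adhesion frequency equals the planted fraction when noise-free", {
  curves <- c(
    lapply(1:33, function(i) {
      make_retract_trace(Lc = 60, model = "FJC", rupture_force = 60)$trace
    }),
    lapply(1:67, function(i) {
      tibble::tibble(separation_nm = seq(0, 400), force_pN = 0)
    })
  )
  expect_equal(adhesion_frequency(curves), 33)
  expect_error(adhesion_frequency(list()), "No curves")
})

test_that("frequency estimator is unbiased over planted probabilities", {
  for (p in c(0.1, 0.25, 0.33)) {
    cfg <- force_sim_config(
      event_probability = p, force_noise_sd_pN = 3,
      Lc_mean_nm = 64.8, Lc_sd_nm = 20, seed = round(1000 * p)
    )
    ret <- gen_retract_curves(cfg, 400)
    freq <- adhesion_frequency(ret$curves)
    # binomial 95% CI around the planted probability, plus detector slack
    ci <- 1.96 * sqrt(p * (1 - p) / 400) * 100
    expect_lt(abs(freq - 100 * p), ci + 2)
  }
})

test_that("contour-length distribution summarizes converged fits", {
  same <- tibble::tibble(
    model = "WLC", contour_length_nm = rep(25, 10), converged = TRUE
  )
  cl <- contour_length_distribution(same)
  expect_equal(cl$mean_nm, 25)
  expect_equal(cl$sd_nm, 0)
  expect_error(
    contour_length_distribution(same[same$converged == FALSE, ]),
    "No converged"
  )
  withr::with_seed(4, {
    mixed <- tibble::tibble(
      model = "WLC",
      contour_length_nm = runif(200, 20, 300),
      converged = TRUE
    )
    clm <- contour_length_distribution(mixed)
    nz <- clm$histogram[clm$histogram$count > 0, ]
    bw <- nz$upper[1] - nz$lower[1]
    expect_gte(min(nz$lower), 20 - bw)
    expect_lte(max(nz$upper), 300 + bw)
    expect_equal(sum(clm$histogram$count), 200)
  })
})
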