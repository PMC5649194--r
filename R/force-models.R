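#' Conical Hertz (Sneddon) indentation force
#'
#' Force on a conical indenter pressed a depth `indentation_nm` into an
#' elastic half-space of Young's modulus `E_kPa`:
#' \deqn{F = \frac{2 E \tan\alpha}{\pi (1 - \nu^2)} \, \delta^2}
#' with \eqn{\alpha} the cone half-angle and \eqn{\nu} the Poisson ratio.
#' Units: indentation in nm, modulus in kPa, force in pN
#' (1 kPa = 1e-3 pN/nm^2).
#'
#' @param indentation_nm Indentation depth(s) in nm, >= 0.
#' @param E_kPa Young's modulus in kPa, > 0.
#' @param tip A [tip_geometry()].
#' @return Force in pN, same length as `indentation_nm`.
#' @examples
#' hertz_force(50, 483) # ~328 pN
#' @export
hertz_force <- function(indentation_nm, E_kPa, tip = tip_geometry()) {
  if (any(indentation_nm < 0)) abort("`indentation_nm` must be >= 0.")
  if (!is.numeric(E_kPa) || length(E_kPa) != 1 || E_kPa <= 0) {
    abort("`E_kPa` must be a single positive number.")
  }
  .hertz_prefactor(tip) * (E_kPa * 1e-3) * indentation_nm^2
}

# geometry prefactor 2 tan(alpha) / (pi (1 - nu^2)), dimensionless
.hertz_prefactor <- function(tip) {
  2 * tan(tip$half_angle_rad) / (pi * (1 - tip$poisson_ratio^2))
}

#' Worm-like-chain extension force
#'
#' Interpolated Marko-Siggia force law for a semi-flexible polymer of
#' contour length `Lc_nm` and persistence length `lp_nm` stretched to
#' extension `extension_nm`:
#' \deqn{F(x) = \frac{k_B T}{l_p}\left[\frac{1}{4}(1 - x/L_c)^{-2}
#'   + x/L_c - \frac{1}{4}\right]}
#' The force is zero at zero extension and diverges as the extension
#' approaches the contour length.
#'
#' @param extension_nm Extension(s) in nm, in \[0, `Lc_nm`).
#' @param lp_nm Persistence length in nm, > 0.
#' @param Lc_nm Contour length in nm, > 0.
#' @param thermal A [thermal_context()].
#' @return Force in pN.
#' @examples
#' wlc_force(48, lp_nm = 0.4, Lc_nm = 96)
#' @export
wlc_force <- function(extension_nm, lp_nm, Lc_nm, thermal = thermal_context()) {
  if (lp_nm <= 0 || Lc_nm <= 0) abort("`lp_nm` and `Lc_nm` must be > 0.")
  if (any(extension_nm < 0) || any(extension_nm >= Lc_nm)) {
    abort("`extension_nm` must lie in [0, Lc_nm).")
  }
  r <- extension_nm / Lc_nm
  (thermal$kBT_pN_nm / lp_nm) * (0.25 * (1 - r)^-2 + r - 0.25)
}

#' Freely-jointed-chain extension at a given force
#'
#' Langevin-function extension of a chain of rigid segments of Kuhn
#' length `lk_nm` and total contour length `Lc_nm` under tension `force_pN`:
#' \deqn{x(F) = L_c\left[\coth\left(\frac{F l_k}{k_B T}\right)
#'   - \frac{k_B T}{F l_k}\right]}
#' The analytic limit x -> F Lc lk / (3 kBT) is used near F = 0.
#'
#' @param force_pN Pulling force(s) in pN, >= 0.
#' @param lk_nm Kuhn length in nm, > 0.
#' @param Lc_nm Contour length in nm, > 0.
#' @param thermal A [thermal_context()].
#' @return Extension in nm, in \[0, `Lc_nm`).
#' @examples
#' fjc_extension(60, lk_nm = 0.3, Lc_nm = 100)
#' @export
fjc_extension <- function(force_pN, lk_nm, Lc_nm, thermal = thermal_context()) {
  if (lk_nm <= 0 || Lc_nm <= 0) abort("`lk_nm` and `Lc_nm` must be > 0.")
  if (any(force_pN < 0)) abort("`force_pN` must be >= 0.")
  y <- force_pN * lk_nm / thermal$kBT_pN_nm
  out <- numeric(length(y))
  small <- y < 1e-4 # coth(y) - 1/y ~ y/3 - y^3/45
  out[small] <- Lc_nm * (y[small] / 3 - y[small]^3 / 45)
  ys <- y[!small]
  out[!small] <- Lc_nm * (1 / tanh(ys) - 1 / ys)
  out
}

#' Freely-jointed-chain force at a given extension
#'
#' Numerical inverse of [fjc_extension()]: the tension at which the chain
#' reaches extension `extension_nm`. Solved by bisection on the force axis
#' to a relative tolerance of 1e-6; used to express the FJC model in the
#' force-extension plane where retract segments are sampled.
#'
#' @inheritParams fjc_extension
#' @param extension_nm Extension(s) in nm, in \[0, `Lc_nm`).
#' @return Force in pN.
#' @export
fjc_force <- function(extension_nm, lk_nm, Lc_nm, thermal = thermal_context()) {
  if (lk_nm <= 0 || Lc_nm <= 0) abort("`lk_nm` and `Lc_nm` must be > 0.")
  if (any(extension_nm < 0) || any(extension_nm >= Lc_nm)) {
    abort("`extension_nm` must lie in [0, Lc_nm).")
  }
  n <- length(extension_nm)
  out <- numeric(n)
  pos <- extension_nm > 0
  if (!any(pos)) return(out)
  x <- extension_nm[pos]
  lo <- rep(1e-9, length(x))
  hi <- rep(thermal$kBT_pN_nm / lk_nm, length(x)) # y = 1 to start
  # grow upper brackets until they over-extend every target
  repeat {
    short <- fjc_extension(hi, lk_nm, Lc_nm, thermal) < x
    if (!any(short)) break
    hi[short] <- hi[short] * 2
  }
  for (i in seq_len(80)) {
    mid <- 0.5 * (lo + hi)
    below <- fjc_extension(mid, lk_nm, Lc_nm, thermal) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (all((hi - lo) / hi < 1e-6)) break
  }
  out[pos] <- 0.5 * (lo + hi)
  out
}

#' Fit the conical Hertz model to an approach trace
#'
#' Least-squares estimate of the Young's modulus from a baseline-corrected
#' approach trace. The contact point is treated as a free nuisance
#' parameter refined within `contact_window_nm` of the initial detector
#' estimate; for each candidate contact point the modulus has a closed-form
#' weighted least-squares solution over points within
#' `max_indentation_nm` of contact, so the fit is a fast one-dimensional
#' profile optimisation.
#'
#' @param curve A force curve tibble (columns `segment`, `separation_nm`,
#'   `force_pN`) or a bare approach trace with columns `separation_nm`,
#'   `force_pN`, baseline-corrected and ordered far to near.
#' @param tip A [tip_geometry()].
#' @param max_indentation_nm Fit window beyond contact, nm (default 50).
#' @param contact_window_nm Half-width of the contact-point refinement
#'   window, nm.
#' @param contact_point_nm Optional externally supplied initial contact
#'   point; when `NULL` it is located with [find_contact_point()].
#' @return One-row tibble: `youngs_modulus_kPa`, `contact_point_nm`,
#'   `residual_ss` (pN^2), `n_points`, `converged`. A trace with no
#'   detectable contact yields `converged = FALSE` and `NA` estimates.
#' @examples
#' tr <- tibble::tibble(
#'   separation_nm = seq(200, 40, by = -1),
#'   force_pN = hertz_force(pmax(120 - seq(200, 40, by = -1), 0), 300)
#' )
#' fit_hertz(tr)
#' @export
fit_hertz <- function(curve, tip = tip_geometry(), max_indentation_nm = 50,
                      contact_window_nm = 30, contact_point_nm = NULL) {
  tr <- .approach_trace(curve)
  if (is.null(contact_point_nm)) {
    contact_point_nm <- find_contact_point(tr)
  }
  if (is.na(contact_point_nm)) {
    return(tibble(
      youngs_modulus_kPa = NA_real_, contact_point_nm = NA_real_,
      residual_ss = NA_real_, n_points = 0L, converged = FALSE
    ))
  }
  pref <- .hertz_prefactor(tip)
  sep <- tr$separation_nm
  force <- tr$force_pN

  fit_at <- function(cp) {
    delta <- cp - sep
    keep <- delta >= 0 & delta <= max_indentation_nm
    if (sum(keep) < 5) {
      # finite penalty keeps optimize() quiet on out-of-range candidates
      return(list(ss = .Machine$double.xmax, E = NA_real_, n = sum(keep)))
    }
    d2 <- delta[keep]^2
    f <- force[keep]
    # F = pref * (E/1000) * delta^2  =>  closed-form LS slope
    slope <- sum(f * d2) / sum(d2 * d2)
    E <- slope / pref * 1e3
    list(ss = sum((f - slope * d2)^2), E = E, n = sum(keep))
  }

  n_in <- sum(sep >= contact_point_nm - max_indentation_nm &
                sep <= contact_point_nm)
  if (n_in < 5) {
    abort("Fewer than 5 points within the indentation window; cannot fit.")
  }
  opt <- optimize(
    function(cp) fit_at(cp)$ss,
    interval = c(contact_point_nm - contact_window_nm,
                 contact_point_nm + contact_window_nm)
  )
  best <- fit_at(opt$minimum)
  converged <- is.finite(best$ss) && !is.na(best$E) && best$E > 0
  tibble(
    youngs_modulus_kPa = if (converged) best$E else NA_real_,
    contact_point_nm = opt$minimum,
    residual_ss = best$ss,
    n_points = as.integer(best$n),
    converged = converged
  )
}

#' Fit a polymer extension model to a retract segment
#'
#' Bounded nonlinear least squares of the worm-like-chain ([wlc_force()])
#' or freely-jointed-chain ([fjc_force()]) force law to an
#' extension-force segment taken between two ruptures of a retract trace.
#' The contour length is constrained to (max observed extension,
#' 10 x max extension\] and the stiffness length (persistence length for
#' WLC, Kuhn length for FJC) to \[0.01, 10\] nm. The optimiser restarts
#' from `restarts` perturbed initialisations (perturbations drawn from the
#' session RNG); the lowest residual wins, ties broken toward the smaller
#' contour length.
#'
#' @param segment Tibble with columns `extension_nm` (>= 0) and `force_pN`
#'   (pulling force magnitude, >= 0); at least 5 points.
#' @param model `"WLC"` or `"FJC"`.
#' @param thermal A [thermal_context()].
#' @param restarts Number of additional perturbed starts (default 3).
#' @return One-row tibble: `model`, `contour_length_nm`,
#'   `stiffness_length_nm`, `residual_ss`, `converged`.
#' @examples
#' x <- seq(5, 78, length.out = 25)
#' seg <- tibble::tibble(extension_nm = x, force_pN = wlc_force(x, 0.5, 96.9))
#' fit_polymer(seg, "WLC")
#' @export
fit_polymer <- function(segment, model = c("WLC", "FJC"),
                        thermal = thermal_context(), restarts = 3) {
  model <- match.arg(model)
  if (!all(c("extension_nm", "force_pN") %in% names(segment))) {
    abort("`segment` needs columns `extension_nm` and `force_pN`.")
  }
  seg <- segment[segment$extension_nm > 0, ]
  if (nrow(seg) < 5) abort("Polymer fit needs at least 5 points.")
  x <- seg$extension_nm
  f <- seg$force_pN
  xmax <- max(x)

  lower <- c(Lc = xmax * (1 + 1e-6), s = 0.01)
  upper <- c(Lc = 10 * xmax, s = 10)
  predict_f <- if (model == "WLC") {
    function(p) wlc_force(x, p[2], p[1], thermal)
  } else {
    function(p) fjc_force(x, p[2], p[1], thermal)
  }
  objective <- function(p) {
    pred <- predict_f(p)
    sum((pred - f)^2)
  }

  # deterministic ladder of contour-length starts plus RNG-perturbed
  # restarts; the profile in Lc is prone to shallow local minima
  starts <- lapply(c(0.95, 0.8, 0.6), function(frac) {
    c(Lc = min(xmax / frac, 10 * xmax * 0.99), s = 0.5)
  })
  for (i in seq_len(restarts)) {
    fac <- exp(runif(2, log(0.5), log(2)))
    cand <- pmin(pmax(starts[[2]] * fac, lower * 1.001), upper * 0.999)
    starts[[length(starts) + 1]] <- cand
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      optim(p0, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, parscale = c(xmax, 0.5))),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) ||
        res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1])) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(tibble(
      model = model, contour_length_nm = NA_real_,
      stiffness_length_nm = NA_real_, residual_ss = NA_real_,
      converged = FALSE
    ))
  }
  tibble(
    model = model,
    contour_length_nm = unname(best$par[1]),
    stiffness_length_nm = unname(best$par[2]),
    residual_ss = best$value,
    converged = best$convergence == 0,
    # stiffness lengths below 0.1 nm are sub-physical (below a monomer);
    # reported unclamped but flagged
    subphysical = unname(best$par[2]) < 0.1
  )
}
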