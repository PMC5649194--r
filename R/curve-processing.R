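# A force curve is a tibble with columns `segment` ("approach"/"retract"),
# `separation_nm` and `force_pN`; approach traces run far -> near, retract
# traces near -> far. Bare single-segment traces (no `segment` column) are
# accepted by per-trace operations.

.trace <- function(curve, which) {
  if ("segment" %in% names(curve)) {
    curve[curve$segment == which, , drop = FALSE]
  } else {
    curve
  }
}
.approach_trace <- function(curve) .trace(curve, "approach")
.retract_trace <- function(curve) .trace(curve, "retract")

# robust noise scale of the non-contact (far-field) outer fraction of a trace
.farfield_idx <- function(separation_nm, fraction = 0.3) {
  span <- range(separation_nm)
  cutoff <- span[2] - fraction * (span[2] - span[1])
  which(separation_nm >= cutoff)
}

#' Subtract a linear baseline from a force curve
#'
#' Fits a straight line to the non-contact region (the outer 30% of the
#' separation range, where the tip is far from the surface) of each trace
#' and subtracts it, so that the far-field force is centred on zero.
#' Applied independently to approach and retract segments.
#'
#' @param curve Force curve tibble (`segment`, `separation_nm`, `force_pN`)
#'   or a bare single trace.
#' @param fraction Outer fraction of the separation range treated as
#'   non-contact (default 0.3).
#' @return The curve with corrected `force_pN`.
#' @export
correct_baseline <- function(curve, fraction = 0.3) {
  fix_one <- function(tr) {
    if (nrow(tr) < 5) abort("Trace too short to baseline-correct.")
    if (diff(range(tr$separation_nm)) <= 0) {
      abort("Degenerate trace: separation has zero span.")
    }
    idx <- .farfield_idx(tr$separation_nm, fraction)
    fit <- stats::lm.fit(
      cbind(1, tr$separation_nm[idx]),
      tr$force_pN[idx]
    )
    b <- fit$coefficients
    tr$force_pN <- tr$force_pN - (b[1] + b[2] * tr$separation_nm)
    tr
  }
  if ("segment" %in% names(curve)) {
    parts <- lapply(split(curve, curve$segment), fix_one)
    out <- dplyr::bind_rows(parts)
    # preserve original segment order
    out[order(match(out$segment, unique(curve$segment))), , drop = FALSE]
  } else {
    fix_one(curve)
  }
}

#' Locate the contact point on an approach trace
#'
#' Scanning from far to near, the contact point is the first separation at
#' which the force exceeds baseline + 3 x sigma_noise and stays above it
#' for at least `min_run` consecutive points. sigma_noise is the robust SD
#' (MAD) of the non-contact outer 30% of the trace, so the threshold
#' adapts to the cantilever noise.
#'
#' @param curve Baseline-corrected approach trace (or full curve).
#' @param n_sigma Threshold multiple of the noise SD (default 3).
#' @param min_run Consecutive above-threshold points required (default 5).
#' @return Contact separation in nm, or `NA` when no contact is found.
#' @export
find_contact_point <- function(curve, n_sigma = 3, min_run = 5) {
  tr <- .approach_trace(curve)
  if (nrow(tr) < min_run + 5) return(NA_real_)
  ord <- order(tr$separation_nm, decreasing = TRUE) # far -> near
  sep <- tr$separation_nm[ord]
  force <- tr$force_pN[ord]
  sigma <- mad(force[.farfield_idx(sep)])
  above <- force > n_sigma * sigma
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0) return(NA_real_)
  sep[starts[hit[1]]]
}

#' Detect adhesion events on a retract trace
#'
#' Finds unbinding events as contiguous regions where the retract force
#' drops below -`min_force_pN` (default 3 x the robust far-field noise
#' SD). Within a region, sudden force releases (a jump back toward
#' baseline larger than the threshold between consecutive points) split
#' it into multiple events. Each event reports the unsigned rupture force
#' (deepest force in its span) and the rupture distance (separation at
#' which the force returns to baseline). Events rupturing closer than
#' `min_distance_nm` to the surface are flagged nonspecific
#' (`specific = FALSE`): they reflect tip-surface snap-off rather than
#' tether extension.
#'
#' @param curve Baseline-corrected retract trace (or full curve);
#'   separation ordered near -> far.
#' @param min_force_pN Force threshold in pN; default `NULL` uses
#'   3 x MAD of the far-field force.
#' @param min_distance_nm Minimum rupture distance for a specific event
#'   (default 5 nm).
#' @param min_points Minimum number of consecutive below-threshold
#'   samples for a region to count as an event (default 5); short
#'   noise excursions below the threshold are not events.
#' @return Tibble with one row per event: `rupture_force_pN`,
#'   `rupture_distance_nm`, `i_start`, `i_end` (row span in the trace),
#'   `specific`. Zero rows for featureless curves.
#' @export
detect_adhesion_events <- function(curve, min_force_pN = NULL,
                                   min_distance_nm = 5, min_points = 5) {
  tr <- .retract_trace(curve)
  ord <- order(tr$separation_nm) # near -> far
  sep <- tr$separation_nm[ord]
  force <- tr$force_pN[ord]
  sigma <- mad(force[.farfield_idx(sep)])
  if (is.null(min_force_pN)) {
    min_force_pN <- 3 * sigma
  }
  if (min_force_pN <= 0) min_force_pN <- 1e-9
  # a rupture is a sudden release toward baseline; the split threshold
  # sits well above the noise of a single-sample force difference
  split_force_pN <- max(min_force_pN, 6 * sigma)
  # hysteresis: an event must dip below -min_force for >= min_points
  # consecutive samples (seed), but it extends until the force returns
  # to baseline (above -release), so noisy oscillation around the
  # detection threshold does not fragment one tether into many events
  release <- max(sigma, min_force_pN / 3)
  below <- force < -min_force_pN
  n <- length(force)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seeds <- which(r$values & r$lengths >= min_points)
  if (length(seeds) == 0) {
    return(tibble(
      rupture_force_pN = numeric(), rupture_distance_nm = numeric(),
      i_start = integer(), i_end = integer(), specific = logical()
    ))
  }
  regions <- lapply(seeds, function(run) {
    i0 <- starts[run]; i1 <- ends[run]
    # two consecutive near-baseline samples end a region, so a single
    # positive noise excursion does not truncate a tether mid-ramp
    while (i0 > 1 && (force[i0 - 1] < -release ||
                      (i0 > 2 && force[i0 - 2] < -release))) {
      i0 <- i0 - 1
    }
    while (i1 < n && (force[i1 + 1] < -release ||
                      (i1 < n - 1 && force[i1 + 2] < -release))) {
      i1 <- i1 + 1
    }
    c(i0, i1)
  })
  # merge overlapping extended regions
  merged <- list(regions[[1]])
  for (rg in regions[-1]) {
    last <- merged[[length(merged)]]
    if (rg[1] <= last[2] + 1) {
      merged[[length(merged)]] <- c(last[1], max(last[2], rg[2]))
    } else {
      merged[[length(merged) + 1]] <- rg
    }
  }
  events <- list()
  for (rg in merged) {
    i0 <- rg[1]; i1 <- rg[2]
    # split at sudden releases (ruptures) inside the region
    jump <- which(diff(force[i0:i1]) > split_force_pN) + i0 - 1
    bounds <- sort(unique(c(jump, i1)))
    s <- i0
    for (b in bounds) {
      idx <- s:b
      peak <- idx[which.min(force[idx])]
      # sub-regions below the seed threshold only do not count
      if (min(force[idx]) >= -min_force_pN || length(idx) < min_points) {
        s <- b + 1
        next
      }
      rupture_i <- min(b + 1, n)
      events[[length(events) + 1]] <- tibble(
        rupture_force_pN = -force[peak],
        rupture_distance_nm = sep[rupture_i],
        i_start = as.integer(s), i_end = as.integer(b),
        specific = sep[rupture_i] >= min_distance_nm
      )
      s <- b + 1
    }
  }
  if (length(events) == 0) {
    return(tibble(
      rupture_force_pN = numeric(), rupture_distance_nm = numeric(),
      i_start = integer(), i_end = integer(), specific = logical()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(events), .data$rupture_distance_nm)
}

#' Classify a retract curve by its specific adhesion events
#'
#' Routes curves to the polymer model appropriate for their unbinding
#' pattern: no specific event, a single event (fitted with the FJC
#' model), or multiple events (fitted with the WLC model).
#'
#' @param events Event tibble from [detect_adhesion_events()].
#' @return `"none"`, `"single"`, or `"multiple"`.
#' @export
classify_curve <- function(events) {
  n <- sum(events$specific)
  if (n == 0) "none" else if (n == 1) "single" else "multiple"
}

#' Extract fit segments between ruptures of a retract trace
#'
#' Returns, for each specific adhesion event, the extension-force segment
#' running from the previous rupture (or the surface) up to the event's
#' rupture, in the form consumed by [fit_polymer()]: extension in nm
#' (tip-sample separation) and pulling force in pN (sign-flipped retract
#' force).
#'
#' @param curve Baseline-corrected retract trace (or full curve).
#' @param events Event tibble from [detect_adhesion_events()]; defaults to
#'   detecting them on `curve`.
#' @return List of tibbles (`extension_nm`, `force_pN`), one per specific
#'   event, ordered by rupture distance.
#' @export
extract_event_segments <- function(curve, events = NULL) {
  tr <- .retract_trace(curve)
  ord <- order(tr$separation_nm)
  sep <- tr$separation_nm[ord]
  force <- tr$force_pN[ord]
  if (is.null(events)) {
    events <- detect_adhesion_events(
      tibble(separation_nm = sep, force_pN = force)
    )
  }
  ev <- events[events$specific, , drop = FALSE]
  prev_end <- 1L
  out <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    idx <- prev_end:ev$i_end[k]
    out[[k]] <- tibble(
      extension_nm = sep[idx],
      force_pN = -force[idx]
    )
    prev_end <- ev$i_end[k] + 1L
  }
  out
}

#' Modal Young's modulus of a set of Hertz fits
#'
#' Builds a histogram (Freedman-Diaconis bins) of the fitted moduli and
#' fits a single Gaussian to the bin counts by least squares; the fitted
#' mean is reported as the modal (most probable) modulus and the fitted
#' sigma as its spread. If the Gaussian fit fails, the histogram argmax
#' is used with `sigma_kPa = NA` (ties broken toward the lower modulus).
#'
#' @param fits Tibble of Hertz fits ([fit_hertz()] rows); only converged
#'   fits are used and at least 30 are required.
#' @return A `modulus_distribution` object: `mode_kPa`, `sigma_kPa`,
#'   `histogram` (tibble of bin mids/edges/counts), `n_fits`, `method`.
#' @export
modal_modulus <- function(fits) {
  e <- fits$youngs_modulus_kPa[fits$converged]
  e <- e[is.finite(e)]
  if (length(e) < 30) abort("Need at least 30 converged fits.")
  gf <- .gaussian_mode(e)
  structure(
    c(gf, list(n_fits = length(e))),
    class = "modulus_distribution"
  )
}

# histogram + least-squares Gaussian on counts; shared by modulus and
# contour-length summaries
.gaussian_mode <- function(x) {
  if (sd(x) == 0) {
    return(list(
      mode_kPa = x[1], sigma_kPa = 0,
      histogram = tibble(
        mid = x[1], lower = x[1], upper = x[1], count = length(x)
      ),
      method = "degenerate"
    ))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  histogram <- tibble(
    mid = h$mids,
    lower = head(h$breaks, -1),
    upper = tail(h$breaks, -1),
    count = h$counts
  )
  ss <- function(p) {
    sum((h$counts - p[1] * exp(-(h$mids - p[2])^2 / (2 * p[3]^2)))^2)
  }
  # two starts: global moments, and the histogram argmax (keeps the fit
  # anchored on the dominant peak when the sample is a mixture)
  amax_mid <- h$mids[which.max(h$counts)]
  bw <- h$mids[2] - h$mids[1]
  starts <- list(
    c(A = max(h$counts), mu = mean(x), sigma = sd(x)),
    c(A = max(h$counts), mu = amax_mid, sigma = 2 * bw)
  )
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      optim(st, ss, method = "L-BFGS-B",
            lower = c(1e-6, min(x), bw / 10),
            upper = c(10 * max(h$counts), max(x), 10 * sd(x))),
      error = function(e) NULL
    )
    if (is.null(cand) || cand$convergence != 0) next
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  if (is.null(fit)) {
    amax <- which(h$counts == max(h$counts))[1] # tie -> lower bin
    return(list(
      mode_kPa = h$mids[amax], sigma_kPa = NA_real_,
      histogram = histogram, method = "argmax"
    ))
  }
  list(
    mode_kPa = unname(fit$par[2]), sigma_kPa = unname(fit$par[3]),
    histogram = histogram, method = "gaussian"
  )
}

#' @export
print.modulus_distribution <- function(x, ...) {
  cat(sprintf(
    "<modulus_distribution> mode %.1f kPa +/- %.1f kPa (n = %d fits, %s)\n",
    x$mode_kPa, x$sigma_kPa, x$n_fits, x$method
  ))
  invisible(x)
}

#' Fraction of curves carrying specific adhesion events
#'
#' The adhesion-event frequency of a single-molecule force spectroscopy
#' experiment: the percentage of retract curves with at least one
#' specific unbinding event.
#'
#' @param curves List of force curves (or a bundle tibble with a `curve`
#'   list-column). Curves are baseline-corrected before event detection.
#' @param ... Passed to [detect_adhesion_events()].
#' @return Percentage in \[0, 100\].
#' @export
adhesion_frequency <- function(curves, ...) {
  curves <- .curve_list(curves)
  if (length(curves) == 0) abort("No curves supplied.")
  has_event <- vapply(curves, function(cv) {
    ev <- detect_adhesion_events(correct_baseline(cv), ...)
    any(ev$specific)
  }, logical(1))
  100 * mean(has_event)
}

.curve_list <- function(curves) {
  if (is.data.frame(curves) && "curve" %in% names(curves)) {
    curves$curve
  } else if (is.data.frame(curves)) {
    list(curves)
  } else {
    curves
  }
}

#' Contour-length distribution of polymer fits
#'
#' Histogram, mean and SD of fitted contour lengths over a set of
#' converged polymer-model fits.
#'
#' @param fits Tibble of [fit_polymer()] rows.
#' @return A `contour_length_distribution` object: `histogram` (tibble),
#'   `mean_nm`, `sd_nm`, `n_fits`.
#' @export
contour_length_distribution <- function(fits) {
  lc <- fits$contour_length_nm[fits$converged]
  lc <- lc[is.finite(lc)]
  if (length(lc) == 0) abort("No converged fits supplied.")
  if (length(lc) == 1 || sd(lc) == 0) {
    histogram <- tibble(
      mid = lc[1], lower = lc[1], upper = lc[1], count = length(lc)
    )
  } else {
    h <- graphics::hist(lc, breaks = "FD", plot = FALSE)
    histogram <- tibble(
      mid = h$mids,
      lower = head(h$breaks, -1),
      upper = tail(h$breaks, -1),
      count = h$counts
    )
  }
  structure(
    list(
      histogram = histogram,
      mean_nm = mean(lc),
      sd_nm = if (length(lc) > 1) sd(lc) else 0,
      n_fits = length(lc)
    ),
    class = "contour_length_distribution"
  )
}

#' @export
print.contour_length_distribution <- function(x, ...) {
  cat(sprintf(
    "<contour_length_distribution> mean %.1f nm, SD %.1f nm (n = %d fits)\n",
    x$mean_nm, x$sd_nm, x$n_fits
  ))
  invisible(x)
}
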