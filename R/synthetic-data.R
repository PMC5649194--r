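# run `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# normal draws truncated to > lower by redraw
.rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Configuration for synthetic force-curve generation
#'
#' Collects every parameter of the force-curve simulators. Defaults
#' describe the laboratory strain BY4743: 32 x 32 force-volume grids,
#' per-curve moduli drawn from 483 +/- 61 kPa, contact at 120 nm, 10 pN
#' force noise; retract fingerprints with a 10% specific-event
#' probability, FJC mechanics with contour lengths 64.8 +/- 30 nm, Kuhn
#' length 0.3 nm and rupture forces 60 +/- 5 pN. Use
#' [force_sim_preset()] for the other strains.
#'
#' @param grid_rows,grid_cols Force-volume grid size (default 32 x 32,
#'   i.e. 1,024 curves per cell).
#' @param E_mean_kPa,E_sd_kPa Young's modulus distribution (kPa).
#' @param contact_point_nm Contact position on the separation axis (nm).
#' @param force_noise_sd_pN Gaussian force noise SD (pN).
#' @param tip A [tip_geometry()].
#' @param event_probability Probability a retract curve carries at least
#'   one specific adhesion fingerprint, in \[0, 1\].
#' @param events_per_curve Probability weights for 1, 2, ... events given
#'   a curve carries any (default `1`: always a single event).
#' @param polymer_model `"FJC"` or `"WLC"` fingerprint mechanics.
#' @param Lc_mean_nm,Lc_sd_nm Contour-length distribution (nm),
#'   truncated > 0.
#' @param stiffness_length_nm Kuhn length (FJC) or persistence length
#'   (WLC) in nm.
#' @param rupture_force_mean_pN,rupture_force_sd_pN Rupture-force
#'   distribution (pN).
#' @param max_separation_nm Retract trace extent (nm).
#' @param sample_step_nm Separation sampling step (nm).
#' @param spring_constant_N_per_m Cantilever spring constant (N/m).
#' @param approach_speed_um_s Approach/retract speed (um/s).
#' @param thermal A [thermal_context()].
#' @param seed RNG seed; identical configs generate identical data.
#' @return A `force_sim_config` list.
#' @export
force_sim_config <- function(grid_rows = 32, grid_cols = 32,
                             E_mean_kPa = 483, E_sd_kPa = 61,
                             contact_point_nm = 120,
                             force_noise_sd_pN = 10,
                             tip = tip_geometry(),
                             event_probability = 0.1,
                             events_per_curve = 1,
                             polymer_model = c("FJC", "WLC"),
                             Lc_mean_nm = 64.8, Lc_sd_nm = 30,
                             stiffness_length_nm = 0.3,
                             rupture_force_mean_pN = 60,
                             rupture_force_sd_pN = 5,
                             max_separation_nm = 400,
                             sample_step_nm = 1,
                             spring_constant_N_per_m = 0.015,
                             approach_speed_um_s = 2,
                             thermal = thermal_context(),
                             seed = 1) {
  polymer_model <- match.arg(polymer_model)
  stopifnot(
    event_probability >= 0, event_probability <= 1,
    E_mean_kPa > 0, Lc_mean_nm > 0, stiffness_length_nm > 0,
    rupture_force_mean_pN > 0, sample_step_nm > 0
  )
  structure(
    list(
      grid_rows = grid_rows, grid_cols = grid_cols,
      E_mean_kPa = E_mean_kPa, E_sd_kPa = E_sd_kPa,
      contact_point_nm = contact_point_nm,
      force_noise_sd_pN = force_noise_sd_pN,
      tip = tip,
      event_probability = event_probability,
      events_per_curve = events_per_curve,
      polymer_model = polymer_model,
      Lc_mean_nm = Lc_mean_nm, Lc_sd_nm = Lc_sd_nm,
      stiffness_length_nm = stiffness_length_nm,
      rupture_force_mean_pN = rupture_force_mean_pN,
      rupture_force_sd_pN = rupture_force_sd_pN,
      max_separation_nm = max_separation_nm,
      sample_step_nm = sample_step_nm,
      spring_constant_N_per_m = spring_constant_N_per_m,
      approach_speed_um_s = approach_speed_um_s,
      thermal = thermal,
      seed = seed
    ),
    class = "force_sim_config"
  )
}

#' Strain-specific force-simulation presets
#'
#' Builds a [force_sim_config()] from the bundled [strain_presets()]
#' phenotype table: modulus distribution from the stiffness column,
#' event probability from the adhesion-event frequency, contour lengths
#' from the contour-length column. L69 uses WLC mechanics (persistence
#' length 0.5 nm, multiple events); the other strains use single-event
#' FJC mechanics (Kuhn length 0.3 nm).
#'
#' @param strain One of `"BY4743"`, `"L71"`, `"L62"`, `"L60"`, `"L69"`.
#' @param ... Overrides passed to [force_sim_config()].
#' @return A `force_sim_config`.
#' @export
force_sim_preset <- function(strain, ...) {
  presets <- strain_presets()
  row <- presets[presets$strain == strain, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown strain `", strain, "`."))
  }
  is_wlc <- strain == "L69"
  defaults <- list(
    E_mean_kPa = row$stiffness_kPa, E_sd_kPa = row$stiffness_kPa_sd,
    event_probability = row$adhesion_pct / 100,
    Lc_mean_nm = row$contour_nm, Lc_sd_nm = row$contour_nm_sd,
    polymer_model = if (is_wlc) "WLC" else "FJC",
    stiffness_length_nm = if (is_wlc) 0.5 else 0.3,
    events_per_curve = if (is_wlc) c(0.5, 0.3, 0.2) else 1
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(force_sim_config, args)
}

#' Generate a synthetic force-volume map
#'
#' Simulates a grid of approach/retract curves over one cell. Each
#' curve's modulus is drawn from the configured Gaussian (truncated
#' > 0); the approach trace is baseline noise before contact and conical
#' Hertz force beyond it, the retract trace is featureless baseline.
#' Identical configurations (including seed) generate identical maps.
#'
#' @param config A [force_sim_config()].
#' @return List with `map` (tibble: `row`, `col`, `curve` list-column of
#'   force-curve tibbles, with bundle metadata in attributes) and
#'   `truth` (tibble of the drawn per-curve modulus and contact point).
#' @export
gen_force_volume <- function(config) {
  .with_seed(config$seed, {
    n <- config$grid_rows * config$grid_cols
    E <- .rnorm_trunc(n, config$E_mean_kPa, config$E_sd_kPa)
    cp <- config$contact_point_nm
    sep_app <- seq(cp + 130, cp - 70, by = -config$sample_step_nm)
    curves <- vector("list", n)
    grid <- expand.grid(
      col = seq_len(config$grid_cols),
      row = seq_len(config$grid_rows)
    )[, c("row", "col")]
    for (i in seq_len(n)) {
      delta <- pmax(cp - sep_app, 0)
      f_app <- hertz_force(delta, E[i], config$tip) +
        rnorm(length(sep_app), 0, config$force_noise_sd_pN)
      f_ret <- rnorm(length(sep_app), 0, config$force_noise_sd_pN)
      curves[[i]] <- tibble(
        segment = rep(c("approach", "retract"), each = length(sep_app)),
        separation_nm = c(sep_app, rev(sep_app)),
        force_pN = c(f_app, f_ret)
      )
    }
    map <- tibble(row = grid$row, col = grid$col, curve = curves)
    attr(map, "meta") <- list(
      spring_constant_N_per_m = config$spring_constant_N_per_m,
      speed_um_s = config$approach_speed_um_s,
      grid_rows = config$grid_rows, grid_cols = config$grid_cols,
      coordinate_mode = "separation"
    )
    truth <- tibble(
      row = grid$row, col = grid$col,
      E_kPa = E, contact_point_nm = cp
    )
    list(map = map, truth = truth)
  })
}

# rupture extension for a polymer fingerprint at a given rupture force
.rupture_extension <- function(model, rupture_force, Lc, s, thermal) {
  if (model == "FJC") {
    fjc_extension(rupture_force, s, Lc, thermal)
  } else {
    uniroot(
      function(x) wlc_force(x, s, Lc, thermal) - rupture_force,
      lower = 1e-9, upper = Lc * (1 - 1e-9), tol = 1e-9
    )$root
  }
}

#' Generate synthetic retract curves with planted adhesion fingerprints
#'
#' Each curve independently carries specific adhesion fingerprints with
#' probability `event_probability`. A fingerprint follows the configured
#' polymer model (negative force on retract, per AFM convention) up to
#' its drawn rupture force, then snaps to baseline; multiple events
#' concatenate with increasing contour length. Gaussian force noise is
#' added throughout.
#'
#' @param config A [force_sim_config()].
#' @param n_curves Number of retract curves to generate.
#' @return List with `curves` (list of retract-trace tibbles with
#'   columns `separation_nm`, `force_pN`, ordered near -> far) and
#'   `truth` (list: `curves` tibble of per-curve event counts, `events`
#'   tibble of planted parameters).
#' @export
gen_retract_curves <- function(config, n_curves) {
  .with_seed(config$seed, {
    sep <- seq(0, config$max_separation_nm, by = config$sample_step_nm)
    weights <- config$events_per_curve / sum(config$events_per_curve)
    curves <- vector("list", n_curves)
    truth_curves <- vector("list", n_curves)
    truth_events <- list()
    for (i in seq_len(n_curves)) {
      force <- rnorm(length(sep), 0, config$force_noise_sd_pN)
      has_event <- runif(1) < config$event_probability
      n_ev <- 0L
      if (has_event) {
        n_ev <- sample.int(length(weights), 1, prob = weights)
        Lc <- sort(.rnorm_trunc(n_ev, config$Lc_mean_nm, config$Lc_sd_nm))
        fr <- .rnorm_trunc(n_ev, config$rupture_force_mean_pN,
                           config$rupture_force_sd_pN)
        x_rupt <- vapply(seq_len(n_ev), function(k) {
          .rupture_extension(config$polymer_model, fr[k], Lc[k],
                             config$stiffness_length_nm, config$thermal)
        }, numeric(1))
        keep <- !duplicated(cummax(x_rupt)) & x_rupt <= max(sep)
        Lc <- Lc[keep]; fr <- fr[keep]; x_rupt <- x_rupt[keep]
        n_ev <- length(Lc)
        prev <- 0
        for (k in seq_len(n_ev)) {
          act <- sep > prev & sep <= x_rupt[k]
          if (any(act)) {
            fmodel <- if (config$polymer_model == "FJC") {
              fjc_force(sep[act], config$stiffness_length_nm, Lc[k],
                        config$thermal)
            } else {
              wlc_force(sep[act], config$stiffness_length_nm, Lc[k],
                        config$thermal)
            }
            force[act] <- force[act] - fmodel
          }
          prev <- x_rupt[k]
          truth_events[[length(truth_events) + 1]] <- tibble(
            curve = i, event = k, Lc_nm = Lc[k],
            stiffness_length_nm = config$stiffness_length_nm,
            rupture_force_pN = fr[k], rupture_x_nm = x_rupt[k]
          )
        }
      }
      curves[[i]] <- tibble(separation_nm = sep, force_pN = force)
      truth_curves[[i]] <- tibble(
        curve = i, has_event = has_event, n_events = n_ev
      )
    }
    list(
      curves = curves,
      truth = list(
        curves = dplyr::bind_rows(truth_curves),
        events = if (length(truth_events)) {
          dplyr::bind_rows(truth_events)
        } else {
          tibble(
            curve = integer(), event = integer(), Lc_nm = numeric(),
            stiffness_length_nm = numeric(), rupture_force_pN = numeric(),
            rupture_x_nm = numeric()
          )
        }
      )
    )
  })
}

#' Configuration for synthetic expression data
#'
#' Emulates a one-colour microarray study: five strains with three
#' biological replicates each, probe-level replicate spots, a 0/1
#' spot-quality weight channel, and planted two-fold (log2 FC = 1)
#' differential-expression effects in the non-reference strains,
#' including a common core shared by all of them.
#'
#' @param n_genes Number of genes (default 6000, approximately a yeast
#'   genome).
#' @param strains Strain names; the first is the reference (default:
#'   the five bundled strains, reference BY4743).
#' @param replicates_per_strain Arrays per strain (default 3).
#' @param n_de_per_strain Planted DE genes per non-reference strain,
#'   including the common core (default 180).
#' @param n_core Planted genes differentially expressed in every
#'   non-reference strain (default 71).
#' @param planted_log2fc Minimum planted effect magnitude on the log2
#'   scale (default 1, i.e. two-fold — the smallest effect the DE filter
#'   is meant to call). Strain-specific effects are drawn uniformly in
#'   \[`planted_log2fc`, `planted_log2fc_max`\].
#' @param planted_log2fc_max Upper bound of planted effect magnitudes
#'   (default 3).
#' @param core_min_log2fc Minimum magnitude for the shared core
#'   (default 2): the cross-strain core emulates strong qualitative
#'   differences (absent gene families, auxotrophic markers), well clear
#'   of the fold-change threshold.
#' @param residual_sd Biological + technical noise SD on the log2 scale
#'   (default 0.25).
#' @param replicate_spots_per_gene Probes per gene (default 2).
#' @param weight_dropout_rate Probability a spot is flagged bad
#'   (weight 0; default 0.02).
#' @param baseline_log2_mean,baseline_log2_sd Gene baseline abundance
#'   distribution on the log2 scale (defaults 10, 1.5).
#' @param seed RNG seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 6000,
                            strains = c("BY4743", "L71", "L62", "L60", "L69"),
                            replicates_per_strain = 3,
                            n_de_per_strain = 180,
                            n_core = 71,
                            planted_log2fc = 1,
                            planted_log2fc_max = 3,
                            core_min_log2fc = 2,
                            residual_sd = 0.25,
                            replicate_spots_per_gene = 2,
                            weight_dropout_rate = 0.02,
                            baseline_log2_mean = 10,
                            baseline_log2_sd = 1.5,
                            seed = 1) {
  stopifnot(
    n_de_per_strain <= n_genes, n_core <= n_de_per_strain,
    weight_dropout_rate >= 0, weight_dropout_rate < 1,
    replicates_per_strain >= 2, length(strains) >= 2
  )
  structure(
    list(
      n_genes = n_genes, strains = strains,
      replicates_per_strain = replicates_per_strain,
      n_de_per_strain = n_de_per_strain, n_core = n_core,
      planted_log2fc = planted_log2fc,
      planted_log2fc_max = planted_log2fc_max,
      core_min_log2fc = core_min_log2fc,
      residual_sd = residual_sd,
      replicate_spots_per_gene = replicate_spots_per_gene,
      weight_dropout_rate = weight_dropout_rate,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      seed = seed
    ),
    class = "expr_sim_config"
  )
}

#' Generate synthetic probe-level expression data
#'
#' @param config An [expr_sim_config()].
#' @return List: `raw` (probes x arrays intensity matrix), `weights`
#'   (0/1 matrix), `probe_map` (tibble `probe_id`, `gene`),
#'   `array_groups` (strain of each array) and `truth` (list:
#'   `de_sets` per non-reference strain, `core`, `effects` tibble of
#'   planted per-strain log2 effects).
#' @export
gen_expression <- function(config) {
  .with_seed(config$seed, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    strains <- config$strains
    reps <- config$replicates_per_strain
    arrays <- paste(
      rep(strains, each = reps), rep(seq_len(reps), length(strains)),
      sep = "_"
    )
    array_groups <- rep(strains, each = reps)
    baseline <- rnorm(config$n_genes, config$baseline_log2_mean,
                      config$baseline_log2_sd)
    names(baseline) <- genes

    # planted DE structure: a shared core plus strain-specific extras
    core <- sample(genes, config$n_core)
    core_effect <- sample(c(-1, 1), config$n_core, replace = TRUE) *
      runif(config$n_core, max(config$core_min_log2fc, config$planted_log2fc),
            config$planted_log2fc_max)
    effects <- matrix(
      0, config$n_genes, length(strains),
      dimnames = list(genes, strains)
    )
    de_sets <- list()
    for (s in strains[-1]) {
      extra <- sample(
        setdiff(genes, core), config$n_de_per_strain - config$n_core
      )
      de <- c(core, extra)
      extra_effect <- sample(c(-1, 1), length(extra), replace = TRUE) *
        runif(length(extra), config$planted_log2fc, config$planted_log2fc_max)
      effects[de, s] <- c(core_effect, extra_effect)
      de_sets[[s]] <- sort(de)
    }

    n_spots <- config$n_genes * config$replicate_spots_per_gene
    probe_map <- tibble(
      probe_id = sprintf(
        "%s_p%d", rep(genes, each = config$replicate_spots_per_gene),
        rep(seq_len(config$replicate_spots_per_gene), config$n_genes)
      ),
      gene = rep(genes, each = config$replicate_spots_per_gene)
    )
    spot_gene <- probe_map$gene
    raw <- matrix(
      NA_real_, n_spots, length(arrays),
      dimnames = list(probe_map$probe_id, arrays)
    )
    for (j in seq_along(arrays)) {
      mu <- baseline[spot_gene] + effects[spot_gene, array_groups[j]]
      raw[, j] <- 2^(mu + rnorm(n_spots, 0, config$residual_sd))
    }
    weights <- matrix(
      rbinom(length(raw), 1, 1 - config$weight_dropout_rate),
      nrow(raw), ncol(raw), dimnames = dimnames(raw)
    )
    # guard: no array may lose every spot
    for (j in which(colSums(weights) == 0)) weights[1, j] <- 1

    effects_tbl <- as_tibble(effects, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "strain",
                          values_to = "log2_effect") |>
      dplyr::filter(.data$log2_effect != 0)
    list(
      raw = raw, weights = weights, probe_map = probe_map,
      array_groups = array_groups,
      truth = list(
        de_sets = de_sets, core = sort(core), effects = effects_tbl
      )
    )
  })
}

#' Generate phenotypes linked to planted gene sets
#'
#' Builds a phenotype block whose columns are noisy linear readouts of
#' designated gene-set mean-expression profiles, emulating latent
#' gene-phenotype correlation structure. Each linked phenotype is the
#' standardized mean profile of its genes plus Gaussian noise of SD
#' 1/`snr`; `links` entries set to `NULL` yield pure-noise decoy
#' phenotypes (zero SNR).
#'
#' @param expr Genes x samples matrix of expression values.
#' @param links Named list: phenotype name -> character vector of gene
#'   names (rows of `expr`), or `NULL` for a decoy phenotype.
#' @param snr Signal-to-noise ratio of linked phenotypes (default 3;
#'   `Inf` = noise-free).
#' @param seed RNG seed.
#' @return List: `Y` (samples x phenotypes matrix) and `truth` (the
#'   `links` list).
#' @export
gen_linked_phenotypes <- function(expr, links, snr = 3, seed = 1) {
  stopifnot(is.matrix(expr))
  unknown <- setdiff(unlist(links), rownames(expr))
  if (length(unknown) > 0) {
    abort(paste(
      "Link references unknown genes:",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  .with_seed(seed, {
    n <- ncol(expr)
    Y <- matrix(
      NA_real_, n, length(links),
      dimnames = list(colnames(expr), names(links))
    )
    for (k in seq_along(links)) {
      if (is.null(links[[k]])) {
        Y[, k] <- rnorm(n)
      } else {
        signal <- colMeans(expr[links[[k]], , drop = FALSE])
        signal <- as.vector(scale(signal))
        noise_sd <- if (is.infinite(snr)) 0 else 1 / snr
        Y[, k] <- signal + rnorm(n, 0, noise_sd)
      }
    }
    list(Y = Y, truth = links)
  })
}
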