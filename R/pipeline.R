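#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end simulated study. Defaults
#' mirror the study design: five strains, 32 x 32 force-volume maps
#' (1,024 indentation curves per cell), single-molecule retract curves
#' per strain, three expression replicates per strain with two-fold
#' planted effects, DE thresholds (fold change >= 2, p < 0.01), and a
#' two-component sPLS with 50 genes kept per component, cut into 4
#' phenotype and 6 gene groups.
#'
#' @param strains Strains to simulate (subset of [strain_presets()]).
#' @param grid_rows,grid_cols Force-volume grid per cell.
#' @param n_retract Retract curves per strain.
#' @param n_genes,replicates,n_de_per_strain,n_core Expression design.
#' @param fc_threshold,p_threshold DE filter thresholds.
#' @param ncomp,keepX sPLS components and genes kept per component.
#' @param k_pheno,k_gene Similarity-map group counts.
#' @param max_polymer_fits Cap on per-strain polymer fits (keeps the
#'   contour-length stage proportionate; `Inf` fits every event).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(strains = c("BY4743", "L71", "L62", "L60", "L69"),
                            grid_rows = 32, grid_cols = 32,
                            n_retract = 1000,
                            n_genes = 6000, replicates = 3,
                            n_de_per_strain = 180, n_core = 71,
                            fc_threshold = 2, p_threshold = 0.01,
                            ncomp = 2, keepX = 50,
                            k_pheno = 4, k_gene = 6,
                            max_polymer_fits = 200,
                            seed = 1) {
  stopifnot(fc_threshold > 0, p_threshold > 0, ncomp >= 1, keepX >= 1)
  structure(
    as.list(environment()),
    class = "pipeline_config"
  )
}

#' Run the simulated end-to-end study
#'
#' Generates synthetic inputs for every configured strain and pushes
#' them through the full analysis: Hertz fits and modal modulus per
#' strain, adhesion-event frequency and contour-length estimates from
#' retract curves (FJC for single-event curves, WLC for multi-event
#' curves), probe-level expression preprocessing, moderated-t
#' differential expression against the first (reference) strain with BH
#' adjustment and fold-change filtering, the cross-strain common DE set,
#' and sPLS integration of expression with the phenotype block,
#' summarised as a correlation circle and a clustered similarity map.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, summary TSVs and a run
#'   manifest are written (atomically) into it.
#' @return A `wallmech_report` list: `per_strain` (tibble of measured
#'   modulus, adhesion frequency and contour length), `phenotypes`
#'   (Table-1-shaped tibble combining preset composition with measured
#'   biophysics), `de` (per-strain result tibbles, filtered sets, common
#'   set), `integration` (sPLS model, correlation circle, similarity
#'   map), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  presets <- strain_presets()
  strains <- config$strains
  stopifnot(all(strains %in% presets$strain), length(strains) >= 2)

  per_strain <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    s <- strains[i]
    fv_cfg <- force_sim_preset(
      s, grid_rows = config$grid_rows, grid_cols = config$grid_cols,
      seed = config$seed + 7919L * i
    )
    fv <- gen_force_volume(fv_cfg)
    hfits <- dplyr::bind_rows(lapply(fv$map$curve, function(cv) {
      fit_hertz(correct_baseline(cv), tip = fv_cfg$tip)
    }))
    mm <- modal_modulus(hfits)

    # single-molecule stage: cantilever noise ~3 pN on soft retract curves
    sm_cfg <- force_sim_preset(s, force_noise_sd_pN = 3,
                               seed = config$seed + 7919L * i + 1L)
    ret <- gen_retract_curves(sm_cfg, config$n_retract)
    freq <- adhesion_frequency(ret$curves)
    pfits <- .with_seed(
      config$seed + 7919L * i + 2L,
      .fit_retract_set(ret$curves, sm_cfg$thermal, config$max_polymer_fits)
    )
    cl <- if (nrow(pfits) > 0) {
      contour_length_distribution(pfits)
    } else {
      list(mean_nm = NA_real_, sd_nm = NA_real_, n_fits = 0L)
    }
    per_strain[[i]] <- tibble(
      strain = s,
      modulus_mode_kPa = mm$mode_kPa,
      modulus_sigma_kPa = mm$sigma_kPa,
      n_hertz_fits = mm$n_fits,
      adhesion_pct = freq,
      contour_mean_nm = cl$mean_nm,
      contour_sd_nm = cl$sd_nm,
      n_polymer_fits = cl$n_fits
    )
  }
  per_strain <- dplyr::bind_rows(per_strain)

  # phenotype table: preset composition + measured biophysics
  pheno <- presets[match(strains, presets$strain), ]
  pheno$stiffness_kPa <- per_strain$modulus_mode_kPa
  pheno$stiffness_kPa_sd <- per_strain$modulus_sigma_kPa
  pheno$adhesion_pct <- per_strain$adhesion_pct
  pheno$contour_nm <- per_strain$contour_mean_nm
  pheno$contour_nm_sd <- per_strain$contour_sd_nm

  # expression + differential expression vs the reference strain
  ex_cfg <- expr_sim_config(
    n_genes = config$n_genes, strains = strains,
    replicates_per_strain = config$replicates,
    n_de_per_strain = config$n_de_per_strain, n_core = config$n_core,
    seed = config$seed + 104729L
  )
  sim <- gen_expression(ex_cfg)
  expr <- preprocess_expression(
    sim$raw, sim$weights, sim$probe_map, sim$array_groups
  )
  ref <- strains[1]
  de_tables <- list()
  de_sets <- list()
  for (s in strains[-1]) {
    res <- moderated_ttest(
      expr[, sim$array_groups == s, drop = FALSE],
      expr[, sim$array_groups == ref, drop = FALSE]
    )
    res$q <- bh_adjust(res$p)
    de_tables[[s]] <- res
    de_sets[[s]] <- de_filter(res, config$fc_threshold, config$p_threshold)
  }
  common <- common_set(de_sets)

  # integration: replicate-level expression vs phenotype block
  X <- center_unit_scale(t(expr))
  Yrep <- as.matrix(pheno[match(sim$array_groups, pheno$strain),
                          setdiff(.pheno_fields, "strain")])
  rownames(Yrep) <- colnames(expr)
  Y <- center_unit_scale(Yrep)
  model <- spls_fit(X, Y, ncomp = config$ncomp, keepX = config$keepX)
  circle <- correlation_circle(model)
  simmap <- similarity_map(model, k_pheno = min(config$k_pheno, ncol(Y)),
                           k_gene = config$k_gene)

  report <- structure(
    list(
      per_strain = per_strain,
      phenotypes = pheno,
      de = list(tables = de_tables, sets = de_sets, common = common),
      integration = list(model = model, circle = circle,
                         similarity = simmap),
      config = config
    ),
    class = "wallmech_report"
  )
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

# classify each retract curve and fit the routed polymer model
.fit_retract_set <- function(curves, thermal, max_fits = Inf) {
  fits <- list()
  for (cv in curves) {
    if (length(fits) >= max_fits) break
    cv <- correct_baseline(cv)
    ev <- detect_adhesion_events(cv)
    cls <- classify_curve(ev)
    if (cls == "none") next
    model <- if (cls == "single") "FJC" else "WLC"
    segs <- extract_event_segments(cv, ev)
    for (seg in segs) {
      f <- tryCatch(
        fit_polymer(seg, model, thermal),
        error = function(e) NULL
      )
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
  }
  dplyr::bind_rows(fits)
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name, units) {
    lines <- c(
      paste0("# units: ", units),
      paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(trimws(format(r, digits = 10)),
                                     collapse = "\t"))
    )
    .write_atomic(lines, file.path(out_dir, name))
  }
  tsv(report$per_strain, "per_strain_summary.tsv",
      "modulus kPa; adhesion %; contour nm")
  write_phenotype_table(report$phenotypes,
                        file.path(out_dir, "phenotypes.tsv"))
  for (s in names(report$de$tables)) {
    tsv(report$de$tables[[s]][, c("gene", "log2_fc", "t_mod", "p", "q")],
        paste0("de_", s, ".tsv"), "log2 fold change; t; p; BH q")
  }
  circ <- report$integration$circle
  tsv(circ, "correlation_circle.tsv", "correlations, dimensionless")
  sm <- report$integration$similarity
  sim_df <- as_tibble(sm$matrix, rownames = "phenotype")
  tsv(sim_df, "similarity_matrix.tsv", "correlation-scale similarity")
  tsv(
    tibble(variable = names(sm$col_groups), group = sm$col_groups),
    "gene_groups.tsv", "cluster index"
  )
  tsv(
    tibble(variable = names(sm$row_groups), group = sm$row_groups),
    "phenotype_groups.tsv", "cluster index"
  )
  manifest <- c(
    paste0("wallmech_version\t",
           as.character(utils::packageVersion("wallmech"))),
    paste0("seed\t", report$config$seed),
    paste0("fc_threshold\t", report$config$fc_threshold),
    paste0("p_threshold\t", report$config$p_threshold),
    paste0("ncomp\t", report$config$ncomp),
    paste0("keepX\t", report$config$keepX),
    paste0("k_pheno\t", report$config$k_pheno),
    paste0("k_gene\t", report$config$k_gene)
  )
  .write_atomic(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.wallmech_report <- function(x, ...) {
  cat("<wallmech_report>\n")
  print(x$per_strain)
  cat(sprintf(
    "DE: %s; common set: %d genes\n",
    paste(sprintf("%s=%d", names(x$de$sets),
                  lengths(x$de$sets)), collapse = ", "),
    length(x$de$common$intersection)
  ))
  invisible(x)
}
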