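# atomic write contract: write to a temp file in the target directory,
# then rename into place, so interrupted runs never leave truncated files
.write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

.fmt_num <- function(x) sprintf("%.10g", x)

#' Write a force-curve bundle
#'
#' Serializes force curves to the plain-text bundle format: header lines
#' `# key<TAB>value`, then per curve a `@curve <row> <col>` marker and
#' `>approach` / `>retract` sections of tab-separated
#' (separation_nm, force_pN) pairs. Writing is atomic and deterministic,
#' so re-writing the result of [read_force_bundle()] reproduces the file
#' byte for byte.
#'
#' @param curves Bundle tibble (`row`, `col`, `curve` list-column) as
#'   produced by [gen_force_volume()], or a plain list of curve tibbles.
#' @param path Output file path.
#' @param meta Named list of header metadata; defaults to the bundle's
#'   `"meta"` attribute.
#' @return `path`, invisibly.
#' @export
write_force_bundle <- function(curves, path, meta = NULL) {
  meta <- meta %||% attr(curves, "meta") %||% list()
  meta$coordinate_mode <- meta$coordinate_mode %||% "separation"
  if (is.data.frame(curves) && "curve" %in% names(curves)) {
    rows <- curves$row
    cols <- curves$col
    curve_list <- curves$curve
  } else {
    curve_list <- .curve_list(curves)
    rows <- seq_along(curve_list)
    cols <- rep(1L, length(curve_list))
  }
  chunks <- list(
    vapply(names(meta), function(key) {
      paste0("# ", key, "\t", .fmt_num_or_chr(meta[[key]]))
    }, character(1))
  )
  for (i in seq_along(curve_list)) {
    cv <- curve_list[[i]]
    segs <- if ("segment" %in% names(cv)) unique(cv$segment) else "retract"
    block <- lapply(segs, function(sg) {
      tr <- .trace(cv, sg)
      c(paste0(">", sg),
        paste(.fmt_num(tr$separation_nm), .fmt_num(tr$force_pN), sep = "\t"))
    })
    chunks[[i + 1]] <- c(sprintf("@curve %d %d", rows[i], cols[i]),
                         unlist(block))
  }
  .write_atomic(unlist(chunks), path)
  invisible(path)
}

.fmt_num_or_chr <- function(x) {
  if (is.numeric(x)) .fmt_num(x) else as.character(x)
}

#' Read a force-curve bundle
#'
#' Parses the bundle grammar written by [write_force_bundle()].
#' Height-mode bundles (`coordinate_mode = height`) are converted to
#' tip-sample separation by subtracting the cantilever deflection
#' (force / spring constant) from the piezo height; this requires the
#' `spring_constant_N_per_m` header. Separation must be strictly
#' monotone within each trace.
#'
#' @param path Bundle file path.
#' @return Tibble (`row`, `col`, `curve` list-column) with the parsed
#'   header in the `"meta"` attribute.
#' @export
read_force_bundle <- function(path) {
  lines <- readLines(path)
  n_lines <- length(lines)
  is_header <- startsWith(lines, "# ")
  is_curve <- startsWith(lines, "@curve")
  is_sect <- startsWith(lines, ">")
  is_blank <- lines == ""
  is_data <- !(is_header | is_curve | is_sect | is_blank)

  meta <- list()
  for (ln in which(is_header)) {
    kv <- strsplit(sub("^# ", "", lines[ln]), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("Malformed header at line %d.", ln))
    num <- suppressWarnings(as.numeric(kv[2]))
    meta[[kv[1]]] <- if (is.na(num)) kv[2] else num
  }

  # parse all data rows at once; locate each row's enclosing section/curve
  data_idx <- which(is_data)
  if (length(data_idx) > 0) {
    parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
    bad_shape <- lengths(parts) != 2
    if (any(bad_shape)) {
      abort(sprintf("Malformed data row at line %d.",
                    data_idx[which(bad_shape)[1]]))
    }
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals)) {
      bad_row <- ceiling(which(is.na(vals))[1] / 2)
      abort(sprintf("Malformed data row at line %d.", data_idx[bad_row]))
    }
    sep_all <- vals[c(TRUE, FALSE)]
    force_all <- vals[c(FALSE, TRUE)]
  } else {
    sep_all <- force_all <- numeric()
  }
  last_curve <- cummax(ifelse(is_curve, seq_len(n_lines), 0L))
  last_sect <- cummax(ifelse(is_sect, seq_len(n_lines), 0L))
  if (length(data_idx) > 0) {
    orphan <- last_sect[data_idx] == 0 | last_sect[data_idx] < last_curve[data_idx]
    if (any(orphan)) {
      abort(sprintf("Data outside a section at line %d.",
                    data_idx[which(orphan)[1]]))
    }
  }

  curves <- list()
  for (cl in which(is_curve)) {
    rc <- suppressWarnings(
      as.integer(strsplit(lines[cl], " ", fixed = TRUE)[[1]][2:3])
    )
    if (anyNA(rc)) abort(sprintf("Malformed @curve marker at line %d.", cl))
    nxt <- which(is_curve & seq_len(n_lines) > cl)
    end <- if (length(nxt)) nxt[1] - 1L else n_lines
    sects <- which(is_sect & seq_len(n_lines) >= cl & seq_len(n_lines) <= end)
    parts <- lapply(sects, function(sl) {
      sg <- sub("^>", "", lines[sl])
      if (!sg %in% c("approach", "retract")) {
        abort(sprintf("Unknown section '%s' at line %d.", sg, sl))
      }
      keep <- data_idx > sl & data_idx <= end & last_sect[data_idx] == sl
      tibble(
        segment = sg,
        separation_nm = sep_all[keep],
        force_pN = force_all[keep]
      )
    })
    curves[[length(curves) + 1]] <- list(
      row = rc[1], col = rc[2], curve = dplyr::bind_rows(parts)
    )
  }

  mode <- meta$coordinate_mode %||% "separation"
  if (mode == "height" && is.null(meta$spring_constant_N_per_m)) {
    abort("Height-mode bundle is missing `spring_constant_N_per_m`.")
  }
  k <- meta$spring_constant_N_per_m
  if (!is.null(k) && (k < 0.005 || k > 0.1)) {
    abort("Spring constant outside the plausible [0.005, 0.1] N/m range.")
  }
  out <- tibble(
    row = vapply(curves, `[[`, integer(1), "row"),
    col = vapply(curves, `[[`, integer(1), "col"),
    curve = lapply(curves, `[[`, "curve")
  )
  out$curve <- lapply(out$curve, function(cv) {
    if (mode == "height") {
      # separation = piezo height - deflection; k [N/m] = 1000 pN/nm
      defl <- cv$force_pN / (meta$spring_constant_N_per_m * 1000)
      cv$separation_nm <- cv$separation_nm - defl
    }
    for (sg in unique(cv$segment)) {
      s <- cv$separation_nm[cv$segment == sg]
      if (any(diff(s) == 0) || !(all(diff(s) > 0) || all(diff(s) < 0))) {
        abort("Separation is not strictly monotone within a trace.")
      }
    }
    cv
  })
  attr(out, "meta") <- meta
  out
}

.pheno_fields <- c(
  "strain", "chitin_pct", "b13_pct", "b16_pct", "mannan_pct",
  "hydrophobicity_pct", "stiffness_kPa", "adhesion_pct", "contour_nm",
  "size_um"
)

#' Read / write a phenotype table TSV
#'
#' One row per strain; header columns `strain chitin_pct b13_pct
#' b16_pct mannan_pct hydrophobicity_pct stiffness_kPa adhesion_pct
#' contour_nm size_um`, with optional `<field>_sd` companions. A leading
#' `#` comment line documents the units.
#'
#' @param path TSV file path.
#' @return `read_phenotype_table()`: tibble of phenotypes.
#' @export
read_phenotype_table <- function(path) {
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE
  )
  missing <- setdiff(.pheno_fields, names(tab))
  if (length(missing) > 0) {
    abort(paste("Phenotype table is missing columns:",
                paste(missing, collapse = ", ")))
  }
  tab
}

#' @rdname read_phenotype_table
#' @param table Phenotype tibble in the [strain_presets()] schema.
#' @export
write_phenotype_table <- function(table, path) {
  header <- paste(
    "# units: composition columns % of cell-wall mass;",
    "hydrophobicity/adhesion %; stiffness kPa; contour nm; size um"
  )
  body <- c(
    paste(names(table), collapse = "\t"),
    apply(table, 1, function(r) paste(trimws(r), collapse = "\t"))
  )
  .write_atomic(c(header, body), path)
  invisible(path)
}

#' Read / write probe-level expression data as TSV
#'
#' Expression values: first column `probe_id`, then one column per array
#' named `<strain>_<replicate>`. The companion weight file shares the
#' shape; the probe map is `probe_id<TAB>gene`.
#'
#' @param values_path,weights_path,probe_map_path TSV paths.
#' @return List `raw`, `weights` (matrices with probe rownames),
#'   `probe_map` (tibble), `array_groups` (strain per array, from the
#'   column names).
#' @export
read_expression_tsv <- function(values_path, weights_path, probe_map_path) {
  vals <- readr::read_tsv(values_path, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  wts <- readr::read_tsv(weights_path, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  pm <- readr::read_tsv(probe_map_path, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  raw <- as.matrix(vals[, -1])
  rownames(raw) <- vals$probe_id
  weights <- as.matrix(wts[, -1])
  rownames(weights) <- wts$probe_id
  list(
    raw = raw, weights = weights, probe_map = pm,
    array_groups = sub("_[^_]+$", "", colnames(raw))
  )
}

#' @rdname read_expression_tsv
#' @param sim Result of [gen_expression()].
#' @param dir Output directory (created if needed).
#' @return `write_expression_tsv()`: named vector of the three paths.
#' @export
write_expression_tsv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    values = file.path(dir, "expression.tsv"),
    weights = file.path(dir, "weights.tsv"),
    probe_map = file.path(dir, "probe_map.tsv")
  )
  mat_lines <- function(m, digits_fun) {
    c(
      paste(c("probe_id", colnames(m)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], digits_fun(m[i, ])), collapse = "\t")
      }, character(1))
    )
  }
  .write_atomic(
    c("# units: raw fluorescence intensity",
      mat_lines(sim$raw, .fmt_num)),
    paths["values"]
  )
  .write_atomic(
    c("# units: 0/1 spot quality weight",
      mat_lines(sim$weights, function(x) sprintf("%d", x))),
    paths["weights"]
  )
  .write_atomic(
    c("probe_id\tgene",
      paste(sim$probe_map$probe_id, sim$probe_map$gene, sep = "\t")),
    paths["probe_map"]
  )
  invisible(paths)
}
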