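#' Octane-adhesion (MATH) hydrophobicity index
#'
#' Percentage of cells partitioning from an aqueous suspension into an
#' apolar solvent, from the optical densities of the aqueous phase before
#' (`A0`) and after (`AF`) octane contact. The default bounded convention
#' is \eqn{100 (A_0 - A_F)/A_0}, which lies in \[0, 100\]; the literal
#' convention \eqn{100 (A_0 - A_F)/A_F} (unbounded as \eqn{A_F \to 0}) is
#' available for comparison.
#'
#' @param A0 Optical density before octane exposure (> 0).
#' @param AF Optical density after octane exposure (0 <= AF <= A0).
#' @param convention `"bounded"` (denominator A0, default) or `"literal"`
#'   (denominator AF).
#' @return Hydrophobicity index in percent.
#' @examples
#' hydrophobicity_index(1.0, 0.6) # 40
#' @export
hydrophobicity_index <- function(A0, AF, convention = c("bounded", "literal")) {
  convention <- match.arg(convention)
  if (any(A0 <= 0)) abort("`A0` must be > 0.")
  if (any(AF < 0) || any(AF > A0)) {
    abort("`AF` must satisfy 0 <= AF <= A0 (octane cannot create cells).")
  }
  denom <- if (convention == "bounded") A0 else AF
  100 * (A0 - AF) / denom
}

#' Proportion of beta-1,6-glucans among total beta-glucans
#'
#' @param b16_pct beta-1,6-glucan content (% of cell-wall mass, >= 0).
#' @param b13_pct beta-1,3-glucan content (% of cell-wall mass, >= 0).
#' @return Fraction b16 / (b16 + b13) in \[0, 1\].
#' @examples
#' glucan_ratio(23.1, 20.4)
#' @export
glucan_ratio <- function(b16_pct, b13_pct) {
  if (any(b16_pct < 0) || any(b13_pct < 0)) {
    abort("Glucan contents must be >= 0.")
  }
  tot <- b16_pct + b13_pct
  if (any(tot == 0)) abort("Total beta-glucan content is zero.")
  b16_pct / tot
}

#' Mannosyl units in a mannan chain of given contour length
#'
#' Converts a fitted contour length to an approximate number of
#' alpha-linked mannosyl units, given the mean size of one mannosyl
#' monomer (about 0.5 nm).
#'
#' @param contour_length_nm Contour length(s) in nm.
#' @param monomer_nm Length of one mannosyl unit in nm (default 0.5).
#' @return Estimated number of monomer units.
#' @examples
#' mannosyl_units(c(100, 20)) # 200, 40
#' @export
mannosyl_units <- function(contour_length_nm, monomer_nm = 0.5) {
  if (monomer_nm <= 0) abort("`monomer_nm` must be > 0.")
  contour_length_nm / monomer_nm
}

#' Reference phenotype table for five S. cerevisiae strains
#'
#' Bundled biochemical and biophysical measurements (mean and SD) for the
#' laboratory strain BY4743 and four industrial strains: cell-wall
#' composition (% of wall mass), surface hydrophobicity (%), cell-wall
#' stiffness (kPa), specific adhesion-event frequency (%), mannan contour
#' length (nm) and cell size (um). These values parameterise the
#' synthetic-data generators' strain presets.
#'
#' @return Tibble, one row per strain, with `<field>` and `<field>_sd`
#'   columns following the phenotype-table schema (see
#'   [read_phenotype_table()]).
#' @export
strain_presets <- function() {
  tibble::tribble(
    ~strain, ~chitin_pct, ~chitin_pct_sd, ~b13_pct, ~b13_pct_sd,
    ~b16_pct, ~b16_pct_sd, ~mannan_pct, ~mannan_pct_sd,
    ~hydrophobicity_pct, ~hydrophobicity_pct_sd,
    ~stiffness_kPa, ~stiffness_kPa_sd, ~adhesion_pct, ~adhesion_pct_sd,
    ~contour_nm, ~contour_nm_sd, ~size_um, ~size_um_sd,
    "BY4743", 4.3, 0.8, 44.7, 2.9, 19.5, 1.3, 33.5, 2.8,
    7.8, 4.2, 483, 61, 8, 1.5, 64.8, 30, 3.8, 0.7,
    "L71", 5.7, 1.1, 30.8, 2.2, 29.4, 1.7, 32.3, 1.3,
    25.1, 5.3, 637, 178, 25, 6, 20, 14.7, 5.0, 1.2,
    "L62", 9.9, 1.1, 20.4, 1.9, 23.1, 2.7, 46.5, 1.3,
    23.8, 9.7, 239, 52, 33, 4, 52.6, 13, 3.8, 0.9,
    "L60", 4.5, 0.7, 19.6, 5.4, 24.1, 4.7, 46.5, 3.7,
    23.1, 6.8, 438, 64, 28, 4, 25.1, 4.3, 4.4, 1.0,
    "L69", 3.9, 1.0, 34.1, 3.6, 18.8, 3.1, 43.5, 2.5,
    45.6, 5.7, 230, 82, 21, 2, 96.9, 8.3, 4.2, 1.1
  )
}

#' Validate a phenotype table against its invariants
#'
#' Checks every strain row: percentages within \[0, 100\], SD columns
#' non-negative, and the cell-wall composition sum
#' (chitin + beta-1,3 + beta-1,6 + mannan) within \[90, 110\]% of wall
#' mass.
#'
#' @param table Phenotype tibble in the [strain_presets()] schema.
#' @return Tibble of violations (`strain`, `field`, `problem`); zero rows
#'   when the table is valid.
#' @examples
#' validate_phenotype_table(strain_presets()) # no violations
#' @export
validate_phenotype_table <- function(table) {
  pct_fields <- c(
    "chitin_pct", "b13_pct", "b16_pct", "mannan_pct",
    "hydrophobicity_pct", "adhesion_pct"
  )
  viols <- list()
  note <- function(strain, field, problem) {
    viols[[length(viols) + 1]] <<- tibble(
      strain = strain, field = field, problem = problem
    )
  }
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    strain <- as.character(row$strain %||% i)
    for (f in intersect(pct_fields, names(table))) {
      v <- row[[f]]
      if (is.finite(v) && (v < 0 || v > 100)) {
        note(strain, f, sprintf("%.1f outside [0, 100]", v))
      }
    }
    for (f in grep("_sd$", names(table), value = TRUE)) {
      v <- row[[f]]
      if (is.finite(v) && v < 0) note(strain, f, "negative SD")
    }
    comp_fields <- c("chitin_pct", "b13_pct", "b16_pct", "mannan_pct")
    if (all(comp_fields %in% names(table))) {
      s <- sum(vapply(comp_fields, function(f) row[[f]], numeric(1)))
      if (is.finite(s) && (s < 90 || s > 110)) {
        note(strain, "composition_sum", sprintf("%.1f outside [90, 110]", s))
      }
    }
    for (f in intersect(
      c("stiffness_kPa", "contour_nm", "size_um"), names(table)
    )) {
      v <- row[[f]]
      if (is.finite(v) && v <= 0) note(strain, f, "non-positive value")
    }
  }
  if (length(viols) == 0) {
    tibble(strain = character(), field = character(), problem = character())
  } else {
    dplyr::bind_rows(viols)
  }
}
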