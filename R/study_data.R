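#' ELISA detection limits and assay scales
#'
#' Cytokine concentrations below the ELISA detection limit are left-censored:
#' 15.625 pg/ml for TNF-alpha and 156.25 pg/ml for IL-10. The CCK-8
#' viability read-out (relative absorbance) has no detection limit in this
#' data model.
#'
#' @return named numeric vector of lower detection limits per analyte.
#' @export
detection_limits <- function() {
  c(TNFa = 15.625, IL10 = 156.25, viability = -Inf)
}

analyte_levels <- function() c("TNFa", "IL10", "viability")

fraction_levels <- function() {
  c("GOS", "GOS/FOS", "GOS/FOS/AOS", "glucose/lactose")
}

#' The catalogue of incubation conditions
#'
#' Full cross of LPS challenge (0 or 1 ug/ml) with the three
#' oligosaccharide fractions and the matched glucose/lactose control, each
#' at 0.5, 1 and 2% w/v total oligosaccharide (the control matched to the
#' sugar content of the corresponding GOS dose), plus the blank and
#' LPS-alone conditions. Doses are derived from the incubation compositions
#' of [default_incubation_compositions()], so the catalogue and the
#' formulation arithmetic agree by construction.
#'
#' Dose columns used as model covariates are the % w/v concentrations of
#' each oligosaccharide component separately (`gos_pct`, `fos_pct`,
#' `aos_pct`), e.g. "GOS/FOS/AOS 2%" has gos 1.5, fos 0.1667, aos 0.3333.
#'
#' @return data.frame with one row per condition: `label`, `arm`
#'   (`blank`, `oligosaccharide` or `sugar_control`), `fraction`,
#'   `conc_pct` (total oligosaccharide % of the series), `lps_ug_per_ml`,
#'   `gos_pct`, `fos_pct`, `aos_pct`, `glucose_mg_per_ml`,
#'   `lactose_mg_per_ml`.
#' @export
default_condition_catalogue <- function() {
  comps2 <- default_incubation_compositions()
  base <- data.frame(
    label = c("blank", "LPS"),
    arm = "blank", fraction = NA_character_, conc_pct = NA_real_,
    lps_ug_per_ml = c(0, 1),
    gos_pct = 0, fos_pct = 0, aos_pct = 0,
    glucose_mg_per_ml = 0, lactose_mg_per_ml = 0,
    stringsAsFactors = FALSE
  )
  rows <- list(base)
  for (frac in fraction_levels()) {
    comp2 <- comps2[[paste(frac, "2%")]]
    for (conc in c(0.5, 1, 2)) {
      comp <- dilute(comp2, 2 / conc)
      oligo <- function(nm) {
        if (nm %in% names(comp$oligo_mg)) comp$oligo_mg[[nm]] / 100 else 0
      }
      for (lps in c(0, 1)) {
        lbl <- paste0(if (lps > 0) "LPS + " else "", frac, " ",
                      format(conc, drop0trailing = TRUE), "%")
        rows[[length(rows) + 1L]] <- data.frame(
          label = lbl,
          arm = if (frac == "glucose/lactose") "sugar_control" else "oligosaccharide",
          fraction = frac, conc_pct = conc, lps_ug_per_ml = lps,
          gos_pct = oligo("GOS"), fos_pct = oligo("FOS"),
          aos_pct = oligo("AOS"),
          glucose_mg_per_ml = comp$glucose_mg / 10,
          lactose_mg_per_ml = comp$lactose_mg / 10,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study design: horses, arms, conditions, replication
#'
#' Three experimental arms drew on different donor horses: five horses for
#' the oligosaccharide-fraction experiments, four for the glucose/lactose
#' control experiments and three for the cell-viability assays. Every
#' incubation was run in triplicate or quadruplicate wells per horse.
#'
#' @param n_oligo,n_sugar,n_viability horses per arm (defaults 5, 4, 3).
#' @param replicates wells per horse x condition, 3 or 4 (default 3).
#' @param catalogue condition catalogue, default
#'   [default_condition_catalogue()].
#' @return object of class `study_design`: `horses` (data.frame `horse_id`,
#'   `arm`), `catalogue`, `detection_limits`, `replicates`.
#' @export
study_design <- function(n_oligo = 5, n_sugar = 4, n_viability = 3,
                         replicates = 3,
                         catalogue = default_condition_catalogue()) {
  stopifnot(replicates %in% c(3, 4), n_oligo >= 0, n_sugar >= 0,
            n_viability >= 0)
  horses <- data.frame(
    horse_id = c(sprintf("O%d", seq_len(n_oligo)),
                 sprintf("S%d", seq_len(n_sugar)),
                 sprintf("V%d", seq_len(n_viability))),
    arm = rep(c("oligosaccharide", "sugar_control", "viability"),
              c(n_oligo, n_sugar, n_viability)),
    stringsAsFactors = FALSE
  )
  structure(list(horses = horses, catalogue = catalogue,
                 detection_limits = detection_limits(),
                 replicates = replicates),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>", nrow(x$horses), "horses (",
      paste(names(table(x$horses$arm)), table(x$horses$arm),
            collapse = ", "), ")\n")
  cat("  ", nrow(x$catalogue), " conditions, ", x$replicates,
      " replicate wells\n", sep = "")
  invisible(x)
}

# Conditions measured in a given arm: cytokine arms share blank + LPS-alone;
# the viability arm covers the full catalogue.
conditions_for_arm <- function(catalogue, arm) {
  switch(arm,
    oligosaccharide = catalogue[catalogue$arm %in% c("blank", "oligosaccharide"), ],
    sugar_control = catalogue[catalogue$arm %in% c("blank", "sugar_control"), ],
    viability = catalogue,
    stop("unknown arm: ", arm)
  )
}

plate_columns <- function() {
  c("horse_id", "condition", "analyte", "replicate", "value",
    "below_detection")
}

#' Read a plate-level measurement CSV
#'
#' Schema (documented, fixed): columns `horse_id`, `condition`, `analyte`
#' (`TNFa`/`IL10`/`viability`), `replicate`, `value` (pg/ml for cytokines,
#' relative absorbance for viability), `below_detection` (logical). Rows
#' flagged `below_detection` retain the analyte's detection limit in
#' `value` as the censoring bound.
#'
#' @param path CSV file path.
#' @param catalogue condition catalogue the labels must belong to.
#' @return object of class `plate_data`: list with `wells` (validated
#'   data.frame), `horses`, and `n_censored` per analyte.
#' @export
read_plate_csv <- function(path, catalogue = default_condition_catalogue()) {
  if (!file.exists(path)) stop("no such file: ", path)
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(wells) == 0) stop("plate file '", path, "' contains no rows")
  missing_cols <- setdiff(plate_columns(), names(wells))
  if (length(missing_cols)) {
    stop("plate file '", path, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  wells <- wells[plate_columns()]
  wells$below_detection <- as.logical(wells$below_detection)
  validate_wells(wells, catalogue)
  lim <- detection_limits()
  cens <- wells$below_detection
  wells$value[cens] <- lim[wells$analyte[cens]]
  structure(list(
    wells = wells,
    horses = sort(unique(wells$horse_id)),
    n_censored = tapply(wells$below_detection, wells$analyte, sum)
  ), class = "plate_data")
}

validate_wells <- function(wells, catalogue) {
  rowid <- seq_len(nrow(wells))
  bad <- !(wells$condition %in% catalogue$label)
  if (any(bad)) {
    stop("unknown condition label(s) ",
         paste(unique(wells$condition[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(rowid[bad], 5), collapse = ", "))
  }
  bad <- !(wells$analyte %in% analyte_levels())
  if (any(bad)) {
    stop("unknown analyte(s) ", paste(unique(wells$analyte[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(rowid[bad], 5), collapse = ", "))
  }
  bad <- !wells$below_detection & (!is.finite(wells$value) | wells$value <= 0)
  if (any(bad)) {
    stop("non-positive or missing value without below_detection flag at row(s) ",
         paste(utils::head(rowid[bad], 5), collapse = ", "))
  }
  lim <- detection_limits()
  bad <- !wells$below_detection & wells$value < lim[wells$analyte]
  if (any(bad)) {
    stop("value below the analyte detection limit but not flagged ",
         "below_detection at row(s) ",
         paste(utils::head(rowid[bad], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write plate-level measurements to CSV
#'
#' @param wells data.frame in the plate schema (see [read_plate_csv()]), or
#'   a `plate_data` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  if (inherits(wells, "plate_data")) wells <- wells$wells
  utils::write.csv(wells[plate_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Write condition summaries and contrasts to a CSV report
#'
#' One file holding both blocks, distinguished by a `type` column:
#' `summary` rows carry the point estimate and 95% credible bounds (1
#' decimal on the pg/ml scale, 3 decimals for relative viability);
#' `contrast` rows carry the signed integer percent change, the 95% ratio
#' interval and the significance mark.
#'
#' @param summaries data.frame from [summarize_conditions()].
#' @param contrasts data.frame of contrasts (may be `NULL` or empty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, contrasts, path) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("summaries must be non-empty")
  }
  dec <- ifelse(summaries$analyte == "viability", 3, 1)
  out <- data.frame(
    type = "summary",
    condition = summaries$condition,
    analyte = summaries$analyte,
    point_estimate = round_half_away(summaries$point_estimate, dec),
    lower = round_half_away(summaries$lower, dec),
    upper = round_half_away(summaries$upper, dec),
    reference = NA_character_,
    percent_change = NA_real_,
    ratio_lower = NA_real_,
    ratio_upper = NA_real_,
    significant = NA,
    stringsAsFactors = FALSE
  )
  if (!is.null(contrasts) && nrow(contrasts) > 0) {
    out <- rbind(out, data.frame(
      type = "contrast",
      condition = contrasts$condition,
      analyte = contrasts$analyte,
      point_estimate = NA_real_, lower = NA_real_, upper = NA_real_,
      reference = contrasts$reference,
      percent_change = contrasts$percent_change,
      ratio_lower = round_half_away(contrasts$ratio_lower, 3),
      ratio_upper = round_half_away(contrasts$ratio_upper, 3),
      significant = contrasts$significant,
      stringsAsFactors = FALSE
    ))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a summary/contrast CSV written by [write_summary_csv()]
#'
#' @param path CSV path.
#' @return list with `summaries` and `contrasts` data.frames.
#' @export
read_summary_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(
    summaries = x[x$type == "summary",
                  c("condition", "analyte", "point_estimate", "lower", "upper")],
    contrasts = x[x$type == "contrast",
                  c("condition", "reference", "analyte", "percent_change",
                    "ratio_lower", "ratio_upper", "significant")]
  )
}
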