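#' Commercial carbohydrate product composition
#'
#' The oligosaccharide fractions used in the incubation experiments are
#' commercial products that carry mono- and disaccharides, maltodextrin and
#' moisture alongside the oligosaccharide of interest. A `product_spec`
#' records the declared mass fractions of one such product.
#'
#' @param name product name.
#' @param oligo_fraction mass fraction of the oligosaccharide itself.
#' @param glucose_fraction,lactose_fraction,maltodextrin_fraction,monomer_fraction,moisture_fraction
#'   mass fractions of the co-carried components (default 0).
#' @return an object of class `product_spec`.
#' @examples
#' product_spec("GOS syrup", 0.45, glucose_fraction = 0.14,
#'              lactose_fraction = 0.16, moisture_fraction = 0.25)
#' @export
product_spec <- function(name, oligo_fraction, glucose_fraction = 0,
                         lactose_fraction = 0, maltodextrin_fraction = 0,
                         monomer_fraction = 0, moisture_fraction = 0) {
  fr <- c(oligo = oligo_fraction, glucose = glucose_fraction,
          lactose = lactose_fraction, maltodextrin = maltodextrin_fraction,
          monomer = monomer_fraction, moisture = moisture_fraction)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    stop("product '", name, "': all mass fractions must be finite and >= 0")
  }
  if (sum(fr) > 1 + 1e-6) {
    stop("product '", name, "': mass fractions sum to ", sum(fr),
         " which exceeds 1")
  }
  structure(list(name = name, fractions = fr), class = "product_spec")
}

#' @export
print.product_spec <- function(x, ...) {
  cat("<product_spec>", x$name, "\n")
  fr <- x$fractions[x$fractions > 0]
  cat(paste0("  ", names(fr), ": ", format(100 * fr), "%", collapse = "\n"),
      "\n")
  invisible(x)
}

#' Default commercial products behind the three oligosaccharide fractions
#'
#' GOS syrup: ~45% GOS, 14% glucose, 16% lactose, 25% water.
#' Long-chain FOS: ~96.5% FOS, 3.5% maltodextrin.
#' Pectin-derived AOS: ~85.5% AOS, 7.25% monomers, 7.25% moisture.
#'
#' @return named list of [product_spec()] objects (`GOS`, `FOS`, `AOS`).
#' @export
default_products <- function() {
  list(
    GOS = product_spec("GOS syrup (dp 2-6)", 0.45,
                       glucose_fraction = 0.14, lactose_fraction = 0.16,
                       moisture_fraction = 0.25),
    FOS = product_spec("long-chain FOS (dp >= 23)", 0.965,
                       maltodextrin_fraction = 0.035),
    AOS = product_spec("pectin-derived AOS (dp 1-20)", 0.855,
                       monomer_fraction = 0.0725,
                       moisture_fraction = 0.0725)
  )
}

#' Split a total oligosaccharide mass across components by ratio
#'
#' The mixed fractions are specified by oligosaccharide-content ratios
#' (GOS:FOS = 9:1, GOS:FOS:AOS = 9:1:2); targets are per-10-ml
#' oligosaccharide masses, not product masses.
#'
#' @param total_mg total oligosaccharide mass per 10 ml of medium.
#' @param ratio named numeric ratio, e.g. `c(GOS = 9, FOS = 1, AOS = 2)`.
#' @return named vector of per-component oligosaccharide target masses (mg).
#' @examples
#' oligo_targets(200, c(GOS = 9, FOS = 1, AOS = 2))  # 150, 16.67, 33.33
#' @export
oligo_targets <- function(total_mg, ratio) {
  stopifnot(total_mg >= 0, all(ratio > 0), !is.null(names(ratio)))
  total_mg * ratio / sum(ratio)
}

#' Compose an incubation mixture from product specifications
#'
#' Given target oligosaccharide masses (mg per 10 ml of medium) for each
#' component, computes the required mass of each commercial product
#' (target / oligo fraction) and the mono-/disaccharide, maltodextrin and
#' monomer masses that the products co-carry.
#'
#' @param target_oligo_mg named numeric vector of target oligosaccharide
#'   masses in mg per 10 ml, e.g. `c(GOS = 200)`; names must match
#'   `products`.
#' @param products named list of [product_spec()] (default
#'   [default_products()]).
#' @return an object of class `incubation_composition`: per-10-ml masses in
#'   mg (`oligo_mg` by component, `glucose_mg`, `lactose_mg`,
#'   `maltodextrin_mg`, `monomer_mg`, `product_mg` by component) and the
#'   total oligosaccharide concentration `total_oligo_pct` in % w/v.
#' @examples
#' comp <- compose_incubation(c(GOS = 200))
#' round_half_away(comp$glucose_mg, 2)  # 62.22
#' @export
compose_incubation <- function(target_oligo_mg, products = default_products()) {
  stopifnot(is.numeric(target_oligo_mg))
  if (length(target_oligo_mg) && is.null(names(target_oligo_mg))) {
    stop("target oligosaccharide masses must be named by component")
  }
  if (any(target_oligo_mg < 0)) stop("target masses must be >= 0")
  co <- c(glucose = 0, lactose = 0, maltodextrin = 0, monomer = 0)
  oligo <- numeric(0)
  product_mg <- numeric(0)
  for (comp in names(target_oligo_mg)) {
    tgt <- target_oligo_mg[[comp]]
    spec <- products[[comp]]
    if (is.null(spec) || spec$fractions[["oligo"]] <= 0) {
      stop("component '", comp,
           "' has no product with a positive oligosaccharide fraction")
    }
    pm <- tgt / spec$fractions[["oligo"]]
    oligo[comp] <- tgt
    product_mg[comp] <- pm
    for (k in names(co)) co[k] <- co[k] + pm * spec$fractions[[k]]
  }
  structure(list(
    oligo_mg = oligo,
    glucose_mg = unname(co["glucose"]),
    lactose_mg = unname(co["lactose"]),
    maltodextrin_mg = unname(co["maltodextrin"]),
    monomer_mg = unname(co["monomer"]),
    product_mg = product_mg,
    total_oligo_pct = sum(oligo) / 100  # mg per 10 ml -> g per 100 ml
  ), class = "incubation_composition")
}

#' @export
print.incubation_composition <- function(x, ...) {
  cat("<incubation_composition> ", format(x$total_oligo_pct),
      "% w/v oligosaccharides (per 10 ml)\n", sep = "")
  if (length(x$oligo_mg)) {
    cat(paste0("  ", names(x$oligo_mg), ": ",
               round_half_away(x$oligo_mg, 2), " mg", collapse = "\n"), "\n")
  }
  co <- c(glucose = x$glucose_mg, lactose = x$lactose_mg,
          maltodextrin = x$maltodextrin_mg, monomer = x$monomer_mg)
  co <- co[co > 0]
  if (length(co)) {
    cat(paste0("  + ", names(co), ": ", round_half_away(co, 2), " mg",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Dilute an incubation composition
#'
#' Lower-strength solutions are obtained by diluting the 2% stock in
#' supplemented medium; every mass and the % w/v concentration scale down by
#' the same factor.
#'
#' @param comp an `incubation_composition`.
#' @param factor dilution factor, >= 1 (1:1 dilution = factor 2).
#' @return the diluted `incubation_composition`.
#' @export
dilute <- function(comp, factor) {
  stopifnot(inherits(comp, "incubation_composition"))
  if (!is.finite(factor) || factor < 1) {
    stop("dilution factor must be >= 1: concentration cannot increase by dilution")
  }
  for (f in c("oligo_mg", "glucose_mg", "lactose_mg", "maltodextrin_mg",
              "monomer_mg", "product_mg", "total_oligo_pct")) {
    comp[[f]] <- comp[[f]] / factor
  }
  comp
}

#' One Limulus-assay endotoxin measurement
#'
#' @param solution_label solution measured (e.g. `"GOS/FOS 1%"`).
#' @param concentration_pct solids concentration of the measured solution
#'   (% w/v), > 0.
#' @param endotoxin measured activity in EU/ml, >= 0. The assay's
#'   quantifiable window is 0.1-1 EU/ml per dilution.
#' @param sd optional standard deviation (EU/ml).
#' @return object of class `endotoxin_measurement`.
#' @export
endotoxin_measurement <- function(solution_label, concentration_pct,
                                  endotoxin, sd = NA_real_) {
  stopifnot(is.finite(concentration_pct), is.finite(endotoxin))
  if (endotoxin < 0) stop("endotoxin activity must be >= 0")
  if (concentration_pct <= 0) stop("solution concentration must be > 0")
  structure(list(solution_label = solution_label,
                 concentration_pct = concentration_pct,
                 endotoxin = endotoxin, sd = sd),
            class = "endotoxin_measurement")
}

#' Reported endotoxin measurements of the applied solutions
#'
#' GOS was measured directly at 2%; the GOS/FOS and GOS/FOS/AOS values were
#' measured in the 1% solutions (to stay inside the assay's 0.1-1 EU/ml
#' window) and extrapolated to 2%.
#'
#' @return named list of [endotoxin_measurement()] objects.
#' @export
default_endotoxin_measurements <- function() {
  list(
    GOS = endotoxin_measurement("GOS 2%", 2, 0.24, sd = 0.02),
    `GOS/FOS` = endotoxin_measurement("GOS/FOS 1%", 1, 0.53, sd = 0.07),
    `GOS/FOS/AOS` = endotoxin_measurement("GOS/FOS/AOS 1%", 1, 0.96, sd = 0.07)
  )
}

#' Extrapolate an endotoxin measurement to another solids concentration
#'
#' Endotoxin is carried by the carbohydrate solids, so activity scales
#' linearly with the solids concentration.
#'
#' @param measured an [endotoxin_measurement()].
#' @param target_pct target solids concentration (% w/v).
#' @return extrapolated activity in EU/ml.
#' @examples
#' m <- endotoxin_measurement("GOS/FOS 1%", 1, 0.53)
#' extrapolate_endotoxin(m, 2)  # 1.06
#' @export
extrapolate_endotoxin <- function(measured, target_pct) {
  stopifnot(inherits(measured, "endotoxin_measurement"))
  if (measured$concentration_pct <= 0) {
    stop("measured solution concentration must be > 0")
  }
  measured$endotoxin * target_pct / measured$concentration_pct
}

#' Convert endotoxin activity to the reported LPS mass-concentration range
#'
#' The LPS manufacturer's equivalence is 1 ng LPS = 5-10 EU. Note the
#' reported ng/ml ranges multiply EU/ml by 5 and 10 (e.g. 0.24 EU/ml is
#' reported as 1.20-2.40 ng/ml) although the stated equivalence, read
#' literally, would divide; this function reproduces the published
#' convention deliberately and does not "correct" it.
#'
#' @param eu_per_ml endotoxin activity, EU/ml, >= 0.
#' @param eu_per_ng_low,eu_per_ng_high the equivalence bounds (default 5
#'   and 10 EU per ng).
#' @return named numeric `c(low, high)` in ng/ml.
#' @examples
#' eu_to_ng_range(0.24)  # 1.2 2.4
#' @export
eu_to_ng_range <- function(eu_per_ml, eu_per_ng_low = 5, eu_per_ng_high = 10) {
  if (!is.finite(eu_per_ml) || eu_per_ml < 0) {
    stop("endotoxin activity must be finite and >= 0")
  }
  c(low = eu_per_ml * eu_per_ng_low, high = eu_per_ml * eu_per_ng_high)
}

#' Compositions of the applied 2% incubation solutions
#'
#' The three oligosaccharide fractions at 2% w/v total oligosaccharide
#' (200 mg per 10 ml of medium) and the matched glucose/lactose control,
#' whose sugar content corresponds to the GOS fraction (the fraction with
#' the highest mono-/disaccharide load).
#'
#' @param products product specifications, default [default_products()].
#' @return named list of `incubation_composition` objects
#'   (`"GOS 2%"`, `"GOS/FOS 2%"`, `"GOS/FOS/AOS 2%"`, `"glucose/lactose 2%"`).
#' @export
default_incubation_compositions <- function(products = default_products()) {
  gos <- compose_incubation(c(GOS = 200), products)
  gf <- compose_incubation(oligo_targets(200, c(GOS = 9, FOS = 1)), products)
  gfa <- compose_incubation(oligo_targets(200, c(GOS = 9, FOS = 1, AOS = 2)),
                            products)
  ctrl <- compose_incubation(numeric(0), products)
  ctrl$glucose_mg <- gos$glucose_mg
  ctrl$lactose_mg <- gos$lactose_mg
  list(`GOS 2%` = gos, `GOS/FOS 2%` = gf, `GOS/FOS/AOS 2%` = gfa,
       `glucose/lactose 2%` = ctrl)
}

#' Tabulate incubation compositions (per 10 ml of medium)
#'
#' Produces the per-10-ml composition table of the applied solutions, every
#' mass rounded half-away-from-zero to 2 decimals as reported.
#'
#' @param compositions named list of `incubation_composition` objects,
#'   default [default_incubation_compositions()].
#' @return data.frame with one row per solution: oligosaccharide masses by
#'   component, glucose, lactose, maltodextrin and monomer masses (mg).
#' @export
incubation_table <- function(compositions = default_incubation_compositions()) {
  rows <- lapply(names(compositions), function(lbl) {
    comp <- compositions[[lbl]]
    g <- function(x, nm) if (nm %in% names(x)) x[[nm]] else 0
    data.frame(
      incubation = lbl,
      gos_mg = round_half_away(g(comp$oligo_mg, "GOS"), 2),
      fos_mg = round_half_away(g(comp$oligo_mg, "FOS"), 2),
      aos_mg = round_half_away(g(comp$oligo_mg, "AOS"), 2),
      maltodextrin_mg = round_half_away(comp$maltodextrin_mg, 2),
      monomer_mg = round_half_away(comp$monomer_mg, 2),
      glucose_mg = round_half_away(comp$glucose_mg, 2),
      lactose_mg = round_half_away(comp$lactose_mg, 2),
      total_oligo_pct = comp$total_oligo_pct,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
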