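#' Pooled posterior draws of a condition's expected response
#'
#' Extracts the saved draws of one condition's cell-mean coefficient
#' (expected log response) across all chains and returns them
#' exponentiated, i.e. on the pg/ml (or relative viability) scale.
#'
#' @param draws a [run_chains()] result.
#' @param condition condition label.
#' @return numeric vector of pooled draws on the response scale.
#' @export
condition_draws <- function(draws, condition) {
  stopifnot(inherits(draws, "posterior_draws"))
  par <- paste0("beta[", condition, "]")
  if (!par %in% draws$parameters) {
    stop("condition '", condition, "' has no cell-mean parameter in the fit")
  }
  exp(as.vector(draws$samples[, , par]))
}

#' Summarise one condition: point estimate and 95% credible interval
#'
#' The point estimate is the posterior median of the exponentiated cell
#' mean; the bounds are its 2.5% and 97.5% posterior percentiles. Because
#' percentiles commute with the (monotone) exponential, these equal the
#' exponentiated log-scale percentiles.
#'
#' @inheritParams condition_draws
#' @return one-row data.frame: `condition`, `analyte`, `point_estimate`,
#'   `lower`, `upper` (response scale).
#' @export
summarize_condition <- function(draws, condition) {
  d <- condition_draws(draws, condition)
  q <- exp(stats::quantile(log(d), c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(condition = condition, analyte = draws$analyte,
             point_estimate = q[1], lower = q[2], upper = q[3],
             stringsAsFactors = FALSE)
}

#' Summarise every condition in a fit
#'
#' @inheritParams condition_draws
#' @param conditions condition labels (default: all in the fit).
#' @return data.frame, one row per condition (see [summarize_condition()]).
#' @export
summarize_conditions <- function(draws, conditions = draws$condition_labels) {
  out <- do.call(rbind, lapply(conditions,
                               function(cc) summarize_condition(draws, cc)))
  rownames(out) <- NULL
  out
}

#' Percent change between two point estimates
#'
#' `100 * (a/b - 1)`, rounded to the nearest integer (ties away from
#' zero); negative values are reductions.
#'
#' @param a point estimate of the condition of interest, > 0.
#' @param b reference point estimate, > 0.
#' @return signed integer percent change.
#' @examples
#' percent_change(35.5, 24.9)   # +43
#' percent_change(61.4, 133.5)  # -54
#' @export
percent_change <- function(a, b) {
  if (!all(is.finite(c(a, b))) || any(c(a, b) <= 0)) {
    stop("percent change requires positive finite point estimates")
  }
  as.integer(round_half_away(100 * (a / b - 1)))
}

#' Contrast two conditions on the ratio scale
#'
#' Per-draw ratio of the exponentiated cell means; the contrast is
#' significant iff the 95% credible interval of the ratio excludes 1
#' (equivalently, the log-ratio interval excludes 0). The percent change
#' is computed from the two conditions' summary point estimates.
#'
#' @inheritParams condition_draws
#' @param condition,reference the two condition labels (numerator,
#'   denominator); must differ.
#' @return one-row data.frame: `condition`, `reference`, `analyte`,
#'   `percent_change`, `ratio`, `ratio_lower`, `ratio_upper`,
#'   `significant`.
#' @export
compare <- function(draws, condition, reference) {
  if (identical(condition, reference)) {
    stop("cannot contrast a condition with itself")
  }
  da <- condition_draws(draws, condition)
  db <- condition_draws(draws, reference)
  ratio <- da / db
  q <- exp(stats::quantile(log(ratio), c(0.5, 0.025, 0.975), names = FALSE))
  pc <- percent_change(stats::median(da), stats::median(db))
  data.frame(condition = condition, reference = reference,
             analyte = draws$analyte, percent_change = pc,
             ratio = q[1], ratio_lower = q[2], ratio_upper = q[3],
             significant = q[2] > 1 || q[3] < 1,
             stringsAsFactors = FALSE)
}

#' Cell viability relative to blank controls
#'
#' Per-draw ratio of a condition's cell mean to the blank cell mean in the
#' viability model; a significant increase means the 2.5% bound of the
#' ratio exceeds 1.
#'
#' @inheritParams condition_draws
#' @param condition condition label.
#' @param blank label of the blank condition (default `"blank"`).
#' @return one-row data.frame: `condition`, `analyte`, `point_estimate`
#'   (relative viability), `lower`, `upper`, `significant_increase`.
#' @export
viability_relative <- function(draws, condition, blank = "blank") {
  if (!paste0("beta[", blank, "]") %in% draws$parameters) {
    stop("the fit contains no blank condition to take ratios against")
  }
  ratio <- condition_draws(draws, condition) / condition_draws(draws, blank)
  q <- exp(stats::quantile(log(ratio), c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(condition = condition, analyte = draws$analyte,
             point_estimate = q[1], lower = q[2], upper = q[3],
             significant_increase = q[2] > 1,
             stringsAsFactors = FALSE)
}

# The reporting conventions for marking significance: every condition is
# contrasted against its challenge reference (blank when unchallenged,
# LPS-alone when challenged) and against the next-lower concentration of
# the same fraction in the same challenge state.
standard_contrast_pairs <- function(conditions,
                                    catalogue = default_condition_catalogue()) {
  rows <- catalogue[match(conditions, catalogue$label), , drop = FALSE]
  pairs <- list()
  add <- function(a, b, kind) {
    if (a %in% conditions && b %in% conditions && a != b) {
      pairs[[length(pairs) + 1L]] <<- data.frame(condition = a, reference = b,
                                                 kind = kind,
                                                 stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(rows))) {
    if (rows$arm[i] == "blank") next
    ref <- if (rows$lps_ug_per_ml[i] > 0) "LPS" else "blank"
    add(rows$label[i], ref, "vs_reference")
    concs <- sort(unique(rows$conc_pct[!is.na(rows$conc_pct)]))
    pos <- match(rows$conc_pct[i], concs)
    if (!is.na(pos) && pos > 1) {
      lower <- rows$label[rows$fraction %in% rows$fraction[i] &
                            rows$lps_ug_per_ml == rows$lps_ug_per_ml[i] &
                            rows$conc_pct %in% concs[pos - 1]]
      if (length(lower) == 1) add(rows$label[i], lower, "vs_next_lower")
    }
    # matched sugar control in the same challenge state and concentration
    if (rows$arm[i] == "oligosaccharide") {
      ctrl <- catalogue$label[catalogue$arm == "sugar_control" &
                                catalogue$lps_ug_per_ml == rows$lps_ug_per_ml[i] &
                                catalogue$conc_pct %in% rows$conc_pct[i]]
      if (length(ctrl) == 1) add(rows$label[i], ctrl, "vs_sugar_control")
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(condition = character(), reference = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, pairs)
}

#' Build the analysis report for one fitted analyte
#'
#' Assembles the published-table layout: per-condition point estimates with
#' 95% credible intervals, annotated `*` when significantly different from
#' the challenge reference (blank for unchallenged conditions, LPS-alone
#' for challenged ones) and `#` when significantly different from the
#' next-lower concentration of the same fraction; plus the full contrast
#' table (including oligosaccharide-vs-matched-sugar-control contrasts
#' where both sides are in the fit) and the convergence report.
#'
#' @inheritParams condition_draws
#' @param convergence the [check_convergence()] report for these draws;
#'   required — reporting without a convergence check is refused.
#' @param catalogue condition catalogue (for challenge state and dose
#'   ordering).
#' @param extra_contrasts optional data.frame with columns `condition`,
#'   `reference` of additional pairs to include.
#' @return object of class `analysis_report`: `summaries` (with `marker`
#'   column), `contrasts`, `convergence`, `config` (MCMC settings echo,
#'   including the seed).
#' @export
build_report <- function(draws, convergence,
                         catalogue = default_condition_catalogue(),
                         extra_contrasts = NULL) {
  if (missing(convergence) || is.null(convergence)) {
    stop("no convergence report supplied; run check_convergence() on the ",
         "draws before reporting")
  }
  stopifnot(inherits(convergence, "convergence_report"))
  summaries <- summarize_conditions(draws)
  pairs <- standard_contrast_pairs(draws$condition_labels, catalogue)
  if (!is.null(extra_contrasts) && nrow(extra_contrasts)) {
    pairs <- rbind(pairs, data.frame(condition = extra_contrasts$condition,
                                     reference = extra_contrasts$reference,
                                     kind = "extra",
                                     stringsAsFactors = FALSE))
  }
  contrasts <- if (nrow(pairs)) {
    cbind(do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      compare(draws, pairs$condition[i], pairs$reference[i])
    })), kind = pairs$kind)
  } else {
    data.frame()
  }
  marker <- vapply(summaries$condition, function(cc) {
    sig <- function(kind) {
      hit <- contrasts$condition == cc & contrasts$kind == kind
      any(hit) && any(contrasts$significant[hit])
    }
    paste0(if (sig("vs_reference")) "*" else "",
           if (sig("vs_next_lower")) "#" else "")
  }, character(1))
  summaries$marker <- unname(marker)
  structure(list(summaries = summaries, contrasts = contrasts,
                 convergence = convergence,
                 config = draws$config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", x$summaries$analyte[1], "\n", sep = "")
  s <- x$summaries
  dec <- if (s$analyte[1] == "viability") 3 else 1
  cat(sprintf("  %-28s %9s %9s %9s %s\n", "condition", "estimate", "lower",
              "upper", ""))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-28s %9.*f %9.*f %9.*f %s\n", s$condition[i],
                dec, s$point_estimate[i], dec, s$lower[i], dec, s$upper[i],
                s$marker[i]))
  }
  cat("  ", nrow(x$contrasts), " contrasts; max PSRF ",
      format(max(x$convergence$psrf), digits = 4), "\n", sep = "")
  invisible(x)
}
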