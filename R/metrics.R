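# Output statistics: threshold fractions and histograms of surface strain,
# mean caudal contact pressure, and cohort variability summaries.

#' Area-weighted fraction of surface above a strain threshold
#'
#' Percentage of strut surface whose absolute maximum principal strain
#' strictly exceeds the threshold (the bone-maintenance/formation stimulus
#' level, 200 microstrain by default). Samples are weighted by surface
#' area; with unit weights this reduces to a plain count fraction. Samples
#' at exactly the threshold do not count.
#'
#' @param field A [surface_strain()] field (non-empty).
#' @param threshold_ue Threshold in microstrain (default 200).
#' @return Percentage in `[0, 100]`.
#' @examples
#' f <- data.frame(principal_ue = c(100, 300), weight_mm2 = c(1, 1))
#' threshold_fraction(f)  # 50
#' @export
threshold_fraction <- function(field, threshold_ue = 200) {
  if (is.null(field) || !nrow(field)) stop_arg("strain field is empty")
  if (any(field$weight_mm2 <= 0)) stop_arg("weights must be > 0")
  100 * sum(field$weight_mm2[abs(field$principal_ue) > threshold_ue]) /
    sum(field$weight_mm2)
}

#' Area-weighted strain histogram
#'
#' Shares of strut surface per absolute-strain bin. Bins are half-open
#' `[e_i, e_{i+1})` with the last bin open-ended (`>= last edge`); the
#' percentages sum to 100.
#'
#' @param field A [surface_strain()] field.
#' @param edges_ue Strictly increasing bin edges in microstrain; the first
#'   edge is the lower bound of the first bin (default `c(0, 100, 200, 500)`).
#' @return Named numeric vector of percentages, one per bin.
#' @export
strain_histogram <- function(field, edges_ue = c(0, 100, 200, 500)) {
  if (is.null(field) || !nrow(field)) stop_arg("strain field is empty")
  if (length(edges_ue) < 2 || any(diff(edges_ue) <= 0))
    stop_arg("`edges_ue` must be strictly increasing")
  a <- abs(field$principal_ue)
  w <- field$weight_mm2
  bins <- findInterval(a, edges_ue, left.open = FALSE)  # 0 = below first edge
  labs <- c(paste0("[", utils::head(edges_ue, -1), ",",
                   utils::tail(edges_ue, -1), ")"),
            paste0(">=", edges_ue[length(edges_ue)]))
  out <- vapply(seq_along(labs), function(b)
    100 * sum(w[bins == b]) / sum(w), numeric(1))
  below <- sum(bins == 0)
  if (below > 0)   # samples below the first edge fold into the first bin
    out[1] <- out[1] + 100 * sum(w[bins == 0]) / sum(w)
  setNames(out, labs)
}

#' Mean caudal contact pressure
#'
#' Total normal contact force divided by the tributary area of the nodes in
#' active contact on the caudal interface: the mean pressure over the
#' actually loaded contact patch. Returns 0 when nothing is in contact.
#'
#' @param x A [solve_load_case()] solution, or a contact-field data.frame
#'   with columns `side`, `normal_force_N`, `area_mm2`, `status`.
#' @param side Interface side (default `"caudal"`).
#' @param normalize `"active"` (default: active contact area) or
#'   `"nominal"` (full footprint area).
#' @return Pressure in MPa.
#' @export
mean_contact_pressure <- function(x, side = "caudal",
                                  normalize = c("active", "nominal")) {
  normalize <- match.arg(normalize)
  cf <- if (inherits(x, "cage_solution")) x$contact else x
  cf <- cf[cf$side == side, , drop = FALSE]
  if (!nrow(cf)) return(0)
  active <- cf$status != "open" & cf$normal_force_N > 0
  if (!any(active)) return(0)
  area <- if (normalize == "active") sum(cf$area_mm2[active]) else
    sum(cf$area_mm2)
  sum(cf$normal_force_N[active]) / area
}

#' Build a per-case metrics report
#'
#' Bundles the per-condition outputs for one solved case: threshold
#' fraction, strain histogram, mean caudal contact pressure and peak von
#' Mises stress.
#'
#' @param field A [surface_strain()] field.
#' @param solution The corresponding [solve_load_case()] solution.
#' @param threshold_ue Strain threshold (microstrain).
#' @param edges_ue Histogram bin edges (microstrain).
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(field, solution, threshold_ue = 200,
                           edges_ue = c(0, 100, 200, 500)) {
  structure(list(
    fraction_above_threshold = threshold_fraction(field, threshold_ue),
    threshold_ue = threshold_ue,
    histogram = strain_histogram(field, edges_ue),
    mean_caudal_pressure_MPa = mean_contact_pressure(solution),
    peak_von_mises_MPa = von_mises_peak(solution, field = field)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %.1f%% of surface > %g microstrain\n",
              x$fraction_above_threshold, x$threshold_ue))
  cat("  histogram (%):", paste(names(x$histogram),
                                sprintf("%.1f", x$histogram),
                                collapse = "  "), "\n")
  cat(sprintf("  mean caudal pressure %.2f MPa; peak von Mises %.1f MPa\n",
              x$mean_caudal_pressure_MPa, x$peak_von_mises_MPa))
  invisible(x)
}

# unbiased coefficient of variation in percent; NA (with warning) on zero mean
cv_percent <- function(x) {
  m <- mean(x)
  if (abs(m) < .Machine$double.eps) {
    warning("coefficient of variation undefined for zero mean")
    return(NA_real_)
  }
  100 * sd(x) / m
}

#' Cohort variability summary
#'
#' Computes coefficients of variation (unbiased sample SD / mean, percent)
#' of the per-case metrics across patients within each loading condition and
#' across conditions within each patient, plus the headline comparison flag
#' `condition_variation_dominates` (mean across-condition CV > mean
#' across-patient CV). Left/right cage values within one patient are
#' amalgamated by averaging before any CV is taken.
#'
#' @param cases A data.frame with one row per patient x condition x cage and
#'   columns `patient`, `condition`, `cage`, plus the metric columns
#'   (default `fraction_above_threshold`, `mean_caudal_pressure_MPa`).
#' @param metrics Character vector of metric column names to summarize.
#' @return Object of class `cohort_summary`: per-metric CV tables and flags.
#' @export
cohort_summary <- function(cases,
                           metrics = c("fraction_above_threshold",
                                       "mean_caudal_pressure_MPa")) {
  stopifnot(is.data.frame(cases),
            all(c("patient", "condition") %in% names(cases)))
  if (length(unique(cases$patient)) < 2)
    stop_arg("cohort summary needs >= 2 patients")
  # amalgamate left/right cages by averaging within patient x condition
  agg <- stats::aggregate(cases[metrics],
                          by = list(patient = cases$patient,
                                    condition = cases$condition),
                          FUN = mean)
  conds <- unique(agg$condition)
  out <- list()
  for (m in metrics) {
    across_pat <- vapply(conds, function(cc)
      cv_percent(agg[[m]][agg$condition == cc]), numeric(1))
    names(across_pat) <- conds
    if (length(conds) >= 2) {
      pats <- unique(agg$patient)
      across_cond <- vapply(pats, function(pp)
        cv_percent(agg[[m]][agg$patient == pp]), numeric(1))
      names(across_cond) <- pats
    } else {
      warning("single condition supplied: across-condition CV undefined")
      across_cond <- NA_real_
    }
    out[[m]] <- list(
      cv_across_patients = across_pat,
      cv_across_conditions = across_cond,
      condition_variation_dominates =
        if (all(is.na(across_cond))) NA else
          mean(across_cond, na.rm = TRUE) > mean(across_pat, na.rm = TRUE))
  }
  structure(list(metrics = out, table = agg), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (m in names(x$metrics)) {
    s <- x$metrics[[m]]
    cat(sprintf("%s:\n", m))
    cat("  CV across patients (%):",
        paste(names(s$cv_across_patients),
              sprintf("%.1f", s$cv_across_patients), collapse = "  "), "\n")
    cat(sprintf("  condition variation dominates: %s\n",
                s$condition_variation_dominates))
  }
  invisible(x)
}
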