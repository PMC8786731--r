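#' Construct a virtual patient
#'
#' A virtual patient bundles the demographic and spine-state parameters that
#' drive segment loads and surrogate stiffness: body weight and height (which
#' set the follower-load magnitudes), lumbar lordosis, a Pfirrmann
#' degeneration grade per disc level, and a dimensionless bone-quality scalar.
#'
#' @param id Character label.
#' @param weight_kg Body mass in kg (> 0).
#' @param height_cm Standing height in cm (> 0).
#' @param lordosis_deg Lumbar lordotic angle in degrees.
#' @param pfirrmann Named integer vector of Pfirrmann grades (1-5), one per
#'   disc level `L1-L2`, `L2-L3`, `L3-L4`, `L4-L5`, `L5-S1`.
#' @param bone_quality Dimensionless scalar in (0, 1]; 1 is best.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `virtual_patient`.
#' @seealso [sample_cohort()]
#' @export
virtual_patient <- function(id, weight_kg, height_cm, lordosis_deg,
                            pfirrmann, bone_quality = 1, seed = NA_integer_) {
  check_number(weight_kg, "weight_kg", positive = TRUE)
  check_number(height_cm, "height_cm", positive = TRUE)
  check_number(lordosis_deg, "lordosis_deg")
  check_number(bone_quality, "bone_quality", positive = TRUE)
  if (bone_quality > 1) stop_arg("`bone_quality` must lie in (0, 1]")
  lv <- disc_levels()
  if (is.null(names(pfirrmann)) || !all(lv %in% names(pfirrmann)))
    stop_arg("`pfirrmann` must be named with all five disc levels: ",
             paste(lv, collapse = ", "))
  pfirrmann <- as.integer(pfirrmann[lv])
  names(pfirrmann) <- lv
  if (any(pfirrmann < 1L | pfirrmann > 5L))
    stop_arg("Pfirrmann grades must be integers in 1..5")
  structure(list(id = as.character(id), weight_kg = weight_kg,
                 height_cm = height_cm, lordosis_deg = lordosis_deg,
                 pfirrmann = pfirrmann, bone_quality = bone_quality,
                 seed = as.integer(seed)),
            class = "virtual_patient")
}

#' Disc levels of the lumbar chain
#'
#' @return Character vector of the five disc levels, cranial to caudal.
#' @export
disc_levels <- function() c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")

#' Default cohort parameter ranges
#'
#' The default sampling bounds mirror the narrow demographic spread of a
#' reference cohort of fusion candidates sharing one cage size: weight
#' 60-74 kg, height 164-172 cm, lordosis 29-40 degrees, Pfirrmann grades
#' II-IV per disc, and bone quality 0.7-1.0.
#'
#' @return Named list of `c(min, max)` bounds (grades are integer bounds).
#' @export
cohort_ranges <- function() {
  list(weight_kg = c(60, 74), height_cm = c(164, 172),
       lordosis_deg = c(29, 40), pfirrmann = c(2L, 4L),
       bone_quality = c(0.7, 1.0))
}

#' Sample a virtual patient cohort
#'
#' Draws `n` virtual patients independently and uniformly within the supplied
#' parameter bounds (grades uniform on the integer range, one draw per disc
#' level). Sampling is bit-reproducible for a fixed seed and does not disturb
#' the caller's RNG state.
#'
#' @param n Number of patients (>= 1); default 4.
#' @param seed Integer seed; default 42.
#' @param ranges Named list of bounds as returned by [cohort_ranges()];
#'   entries may be collapsed (`min == max`).
#' @return A list of [virtual_patient] objects, classed `virtual_cohort`.
#' @examples
#' cohort <- sample_cohort(4, seed = 42)
#' sapply(cohort, function(p) p$weight_kg)
#' @export
sample_cohort <- function(n = 4, seed = 42, ranges = cohort_ranges()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_arg("`n` must be >= 1")
  n <- as.integer(n)
  defaults <- cohort_ranges()
  for (nm in names(defaults)) ranges[[nm]] <- ranges[[nm]] %||% defaults[[nm]]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[2] < r[1])
      stop_arg(sprintf("range `%s` must be c(min, max) with max >= min", nm))
  }
  runif_r <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  grade_r <- function(r) if (r[1] == r[2]) as.integer(r[1]) else
    sample(seq.int(r[1], r[2]), 1L)
  pts <- with_seed(seed, lapply(seq_len(n), function(i) {
    virtual_patient(
      id = sprintf("P%02d", i),
      weight_kg = runif_r(ranges$weight_kg),
      height_cm = runif_r(ranges$height_cm),
      lordosis_deg = runif_r(ranges$lordosis_deg),
      pfirrmann = setNames(vapply(disc_levels(), function(l)
        grade_r(ranges$pfirrmann), integer(1)), disc_levels()),
      bone_quality = runif_r(ranges$bone_quality),
      seed = seed)
  }))
  structure(pts, class = "virtual_cohort")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("<virtual_patient %s> %.1f kg, %.1f cm, lordosis %.1f deg, bone quality %.2f\n",
              x$id, x$weight_kg, x$height_cm, x$lordosis_deg, x$bone_quality))
  cat("  Pfirrmann:", paste(names(x$pfirrmann), x$pfirrmann, sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("<virtual_cohort> %d patients\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' @export
as.data.frame.virtual_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    d <- data.frame(id = p$id, weight_kg = p$weight_kg,
                    height_cm = p$height_cm, lordosis_deg = p$lordosis_deg,
                    bone_quality = p$bone_quality, seed = p$seed)
    for (lv in names(p$pfirrmann))
      d[[paste0("pfirrmann_", gsub("-", "", lv))]] <- p$pfirrmann[[lv]]
    d
  }))
}

#' Export a cohort as CSV
#'
#' One row per patient, demographics plus per-level Pfirrmann grades.
#'
#' @param cohort A `virtual_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
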