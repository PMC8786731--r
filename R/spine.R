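# Lumped lumbar-spine surrogate: a serial chain of functional spinal units
# (FSUs) with nonlinear moment-rotation maps replaces the continuum L1-S1
# model. It reproduces the loading protocol (follower load + 20 deg
# extension/flexion with off-axis rotations constrained) and delivers the
# operated-segment boundary conditions to the cage FE model.

#' Spine surrogate calibration constants
#'
#' All tunable constants of the lumped spine surrogate, overridable per call
#' (or via the `spine:` section of a run configuration). Stiffness units are
#' N m per degree; pressures MPa.
#'
#' * `k0_Nm_deg`: per-level baseline rotational stiffness at neutral.
#' * `nonlinearity_deg`: softening scale `b` of the stiffening map
#'   `M = k0 b sinh(theta/b)` (smaller = more strongly stiffening).
#' * `asymmetry`: extension/flexion stiffness ratio (< 1: more compliant in
#'   extension, reproducing the asymmetric load-deflection profile).
#' * `pfirrmann_stiffness`: per-grade multiplier on `k0` (degenerated discs
#'   are stiffer).
#' * `pfirrmann_swelling`: per-grade multiplier on the nucleus swelling
#'   pressure (degenerated discs hold less water, hence lower baseline IDP).
#' * `swelling_pressure_MPa`: healthy-disc swelling baseline.
#' * `disc_area_mm2`: per-level nominal nucleus/disc area at 168 cm height
#'   (scaled by (height/168)^2 per patient).
#' * `idp_undrained_gain`: undrained pressure amplification `c_u` of the mean
#'   axial stress `F/A`.
#' * `idp_moment_gain_MPa_per_Nm`: moment sensitivity `c_m`.
#' * `idp_condition_gain`: condition factor `g` with
#'   `g(flexion) > g(extension) >= 0`.
#'
#' @return Named list of calibration constants.
#' @export
spine_calibration <- function() {
  list(
    k0_Nm_deg = c("L1-L2" = 3.8, "L2-L3" = 3.5, "L3-L4" = 3.3,
                  "L4-L5" = 3.2, "L5-S1" = 3.0),
    nonlinearity_deg = 5,
    asymmetry = 0.38,
    pfirrmann_stiffness = c(0.85, 1.0, 1.2, 1.45, 1.7),
    pfirrmann_swelling = c(1.1, 1.0, 0.6, 0.35, 0.2),
    swelling_pressure_MPa = 0.15,
    disc_area_mm2 = c("L1-L2" = 1350, "L2-L3" = 1450, "L3-L4" = 1550,
                      "L4-L5" = 1650, "L5-S1" = 1700),
    idp_undrained_gain = 1.5,
    idp_moment_gain_MPa_per_Nm = 0.025,
    idp_condition_gain = c(neutral = 0, extension = 0.35, flexion = 1.0))
}

#' Construct a functional spinal unit model
#'
#' An FSU is represented by a strictly monotonic (hence invertible)
#' moment-rotation map `M(theta) = k0 * a(theta) * b * sinh(theta / b)` with
#' `a = asymmetry` for extension (theta < 0) and `a = 1` for flexion, plus
#' the disc parameters needed by the intradiscal-pressure surrogate.
#'
#' @param level Disc level label (one of [disc_levels()]).
#' @param k0 Rotational stiffness at neutral, N m per degree (> 0), already
#'   including any degeneration multiplier.
#' @param nonlinearity Softening scale `b` in degrees.
#' @param asymmetry Extension/flexion stiffness ratio (> 0).
#' @param pfirrmann_factor Swelling multiplier for the IDP baseline (1 =
#'   healthy grade II disc).
#' @param disc_area_mm2 Nucleus/disc cross-sectional area, mm^2 (> 0).
#' @param swelling_pressure_MPa Healthy-disc swelling pressure baseline, MPa.
#' @return Object of class `fsu_model`.
#' @export
fsu_model <- function(level, k0, nonlinearity = 5, asymmetry = 0.38,
                      pfirrmann_factor = 1, disc_area_mm2 = 1600,
                      swelling_pressure_MPa = 0.15) {
  check_number(k0, "k0", positive = TRUE)
  check_number(nonlinearity, "nonlinearity", positive = TRUE)
  check_number(asymmetry, "asymmetry", positive = TRUE)
  check_number(disc_area_mm2, "disc_area_mm2", positive = TRUE)
  check_number(swelling_pressure_MPa, "swelling_pressure_MPa", nonneg = TRUE)
  structure(list(level = level, k0 = k0, nonlinearity = nonlinearity,
                 asymmetry = asymmetry, pfirrmann_factor = pfirrmann_factor,
                 disc_area_mm2 = disc_area_mm2,
                 swelling_pressure_MPa = swelling_pressure_MPa),
            class = "fsu_model")
}

# Moment (N m) at rotation theta (deg); vectorized in theta.
fsu_moment <- function(fsu, theta_deg) {
  a <- ifelse(theta_deg < 0, fsu$asymmetry, 1)
  b <- fsu$nonlinearity
  fsu$k0 * a * b * sinh(theta_deg / b)
}

# Rotation (deg) at moment M (N m): analytic inverse of fsu_moment.
fsu_rotation <- function(fsu, M_Nm) {
  a <- ifelse(M_Nm < 0, fsu$asymmetry, 1)
  b <- fsu$nonlinearity
  b * asinh(M_Nm / (fsu$k0 * a * b))
}

#' Build the default FSU chain for a patient
#'
#' Instantiates the five lumbar FSUs (L1-L2 ... L5-S1) from the calibration
#' constants and the patient's Pfirrmann grades: degenerated discs get a
#' stiffer moment-rotation map and a reduced swelling baseline; disc areas
#' scale with the square of body height.
#'
#' @param patient A [virtual_patient()].
#' @param cal Calibration list, see [spine_calibration()].
#' @return Named list of [fsu_model()] objects, cranial to caudal.
#' @export
default_fsu_chain <- function(patient, cal = spine_calibration()) {
  stopifnot(inherits(patient, "virtual_patient"))
  hscale <- (patient$height_cm / 168)^2
  lapply(setNames(disc_levels(), disc_levels()), function(lv) {
    g <- patient$pfirrmann[[lv]]
    fsu_model(level = lv,
              k0 = cal$k0_Nm_deg[[lv]] * cal$pfirrmann_stiffness[g],
              nonlinearity = cal$nonlinearity_deg,
              asymmetry = cal$asymmetry,
              pfirrmann_factor = cal$pfirrmann_swelling[g],
              disc_area_mm2 = cal$disc_area_mm2[[lv]] * hscale,
              swelling_pressure_MPa = cal$swelling_pressure_MPa)
  })
}

#' Posterior instrumentation parameters
#'
#' Pedicle-screw/rod instrumentation modeled as a parallel load path: two
#' titanium rods deforming as fixed-guided beams (both ends rotationally
#' clamped in rigid screw anchors) over the posterior segment height, acting
#' at a posterior lever arm from the disc center. The construct contributes
#' a translational stiffness `k_t = 2 * 12 E I / L^3` and a rotational
#' stiffness `k_t * offset^2` to the instrumented segment.
#'
#' @param rod_diameter_mm Rod diameter (default 5 mm).
#' @param rod_length_mm Free rod length = posterior segment height
#'   (default 35 mm).
#' @param screw_length_mm Pedicle screw shaft length (default 32 mm;
#'   geometric bookkeeping only, screws are treated as rigid anchors).
#' @param screw_diameter_mm Screw diameter (default 5 mm).
#' @param posterior_offset_mm Lever arm from disc center to the rod plane
#'   (default 40 mm).
#' @param material Named numeric `c(E_MPa, nu)`; titanium by default.
#' @return Object of class `instrumentation_params`.
#' @export
instrumentation_params <- function(rod_diameter_mm = 5, rod_length_mm = 35,
                                   screw_length_mm = 32,
                                   screw_diameter_mm = 5,
                                   posterior_offset_mm = 40,
                                   material = c(E_MPa = 116000, nu = 0.32)) {
  for (v in c(rod_diameter_mm, rod_length_mm, screw_length_mm,
              screw_diameter_mm, posterior_offset_mm))
    check_number(v, "instrumentation dimension", positive = TRUE)
  structure(list(rod_diameter_mm = rod_diameter_mm,
                 rod_length_mm = rod_length_mm,
                 screw_length_mm = screw_length_mm,
                 screw_diameter_mm = screw_diameter_mm,
                 posterior_offset_mm = posterior_offset_mm,
                 material = c(E_MPa = as.numeric(material[[1]]),
                              nu = as.numeric(material[[2]]))),
            class = "instrumentation_params")
}

# Translational stiffness of the two-rod construct (N/mm): fixed-guided
# bending of each rod, 12 E I / L^3.
instrumentation_axial_stiffness <- function(inst) {
  I <- pi * inst$rod_diameter_mm^4 / 64
  2 * 12 * inst$material[["E_MPa"]] * I / inst$rod_length_mm^3
}

# Rotational stiffness about the lateral axis (N m per degree).
instrumentation_rot_stiffness <- function(inst) {
  k_t <- instrumentation_axial_stiffness(inst)            # N/mm
  k_rot <- k_t * inst$posterior_offset_mm^2               # N mm / rad
  k_rot / 1000 * pi / 180                                 # N m / deg
}

# ---------------------------------------------------------------------------
# Follower load

# Reference tables of the L1 resultant follower load (N) per loading
# condition, on a (weight kg) x (height cm) grid. Values are calibrated so
# that patients inside the default cohort spread (60-74 kg, 164-172 cm) fall
# within the physiological per-condition ranges 368-454 N (neutral),
# 748-888 N (extension) and 976-1148 N (flexion); loads increase with both
# weight and height.
follower_load_tables <- function() {
  w <- c(55, 80); h <- c(158, 180)
  mk <- function(a, bh, c0) outer(w, h, function(W, H) a * W + bh * (H - 168) + c0)
  list(weights = w, heights = h,
       values = list(neutral   = mk(5.3, 0.4, 55),
                     extension = mk(9.3, 0.7, 195),
                     flexion   = mk(11.0, 0.8, 325)))
}

load_conditions <- function() c("neutral", "extension", "flexion")

#' Patient-specific follower load
#'
#' Bilinear interpolation of a built-in reference table of the compressive
#' follower-load resultant at L1 over patient weight and height, one table
#' per loading condition. Weight/height outside the table hull are clamped
#' with a warning.
#'
#' @param patient A [virtual_patient()].
#' @param condition `"neutral"`, `"extension"` or `"flexion"`.
#' @param tables Reference tables (override for sensitivity studies); see
#'   `trusscage:::follower_load_tables()` for the layout.
#' @return Follower load in N (single number).
#' @examples
#' p <- sample_cohort(1, seed = 1)[[1]]
#' follower_load(p, "neutral")
#' @export
follower_load <- function(patient, condition = load_conditions(),
                          tables = follower_load_tables()) {
  condition <- match.arg(condition)
  stopifnot(inherits(patient, "virtual_patient"))
  w <- patient$weight_kg; h <- patient$height_cm
  wr <- range(tables$weights); hr <- range(tables$heights)
  if (w < wr[1] || w > wr[2] || h < hr[1] || h > hr[2]) {
    warning(sprintf(
      "patient %s (%.1f kg, %.1f cm) outside follower-load table hull; clamped",
      patient$id, w, h))
    w <- min(max(w, wr[1]), wr[2]); h <- min(max(h, hr[1]), hr[2])
  }
  V <- tables$values[[condition]]
  iw <- findInterval(w, tables$weights, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ih <- findInterval(h, tables$heights, rightmost.closed = TRUE,
                     all.inside = TRUE)
  tw <- (w - tables$weights[iw]) / diff(tables$weights[iw + 0:1])
  th <- (h - tables$heights[ih]) / diff(tables$heights[ih + 0:1])
  (1 - tw) * (1 - th) * V[iw, ih] + tw * (1 - th) * V[iw + 1, ih] +
    (1 - tw) * th * V[iw, ih + 1] + tw * th * V[iw + 1, ih + 1]
}

#' Define a load case
#'
#' The three conditions of the loading protocol: `neutral` (follower load
#' only), `extension` (-20 degrees total lumbar rotation) and `flexion`
#' (+20 degrees), with the condition-specific follower load applied
#' simultaneously with the rotation ramp. Negative rotations denote
#' extension.
#'
#' @param condition One of [load_conditions()].
#' @param patient Optional [virtual_patient()]; if given, `follower_load_N`
#'   defaults to [follower_load()] for that patient.
#' @param total_rotation_deg Total lumbar rotation; defaults to 0 / -20 / +20
#'   by condition.
#' @param follower_load_N Compressive follower load, N (> 0).
#' @param n_ramp_steps Ramp step count (bookkeeping for logs; the response is
#'   path-independent for this monotone quasi-static protocol).
#' @return Object of class `load_case`.
#' @export
load_case <- function(condition = load_conditions(), patient = NULL,
                      total_rotation_deg = NULL, follower_load_N = NULL,
                      n_ramp_steps = 5) {
  condition <- match.arg(condition)
  if (is.null(total_rotation_deg))
    total_rotation_deg <- switch(condition, neutral = 0, extension = -20,
                                 flexion = 20)
  if (is.null(follower_load_N)) {
    if (is.null(patient))
      stop_arg("either `patient` or `follower_load_N` must be supplied")
    follower_load_N <- follower_load(patient, condition)
  }
  check_number(follower_load_N, "follower_load_N", positive = TRUE)
  structure(list(condition = condition,
                 total_rotation_deg = total_rotation_deg,
                 follower_load_N = follower_load_N,
                 n_ramp_steps = as.integer(n_ramp_steps)),
            class = "load_case")
}

#' Distribute lumbar rotation over the FSU chain
#'
#' Solves series equilibrium of the FSU chain: one chain moment `M` is
#' transmitted through every unit, and `M` is found by bisection such that
#' the per-unit rotations `theta_i(M)` (inverse moment-rotation maps; the
#' instrumented level uses the augmented map with the instrumentation's
#' parallel rotational stiffness) sum to the requested total rotation to
#' better than 1e-8 degrees. Per-disc intradiscal pressures are evaluated at
#' the chain moment and the case's follower load.
#'
#' @param fsus Named list of [fsu_model()] objects (the chain, cranial to
#'   caudal).
#' @param instrumented_level Level label carrying the pedicle-screw/rod
#'   construct (default `"L4-L5"`).
#' @param lcase A [load_case()].
#' @param instrumentation An [instrumentation_params()] object.
#' @param cal Calibration constants for the IDP surrogate.
#' @return Object of class `spine_state`: per-FSU rotations (deg), chain
#'   moment = cranial reaction moment (N m), per-disc IDP (MPa; `NA` at the
#'   operated level, whose disc is resected).
#' @examples
#' p <- sample_cohort(1, seed = 1)[[1]]
#' st <- distribute_rotation(default_fsu_chain(p), "L4-L5",
#'                           load_case("flexion", p))
#' st
#' @export
distribute_rotation <- function(fsus, instrumented_level = "L4-L5",
                                lcase, instrumentation = instrumentation_params(),
                                cal = spine_calibration()) {
  stopifnot(inherits(lcase, "load_case"))
  lv <- names(fsus)
  if (is.null(lv) || !instrumented_level %in% lv)
    stop_arg("`fsus` must be a named list containing the instrumented level")
  if (sum(lv == instrumented_level) != 1L)
    stop_arg("exactly one instrumented level is required")
  k_inst <- instrumentation_rot_stiffness(instrumentation)  # N m / deg
  target <- lcase$total_rotation_deg

  theta_of_M <- function(M) {
    vapply(lv, function(l) {
      if (l == instrumented_level) {
        if (M == 0) return(0)
        # invert M = M_fsu(theta) + k_inst * theta (strictly monotone)
        f <- function(th) fsu_moment(fsus[[l]], th) + k_inst * th - M
        uniroot(f, interval = c(-180, 180), tol = 1e-13)$root
      } else fsu_rotation(fsus[[l]], M)
    }, numeric(1))
  }

  if (target == 0) {
    M <- 0; theta <- setNames(rep(0, length(lv)), lv)
  } else {
    # bracket the chain moment, then bisect on the rotation residual
    M_hi <- sign(target)
    while (sign(target) * (sum(theta_of_M(M_hi)) - target) < 0)
      M_hi <- 2 * M_hi
    M_lo <- 0
    for (it in seq_len(200)) {
      M <- (M_lo + M_hi) / 2
      r <- sum(theta_of_M(M)) - target
      if (abs(r) < 1e-8) break
      if (sign(target) * r < 0) M_lo <- M else M_hi <- M
    }
    if (abs(sum(theta_of_M(M)) - target) >= 1e-8)
      stop("chain-moment bisection did not converge in 200 iterations")
    theta <- theta_of_M(M)
  }

  idp <- vapply(lv, function(l) {
    if (l == instrumented_level) return(NA_real_)
    disc_idp(fsus[[l]], lcase$follower_load_N, M, lcase$condition, cal)
  }, numeric(1))

  structure(list(rotations_deg = theta, moment_Nm = M,
                 cranial_reaction_moment_Nm = M, idp_MPa = idp,
                 condition = lcase$condition,
                 follower_load_N = lcase$follower_load_N,
                 instrumented_level = instrumented_level),
            class = "spine_state")
}

#' @export
print.spine_state <- function(x, ...) {
  cat(sprintf("<spine_state> %s: chain moment %.2f N m, follower load %.0f N\n",
              x$condition, x$moment_Nm, x$follower_load_N))
  df <- data.frame(level = names(x$rotations_deg),
                   rotation_deg = round(x$rotations_deg, 3),
                   idp_MPa = round(x$idp_MPa, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Intradiscal pressure surrogate
#'
#' Undrained short-time nucleus pressure: the swelling baseline (scaled by
#' the degeneration factor) plus the undrained response to the mean axial
#' stress and a condition-weighted moment term,
#' `IDP = pi_swell * f_pfirrmann + c_u * F/A + c_m * |M| * g(condition)`,
#' with `g(flexion) > g(extension) >= g(neutral) = 0`. Strictly increasing
#' in both the axial force and the moment magnitude.
#'
#' @param fsu An [fsu_model()].
#' @param axial_force_N Compressive follower-load share, N (>= 0).
#' @param moment_Nm Chain moment, N m (signed; only the magnitude enters).
#' @param condition Loading condition.
#' @param cal Calibration constants.
#' @return Pressure in MPa.
#' @export
disc_idp <- function(fsu, axial_force_N, moment_Nm,
                     condition = load_conditions(),
                     cal = spine_calibration()) {
  condition <- match.arg(condition)
  check_number(axial_force_N, "axial_force_N", nonneg = TRUE)
  check_number(moment_Nm, "moment_Nm")
  if (fsu$disc_area_mm2 <= 0) stop("disc area must be positive")
  fsu$swelling_pressure_MPa * fsu$pfirrmann_factor +
    cal$idp_undrained_gain * axial_force_N / fsu$disc_area_mm2 +
    cal$idp_moment_gain_MPa_per_Nm * abs(moment_Nm) *
      cal$idp_condition_gain[[condition]]
}

#' Extract operated-segment boundary conditions
#'
#' Pulls the instrumented level's rotation share and the condition-level
#' follower load out of a solved [spine_state][distribute_rotation()] and
#' packages them, with the instrumentation parameters, as the boundary
#' conditions of the cage FE model. Loads and rotation are applied
#' simultaneously; the final state is ramp-path independent for this linear
#' (piecewise, through the contact set) problem, so `n_ramp_steps` is carried
#' for logging only.
#'
#' @param state A `spine_state`.
#' @param patient The [virtual_patient()] the state was solved for.
#' @param lcase The [load_case()].
#' @param instrumentation An [instrumentation_params()] object.
#' @return Object of class `segment_bc`: `cranial_plate_rotation_deg`
#'   (signed; negative = extension), `axial_force_N`, `instrumentation`,
#'   `condition`, `n_ramp_steps`.
#' @export
segment_bc <- function(state, patient, lcase,
                       instrumentation = instrumentation_params()) {
  stopifnot(inherits(state, "spine_state"), inherits(lcase, "load_case"))
  lvl <- state$instrumented_level
  if (!lvl %in% names(state$rotations_deg))
    stop_arg("spine state does not contain the instrumented level")
  structure(list(cranial_plate_rotation_deg = state$rotations_deg[[lvl]],
                 axial_force_N = lcase$follower_load_N,
                 instrumentation = instrumentation,
                 condition = lcase$condition,
                 patient_id = patient$id,
                 n_ramp_steps = lcase$n_ramp_steps),
            class = "segment_bc")
}
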