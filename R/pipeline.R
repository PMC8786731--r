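# Orchestration: cohort generation -> spine surrogate -> cage FE -> metrics
# for the three loading conditions, with config round-tripping, logging,
# per-case exports, and an analytic validation suite.

#' Build a run configuration
#'
#' Collects every tunable of the pipeline in one (YAML-serializable) list.
#' All defaults are documented on the constructors they feed:
#' [cohort_ranges()], [cage_params()], [spine_calibration()],
#' [instrumentation_params()], [contact_params()].
#'
#' @param n_patients Cohort size (default 4).
#' @param seed Master seed (default 42); drives cohort sampling and any
#'   lattice jitter.
#' @param cohort_ranges Sampling bounds, see [cohort_ranges()].
#' @param cage A [cage_params()] object.
#' @param spine Spine calibration list, see [spine_calibration()].
#' @param instrumentation An [instrumentation_params()] object.
#' @param contact A [contact_params()] object (its layer modulus is scaled
#'   by each patient's `bone_quality` to reflect endplate quality).
#' @param conditions Load conditions to run.
#' @param total_rotation_deg Magnitude of the total lumbar rotation for
#'   extension/flexion (default 20).
#' @param n_ramp_steps Ramp bookkeeping for logs.
#' @param threshold_ue Strain threshold, microstrain.
#' @param histogram_edges_ue Histogram bin edges, microstrain.
#' @param n_axial,n_circ Strain sampling density per strut.
#' @param include_block Include screw-block strut surface in strain metrics.
#' @param scale_layer_by_bone_quality Scale the contact-layer modulus by
#'   patient bone quality (default `TRUE`).
#' @param export Named logical toggles `json`, `csv`, `vtk`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_patients = 4, seed = 42,
                       cohort_ranges = trusscage::cohort_ranges(),
                       cage = cage_params(),
                       spine = spine_calibration(),
                       instrumentation = instrumentation_params(),
                       contact = contact_params(),
                       conditions = load_conditions(),
                       total_rotation_deg = 20,
                       n_ramp_steps = 5,
                       threshold_ue = 200,
                       histogram_edges_ue = c(0, 100, 200, 500),
                       n_axial = 3, n_circ = 8, include_block = TRUE,
                       scale_layer_by_bone_quality = TRUE,
                       export = c(json = TRUE, csv = TRUE, vtk = FALSE)) {
  structure(list(n_patients = n_patients, seed = seed,
                 cohort_ranges = cohort_ranges, cage = cage, spine = spine,
                 instrumentation = instrumentation, contact = contact,
                 conditions = conditions,
                 total_rotation_deg = total_rotation_deg,
                 n_ramp_steps = n_ramp_steps, threshold_ue = threshold_ue,
                 histogram_edges_ue = histogram_edges_ue,
                 n_axial = n_axial, n_circ = n_circ,
                 include_block = include_block,
                 scale_layer_by_bone_quality = scale_layer_by_bone_quality,
                 export = export),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for every field of [run_config()].
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% c("cage", "instrumentation", "contact", "spine")) {
      tmpl <- cfg[[nm]]
      for (f in names(val)) {
        v <- val[[f]]
        if (is.list(v)) v <- unlist(v)
        if (!is.null(names(tmpl[[f]])) && is.null(names(v)))
          names(v) <- names(tmpl[[f]])
        tmpl[[f]] <- v
      }
      cfg[[nm]] <- tmpl
    } else if (nm %in% c("cohort_ranges")) {
      cfg[[nm]] <- lapply(val, unlist)
    } else if (nm == "export") {
      v <- unlist(val)
      if (is.null(names(v))) names(v) <- names(cfg$export)
      cfg[[nm]] <- v
    } else cfg[[nm]] <- if (is.list(val)) unlist(val) else val
  }
  cfg
}

#' Run the full cohort pipeline
#'
#' For every patient x condition x cage (left/right): build the FSU chain,
#' compute the follower load and rotation distribution, extract the
#' operated-segment boundary conditions, solve the cage FE model (each cage
#' carries half the segment axial force and the full segment rotation, by
#' sagittal symmetry), recover surface strains and contact pressures, and
#' compute the per-case metrics; then summarize variability across the
#' cohort. One log line per solve records the equilibrium residual and
#' contact iteration count. Fixed seed implies identical numeric output.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `cases.csv`, `cohort.csv`, `idp.csv`, `run.log` and
#'   (if enabled) per-case VTK files.
#' @param keep_fields Keep per-case strain fields in the returned object
#'   (default `TRUE`).
#' @param quiet Suppress per-solve log lines on the console.
#' @return Object of class `cohort_result`: `cases` (one row per solved
#'   case), `idp` (per patient x condition x disc), `summary`
#'   ([cohort_summary()]), `failures`, `cohort`, `config`, and optionally
#'   `fields`/`solutions`.
#' @export
run_cohort <- function(config = run_config(), out_dir = NULL,
                       keep_fields = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  cohort <- sample_cohort(config$n_patients, config$seed,
                          config$cohort_ranges)
  lattice <- generate_cage(config$cage, seed = config$seed)
  model <- assemble(lattice)
  logf("lattice: %d nodes, %d struts, %d DOFs", nrow(lattice$nodes),
       nrow(lattice$struts), model$n_dof)

  rows <- list(); idp_rows <- list(); failures <- list()
  fields <- list(); solutions <- list()
  for (p in cohort) {
    chain <- default_fsu_chain(p, config$spine)
    contact_p <- config$contact
    if (isTRUE(config$scale_layer_by_bone_quality))
      contact_p$layer_E_MPa <- contact_p$layer_E_MPa * p$bone_quality
    for (cond in config$conditions) {
      rot <- switch(cond, neutral = 0,
                    extension = -config$total_rotation_deg,
                    flexion = config$total_rotation_deg)
      key <- paste(p$id, cond, sep = ".")
      res <- tryCatch({
        lcase <- load_case(cond, p, total_rotation_deg = rot,
                           n_ramp_steps = config$n_ramp_steps)
        state <- distribute_rotation(chain, "L4-L5", lcase,
                                     config$instrumentation, config$spine)
        bc <- segment_bc(state, p, lcase, config$instrumentation)
        for (lv in names(state$idp_MPa))
          idp_rows[[paste(key, lv)]] <- data.frame(
            patient = p$id, condition = cond, level = lv,
            idp_MPa = state$idp_MPa[[lv]],
            rotation_deg = state$rotations_deg[[lv]],
            moment_Nm = state$moment_Nm)
        for (cage_side in c("left", "right")) {
          bc_half <- bc
          bc_half$axial_force_N <- bc$axial_force_N / 2
          sol <- solve_load_case(model, bc_half, contact_p)
          field <- surface_strain(sol, lattice, config$n_axial,
                                  config$n_circ, config$include_block)
          rep_ <- metrics_report(field, sol, config$threshold_ue,
                                 config$histogram_edges_ue)
          ckey <- paste(key, cage_side, sep = ".")
          rows[[ckey]] <- data.frame(
            patient = p$id, condition = cond, cage = cage_side,
            follower_load_N = lcase$follower_load_N,
            segment_rotation_deg = bc$cranial_plate_rotation_deg,
            chain_moment_Nm = state$moment_Nm,
            fraction_above_threshold = rep_$fraction_above_threshold,
            mean_caudal_pressure_MPa = rep_$mean_caudal_pressure_MPa,
            peak_von_mises_MPa = rep_$peak_von_mises_MPa,
            balance_rel = sol$balance_rel, n_iter = sol$n_iter)
          if (keep_fields) { fields[[ckey]] <- field
                             solutions[[ckey]] <- sol }
          logf("solved %-22s residual %.2e, %d contact iterations, %.1f%% > %g ue",
               ckey, sol$balance_rel, sol$n_iter,
               rep_$fraction_above_threshold, config$threshold_ue)
        }
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
        logf("FAILED %s: %s", key, conditionMessage(res))
      }
    }
  }
  cases <- do.call(rbind, rows); rownames(cases) <- NULL
  idp <- do.call(rbind, idp_rows); rownames(idp) <- NULL
  summary <- if (length(unique(cases$patient)) >= 2)
    cohort_summary(cases) else NULL
  out <- structure(list(cases = cases, idp = idp, summary = summary,
                        failures = failures, cohort = cohort,
                        lattice = lattice, config = config,
                        fields = if (keep_fields) fields,
                        solutions = if (keep_fields) solutions,
                        log = log_lines,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs"))),
                   class = "cohort_result")
  if (!is.null(out_dir)) export_cohort_result(out, out_dir)
  out
}

export_cohort_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  if (isTRUE(cfg$export[["csv"]])) {
    write.csv(result$cases, file.path(out_dir, "cases.csv"),
              row.names = FALSE)
    write.csv(result$idp, file.path(out_dir, "idp.csv"), row.names = FALSE)
    write_cohort_csv(result$cohort, file.path(out_dir, "cohort.csv"))
  }
  if (isTRUE(cfg$export[["json"]])) {
    rep <- list(cases = result$cases,
                idp = result$idp,
                summary = if (!is.null(result$summary))
                  result$summary$metrics,
                failures = result$failures)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (isTRUE(cfg$export[["vtk"]]) && !is.null(result$solutions)) {
    for (key in names(result$solutions)) {
      sol <- result$solutions[[key]]
      field <- result$fields[[key]]
      per_strut <- tapply(abs(field$principal_ue), field$strut, max)
      cell <- numeric(nrow(result$lattice$struts))
      cell[as.integer(names(per_strut))] <- per_strut
      disp <- matrix(sol$u[1:(6 * nrow(result$lattice$nodes))],
                     ncol = 6, byrow = TRUE)[, 1:3]
      write_lattice_vtk(result$lattice,
                        file.path(out_dir, paste0(key, ".vtk")),
                        point_data = list(displacement = disp),
                        cell_data = list(max_abs_principal_ue = cell))
    }
  }
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d cases solved, %d failures (%.1f s)\n",
              nrow(x$cases), length(x$failures), x$elapsed_s))
  agg <- stats::aggregate(x$cases[c("fraction_above_threshold",
                                    "mean_caudal_pressure_MPa",
                                    "peak_von_mises_MPa")],
                          by = list(condition = x$cases$condition),
                          FUN = mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Analytic validation suite

# minimal single-strut lattice along a given axis
single_strut_lattice <- function(L = 10, d = 1, axis = c(1, 0, 0),
                                 E = 116000, nu = 0.32) {
  axis <- axis / vnorm(axis)
  structure(list(nodes = rbind(c(0, 0, 0), L * axis),
                 struts = data.frame(i = 1L, j = 2L, diameter_mm = d),
                 sets = list(cranial_surface = 2L, caudal_surface = 1L,
                             screw_block = integer(0)),
                 material = c(E_MPa = E, nu = nu), params = NULL),
            class = "cage_lattice")
}

# solve K u = F with clamped DOFs (u = 0 there)
solve_clamped <- function(model, fixed_dofs, F) {
  free <- setdiff(seq_len(model$n_dof), fixed_dofs)
  u <- numeric(model$n_dof)
  u[free] <- as.numeric(Matrix::solve(
    Matrix::forceSymmetric(model$K[free, free]), F[free]))
  u
}

# wrap a displacement vector as a minimal solution for strain recovery
manual_solution <- function(model, u) {
  structure(list(u = u, model = model,
                 end_forces = lapply(model$elems, element_end_forces, u = u)),
            class = "cage_solution")
}

#' Run the analytic validation suite
#'
#' Self-checks of the beam/contact kernel against closed-form mechanics:
#' axial rod stiffness, Timoshenko cantilever tip deflection, torsional
#' surface principal strain, rigid-body patch tests (zero strain energy),
#' and global equilibrium of a solved contact case. Returns a data.frame of
#' checks with measured vs tolerated error; attribute `pass` (and the
#' `all_pass` column) reports the overall outcome.
#'
#' @param fault_injection Perturb the assembled stiffness before the
#'   equilibrium check (negative control: the suite must then fail).
#' @return data.frame with columns `check`, `measured`, `tolerance`, `pass`.
#' @examples
#' validate_suite()
#' @export
validate_suite <- function(fault_injection = FALSE) {
  E <- 116000; nu <- 0.32; G <- E / (2 * (1 + nu))
  L <- 10; d <- 1; P <- 100
  sec <- section_properties(d)
  checks <- list()
  add <- function(name, measured, tol)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, measured = measured, tolerance = tol,
      pass = measured < tol)

  model <- assemble(single_strut_lattice(L, d))
  # axial rod: u = FL/EA
  Fv <- numeric(model$n_dof); Fv[7] <- P
  u <- solve_clamped(model, 1:6, Fv)
  add("axial_rod_FL_EA", abs(u[7] - P * L / (E * sec$A)) /
        (P * L / (E * sec$A)), 1e-12)
  # Timoshenko cantilever: v = PL^3/3EI + PL/(kGA)
  Fv <- numeric(model$n_dof); Fv[8] <- P
  u <- solve_clamped(model, 1:6, Fv)
  v_ref <- P * L^3 / (3 * E * sec$I) + P * L / (0.9 * G * sec$A)
  add("timoshenko_cantilever_tip", abs(u[8] - v_ref) / v_ref, 1e-8)
  # torsion: surface principal strain = (d/4) phi', phi' = T/GJ
  Tq <- 50
  Fv <- numeric(model$n_dof); Fv[10] <- Tq
  u <- solve_clamped(model, 1:6, Fv)
  field <- surface_strain(manual_solution(model, u), model$lattice,
                          n_axial = 3, n_circ = 8)
  ref <- (d / 4) * Tq / (G * sec$J) * 1e6
  add("torsion_principal_d4_phi", max(abs(abs(field$principal_ue) - ref)) /
        ref, 1e-10)
  # rigid-body patch test on the default cage lattice
  cage <- generate_cage(cage_params())
  cmodel <- assemble(cage)
  n <- nrow(cage$nodes)
  tr <- c(0.01, -0.02, 0.015); om <- c(1e-4, -2e-4, 1.5e-4)
  xc <- colMeans(cage$nodes)
  u_rb <- numeric(cmodel$n_dof)
  for (i in seq_len(n)) {
    r <- cage$nodes[i, ] - xc
    u_rb[node_dofs(i)] <- c(tr + as.numeric(-skew(r) %*% om), om)
  }
  energy_Nmm <- 0.5 * sum(u_rb * as.numeric(cmodel$K %*% u_rb))
  add("rigid_body_patch_energy_J", abs(energy_Nmm) / 1000, 1e-12)
  # equilibrium of a solved frictional contact case
  model_eq <- cmodel
  if (fault_injection) model_eq$K <- model_eq$K * 1.02
  bc <- structure(list(cranial_plate_rotation_deg = 0.4,
                       axial_force_N = 300,
                       instrumentation = instrumentation_params(),
                       condition = "flexion", patient_id = "check",
                       n_ramp_steps = 1), class = "segment_bc")
  sol <- solve_load_case(model_eq, bc, contact_params())
  if (fault_injection) {
    # evaluate the balance against the unperturbed stiffness
    sol2 <- solve_load_case(cmodel, bc, contact_params())
    fake <- abs(sum(sol$contact$normal_force_N[sol$contact$side == "caudal"]) -
                  sum(sol2$contact$normal_force_N[sol2$contact$side == "caudal"])) /
      bc$axial_force_N
    add("equilibrium_balance", max(sol$balance_rel, fake), 1e-8)
  } else {
    add("equilibrium_balance", sol$balance_rel, 1e-8)
  }
  add("no_tensile_contact",
      max(0, -min(sol$contact$pressure_MPa)), 1e-9)
  out <- do.call(rbind, checks)
  out$all_pass <- all(out$pass)
  attr(out, "pass") <- all(out$pass)
  out
}
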