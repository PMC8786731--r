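# Shared fixtures. The default cohort run is expensive relative to the rest
# of the suite, so it is computed once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

default_cohort_result <- function() {
  if (is.null(.fixture_env$res)) {
    .fixture_env$res <- suppressWarnings(
      run_cohort(run_config(), quiet = TRUE, keep_fields = TRUE))
  }
  .fixture_env$res
}

# two-node strut lattice along an arbitrary axis (for analytic oracles)
strut_lattice <- function(L = 10, d = 1, axis = c(1, 0, 0),
                          E = 116000, nu = 0.32) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(nodes = rbind(c(0, 0, 0), L * axis),
                 struts = data.frame(i = 1L, j = 2L, diameter_mm = d),
                 sets = list(cranial_surface = 2L, caudal_surface = 1L,
                             screw_block = integer(0)),
                 material = c(E_MPa = E, nu = nu), params = NULL),
            class = "cage_lattice")
}

# clamp the listed DOFs to zero and solve K u = F
solve_clamped <- function(model, fixed_dofs, F) {
  free <- setdiff(seq_len(model$n_dof), fixed_dofs)
  u <- numeric(model$n_dof)
  u[free] <- as.numeric(Matrix::solve(
    Matrix::forceSymmetric(model$K[free, free]), F[free]))
  u
}

# wrap a displacement vector for strain recovery without a contact solve
manual_solution <- function(model, u) {
  structure(list(u = u, model = model,
                 end_forces = lapply(model$elems, function(el)
                   as.numeric(el$K_local %*% (el$T %*% u[el$dofs])))),
            class = "cage_solution")
}

# segment BC without going through the spine surrogate
direct_bc <- function(rotation_deg = 0, axial_force_N = 200,
                      inst = instrumentation_params(), condition = "flexion") {
  structure(list(cranial_plate_rotation_deg = rotation_deg,
                 axial_force_N = axial_force_N, instrumentation = inst,
                 condition = condition, patient_id = "fixture",
                 n_ramp_steps = 1),
            class = "segment_bc")
}
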