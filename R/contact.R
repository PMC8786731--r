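# Operated-segment solve: the beam lattice sits between a fixed caudal plate
# and a rigid cranial plate (prescribed sagittal rotation + applied axial
# force), coupled through foundation springs that represent the 2 mm contact
# layers. Unilateral mode releases normal springs in tension (active-set
# iteration) and caps tangential forces at mu * normal via an elastic-
# predictor/Coulomb-cap return mapping: tangential springs stay assembled
# and an under-relaxed correction force drives the net tangential force onto
# the friction cone. The pedicle-screw/rod construct is a bonded parallel
# spring between the cranial plate and ground at a posterior lever arm.

#' Contact layer parameters
#'
#' Foundation-spring representation of the compliant cage-endplate contact
#' layers: per interface node a normal spring `k_n = E A_trib / t` and
#' tangential springs `k_t = k_n / (2 (1 + nu))`, with the tributary area
#' `A_trib` = footprint area / number of surface nodes on that face.
#'
#' @param layer_E_MPa Layer Young's modulus (default 1000 MPa).
#' @param layer_nu Layer Poisson ratio (default 0.30).
#' @param layer_thickness_mm Layer thickness (default 2.0 mm).
#' @param friction_mu Coulomb friction coefficient (default 0.20).
#' @param mode `"unilateral"` (hard contact: no tension, friction-capped
#'   sliding) or `"bonded"` (tied, for interface-stiffness side studies).
#' @return Object of class `contact_params`.
#' @export
contact_params <- function(layer_E_MPa = 1000, layer_nu = 0.30,
                           layer_thickness_mm = 2.0, friction_mu = 0.20,
                           mode = c("unilateral", "bonded")) {
  mode <- match.arg(mode)
  check_number(layer_E_MPa, "layer_E_MPa", positive = TRUE)
  check_number(layer_nu, "layer_nu", positive = TRUE)
  check_number(layer_thickness_mm, "layer_thickness_mm", positive = TRUE)
  check_number(friction_mu, "friction_mu", nonneg = TRUE)
  structure(list(layer_E_MPa = layer_E_MPa, layer_nu = layer_nu,
                 layer_thickness_mm = layer_thickness_mm,
                 friction_mu = friction_mu, mode = mode),
            class = "contact_params")
}

footprint_area <- function(lattice) {
  if (!is.null(lattice$params))
    return(prod(lattice$params$footprint_mm))
  cn <- lattice$nodes[lattice$sets$caudal_surface, , drop = FALSE]
  diff(range(cn[, 1])) * diff(range(cn[, 2]))
}

#' Solve one operated-segment load case
#'
#' Caudal interface nodes rest on ground foundation springs; cranial
#' interface nodes couple to a rigid plate whose sagittal rotation is
#' prescribed (off-axis rotations and in-plane translations fixed) and whose
#' vertical translation is free, loaded by the axial follower-load share.
#' Positive segment rotation (flexion) tilts the plate so its anterior edge
#' moves caudally. In unilateral mode, normal springs are released in
#' tension and re-activated on penetration until the active set is fixed,
#' and tangential forces are capped at `mu * normal` by an under-relaxed
#' Coulomb return mapping in the same outer loop (at most 100 iterations,
#' force tolerance 1e-8 N).
#'
#' @param model A [assemble()]d `beam_model`.
#' @param bc A [segment_bc()] (its `axial_force_N` is the force applied to
#'   this model; halve the segment share per cage before calling when
#'   solving left/right cages separately).
#' @param contact A [contact_params()] object.
#' @return Object of class `cage_solution`: displacement vector `u` (lattice
#'   DOFs then 6 plate DOFs), the `contact` field per interface node
#'   (normal/tangential force, pressure, status), plate/ground reactions,
#'   the instrumentation axial share, the global force-balance residual, and
#'   iteration diagnostics.
#' @examples
#' model <- assemble(generate_cage(cage_params()))
#' bc <- structure(list(cranial_plate_rotation_deg = 0.3, axial_force_N = 250,
#'                      instrumentation = instrumentation_params(),
#'                      condition = "flexion", n_ramp_steps = 1),
#'                 class = "segment_bc")
#' sol <- solve_load_case(model, bc, contact_params())
#' sol$balance_rel
#' @export
solve_load_case <- function(model, bc, contact = contact_params()) {
  stopifnot(inherits(model, "beam_model"), inherits(bc, "segment_bc"),
            inherits(contact, "contact_params"))
  lat <- model$lattice
  n_lat <- model$n_dof
  n_tot <- n_lat + 6L
  plate_dofs <- n_lat + 1:6

  cran <- lat$sets$cranial_surface
  caud <- lat$sets$caudal_surface
  A_foot <- footprint_area(lat)
  A_cran <- A_foot / length(cran)
  A_caud <- A_foot / length(caud)
  kn_cran <- contact$layer_E_MPa * A_cran / contact$layer_thickness_mm
  kn_caud <- contact$layer_E_MPa * A_caud / contact$layer_thickness_mm
  kt_cran <- kn_cran / (2 * (1 + contact$layer_nu))
  kt_caud <- kn_caud / (2 * (1 + contact$layer_nu))

  xc <- colMeans(lat$nodes[cran, , drop = FALSE])   # plate centroid
  # plate kinematic map at point p: u_plate(p) = [I | -skew(r)] q
  Gmat <- function(p) cbind(diag(3), -skew(p - xc))
  G_cran <- lapply(cran, function(i) Gmat(lat$nodes[i, ]))

  inst <- bc$instrumentation
  k_inst <- instrumentation_axial_stiffness(inst)
  p_inst <- c(0, xc[2] - inst$posterior_offset_mm, xc[3])
  g_inst <- t(Gmat(p_inst)) %*% c(0, 0, 1)          # 6x1 over plate dofs

  # prescribed plate DOFs: in-plane translations and off-axis rotations
  # fixed; sagittal rotation about the lateral (x) axis prescribed. With y
  # anterior, flexion (positive) is a negative rotation about +x.
  phi <- -deg2rad(bc$cranial_plate_rotation_deg)
  presc_idx <- plate_dofs[c(1, 2, 4, 5, 6)]
  presc_val <- c(0, 0, phi, 0, 0)
  free_mask <- rep(TRUE, n_tot)
  free_mask[presc_idx] <- FALSE

  F_applied <- numeric(n_tot)
  F_applied[plate_dofs[3]] <- -bc$axial_force_N     # axial share, downward

  unilateral <- contact$mode == "unilateral"
  mu <- contact$friction_mu

  K_beam <- Matrix::bdiag(model$K, Matrix::Matrix(0, 6, 6, sparse = TRUE))

  # state: normal-spring active flags; friction correction forces (x, y)
  act_caud <- rep(TRUE, length(caud)); act_cran <- rep(TRUE, length(cran))
  corr_caud <- matrix(0, length(caud), 2)
  corr_cran <- matrix(0, length(cran), 2)

  # spring triplets are precomputed once; per iteration only the values are
  # masked by the active flags
  spring_tpl <- local({
    ti <- list(); tj <- list(); tx <- list(); grp <- list(); m <- 0L
    put <- function(dofs, Kblk, g) {
      m <<- m + 1L
      idx <- expand.grid(a = dofs, b = dofs)
      ti[[m]] <<- idx$a; tj[[m]] <<- idx$b
      tx[[m]] <<- as.vector(Kblk); grp[[m]] <<- rep(g, length(dofs)^2)
    }
    for (a in seq_along(caud))
      put(node_dofs(caud[a])[1:3], diag(c(kt_caud, kt_caud, kn_caud)),
          a)
    for (a in seq_along(cran)) {
      dofs <- c(node_dofs(cran[a])[1:3], plate_dofs)
      B <- cbind(diag(3), -G_cran[[a]])              # delta = B [u_node; q]
      put(dofs, crossprod(B, diag(c(kt_cran, kt_cran, kn_cran)) %*% B),
          length(caud) + a)
    }
    put(plate_dofs, k_inst * tcrossprod(g_inst), 0L)
    list(i = unlist(ti), j = unlist(tj), x = unlist(tx), grp = unlist(grp))
  })

  assemble_springs <- function() {
    on <- c(act_caud, act_cran)
    keep <- spring_tpl$grp == 0L | on[pmax(spring_tpl$grp, 1L)]
    Matrix::sparseMatrix(i = spring_tpl$i[keep], j = spring_tpl$j[keep],
                         x = spring_tpl$x[keep], dims = c(n_tot, n_tot))
  }

  external_forces <- function() {
    F_ext <- F_applied
    for (a in seq_along(caud)) if (act_caud[a]) {
      d <- node_dofs(caud[a])[1:2]
      F_ext[d] <- F_ext[d] + corr_caud[a, ]
    }
    for (a in seq_along(cran)) if (act_cran[a]) {
      d <- node_dofs(cran[a])[1:2]
      F_ext[d] <- F_ext[d] + corr_cran[a, ]
      F_ext[plate_dofs] <- F_ext[plate_dofs] -
        as.numeric(t(G_cran[[a]]) %*% c(corr_cran[a, ], 0))
    }
    F_ext
  }

  solve_once <- function(K, F_ext) {
    u <- numeric(n_tot)
    u[presc_idx] <- presc_val
    rhs <- F_ext[free_mask] -
      as.numeric(K[free_mask, !free_mask, drop = FALSE] %*% presc_val)
    u[free_mask] <- as.numeric(Matrix::solve(
      Matrix::forceSymmetric(K[free_mask, free_mask]), rhs))
    u
  }

  normal_state <- function(u) {
    q <- u[plate_dofs]
    uz_caud <- u[(caud - 1L) * 6L + 3L]
    delta_cran <- t(vapply(seq_along(cran), function(a) {
      un <- u[node_dofs(cran[a])[1:3]]
      un - as.numeric(G_cran[[a]] %*% q)
    }, numeric(3)))
    # hysteresis between release (tension beyond -1e-10 N) and
    # re-activation (penetration beyond 1e-8 mm) suppresses chattering of
    # nodes sitting numerically on the contact boundary
    list(N_caud = ifelse(act_caud, -kn_caud * uz_caud, 0),
         N_cran = ifelse(act_cran, kn_cran * delta_cran[, 3], 0),
         pen_caud = uz_caud < -1e-8,
         pen_cran = delta_cran[, 3] > 1e-8,
         ut_caud = cbind(u[(caud - 1L) * 6L + 1L], u[(caud - 1L) * 6L + 2L]),
         dt_cran = delta_cran[, 1:2, drop = FALSE])
  }

  # total tangential force transmitted at a node = spring force + correction
  friction_target <- function(act, N, kt, dt, corr) {
    slip <- rep(FALSE, length(act))
    target <- matrix(0, length(act), 2)
    for (a in seq_along(act)) {
      if (!act[a]) next
      f_spring <- -kt * dt[a, ]
      f_net <- f_spring + corr[a, ]
      fn <- max(N[a], 0)
      if (vnorm(f_spring) > mu * fn + 1e-12 && vnorm(dt[a, ]) > 1e-14) {
        slip[a] <- TRUE
        f_cap <- -mu * fn * dt[a, ] / vnorm(dt[a, ])   # oppose relative slide
        target[a, ] <- f_cap - f_spring
      }                                                # stick: target corr 0
    }
    list(slip = slip, target = target)
  }

  # inner loop: active-set iteration at frozen friction forces (release
  # tensile normal springs, re-activate on penetration) until the set is
  # fixed; outer loop: damped Coulomb return mapping on the tangential
  # correction forces.
  n_iter <- 0L; converged <- FALSE; u <- numeric(n_tot)
  slip_caud <- rep(FALSE, length(caud)); slip_cran <- rep(FALSE, length(cran))
  frozen_caud <- rep(FALSE, length(caud)); frozen_cran <- rep(FALSE, length(cran))
  dforce <- Inf; dforce_prev <- Inf; omega <- 0.5; n_decreasing <- 0L
  for (outer in seq_len(100)) {
    sets_stable <- FALSE
    sig_hist <- character(0)
    for (inner in seq_len(100)) {
      n_iter <- n_iter + 1L
      K <- K_beam + assemble_springs()
      u <- solve_once(K, external_forces())
      st <- normal_state(u)
      if (!unilateral) { sets_stable <- TRUE; break }
      new_act_caud <- ifelse(act_caud, st$N_caud > -1e-10,
                             st$pen_caud & !frozen_caud)
      new_act_cran <- ifelse(act_cran, st$N_cran > -1e-10,
                             st$pen_cran & !frozen_cran)
      sets_stable <- identical(new_act_caud, act_caud) &&
        identical(new_act_cran, act_cran)
      # grazing-contact degeneracy: a node (pair) can cycle between "released
      # but marginally penetrating" and "active but marginally tensile".
      # Detect the set cycle and freeze such nodes in the released state:
      # equilibrium of the remaining forces stays exact and no tensile
      # pressure is transmitted; only a sub-micrometre penetration remains
      # unpenalized.
      sig <- paste(c(new_act_caud, new_act_cran), collapse = "")
      if (!sets_stable && sig %in% sig_hist) {
        togg_caud <- new_act_caud != act_caud
        togg_cran <- new_act_cran != act_cran
        frozen_caud <- frozen_caud | togg_caud
        frozen_cran <- frozen_cran | togg_cran
        new_act_caud[togg_caud] <- FALSE
        new_act_cran[togg_cran] <- FALSE
        sig_hist <- character(0)
      } else sig_hist <- c(utils::tail(sig_hist, 3), sig)
      act_caud <- new_act_caud; act_cran <- new_act_cran
      corr_caud[!act_caud, ] <- 0; corr_cran[!act_cran, ] <- 0
      if (sets_stable) break
    }
    if (!sets_stable)
      stop(sprintf(paste0(
        "contact active-set iteration did not converge in 100 iterations ",
        "(active caudal %d/%d, cranial %d/%d)"),
        sum(act_caud), length(caud), sum(act_cran), length(cran)))

    if (!unilateral || mu == 0) { converged <- TRUE; break }
    fc <- friction_target(act_caud, st$N_caud, kt_caud, st$ut_caud,
                          corr_caud)
    fr <- friction_target(act_cran, st$N_cran, kt_cran, st$dt_cran,
                          corr_cran)
    new_corr_caud <- corr_caud + omega * (fc$target - corr_caud)
    new_corr_cran <- corr_cran + omega * (fr$target - corr_cran)
    slip_caud <- fc$slip; slip_cran <- fr$slip
    dforce <- max(abs(new_corr_caud - corr_caud),
                  abs(new_corr_cran - corr_cran), 0)
    corr_caud <- new_corr_caud; corr_cran <- new_corr_cran
    if (dforce < 1e-8) { converged <- TRUE; break }
    # accelerate the damped fixed point while it contracts steadily
    if (dforce < dforce_prev) {
      n_decreasing <- n_decreasing + 1L
      if (n_decreasing >= 3L) omega <- min(0.95, omega * 1.2)
    } else { n_decreasing <- 0L; omega <- 0.5 }
    dforce_prev <- dforce
  }
  if (!converged)
    stop(sprintf(paste0(
      "friction return mapping did not converge in 100 outer iterations ",
      "(last force change %.3e N)"), dforce))

  # --- contact field and reactions --------------------------------------
  st <- normal_state(u)
  ft_caud <- -kt_caud * st$ut_caud + corr_caud
  ft_caud[!act_caud, ] <- 0
  ft_cran <- -kt_cran * st$dt_cran + corr_cran
  ft_cran[!act_cran, ] <- 0

  status_of <- function(act, slip)
    ifelse(!act, "open", ifelse(slip, "slip", "stick"))
  contact_field <- rbind(
    data.frame(node = caud, side = "caudal",
               x = lat$nodes[caud, 1], y = lat$nodes[caud, 2],
               area_mm2 = A_caud, normal_force_N = st$N_caud,
               pressure_MPa = st$N_caud / A_caud,
               tangential_force_N = sqrt(rowSums(ft_caud^2)),
               traction_MPa = sqrt(rowSums(ft_caud^2)) / A_caud,
               status = status_of(act_caud, slip_caud)),
    data.frame(node = cran, side = "cranial",
               x = lat$nodes[cran, 1], y = lat$nodes[cran, 2],
               area_mm2 = A_cran, normal_force_N = st$N_cran,
               pressure_MPa = st$N_cran / A_cran,
               tangential_force_N = sqrt(rowSums(ft_cran^2)),
               traction_MPa = sqrt(rowSums(ft_cran^2)) / A_cran,
               status = status_of(act_cran, slip_cran)))

  # forces exerted on the structure by ground/supports
  ground_caud <- colSums(cbind(ft_caud, st$N_caud))  # on caudal nodes
  q <- u[plate_dofs]
  inst_stretch <- as.numeric(crossprod(g_inst, q))
  inst_force_plate <- -k_inst * inst_stretch          # z-force on plate
  K <- K_beam + assemble_springs()
  resid <- as.numeric(K %*% u - external_forces())
  R_presc <- resid[presc_idx]                         # (Fx, Fy, Mx, My, Mz)
  balance <- c(ground_caud[1] + R_presc[1],
               ground_caud[2] + R_presc[2],
               ground_caud[3] + inst_force_plate - bc$axial_force_N)
  balance_rel <- vnorm(balance) / max(bc$axial_force_N, 1e-12)

  end_forces <- lapply(model$elems, element_end_forces, u = u)

  structure(list(u = u, plate_q = q, model = model, bc = bc,
                 contact_params = contact, contact = contact_field,
                 end_forces = end_forces,
                 reactions = list(ground_caudal = ground_caud,
                                  instrumentation_axial_N = inst_force_plate,
                                  plate_prescribed = R_presc),
                 balance = balance, balance_rel = balance_rel,
                 residual_free = max(abs(resid[free_mask])),
                 n_iter = n_iter),
            class = "cage_solution")
}

#' @export
print.cage_solution <- function(x, ...) {
  cat(sprintf("<cage_solution> %s: rotation %.3f deg, axial %.0f N\n",
              x$bc$condition, x$bc$cranial_plate_rotation_deg,
              x$bc$axial_force_N))
  ac <- x$contact[x$contact$side == "caudal", ]
  cat(sprintf("  caudal contact: %d/%d active, mean pressure %.2f MPa\n",
              sum(ac$status != "open"), nrow(ac), mean_contact_pressure(x)))
  cat(sprintf("  instrumentation axial share %.1f N; balance %.2e (rel), %d contact iterations\n",
              x$reactions$instrumentation_axial_N, x$balance_rel, x$n_iter))
  invisible(x)
}
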