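# Surface strain recovery on circular struts. With loads applied only at
# nodes, the internal force distribution of each Timoshenko element is exact
# from its end forces: constant axial force and torque, linear bending
# moments. Surface fibers then carry the axial strain
# eps(s, theta) = eps_m(s) + (d/2) [kappa_y(s) sin(theta) +
# kappa_z(s) cos(theta)] and the torsional shear gamma(s) = (d/2) phi'(s).

# Internal force resultants of element `el` at axial station s (mm from
# node i), from the local end-force vector f (forces on the element).
internal_forces <- function(f, s) {
  list(N = -f[1], T = -f[4],
       My = -f[5] - s * f[3],
       Mz = -f[6] + s * f[2])
}

#' Recover surface strains on all struts
#'
#' Samples every strut at `n_axial` axial stations (ends and interior) and
#' `n_circ` circumferential angles on the strut surface. At each sample the
#' axial fiber strain combines membrane strain and the two bending
#' curvatures; the torsional shear follows from the twist rate. The
#' reported quantity is the absolute maximum principal strain
#' `|eps|/2 + sqrt((eps/2)^2 + (gamma/2)^2)` in microstrain, carrying the
#' sign of the fiber strain for tensile/compressive labelling. Samples are
#' weighted by their share of lateral strut surface area and labelled
#' anterior/posterior relative to the cage mid-length.
#'
#' @param solution A [solve_load_case()] result.
#' @param lattice The `cage_lattice` the solution was computed on (defaults
#'   to the solution's own model lattice).
#' @param n_axial Axial stations per strut (>= 2; default 3).
#' @param n_circ Circumferential samples (>= 4; default 8).
#' @param include_block Include struts of the screw-insertion block
#'   (default `TRUE`).
#' @return Object of class `strain_field`: a data.frame of samples with
#'   columns `strut`, `s_mm`, `theta`, `eps`, `gamma`, `principal_ue`
#'   (signed microstrain), `region`, `weight_mm2`.
#' @export
surface_strain <- function(solution, lattice = solution$model$lattice,
                           n_axial = 3, n_circ = 8, include_block = TRUE) {
  stopifnot(inherits(solution, "cage_solution"))
  if (n_axial < 2 || n_circ < 4)
    stop_arg("need n_axial >= 2 and n_circ >= 4")
  elems <- solution$model$elems
  block <- lattice$sets$screw_block
  y_mid <- if (!is.null(lattice$params))
    lattice$params$footprint_mm[1] / 2 else mean(range(lattice$nodes[, 2]))
  theta <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  out <- vector("list", length(elems))
  for (k in seq_along(elems)) {
    el <- elems[[k]]
    if (!include_block && el$i %in% block && el$j %in% block) next
    f <- solution$end_forces[[k]]
    svals <- seq(0, el$L, length.out = n_axial)
    w <- pi * el$d * el$L / (n_axial * n_circ)
    p1 <- lattice$nodes[el$i, ]; p2 <- lattice$nodes[el$j, ]
    rows <- vector("list", n_axial)
    for (a in seq_len(n_axial)) {
      s <- svals[a]
      fr <- internal_forces(f, s)
      eps_m <- fr$N / (el$E * el$A)
      ky <- fr$My / (el$E * el$I)
      kz <- fr$Mz / (el$E * el$I)
      gam <- (el$d / 2) * fr$T / (el$G * el$J)
      eps <- eps_m + (el$d / 2) * (ky * sin(theta) + kz * cos(theta))
      princ <- abs(eps) / 2 + sqrt((eps / 2)^2 + (gam / 2)^2)
      sgn <- ifelse(eps < 0, -1, 1)
      pos_y <- p1[2] + (s / el$L) * (p2[2] - p1[2])
      rows[[a]] <- data.frame(
        strut = k, s_mm = s, theta = theta, eps = eps, gamma = gam,
        principal_ue = sgn * princ * 1e6,
        region = if (pos_y > y_mid) "anterior" else "posterior",
        weight_mm2 = w)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  structure(samples, class = c("strain_field", "data.frame"))
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d surface samples on %d struts; total area %.1f mm^2\n",
              nrow(x), length(unique(x$strut)), sum(x$weight_mm2)))
  q <- stats::quantile(abs(x$principal_ue), c(0.5, 0.95, 1))
  cat(sprintf("  |principal strain| median %.0f, p95 %.0f, max %.0f microstrain\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Peak von Mises stress over the strut surface
#'
#' Per surface sample the axial stress is `E * eps` and the torsional shear
#' stress `G * gamma`; the von Mises equivalent is
#' `sqrt(sigma^2 + 3 tau^2)`. Returns the maximum over all samples, in MPa.
#'
#' @inheritParams surface_strain
#' @param field Optional precomputed [surface_strain()] field (saves
#'   resampling).
#' @return Peak von Mises stress, MPa.
#' @export
von_mises_peak <- function(solution, lattice = solution$model$lattice,
                           field = NULL, n_axial = 3, n_circ = 8,
                           include_block = TRUE) {
  if (is.null(field))
    field <- surface_strain(solution, lattice, n_axial, n_circ, include_block)
  E <- lattice$material[["E_MPa"]]
  G <- E / (2 * (1 + lattice$material[["nu"]]))
  if (!nrow(field)) return(0)
  sigma <- E * field$eps
  tau <- G * field$gamma
  max(sqrt(sigma^2 + 3 * tau^2))
}
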