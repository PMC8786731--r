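# 3D two-node Timoshenko beam elements on circular sections, assembled into
# a global sparse stiffness. DOF ordering: 6 per node (ux, uy, uz, rx, ry,
# rz), node i occupying rows (i-1)*6 + 1:6. Units: mm, N, rad.

# Section properties of a circular strut of diameter d.
section_properties <- function(d) {
  list(A = pi * d^2 / 4, I = pi * d^4 / 64, J = pi * d^4 / 32)
}

# Local 12x12 Timoshenko stiffness; local x runs along the strut axis.
# kappa is the shear correction factor (0.9 for circular sections).
timoshenko_k_local <- function(E, G, A, I, J, L, kappa = 0.9) {
  K <- matrix(0, 12, 12)
  ax <- E * A / L
  K[c(1, 7), c(1, 7)] <- ax * matrix(c(1, -1, -1, 1), 2, 2)
  tor <- G * J / L
  K[c(4, 10), c(4, 10)] <- tor * matrix(c(1, -1, -1, 1), 2, 2)
  Phi <- 12 * E * I / (kappa * G * A * L^2)
  c0 <- E * I / (L^3 * (1 + Phi))
  bend <- function(s) {
    # s = +1 for the x-y plane (v, rz), -1 for the x-z plane (w, ry)
    c0 * matrix(c(
      12,        s * 6 * L,          -12,        s * 6 * L,
      s * 6 * L, (4 + Phi) * L^2,    -s * 6 * L, (2 - Phi) * L^2,
      -12,       -s * 6 * L,          12,        -s * 6 * L,
      s * 6 * L, (2 - Phi) * L^2,    -s * 6 * L, (4 + Phi) * L^2),
      4, 4, byrow = TRUE)
  }
  K[c(2, 6, 8, 12), c(2, 6, 8, 12)] <- bend(+1)
  K[c(3, 5, 9, 11), c(3, 5, 9, 11)] <- bend(-1)
  K
}

# Rotation matrix with rows = local axes in global coordinates, so that
# u_local = R %*% u_global.
strut_rotation <- function(p1, p2) {
  ex <- p2 - p1
  L <- vnorm(ex)
  if (L < 1e-12) stop("zero-length strut")
  ex <- ex / L
  ref <- if (abs(ex[3]) < 0.99) c(0, 0, 1) else c(0, 1, 0)
  ey <- c(ref[2] * ex[3] - ref[3] * ex[2],
          ref[3] * ex[1] - ref[1] * ex[3],
          ref[1] * ex[2] - ref[2] * ex[1])          # ref x ex
  ey <- ey / vnorm(ey)
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])            # ex x ey
  rbind(ex, ey, ez, deparse.level = 0)
}

node_dofs <- function(i) (i - 1L) * 6L + 1:6

#' Assemble the beam finite-element model of a cage lattice
#'
#' Each strut becomes a two-node 3D Timoshenko beam with circular-section
#' properties `A = pi d^2/4`, `I = pi d^4/64`, `J = pi d^4/32` and shear
#' correction factor 0.9. Element matrices are rotated into the global frame
#' and assembled into a symmetric sparse stiffness with 6 DOFs per node
#' (before constraints the free-free matrix has exactly the 6 rigid-body
#' zero-energy modes).
#'
#' @param lattice A validated `cage_lattice` (see [generate_cage()]).
#' @param kappa Shear correction factor (default 0.9, circular sections).
#' @return Object of class `beam_model`: sparse stiffness `K` (N/mm blocks),
#'   per-element records (length, rotation, section, DOF map) and the source
#'   lattice.
#' @examples
#' model <- assemble(generate_cage(cage_params()))
#' model
#' @export
assemble <- function(lattice, kappa = 0.9) {
  validate_lattice(lattice)
  E <- lattice$material[["E_MPa"]]
  nu <- lattice$material[["nu"]]
  G <- E / (2 * (1 + nu))
  ns <- nrow(lattice$struts)
  n_dof <- 6L * nrow(lattice$nodes)
  trip_i <- vector("list", ns); trip_j <- vector("list", ns)
  trip_x <- vector("list", ns)
  elems <- vector("list", ns)
  for (k in seq_len(ns)) {
    i <- lattice$struts$i[k]; j <- lattice$struts$j[k]
    d <- lattice$struts$diameter_mm[k]
    p1 <- lattice$nodes[i, ]; p2 <- lattice$nodes[j, ]
    R <- strut_rotation(p1, p2)
    L <- vnorm(p2 - p1)
    sec <- section_properties(d)
    Kl <- timoshenko_k_local(E, G, sec$A, sec$I, sec$J, L, kappa)
    T12 <- matrix(0, 12, 12)
    for (b in 0:3) T12[b * 3 + 1:3, b * 3 + 1:3] <- R
    Kg <- crossprod(T12, Kl %*% T12)
    dofs <- c(node_dofs(i), node_dofs(j))
    idx <- expand.grid(a = dofs, b = dofs)
    trip_i[[k]] <- idx$a; trip_j[[k]] <- idx$b
    trip_x[[k]] <- as.vector(Kg)
    elems[[k]] <- list(i = i, j = j, d = d, L = L, R = R, A = sec$A,
                       I = sec$I, J = sec$J, E = E, G = G, kappa = kappa,
                       K_local = Kl, T = T12, dofs = dofs)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(n_dof, n_dof))
  structure(list(K = K, n_dof = n_dof, elems = elems, lattice = lattice,
                 kappa = kappa),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %d nodes, %d Timoshenko beam elements, %d DOFs\n",
              nrow(x$lattice$nodes), length(x$elems), x$n_dof))
  invisible(x)
}

# Local end-force vector (forces/moments acting ON the element at both
# nodes, in the element frame) for element `el` given the global
# displacement vector `u`.
element_end_forces <- function(el, u) {
  u_e <- u[el$dofs]
  as.numeric(el$K_local %*% (el$T %*% u_e))
}
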