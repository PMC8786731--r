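# Independent dense direct-stiffness oracle for 3D Timoshenko frames,
# derived via the flexibility method (analytic cantilever flexibility of the
# far node, inverted and expanded by rigid-body equilibrium transfer). This
# is a deliberately different derivation from the package's shape-function
# stiffness matrix, so agreement is a genuine cross-check.

oracle_element_k <- function(p1, p2, d, E = 116000, nu = 0.32, kappa = 0.9) {
  G <- E / (2 * (1 + nu))
  A <- pi * d^2 / 4; I <- pi * d^4 / 64; J <- pi * d^4 / 32
  L <- sqrt(sum((p2 - p1)^2))
  # analytic tip flexibility of a cantilever clamped at node 1 (local frame)
  Fm <- matrix(0, 6, 6)
  Fm[1, 1] <- L / (E * A)
  Fm[2, 2] <- L^3 / (3 * E * I) + L / (kappa * G * A)
  Fm[2, 6] <- Fm[6, 2] <- L^2 / (2 * E * I)
  Fm[3, 3] <- L^3 / (3 * E * I) + L / (kappa * G * A)
  Fm[3, 5] <- Fm[5, 3] <- -L^2 / (2 * E * I)
  Fm[4, 4] <- L / (G * J)
  Fm[5, 5] <- Fm[6, 6] <- L / (E * I)
  k22 <- solve(Fm)
  # rigid-body transfer: motion of node 2 induced by node-1 motion
  r <- c(L, 0, 0)
  S <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
  H <- rbind(cbind(diag(3), -S), cbind(matrix(0, 3, 3), diag(3)))
  K_local <- rbind(cbind(t(H) %*% k22 %*% H, -t(H) %*% k22),
                   cbind(-k22 %*% H, k22))
  # rotate to global (rows of R are the local axes)
  ex <- (p2 - p1) / L
  ref <- if (abs(ex[3]) < 0.99) c(0, 0, 1) else c(0, 1, 0)
  ey <- c(ref[2] * ex[3] - ref[3] * ex[2],
          ref[3] * ex[1] - ref[1] * ex[3],
          ref[1] * ex[2] - ref[2] * ex[1])
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  T12 <- matrix(0, 12, 12)
  for (b in 0:3) T12[b * 3 + 1:3, b * 3 + 1:3] <- R
  t(T12) %*% K_local %*% T12
}

# dense direct-stiffness assembly + solve for a small frame
oracle_frame_solve <- function(nodes, struts, d, fixed_nodes, F,
                               E = 116000, nu = 0.32) {
  n <- nrow(nodes)
  K <- matrix(0, 6 * n, 6 * n)
  for (k in seq_len(nrow(struts))) {
    i <- struts$i[k]; j <- struts$j[k]
    Ke <- oracle_element_k(nodes[i, ], nodes[j, ], d, E, nu)
    dofs <- c((i - 1) * 6 + 1:6, (j - 1) * 6 + 1:6)
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  fixed <- as.vector(outer(1:6, (fixed_nodes - 1) * 6, "+"))
  free <- setdiff(seq_len(6 * n), fixed)
  u <- numeric(6 * n)
  u[free] <- solve(K[free, free], F[free])
  u
}
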