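# Surface strain recovery and von Mises stress on circular struts.

test_that("uniform axial stretch reads the same tensile strain at every sample", {
  L <- 10; d <- 1; eps <- 300e-6
  model <- assemble(strut_lattice(L = L, d = d))
  u <- numeric(model$n_dof); u[7] <- eps * L     # node 2 axial displacement
  field <- surface_strain(manual_solution(model, u), model$lattice,
                          n_axial = 3, n_circ = 8)
  expect_equal(field$principal_ue, rep(300, nrow(field)), tolerance = 1e-9)
  expect_true(all(field$principal_ue > 0))       # tensile sign
})

test_that("pure bending gives extreme-fiber strain kappa d/2 with opposite signs across the section", {
  E <- 116000; L <- 10; d <- 1; I <- pi * d^4 / 64
  M <- 500  # N mm end moment -> constant curvature M/EI
  model <- assemble(strut_lattice(L = L, d = d, E = E))
  Fv <- numeric(model$n_dof); Fv[12] <- M        # moment about z at node 2
  u <- solve_clamped(model, 1:6, Fv)
  field <- surface_strain(manual_solution(model, u), model$lattice,
                          n_axial = 3, n_circ = 8)
  kappa <- M / (E * I)
  ref <- kappa * d / 2 * 1e6
  for (s in unique(field$s_mm)) {
    g <- field[field$s_mm == s, ]
    expect_equal(max(g$principal_ue), ref, tolerance = 1e-9)
    expect_equal(min(g$principal_ue), -ref, tolerance = 1e-9)
    # opposite fibers: theta and theta + pi carry opposite strains
    th <- g$theta
    opp <- match(round((th + pi) %% (2 * pi), 9), round(th, 9))
    expect_equal(g$eps, -g$eps[opp], tolerance = 1e-15)
  }
})

test_that("pure torsion yields principal strain (d/4) phi' at every angle (Mohr's circle of pure shear)", {
  E <- 116000; nu <- 0.32; G <- E / (2 * (1 + nu))
  L <- 10; d <- 1; J <- pi * d^4 / 32; Tq <- 80
  model <- assemble(strut_lattice(L = L, d = d, E = E, nu = nu))
  Fv <- numeric(model$n_dof); Fv[10] <- Tq
  u <- solve_clamped(model, 1:6, Fv)
  field <- surface_strain(manual_solution(model, u), model$lattice,
                          n_axial = 2, n_circ = 8)
  # independent hand computation: gamma = (d/2) T/(GJ); pure-shear Mohr
  # circle has principal strain gamma/2 -> (d/4) T/(GJ)
  ref <- (d / 4) * Tq / (G * J) * 1e6
  expect_lt(max(abs(abs(field$principal_ue) - ref)) / ref, 1e-10)
})

test_that("sample weights sum to the lateral strut surface area", {
  cage <- generate_cage(cage_params())
  model <- assemble(cage)
  u <- numeric(model$n_dof)
  field <- surface_strain(manual_solution(model, u), cage)
  lens <- sqrt(rowSums((cage$nodes[cage$struts$i, ] -
                        cage$nodes[cage$struts$j, ])^2))
  expect_equal(sum(field$weight_mm2),
               sum(pi * cage$struts$diameter_mm * lens), tolerance = 1e-12)
  # block exclusion removes exactly the block struts' surface
  field_nb <- surface_strain(manual_solution(model, u), cage,
                             include_block = FALSE)
  in_block <- cage$struts$i %in% cage$sets$screw_block &
    cage$struts$j %in% cage$sets$screw_block
  expect_equal(sum(field_nb$weight_mm2),
               sum(pi * (cage$struts$diameter_mm * lens)[!in_block]),
               tolerance = 1e-12)
})

test_that("von Mises peak matches sigma = E eps for uniaxial and sqrt(3) tau for pure shear", {
  E <- 116000; nu <- 0.32; G <- E / (2 * (1 + nu))
  L <- 10; d <- 1
  model <- assemble(strut_lattice(L = L, d = d, E = E, nu = nu))
  # uniaxial 1000 microstrain -> 116 MPa
  u <- numeric(model$n_dof); u[7] <- 1000e-6 * L
  expect_equal(von_mises_peak(manual_solution(model, u), model$lattice),
               116, tolerance = 1e-9)
  # pure shear tau = 100 MPa -> sqrt(3) * 100
  J <- pi * d^4 / 32
  Tq <- 100 * J / (d / 2)                     # tau = T (d/2) / J
  Fv <- numeric(model$n_dof); Fv[10] <- Tq
  u <- solve_clamped(model, 1:6, Fv)
  expect_equal(von_mises_peak(manual_solution(model, u), model$lattice),
               sqrt(3) * 100, tolerance = 1e-9)
  # zero field -> 0
  expect_equal(von_mises_peak(manual_solution(model, numeric(model$n_dof)),
                              model$lattice), 0)
})
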