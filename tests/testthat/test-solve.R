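# Operated-segment contact solve.

test_that("zero rotation and zero-ish force produce a vanishing displacement and strain field", {
  model <- assemble(generate_cage(cage_params()))
  bc <- direct_bc(rotation_deg = 0, axial_force_N = 1e-9)
  sol <- solve_load_case(model, bc, contact_params())
  expect_lt(max(abs(sol$u)), 1e-12)
  field <- surface_strain(sol)
  expect_lt(max(abs(field$principal_ue)), 1e-6)
})

test_that("pure axial compression in bonded mode inherits the lattice's midsagittal symmetry", {
  model <- assemble(generate_cage(cage_params()))
  bc <- direct_bc(rotation_deg = 0, axial_force_N = 300)
  sol <- solve_load_case(model, bc, contact_params(mode = "bonded"))
  cf <- sol$contact[sol$contact$side == "caudal", ]
  # pressures at (x, y) and (-x, y) must match
  key <- paste(round(cf$y, 6), round(abs(cf$x), 6))
  for (k in unique(key)) {
    g <- cf$pressure_MPa[key == k]
    expect_lt(diff(range(g)) / max(abs(g)), 1e-6)
  }
})

test_that("unilateral contact balances caudal normal forces plus the instrumentation share against the axial load", {
  model <- assemble(generate_cage(cage_params()))
  for (F in c(150, 400)) {
    bc <- direct_bc(rotation_deg = 0, axial_force_N = F)
    sol <- solve_load_case(model, bc, contact_params())
    caud_N <- sum(sol$contact$normal_force_N[sol$contact$side == "caudal"])
    expect_lt(abs(caud_N + sol$reactions$instrumentation_axial_N - F),
              1e-8 * F)
    expect_lt(sol$balance_rel, 1e-8)
    expect_gte(min(sol$contact$pressure_MPa), -1e-9)
  }
})

test_that("flexion loads the anterior half and extension the posterior half", {
  model <- assemble(generate_cage(cage_params()))
  reg_mean <- function(field) {
    w <- tapply(abs(field$principal_ue) * field$weight_mm2, field$region, sum)
    w / tapply(field$weight_mm2, field$region, sum)
  }
  sol_f <- solve_load_case(model, direct_bc(0.4, 250), contact_params())
  m_f <- reg_mean(surface_strain(sol_f))
  expect_gt(m_f[["anterior"]], m_f[["posterior"]])
  sol_e <- solve_load_case(model, direct_bc(-0.2, 200, condition = "extension"),
                           contact_params())
  m_e <- reg_mean(surface_strain(sol_e))
  expect_gt(m_e[["posterior"]], m_e[["anterior"]])
  # contact pressure centroid shifts the same way
  cf <- function(s) {
    cc <- s$contact[s$contact$side == "caudal", ]
    sum(cc$y * cc$normal_force_N) / sum(cc$normal_force_N)
  }
  expect_gt(cf(sol_f), cf(sol_e))
})

test_that("bonded mode reproduces the unilateral solution when all contact stays compressive", {
  model <- assemble(generate_cage(cage_params()))
  bc <- direct_bc(rotation_deg = 0, axial_force_N = 300)
  # friction off isolates the normal behaviour
  s_uni <- solve_load_case(model, bc, contact_params(friction_mu = 0))
  s_bon <- solve_load_case(model, bc, contact_params(friction_mu = 0,
                                                     mode = "bonded"))
  if (all(s_bon$contact$normal_force_N > 0))
    expect_equal(s_uni$u, s_bon$u, tolerance = 1e-10)
})

test_that("tangential tractions never exceed the Coulomb limit", {
  model <- assemble(generate_cage(cage_params()))
  mu <- 0.2
  for (rot in c(0.4, -0.2)) {
    sol <- solve_load_case(model, direct_bc(rot, 250),
                           contact_params(friction_mu = mu))
    act <- sol$contact[sol$contact$status != "open", ]
    expect_true(all(act$tangential_force_N <=
                      mu * act$normal_force_N + 1e-6))
  }
})

test_that("increasing strut diameter at fixed loads strictly decreases the median surface strain", {
  bc <- direct_bc(rotation_deg = 0.4, axial_force_N = 250)
  med <- vapply(c(0.6, 0.8, 1.0), function(d) {
    model <- assemble(generate_cage(cage_params(strut_diameter_mm = d)))
    sol <- solve_load_case(model, bc, contact_params())
    stats::median(abs(surface_strain(sol)$principal_ue))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
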