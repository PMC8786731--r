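# Lumped spine surrogate: follower loads, rotation distribution, IDP.

test_that("follower loads of the default cohort fall in the physiological per-condition ranges", {
  co <- sample_cohort(4, seed = 42)
  ranges <- list(neutral = c(368, 454), extension = c(748, 888),
                 flexion = c(976, 1148))
  for (p in co) for (cond in names(ranges)) {
    f <- follower_load(p, cond)
    expect_gte(f, ranges[[cond]][1])
    expect_lte(f, ranges[[cond]][2])
  }
})

test_that("follower load increases with weight and clamps (with a warning) outside the table hull", {
  base <- sample_cohort(1, seed = 1)[[1]]
  light <- base; light$weight_kg <- 60
  heavy <- base; heavy$weight_kg <- 74
  for (cond in load_conditions())
    expect_gte(follower_load(heavy, cond), follower_load(light, cond))
  giant <- base; giant$weight_kg <- 200
  expect_warning(f <- follower_load(giant, "neutral"), "clamped")
  cap <- base; cap$weight_kg <- 80    # table hull edge
  expect_equal(f, follower_load(cap, "neutral"))
})

test_that("identical linear FSUs split the rotation equally and carry moment 4k (series closed form)", {
  # near-linear map: huge softening scale makes sinh(theta/b) ~ theta/b
  k0 <- 3
  fsus <- lapply(setNames(disc_levels(), disc_levels()), function(lv)
    fsu_model(lv, k0 = k0, nonlinearity = 1e9))
  # negligible instrumentation: hair-thin rods
  inst0 <- instrumentation_params(rod_diameter_mm = 1e-3)
  lc <- load_case("flexion", follower_load_N = 1000)
  st <- distribute_rotation(fsus, "L4-L5", lc, inst0)
  expect_equal(unname(st$rotations_deg), rep(4, 5), tolerance = 1e-7)
  expect_equal(st$moment_Nm, 4 * k0, tolerance = 1e-6)
})

test_that("a rigidly instrumented level attracts no rotation; the others take 5 degrees each", {
  fsus <- lapply(setNames(disc_levels(), disc_levels()), function(lv)
    fsu_model(lv, k0 = 3, nonlinearity = 1e9))
  inst_inf <- instrumentation_params(rod_diameter_mm = 60)  # k -> huge
  lc <- load_case("flexion", follower_load_N = 1000)
  st <- distribute_rotation(fsus, "L4-L5", lc, inst_inf)
  expect_lt(abs(st$rotations_deg[["L4-L5"]]), 1e-3)
  others <- st$rotations_deg[names(st$rotations_deg) != "L4-L5"]
  expect_equal(unname(others), rep(5, 4), tolerance = 1e-3)
})

test_that("rotation conservation and series equilibrium hold for the default cohort", {
  co <- sample_cohort(4, seed = 42)
  for (p in co) {
    chain <- default_fsu_chain(p)
    for (cond in c("extension", "flexion")) {
      lc <- load_case(cond, p)
      st <- distribute_rotation(chain, "L4-L5", lc)
      expect_lt(abs(sum(st$rotations_deg) - lc$total_rotation_deg), 1e-8)
      # the instrumented-level augmented map must return the same chain moment
      lvl_m <- vapply(names(chain), function(lv) {
        m <- trusscage:::fsu_moment(chain[[lv]], st$rotations_deg[[lv]])
        if (lv == "L4-L5")
          m <- m + trusscage:::instrumentation_rot_stiffness(
            instrumentation_params()) * st$rotations_deg[[lv]]
        m
      }, numeric(1))
      expect_equal(unname(lvl_m), rep(st$moment_Nm, 5), tolerance = 1e-6)
    }
  }
})

test_that("neutral position carries zero rotations and moment", {
  p <- sample_cohort(1, seed = 3)[[1]]
  st <- distribute_rotation(default_fsu_chain(p), "L4-L5",
                            load_case("neutral", p))
  expect_identical(unname(st$rotations_deg), rep(0, 5))
  expect_identical(st$moment_Nm, 0)
})

test_that("load-deflection asymmetry: flexion reaction moment exceeds extension in magnitude", {
  co <- sample_cohort(4, seed = 42)
  for (p in co) {
    chain <- default_fsu_chain(p)
    m_f <- distribute_rotation(chain, "L4-L5", load_case("flexion", p))$moment_Nm
    m_e <- distribute_rotation(chain, "L4-L5", load_case("extension", p))$moment_Nm
    expect_gt(m_f, 0); expect_lt(m_e, 0)
    expect_gt(abs(m_f), abs(m_e))
  }
})

test_that("the IDP surrogate is linear in axial force and ordered by degeneration and condition", {
  f2 <- fsu_model("L3-L4", k0 = 3, pfirrmann_factor = 1.0)
  f3 <- fsu_model("L3-L4", k0 = 3, pfirrmann_factor = 0.6)
  # linearity: doubling F doubles the force increment exactly
  base <- disc_idp(f2, 0, 0, "neutral")
  i1 <- disc_idp(f2, 400, 0, "neutral") - base
  i2 <- disc_idp(f2, 800, 0, "neutral") - base
  expect_equal(i2, 2 * i1, tolerance = 1e-12)
  # degenerated disc has lower IDP at identical loads (flexion)
  expect_lt(disc_idp(f3, 1000, 20, "flexion"), disc_idp(f2, 1000, 20, "flexion"))
  # condition weighting: flexion > extension > 0 at same loads
  expect_gt(disc_idp(f2, 900, 15, "flexion"), disc_idp(f2, 900, 15, "extension"))
  expect_gt(disc_idp(f2, 900, 15, "extension"), 0)
  expect_error(disc_idp(f2, -5, 0, "neutral"), ">= 0")
})

test_that("IDP of every default-cohort disc is larger in flexion than extension and positive", {
  co <- sample_cohort(4, seed = 42)
  for (p in co) {
    chain <- default_fsu_chain(p)
    st_f <- distribute_rotation(chain, "L4-L5", load_case("flexion", p))
    st_e <- distribute_rotation(chain, "L4-L5", load_case("extension", p))
    keep <- names(st_f$idp_MPa) != "L4-L5"
    expect_true(all(st_f$idp_MPa[keep] > st_e$idp_MPa[keep]))
    expect_true(all(st_e$idp_MPa[keep] > 0))
  }
})

test_that("segment BC carries the instrumented level's rotation share with the sign convention", {
  p <- sample_cohort(1, seed = 9)[[1]]
  chain <- default_fsu_chain(p)
  for (cond in c("extension", "flexion")) {
    lc <- load_case(cond, p)
    st <- distribute_rotation(chain, "L4-L5", lc)
    bc <- segment_bc(st, p, lc)
    expect_identical(bc$cranial_plate_rotation_deg,
                     st$rotations_deg[["L4-L5"]])
    expect_identical(bc$axial_force_N, lc$follower_load_N)
    if (cond == "extension") expect_lt(bc$cranial_plate_rotation_deg, 0)
    else expect_gt(bc$cranial_plate_rotation_deg, 0)
  }
  # ramp-step count must not change the final BC of this monotone protocol
  lc1 <- load_case("flexion", p, n_ramp_steps = 1)
  lc10 <- load_case("flexion", p, n_ramp_steps = 10)
  st1 <- distribute_rotation(chain, "L4-L5", lc1)
  st10 <- distribute_rotation(chain, "L4-L5", lc10)
  b1 <- segment_bc(st1, p, lc1); b10 <- segment_bc(st10, p, lc10)
  expect_equal(b1$cranial_plate_rotation_deg, b10$cranial_plate_rotation_deg)
  expect_equal(b1$axial_force_N, b10$axial_force_N)
})
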