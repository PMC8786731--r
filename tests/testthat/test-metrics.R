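# Output statistics: threshold fraction, histogram, contact pressure, CVs.

mk_field <- function(strain, w = rep(1, length(strain)))
  data.frame(principal_ue = strain, weight_mm2 = w)

test_that("threshold fraction counts strictly-exceeding samples, area-weighted", {
  expect_equal(threshold_fraction(mk_field(rep(300, 5))), 100)
  expect_equal(threshold_fraction(mk_field(c(100, 100, 300, 300))), 50)
  # boundary samples at exactly the threshold do not count
  x <- c(50, 150, 250, -300, 199, 201, -201)
  expect_equal(threshold_fraction(mk_field(x)), 100 * 4 / 7)
  # brute-force equivalence on unit weights for random fields
  set.seed(1)
  for (i in 1:5) {
    s <- runif(200, -600, 600)
    expect_identical(threshold_fraction(mk_field(s)),
                     100 * mean(abs(s) > 200))
  }
  # weighting: doubling one sample's area doubles its share
  f <- mk_field(c(100, 300), w = c(1, 3))
  expect_equal(threshold_fraction(f), 75)
  expect_error(threshold_fraction(mk_field(numeric(0))), "empty")
})

test_that("threshold limits: zero threshold counts nonzero samples; infinite threshold counts none", {
  f <- mk_field(c(0, 0, 10, -10, 500))
  expect_equal(threshold_fraction(f, 0), 100 * 3 / 5)
  expect_equal(threshold_fraction(f, Inf), 0)
})

test_that("strain histogram bins are half-open, order-invariant and sum to 100", {
  f <- mk_field(c(50, 150, 250, 600))
  h <- strain_histogram(f, c(0, 100, 200, 500))
  expect_equal(unname(h), c(25, 25, 25, 25))
  expect_equal(sum(h), 100, tolerance = 1e-9)
  # all-zero strains land in the first bin
  expect_equal(unname(strain_histogram(mk_field(rep(0, 7)),
                                       c(0, 100, 200, 500))[1]), 100)
  # permutation invariance
  set.seed(2)
  s <- runif(100, 0, 800)
  h1 <- strain_histogram(mk_field(s), c(0, 100, 200, 500))
  h2 <- strain_histogram(mk_field(sample(s)), c(0, 100, 200, 500))
  expect_equal(h1, h2)
  # boundary values belong to the upper bin ([e_i, e_{i+1}))
  hb <- strain_histogram(mk_field(c(100, 200, 500)), c(0, 100, 200, 500))
  expect_equal(unname(hb), c(0, 100 / 3, 100 / 3, 100 / 3))
  expect_error(strain_histogram(f, c(0, 200, 100)), "increasing")
})

test_that("merging adjacent histogram bins sums their percentages exactly", {
  set.seed(3)
  f <- mk_field(runif(300, 0, 900), w = runif(300, 0.5, 2))
  fine <- strain_histogram(f, c(0, 100, 200, 500))
  coarse <- strain_histogram(f, c(0, 100, 500))
  expect_identical(unname(coarse[2]), unname(fine[2] + fine[3]))
  expect_identical(unname(coarse[1]), unname(fine[1]))
  expect_identical(unname(coarse[3]), unname(fine[4]))
})

mk_contact <- function(force, area, status = rep("stick", length(force)))
  data.frame(side = "caudal", normal_force_N = force, area_mm2 = area,
             status = status)

test_that("mean contact pressure normalizes by active contact area", {
  # uniform pressure p on all active nodes returns exactly p
  expect_equal(mean_contact_pressure(mk_contact(rep(12, 9), rep(3, 9))), 4)
  # {10, 30} N over {2, 2} mm^2 -> 40/4 = 10 MPa
  expect_equal(mean_contact_pressure(mk_contact(c(10, 30), c(2, 2))), 10)
  # nothing in contact -> 0
  expect_equal(mean_contact_pressure(
    mk_contact(c(0, 0), c(2, 2), status = c("open", "open"))), 0)
  # open nodes do not dilute the active-area normalization
  cf <- mk_contact(c(10, 30, 0), c(2, 2, 2), c("stick", "slip", "open"))
  expect_equal(mean_contact_pressure(cf), 10)
  expect_equal(mean_contact_pressure(cf, normalize = "nominal"), 40 / 6)
  # node ordering and co-located node splitting leave the mean unchanged
  expect_equal(mean_contact_pressure(mk_contact(c(30, 10), c(2, 2))), 10)
  expect_equal(mean_contact_pressure(mk_contact(c(10, 15, 15), c(2, 1, 1))), 10)
})

test_that("cohort CVs use the unbiased estimator and amalgamate left/right cages first", {
  cases <- expand.grid(patient = paste0("P", 1:4),
                       condition = c("extension", "flexion"),
                       cage = c("left", "right"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cases$fraction_above_threshold <- 10
  cases$mean_caudal_pressure_MPa <- 2
  # flexion per-patient values 8, 10, 10, 12 (identical left/right)
  v <- c(P1 = 8, P2 = 10, P3 = 10, P4 = 12)
  sel <- cases$condition == "flexion"
  cases$fraction_above_threshold[sel] <- v[cases$patient[sel]]
  s <- cohort_summary(cases)
  expect_equal(unname(s$metrics$fraction_above_threshold$
                        cv_across_patients[["flexion"]]),
               100 * sqrt(8 / 3) / 10, tolerance = 1e-9)   # 16.32993 %
  expect_equal(unname(s$metrics$fraction_above_threshold$
                        cv_across_patients[["extension"]]), 0)
  # asymmetric left/right values are averaged before the CV
  cases2 <- cases
  sel_l <- sel & cases2$cage == "left"
  sel_r <- sel & cases2$cage == "right"
  cases2$fraction_above_threshold[sel_l] <- v[cases2$patient[sel_l]] + 1
  cases2$fraction_above_threshold[sel_r] <- v[cases2$patient[sel_r]] - 1
  s2 <- cohort_summary(cases2)
  expect_equal(s2$metrics$fraction_above_threshold$cv_across_patients,
               s$metrics$fraction_above_threshold$cv_across_patients)
})

test_that("degenerate cohort summaries are handled explicitly", {
  cases <- expand.grid(patient = c("P1", "P2", "P3", "P4"),
                       condition = "flexion", cage = "left",
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cases$fraction_above_threshold <- c(7, 7, 7, 7)
  cases$mean_caudal_pressure_MPa <- 1
  w <- capture_warnings(s <- cohort_summary(cases))
  expect_true(any(grepl("single condition", w)))
  expect_equal(unname(s$metrics$fraction_above_threshold$
                        cv_across_patients[["flexion"]]), 0)
  expect_true(is.na(s$metrics$fraction_above_threshold$
                      cv_across_conditions[1]))
  expect_error(cohort_summary(cases[cases$patient == "P1", ]), ">= 2")
  # zero mean -> NA with warning
  cases$fraction_above_threshold <- 0
  cases$condition <- rep(c("flexion", "extension"), 2)
  w0 <- capture_warnings(s0 <- cohort_summary(cases))
  expect_true(any(grepl("zero mean", w0)))
})
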