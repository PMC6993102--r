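test_that("BMI arithmetic is exact and rejects non-positive input", {
  expect_equal(compute_bmi(80, 2.0), 20.0)
  expect_equal(compute_bmi(90, 1.5), 40.0)
  expect_equal(compute_bmi(72.25, 1.7), 25.0)
  expect_equal(compute_bmi(c(80, 90), c(2, 1.5)), c(20, 40))
  expect_error(compute_bmi(0, 1.7), "positive")
  expect_error(compute_bmi(80, -1), "positive")
})

test_that("WHO categories follow the standard cut points with inclusive lower bounds", {
  expect_equal(as.character(who_category(32)), "obese_1")
  expect_equal(as.character(who_category(25.0)), "overweight")
  expect_equal(as.character(who_category(41)), "obese_3")
  expect_equal(as.character(who_category(c(18, 24.99, 30, 35, 40))),
               c("eutrophic", "eutrophic", "obese_1", "obese_2", "obese_3"))
  # below the eutrophic floor is flagged, never silently eutrophic
  expect_equal(as.character(who_category(17.5)), "underweight")
  expect_error(who_category(0), "positive")

  expect_equal(as.character(bmi_class(c(22, 27, 33))),
               c("control", "case", "case"))
  expect_true(is.na(bmi_class(17)))
})

test_that("generated cohorts are reproducible, balanced and internally consistent", {
  a <- tiny_cohort(seed = 42)
  b <- tiny_cohort(seed = 42)
  c <- tiny_cohort(seed = 43)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_false(identical(a$matrix$values, c$matrix$values))

  m <- a$matrix
  expect_equal(dim(m), c(2 * 12 * 3, 60))
  expect_equal(m$mz, 250L + 0:59)
  expect_true(all(m$values >= 0))
  pt <- patient_table(m)
  expect_equal(sum(pt$class == "case"), 12)
  expect_equal(sum(pt$class == "control"), 12)

  s <- a$subjects
  expect_equal(s$bmi, s$weight / s$height^2, tolerance = 1e-9)
  expect_identical(as.character(bmi_class(s$bmi)), s$class)
  expect_true(all(who_category(s$bmi[s$class == "case"]) >= "overweight"))
})

test_that("planted dependent members are exact linear combinations of their generators", {
  coh <- tiny_cohort(seed = 3)
  v <- coh$matrix$values
  mz <- coh$matrix$mz
  dg <- coh$truth$dependent_groups
  for (k in seq_len(nrow(dg))) {
    expect_equal(v[, match(dg$member_mz[k], mz)],
                 dg$coefficient[k] * v[, match(dg$generator_mz[k], mz)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # with jitter, dependence holds only within the stated tolerance
  coh_j <- generate_cohort(tiny_spec(member_jitter_sd = 0.01), seed = 3)
  vj <- coh_j$matrix$values
  r <- vj[, match(dg$member_mz[1], mz)] /
    (dg$coefficient[1] * vj[, match(dg$generator_mz[1], mz)])
  expect_true(all(abs(log(r)) < 0.06))
  expect_gt(stats::sd(log(r)), 0)
})

test_that("zero marker shift leaves class distributions indistinguishable", {
  spec <- tiny_spec(marker_channels = data.frame(mz = c(255L, 270L),
                                                 shift = 0))
  coh <- generate_cohort(spec, seed = 5)
  x <- normalize_rows(coh$matrix)
  d <- detect_markers(x, c(255L, 270L))
  expect_true(all(abs(d$delta_j) < 0.25))
  expect_false(any(d$is_marker))
})

test_that("default spec matches the emulated acquisition design", {
  spec <- synthetic_spec()
  expect_equal(spec$n_channels, 1752)
  expect_equal(range(spec$mz), c(250L, 2001L))
  expect_equal(nrow(spec$marker_channels), 5)
  expect_equal(nrow(spec$dependent_groups), 20)
  coh <- generate_cohort(spec, seed = 1)
  expect_equal(dim(coh$matrix), c(2 * 90 * 5, 1752))
})

test_that("spec validation rejects inconsistent plants and bad rates", {
  expect_error(synthetic_spec(
    marker_channels = data.frame(mz = 260L, shift = 3),
    dependent_groups = data.frame(generator_mz = 260L, member_mz = 280L,
                                  coefficient = 0.5)),
    "disjoint")
  expect_error(synthetic_spec(
    dependent_groups = data.frame(generator_mz = c(500L, 510L),
                                  member_mz = c(900L, 900L),
                                  coefficient = c(0.5, 0.4))),
    "one dependency group")
  expect_error(synthetic_spec(
    marker_channels = data.frame(mz = 100L, shift = 3)), "outside")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
})

test_that("missing replicates never silence a whole patient", {
  coh <- generate_cohort(tiny_spec(missing_rate = 0.4), seed = 11)
  m <- coh$matrix
  expect_lt(nrow(m$values), 72)
  expect_equal(length(unique(m$patient)), 24)
})

test_that("planted markers at 3-sigma shift separate classes in nearly every draw", {
  spec <- synthetic_spec(
    n_per_class = 50, replicates_per_patient = 5, n_channels = 100,
    marker_channels = data.frame(mz = c(270L, 300L), shift = 3),
    dependent_groups = data.frame(generator_mz = integer(0),
                                  member_mz = integer(0),
                                  coefficient = numeric(0)))
  ok <- vapply(1:20, function(s) {
    x <- normalize_rows(generate_cohort(spec, seed = s)$matrix)
    all(detect_markers(x, c(270L, 300L))$delta_j > 0.4)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
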