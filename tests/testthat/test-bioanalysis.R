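test_that("fold change reproduces the printed compartment ratios", {
  expect_equal(fold_change(250, 150)$reported, 1.7)
  expect_equal(fold_change(430, 200)$reported, 2.2)
  expect_equal(fold_change(123.4, 123.4)$reported, 1.0)
  expect_equal(fold_change(250, 150)$raw, 250 / 150)
  expect_error(fold_change(1, 0), "positive")
})

test_that("fold change is scale invariant and rounds half away from zero", {
  set.seed(41)
  for (i in 1:20) {
    t <- runif(1, 1, 500)
    c0 <- runif(1, 1, 500)
    a <- runif(1, 0.1, 10)
    expect_equal(fold_change(a * t, a * c0)$raw, fold_change(t, c0)$raw)
  }
  # 2.15 must round up to 2.2, not to even
  expect_equal(fold_change(215, 100)$reported, 2.2)
  expect_equal(fold_change(125, 1000)$reported, 0.13)
})

test_that("B:Fe ratio matches the 18:1 anion stoichiometry", {
  theo <- b_fe_stoichiometry()
  expect_equal(unname(theo["mass"]), 18 * 10.811 / 55.845)
  expect_equal(unname(theo["molar"]), 18)
  rec <- data.frame(element = rep(c("B", "Fe"), 2),
                    compartment = rep(c("nucleus", "cytoplasm"), each = 2),
                    amount = c(3.484609, 1, 6.969218, 2))
  r <- b_fe_ratio(rec)
  expect_equal(r$ratio_mass, c(3.484609, 3.484609))
  expect_error(b_fe_ratio(rec[rec$element == "B", ]), "missing element")
})

test_that("measured B:Fe ratio lands near stoichiometry under assay noise", {
  hits <- 0
  for (s in 1:100) {
    r <- b_fe_ratio(gen_icpms_uptake(cv = 0.1, n = 6, seed = s))
    if (all(r$ratio_mass >= 3.0 & r$ratio_mass <= 4.0)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("growth rate follows the relative-change formula", {
  curve <- data.frame(time = c(0, 2, 5, 10), n = c(100, 300, 100, 50))
  expect_equal(growth_rate(curve, 2), 200)
  expect_equal(growth_rate(curve, 5), 0)
  expect_equal(growth_rate(curve, 10), -50)
  # invariant under rescaling the cell-number proxy
  curve2 <- curve
  curve2$n <- curve$n * 7.3
  expect_equal(growth_rate(curve2, 10), growth_rate(curve, 10))
  expect_error(growth_rate(curve, 3), "not sampled")
  expect_error(growth_rate(data.frame(time = c(0, 1), n = c(0, 5)), 1), "positive")
})

test_that("survival fraction is the clonogenic normalization", {
  expect_equal(as.numeric(survival_fraction(50, 100, 0.5)), 1.0)
  expect_equal(as.numeric(survival_fraction(0, 100, 0.5)), 0)
  sf <- survival_fraction(80, 100, 0.5)
  expect_true(attr(sf, "clipped"))
  expect_error(survival_fraction(10, 0, 0.5), "positive")
  expect_error(survival_fraction(10, 100, 0), "plating")
})

test_that("survival estimator is unbiased over generator replicates", {
  est <- vapply(1:1000, function(s)
    mean(survival_fraction(gen_colony_counts(0.4, 100, 0.6, 3, seed = s),
                           100, 0.6)), numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.05)
})

test_that("ROS fold change is a pointwise ratio of means with delta-method SD", {
  tt <- data.frame(time = rep(c(0, 4, 8), each = 2), value = rep(c(2, 4, 6), each = 2))
  rr <- data.frame(time = rep(c(0, 4, 8), each = 2), value = rep(1, 6))
  out <- ros_fold(tt, rr)
  expect_equal(out$fold, c(2, 4, 6))
  expect_equal(out$sd, c(0, 0, 0))
  expect_equal(ros_fold(tt, tt)$fold, c(1, 1, 1))
  rr_bad <- data.frame(time = c(0, 5, 8), value = 1)
  expect_error(ros_fold(tt, rr_bad), "aligned")
  # noiseless generator: growing treated over flat reference rises strictly
  tr <- gen_ros_kinetics(slope_per_hour = 0.03, cv = 0, seed = 1)
  rf <- gen_ros_kinetics(slope_per_hour = 0, cv = 0, seed = 2)
  expect_true(all(diff(ros_fold(tr, rf)$fold) > 0))
})

test_that("IC50 fit recovers exact 4PL data to high precision", {
  d <- gen_dose_response(ic50 = 83.5, cv = 0, seed = 1)
  f <- fit_ic50(d)
  expect_equal(f$ic50, 83.5, tolerance = 1e-3)
  expect_equal(f$top, 1, tolerance = 1e-3)
  expect_equal(f$bottom, 0.05, tolerance = 1e-2)
  expect_false(f$inverted)
  # deterministic given the data
  expect_identical(fit_ic50(d)$ic50, f$ic50)
})

test_that("IC50 fit flags degenerate monotone-increasing input", {
  d <- data.frame(concentration = rep(10^seq(0, 3, by = 0.5), each = 2))
  d$viability <- 0.2 + 0.7 * d$concentration / (100 + d$concentration)
  res <- tryCatch(withCallingHandlers(
    fit_ic50(d),
    warning = function(w) {
      expect_match(conditionMessage(w), "increases with concentration")
      invokeRestart("muffleWarning")
    }), error = function(e) e)
  if (!inherits(res, "error")) expect_true(res$inverted)
  expect_error(fit_ic50(data.frame(concentration = c(1, 2, 3),
                                   viability = c(1, 0.5, 0))), "5 distinct")
})
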