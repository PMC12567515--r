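test_that("every generator is deterministic under a fixed seed and requires one", {
  expect_identical(gen_icpms_uptake(seed = 5), gen_icpms_uptake(seed = 5))
  expect_identical(gen_dose_response(seed = 5), gen_dose_response(seed = 5))
  expect_identical(gen_colony_counts(0.4, seed = 5), gen_colony_counts(0.4, seed = 5))
  expect_identical(gen_ros_kinetics(seed = 5), gen_ros_kinetics(seed = 5))
  expect_identical(gen_biodistribution(seed = 5), gen_biodistribution(seed = 5))
  expect_identical(gen_elemental_map(seed = 5), gen_elemental_map(seed = 5))
  expect_error(gen_icpms_uptake(), "seed")
  expect_error(gen_dose_response(), "seed")
  expect_error(gen_colony_counts(0.4), "seed")
})

test_that("ICP-MS generator honours stoichiometry and converges to truth", {
  u0 <- gen_icpms_uptake(true_B_ng = 150, cv = 0, seed = 1)
  r <- b_fe_ratio(u0)
  expect_equal(r$ratio_mass, rep(b_fe_stoichiometry()[["mass"]], 2))
  # noiseless amounts split exactly by the compartment fraction
  b_nuc <- u0$amount[u0$element == "B" & u0$compartment == "nucleus"]
  expect_true(all(b_nuc == 150 * 0.4))
  # law of large numbers: the lognormal is mean-parameterized
  u <- gen_icpms_uptake(true_B_ng = 150, cv = 0.1, n = 1e4, seed = 2)
  b_tot <- sum(tapply(u$amount[u$element == "B"],
                      u$compartment[u$element == "B"], mean))
  expect_equal(b_tot, 150, tolerance = 0.01)
  expect_error(gen_icpms_uptake(compartment_split = 1.4, seed = 1), "split")
})

test_that("elemental map reproduces compartment levels, masks and fold changes", {
  m0 <- gen_elemental_map(noise_sd = 0, seed = 1)
  expect_equal(mean(m0$map[m0$nucleus_mask]), 430)
  expect_equal(mean(m0$map[m0$cytoplasm_mask]), 250)
  # mask areas close to the analytic disk areas
  expect_lt(abs(sum(m0$nucleus_mask) - pi * 16^2), 2 * pi * 16 * 1.5)
  expect_lt(abs(sum(m0$nucleus_mask | m0$cytoplasm_mask) - pi * 40^2),
            2 * pi * 40 * 1.5)
  # treated-vs-control maps reproduce the 1.7x/2.2x compartment fold changes
  ctrl <- gen_elemental_map(cyto_level = 150, nucleus_level = 200,
                            noise_sd = 0, seed = 2)
  expect_equal(fold_change(mean(m0$map[m0$cytoplasm_mask]),
                           mean(ctrl$map[ctrl$cytoplasm_mask]))$reported, 1.7)
  expect_equal(fold_change(mean(m0$map[m0$nucleus_mask]),
                           mean(ctrl$map[ctrl$nucleus_mask]))$reported, 2.2)
  expect_error(gen_elemental_map(nucleus_radius_px = 50, seed = 1), "inside")
})

test_that("dose-response generator sits on the 4PL curve at zero noise", {
  conc <- c(10, 30, 83.5, 250, 750)
  d <- gen_dose_response(ic50 = 83.5, hill = 1.5, top = 1, bottom = 0.05,
                         cv = 0, concentrations = conc, n = 1, seed = 3)
  # response at the IC50 is the midpoint of the asymptotes
  expect_equal(d$viability[d$concentration == 83.5], (1 + 0.05) / 2)
  expect_error(gen_dose_response(ic50 = 5000, seed = 1), "span")
})

test_that("colony generator is Poisson with the clonogenic mean", {
  expect_true(all(gen_colony_counts(0, seed = 4) == 0))
  big <- gen_colony_counts(0.4, 100, 0.6, wells = 1e4, seed = 5)
  expect_equal(mean(big), 100 * 0.6 * 0.4, tolerance = 0.02)
  big2 <- gen_colony_counts(0.4, 200, 0.6, wells = 1e4, seed = 6)
  expect_equal(mean(big2) / mean(big), 2, tolerance = 0.05)
})

test_that("biodistribution kinetics retain tumour longer than liver and lung", {
  flat <- gen_biodistribution(organ_params = data.frame(
    organ = "tumor", A = 8, lambda = 0), times_h = c(1, 4), n_mice = 3,
    cv = 0, seed = 7)
  expect_equal(flat$pid_g[flat$time_h == 1], flat$pid_g[flat$time_h == 4])
  b <- gen_biodistribution(n_mice = 200, cv = 0.1, seed = 8)
  keep <- function(org, t) mean(b$pid_g[b$organ == org & b$time_h == t])
  expect_gt(keep("tumor", 4) / keep("tumor", 1),
            keep("liver", 4) / keep("liver", 1))
  expect_gt(keep("tumor", 4) / keep("tumor", 1),
            keep("lung", 4) / keep("lung", 1))
})

test_that("biodistribution parameters are recoverable by log-linear regression", {
  b <- gen_biodistribution(times_h = c(1, 2, 4, 8), n_mice = 250, seed = 9)
  tr <- attr(b, "truth")$organ_params
  for (org in c("tumor", "liver")) {
    sub <- b[b$organ == org, ]
    fit <- lm(log(pid_g) ~ time_h, sub)
    lam <- -unname(coef(fit)[2])
    A <- exp(unname(coef(fit)[1]) + 0.5 * var(resid(fit)))  # lognormal mean
    expect_equal(lam, tr$lambda[tr$organ == org], tolerance = 0.05)
    expect_equal(A, tr$A[tr$organ == org], tolerance = 0.05)
  }
})

test_that("ROS generator is flat without slope and fold-invariant to baseline", {
  flat <- gen_ros_kinetics(slope_per_hour = 0, cv = 0, seed = 10)
  expect_identical(length(unique(flat$value)), 1L)
  a <- gen_ros_kinetics(baseline = 1000, slope_per_hour = 0.02, cv = 0, seed = 11)
  b <- gen_ros_kinetics(baseline = 2000, slope_per_hour = 0.02, cv = 0, seed = 11)
  ref_a <- gen_ros_kinetics(baseline = 1000, slope_per_hour = 0, cv = 0, seed = 12)
  ref_b <- gen_ros_kinetics(baseline = 2000, slope_per_hour = 0, cv = 0, seed = 12)
  expect_equal(ros_fold(a, ref_a)$fold, ros_fold(b, ref_b)$fold)
})
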