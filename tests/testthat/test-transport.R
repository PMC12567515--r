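test_that("energy-to-dose conversion follows the Gy definition", {
  expect_equal(dose_from_energy(1, 1e-9), 0.1602, tolerance = 1e-3)
  expect_identical(dose_from_energy(0, 1), 0)
  # 2.31 MeV fully absorbed in the default 5 um nucleus (hand conversion)
  m_nucleus <- 4 / 3 * pi * 5^3 * 1e-12       # g at unit density
  expect_equal(dose_from_energy(2.31, m_nucleus), 0.7068, tolerance = 1e-3)
  expect_error(dose_from_energy(1, 0), "positive")
})

test_that("isotropic sampling is uniform on the unit sphere", {
  set.seed(12)
  d <- sample_isotropic(1e5)
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-12))
  expect_lt(abs(mean(d[, 3])), 0.01)
  ks <- suppressWarnings(stats::ks.test(d[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("runs are bit-reproducible for a fixed seed", {
  cell <- cell_model()
  t1 <- run_mc(beam_spec(0.675, "broad"), cell, 2000, 4, seed = 99)
  t2 <- run_mc(beam_spec(0.675, "broad"), cell, 2000, 4, seed = 99)
  expect_identical(t1$dose_Gy, t2$dose_Gy)
  expect_identical(attr(t1, "batch_dose"), attr(t2, "batch_dose"))
  t3 <- run_mc(beam_spec(0.675, "broad"), cell, 2000, 4, seed = 100)
  expect_false(identical(t1$dose_Gy, t3$dose_Gy))
})

test_that("energy is conserved per batch: injected = deposits + escapes", {
  cell <- cell_model()
  beam <- beam_spec(0.675, "broad", flux_per_s = 1e6, duration_s = 1)
  tal <- run_mc(beam, cell, 1000, 2, seed = 3)
  injected <- beam$flux_per_s * beam$duration_s * 0.675
  expect_equal(sum(tal$energy_MeV) + attr(tal, "escaped_MeV"), injected,
               tolerance = 1e-9)
  # 2 MeV protons escape the 25 um cell: both sides of the ledger nonzero
  tal2 <- run_mc(beam_spec(2, "broad", flux_per_s = 1e6, duration_s = 1),
                 cell, 1000, 2, seed = 3)
  expect_gt(attr(tal2, "escaped_MeV"), 0)
  expect_equal(sum(tal2$energy_MeV) + attr(tal2, "escaped_MeV"), 2e6,
               tolerance = 1e-9)
})

test_that("kernel track length reproduces the quadrature CSDA range", {
  geo <- celldose:::.transport_geometry(sphere_stack(100, "water", "slab"))
  for (e0 in c(0.675, 2)) {
    out <- celldose:::.cd_transport(
      matrix(c(0, 0, -99), 1), matrix(c(0, 0, 1), 1), e0, 1, "proton",
      geo$radii, geo$mat_id, geo$mats, 0.01, 1e-3, FALSE, TRUE)
    expect_equal(out$track_length_um, csda_range(e0, "proton")$range_um,
                 tolerance = 5e-3)
    expect_equal(sum(out$deposit) + out$escaped, e0, tolerance = 1e-12)
  }
})

test_that("single-step semantics: attribution, energy bookkeeping, Bragg rise", {
  cell <- cell_model()
  # a step fully inside the cytoplasm deposits into the cytoplasm
  st <- particle_state("proton", c(0, 0, -12.4), c(0, 0, 1), 0.675)
  s1 <- transport_step(st, cell)
  expect_identical(s1$region, "cytoplasm")
  expect_gt(s1$deposit_MeV, 0)
  # full track: deposits sum exactly to the initial energy; dE/ds rises
  # monotonically toward the track end (Bragg behaviour, straggling off)
  state <- particle_state("proton", c(0, 0, -13), c(0, 0, 1), 0.675)
  dep <- 0
  let_seq <- numeric(0)
  pos_prev <- state$position
  while (state$alive) {
    out <- transport_step(state, cell)
    ds <- sqrt(sum((out$state$position - pos_prev)^2))
    if (out$region != "exterior" && ds > 0)
      let_seq <- c(let_seq, out$deposit_MeV / ds)
    dep <- dep + out$deposit_MeV
    pos_prev <- out$state$position
    state <- out$state
  }
  expect_equal(dep, 0.675, tolerance = 1e-12)
  expect_true(all(diff(let_seq) > -1e-12))
  expect_error(transport_step(state, cell), "alive")
  expect_error(transport_step(particle_state("proton", c(0, 0, -13),
                                             c(0, 0, 1), 1), cell, 0.2),
               "max_fractional_loss")
})

test_that("broad-beam dose on a thin water sphere matches the analytic thin-target value", {
  ss <- sphere_stack(1, "water", "sphere")
  beam <- beam_spec(2, "broad", flux_per_s = 2e7, duration_s = 10)
  tal <- run_mc(beam, ss, 2e4, 10, seed = 7)
  analytic <- attr(tal, "fluence_cm2") * stopping_power(2, "proton") *
    1.602176634e-10
  expect_equal(tal$dose_Gy, analytic, tolerance = 0.01)
})

test_that("tally relative error scales as one over the square root of N", {
  cell <- cell_model()
  ns <- c(1e3, 1e4, 1e5)
  relerr <- vapply(ns, function(n) {
    t <- run_mc(beam_spec(0.675, "broad"), cell, n, batches = 20, seed = 11)
    t$rel_err[t$region == "nucleus"]
  }, numeric(1))
  slope <- unname(coef(lm(log(relerr) ~ log(ns)))[2])
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("beam and geometry constructors validate their invariants", {
  expect_error(beam_spec(-1), "positive")
  expect_error(beam_spec(2, flux_per_s = 0), "fluence")
  expect_error(particle_state("proton", c(0, 0, 0), c(0, 0, 2), 1), "unit norm")
  expect_error(particle_state("proton", c(0, 0, 0), c(0, 0, 1), -1), "non-negative")
  expect_error(sphere_stack(c(2, 1), c("water", "water")), "increasing")
  expect_error(run_mc(beam_spec(2), cell_model(), 10, 1), "batches")
  # square field must cover the cell disk
  expect_error(run_mc(beam_spec(2, "square", side_um = 10), cell_model(), 100, 2),
               "cover")
})
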