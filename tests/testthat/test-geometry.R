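test_that("cell model validates its nesting invariants", {
  expect_s3_class(cell_model(), "cell_model")
  expect_error(cell_model(nucleus_radius = 13), "nucleus < cell")
  expect_error(cell_model(boron_sphere_radius = 0), "nucleus < cell")
  expect_error(cell_model(boron_sphere_radius = 4.95, shell_count = 10,
                          shell_thickness_nm = 10), "nucleus < cell")
})

test_that("region volumes close to the cell volume and masses follow density", {
  cell <- cell_model()
  tab <- region_table(cell)
  expect_equal(sum(tab$volume_um3), 4 / 3 * pi * 12.5^3, tolerance = 1e-9)
  expect_equal(tab$mass_g, tab$volume_um3 * 1e-12)   # all water at 1 g/cm^3
  tab_b <- region_table(cell_model(boron_material = "boron"))
  expect_equal(tab_b$mass_g[1], tab_b$volume_um3[1] * 1e-12 * 2.37)
})

test_that("point location assigns regions with inner-region boundary ties", {
  cell <- cell_model()
  expect_identical(locate(c(0, 0, 0), cell), "boron_sphere")
  expect_identical(locate(c(10, 0, 0), cell), "cytoplasm")
  expect_identical(locate(c(0, 0, 3), cell), "nucleus")
  expect_identical(locate(c(0, 20, 0), cell), "exterior")
  # 25 nm beyond the boron surface falls in the 3rd 10-nm shell (1-based)
  expect_identical(locate(c(0, 0, 1.5 + 0.025), cell), "shell_3")
  # boundary ties go inward
  expect_identical(locate(c(0, 0, 1.5), cell), "boron_sphere")
  expect_identical(locate(c(5, 0, 0), cell), "nucleus")
  expect_identical(locate(c(0, 12.5, 0), cell), "cytoplasm")
  expect_error(locate(c(0, 0), cell), "length-3")
})

test_that("diametral ray trace yields the analytic chord decomposition", {
  cell <- cell_model()
  tr <- ray_trace(c(0, 0, -20), c(0, 0, 1), cell)
  expect_equal(sum(tr$length_um), 25)
  agg <- tapply(tr$length_um, tr$region, sum)
  expect_equal(unname(agg[["cytoplasm"]]), 2 * (12.5 - 5))
  expect_equal(unname(agg[["boron_sphere"]]), 3)
  # nucleus segment: nucleus radius minus boron sphere minus the 100 nm stack
  expect_equal(unname(agg[["nucleus"]]), 2 * (5 - 1.5 - 0.1))
  for (k in 1:10) expect_equal(unname(agg[[paste0("shell_", k)]]), 0.02)
})

test_that("rays that miss or graze the cell produce the right segments", {
  cell <- cell_model()
  miss <- ray_trace(c(13, 0, -30), c(0, 0, 1), cell)
  expect_identical(nrow(miss), 0L)
  tang <- ray_trace(c(5, 0, -30), c(0, 0, 1), cell)
  expect_identical(unique(tang$region), "cytoplasm")
})

test_that("ray tracing matches per-sphere analytic chords for random rays", {
  cell <- cell_model()
  radii <- c(1.5, 1.5 + (1:10) * 0.01, 5, 12.5)
  set.seed(31)
  for (i in 1:50) {
    b <- runif(1, 0, 13)                       # impact parameter
    tr <- ray_trace(c(b, 0, -30), c(0, 0, 1), cell)
    chord <- function(R) if (b < R) 2 * sqrt(R^2 - b^2) else 0
    expect_equal(sum(tr$length_um), chord(12.5), tolerance = 1e-9)
    if (nrow(tr)) {
      agg <- tapply(tr$length_um, tr$region, sum)
      expect_equal(unname(agg[["cytoplasm"]]), chord(12.5) - chord(5),
                   tolerance = 1e-9)
    }
  }
  # locate/ray_trace agreement on oblique rays
  set.seed(32)
  for (i in 1:25) {
    o <- c(runif(2, -4, 4), -30)
    d <- c(runif(2, -0.1, 0.1), 1)
    d <- d / sqrt(sum(d^2))
    tr <- ray_trace(o, d, cell)
    if (!nrow(tr)) next
    # reconstruct segment midpoints by walking the entry parameter
    ts <- sqrt(sum(o^2))  # not used directly; verify via cumulative lengths
    # entry point: advance to first boundary
    b2 <- sum(o * d)
    disc <- b2^2 - (sum(o^2) - 12.5^2)
    t_entry <- -b2 - sqrt(disc)
    bounds <- t_entry + cumsum(c(0, tr$length_um))
    mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
    for (j in seq_len(nrow(tr))) {
      expect_identical(locate(o + mids[j] * d, cell), tr$region[j])
    }
  }
})

test_that("ray trace rejects bad directions", {
  cell <- cell_model()
  expect_error(ray_trace(c(0, 0, -20), c(0, 0, 0), cell), "non-zero")
  expect_error(ray_trace(c(0, 0, -20), c(0, 0, 1.1), cell), "unit norm")
})

test_that("degrader tuning reaches the resonance energy by bisection", {
  st <- tune_degrader(2.0, 675)
  expect_s3_class(st, "degrader_stack")
  m <- attr(st, "mean_MeV") * 1e3
  expect_gte(m, 665)
  expect_lte(m, 685)
  expect_gt(attr(st, "sigma_MeV"), 0)   # straggling accumulates in the stack
  # bisection result agrees with a local brute-force scan of the air path
  air <- st$thickness_um[st$materials == "air"]
  scan <- seq(air - 2000, air + 2000, by = 200)
  e_scan <- vapply(scan, function(a)
    degrade_beam(2.0, degrader_stack(c("mylar", "mylar", "air"), c(6, 6, a)))$mean_MeV,
    numeric(1))
  best <- scan[which.min(abs(e_scan - 0.675))]
  expect_lt(abs(best - air), 500)   # within the scan resolution of the bisection
})

test_that("degrader tuning handles limiting and unreachable targets", {
  # nearly undegraded beam: tiny air path, no foils
  st <- tune_degrader(2.0, 1990, mylar_foils_um = numeric(0), tolerance_keV = 10)
  expect_lt(sum(st$thickness_um), 1e4)   # under 1 cm of air
  # fixed foils alone already overshoot the target
  expect_error(tune_degrader(2.0, 1990), "unreachable")
  expect_error(tune_degrader(2.0, 2100), "below the beam")
})

test_that("degraded beam energy decreases monotonically with air path", {
  es <- vapply(c(1, 10, 20, 40) * 1e3, function(a)
    degrade_beam(2.0, degrader_stack("air", a))$mean_MeV, numeric(1))
  expect_true(all(diff(es) < 0))
})
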