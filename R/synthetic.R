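# Synthetic-data generators: every input the analysis stages consume, with
# known ground truth attached, so the whole pipeline runs without external
# data. Noise families: lognormal for concentrations and fluorescence,
# Poisson for colony counts, Gaussian for pixel maps. Defaults follow the
# study's printed magnitudes (IC50s of 83.5 and 103 uM, 250/430 ug/g
# elemental-map levels, 7.5 mg B/kg injections).

# lognormal with mean exactly `mean` and coefficient of variation `cv`
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

.check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
}

#' Synthetic ICP-MS uptake records
#'
#' Boron amounts lognormal around the true content; iron tied to boron by
#' the compound's 18:1 B:Fe stoichiometry (mass ratio 3.484) with its own
#' independent lognormal noise; amounts split between nucleus and cytoplasm
#' by a fixed fraction.
#'
#' @param true_B_ng true boron content, ng per 1e6 cells.
#' @param compartment_split fraction of the content in the nucleus, in [0,1].
#' @param cv coefficient of variation of the lognormal noise (>= 0).
#' @param n replicates.
#' @param seed mandatory integer seed.
#' @return data.frame of `UptakeRecord`s (`element`, `compartment`,
#'   `amount`, `group`, `replicate`) with the truth in `attr(, "truth")`.
#' @export
gen_icpms_uptake <- function(true_B_ng = 150, compartment_split = 0.4,
                             cv = 0.1, n = 6, seed) {
  .check_seed(seed)
  if (cv < 0) stop("cv must be non-negative")
  if (compartment_split < 0 || compartment_split > 1)
    stop("compartment split must lie in [0, 1]")
  ratio <- b_fe_stoichiometry()[["mass"]]
  split <- c(nucleus = compartment_split, cytoplasm = 1 - compartment_split)
  rows <- lapply(names(split), function(cc) {
    b <- .rlnorm_mean_cv(n, true_B_ng * split[[cc]], cv)
    fe <- .rlnorm_mean_cv(n, true_B_ng * split[[cc]] / ratio, cv)
    data.frame(element = rep(c("B", "Fe"), each = n),
               compartment = cc, amount = c(b, fe), group = "treated",
               replicate = rep(seq_len(n), 2))
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(true_B_ng = true_B_ng, b_fe_mass_ratio = ratio,
                             compartment_split = compartment_split, cv = cv)
  out
}

#' Synthetic 2-D elemental map
#'
#' Disk-in-disk image: a nucleus disk at the configured level inside a
#' cytoplasm disk at its level, plus Gaussian pixel noise; compartment masks
#' are returned for ground-truth summaries.
#'
#' @param cell_radius_px,nucleus_radius_px disk radii in pixels
#'   (nucleus < cell).
#' @param cyto_level,nucleus_level mean concentrations, ug/g dry weight.
#' @param noise_sd Gaussian pixel noise SD.
#' @param seed mandatory integer seed.
#' @return list with `map` (matrix), `nucleus_mask`, `cytoplasm_mask`
#'   (logical matrices) and `truth`.
#' @export
gen_elemental_map <- function(cell_radius_px = 40, nucleus_radius_px = 16,
                              cyto_level = 250, nucleus_level = 430,
                              noise_sd = 10, seed) {
  .check_seed(seed)
  if (nucleus_radius_px >= cell_radius_px) stop("nucleus must fit inside cell")
  if (cyto_level <= 0 || nucleus_level <= 0) stop("levels must be positive")
  n <- 2 * cell_radius_px + 1
  ax <- seq_len(n) - (cell_radius_px + 1)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  nuc <- r <= nucleus_radius_px
  cyto <- r <= cell_radius_px & !nuc
  map <- matrix(0, n, n)
  map[nuc] <- nucleus_level
  map[cyto] <- cyto_level
  if (noise_sd > 0) map[nuc | cyto] <- map[nuc | cyto] +
      stats::rnorm(sum(nuc | cyto), 0, noise_sd)
  list(map = map, nucleus_mask = nuc, cytoplasm_mask = cyto,
       truth = list(cyto_level = cyto_level, nucleus_level = nucleus_level,
                    noise_sd = noise_sd))
}

#' Synthetic dose-response plate table
#'
#' Four-parameter-logistic mean response with multiplicative lognormal
#' noise.
#'
#' @param ic50 true IC50, uM.
#' @param hill Hill slope (> 0, viability decreasing).
#' @param top,bottom asymptotes (viability fractions).
#' @param cv lognormal noise CV.
#' @param concentrations tested concentrations, uM (should span the IC50).
#' @param n replicate wells per concentration.
#' @param seed mandatory integer seed.
#' @return data.frame (`concentration`, `viability`, `replicate`) with the
#'   truth attached.
#' @export
gen_dose_response <- function(ic50 = 83.5, hill = 1.5, top = 1, bottom = 0.05,
                              cv = 0.08,
                              concentrations = 10^seq(0.5, 3, by = 0.25),
                              n = 4, seed) {
  .check_seed(seed)
  if (cv < 0) stop("cv must be non-negative")
  if (min(concentrations) > ic50 || max(concentrations) < ic50)
    stop("concentrations must span the IC50")
  mu <- bottom + (top - bottom) / (1 + (concentrations / ic50)^hill)
  out <- do.call(rbind, lapply(seq_along(concentrations), function(i)
    data.frame(concentration = concentrations[i],
               viability = .rlnorm_mean_cv(n, mu[i], cv),
               replicate = seq_len(n))))
  attr(out, "truth") <- list(ic50 = ic50, hill = hill, top = top,
                             bottom = bottom, cv = cv)
  out
}

#' Synthetic clonogenic colony counts
#'
#' Poisson counts with mean `seeded * plating efficiency * survival`.
#'
#' @param sf_true true survival fraction.
#' @param seeded cells seeded per well.
#' @param pe_control control plating efficiency.
#' @param wells number of wells.
#' @param seed mandatory integer seed.
#' @return integer vector of counts with the truth attached.
#' @export
gen_colony_counts <- function(sf_true, seeded = 100, pe_control = 0.6,
                              wells = 3, seed) {
  .check_seed(seed)
  counts <- stats::rpois(wells, seeded * pe_control * sf_true)
  attr(counts, "truth") <- list(sf_true = sf_true, seeded = seeded,
                                pe_control = pe_control)
  counts
}

#' Synthetic biodistribution (%ID/g) table
#'
#' Mono-exponential organ kinetics `%ID/g = A exp(-lambda t)` with lognormal
#' inter-animal noise; the tumour clears more slowly than liver and lung by
#' default, emulating selective tumour retention.
#'
#' @param dose_mgB_per_kg injected dose (metadata only).
#' @param organ_params data.frame with `organ`, `A` (%ID/g at t = 0) and
#'   `lambda` (1/h).
#' @param times_h sampling times, h.
#' @param n_mice animals per time point.
#' @param cv lognormal inter-animal CV.
#' @param seed mandatory integer seed.
#' @return data.frame (`organ`, `time_h`, `mouse`, `pid_g`) with the truth
#'   attached.
#' @export
gen_biodistribution <- function(dose_mgB_per_kg = 7.5,
                                organ_params = data.frame(
                                  organ = c("tumor", "liver", "lung", "kidney",
                                            "spleen", "blood", "muscle"),
                                  A = c(8, 14, 9, 10, 7, 12, 3),
                                  lambda = c(0.05, 0.35, 0.40, 0.25, 0.20,
                                             0.30, 0.15)),
                                times_h = c(1, 4), n_mice = 4, cv = 0.15, seed) {
  .check_seed(seed)
  if (any(times_h <= 0)) stop("times must be positive")
  if (any(organ_params$lambda < 0)) stop("clearance rates must be non-negative")
  out <- do.call(rbind, lapply(seq_len(nrow(organ_params)), function(i) {
    do.call(rbind, lapply(times_h, function(t) {
      mu <- organ_params$A[i] * exp(-organ_params$lambda[i] * t)
      data.frame(organ = organ_params$organ[i], time_h = t,
                 mouse = seq_len(n_mice),
                 pid_g = .rlnorm_mean_cv(n_mice, mu, cv))
    }))
  }))
  attr(out, "truth") <- list(dose_mgB_per_kg = dose_mgB_per_kg,
                             organ_params = organ_params, cv = cv)
  out
}

#' Synthetic ROS fluorescence kinetics
#'
#' Linear fluorescence growth `baseline * (1 + slope_per_hour * t)` with
#' multiplicative lognormal noise, sampled on a regular grid up to the
#' horizon.
#'
#' @param baseline fluorescence at t = 0 (arbitrary units).
#' @param slope_per_hour fractional growth per hour (0 for a flat control).
#' @param horizon_h last time point, h.
#' @param by_h grid spacing, h.
#' @param cv lognormal noise CV.
#' @param n replicate wells.
#' @param seed mandatory integer seed.
#' @return data.frame (`time`, `value`, `replicate`) with the truth attached.
#' @export
gen_ros_kinetics <- function(baseline = 1000, slope_per_hour = 0.02,
                             horizon_h = 48, by_h = 4, cv = 0.05, n = 4, seed) {
  .check_seed(seed)
  times <- seq(0, horizon_h, by = by_h)
  out <- do.call(rbind, lapply(times, function(t) {
    mu <- baseline * (1 + slope_per_hour * t)
    data.frame(time = t, value = .rlnorm_mean_cv(n, mu, cv),
               replicate = seq_len(n))
  }))
  attr(out, "truth") <- list(baseline = baseline,
                             slope_per_hour = slope_per_hour, cv = cv)
  out
}
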