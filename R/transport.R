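# Condensed-history Monte Carlo transport: beam definition, single-step
# semantics, batched runs with per-region tallies and dose conversion.
#
# Straight-line CSDA tracks (no multiple scattering, no nuclear elastics):
# adequate over the sub-30 um paths of a single cell. Step length is capped
# at a 1% fractional energy loss or the next sphere boundary, whichever is
# shorter; particles are killed below 1 keV with local deposition.

.MEV_TO_J <- 1.602176634e-13

#' Beam specification
#'
#' @param energy_MeV mean kinetic energy at the cell entrance, MeV.
#' @param field `"broad"` (uniform disk covering the cell), `"square"`
#'   (uniform square spot of side `side_um`, sampled by importance over the
#'   cell disk) or `"point"` (axial pencil).
#' @param side_um square field side, um (default the 70 um raster spot).
#' @param flux_per_s protons per second.
#' @param duration_s irradiation time, s.
#' @param energy_spread_keV Gaussian sigma of the entrance energy, keV.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(energy_MeV = 2.0, field = c("broad", "square", "point"),
                      side_um = 70, flux_per_s = 2e7, duration_s = 10,
                      energy_spread_keV = 0) {
  field <- match.arg(field)
  if (energy_MeV <= 0) stop("energy must be positive")
  n_phys <- flux_per_s * duration_s
  if (n_phys <= 0) stop("total fluence must be positive")
  structure(list(energy_MeV = energy_MeV, field = field, side_um = side_um,
                 flux_per_s = flux_per_s, duration_s = duration_s,
                 energy_spread_keV = energy_spread_keV,
                 n_physical = n_phys),
            class = "beam_spec")
}

#' Particle state
#'
#' One Monte Carlo history's state.
#'
#' @param species `"proton"` or `"alpha"`.
#' @param position length-3 position, um.
#' @param direction length-3 unit direction.
#' @param energy_MeV kinetic energy, MeV.
#' @param weight statistical weight (>= 0).
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(species, position, direction, energy_MeV, weight = 1) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-12) stop("direction must be unit norm within 1e-12")
  if (energy_MeV < 0) stop("kinetic energy must be non-negative")
  if (weight < 0) stop("weight must be non-negative")
  structure(list(species = species, position = as.numeric(position),
                 direction = as.numeric(direction), energy_MeV = energy_MeV,
                 weight = weight, alive = energy_MeV > 0),
            class = "particle_state")
}

#' Generic nested-sphere geometry
#'
#' A transport geometry that is just a stack of concentric spheres with a
#' material per region — the cell model reduces to this, and degenerate
#' stacks (a single water sphere) serve as analytic benchmarks.
#'
#' @param radii_um increasing outer radii, um.
#' @param materials material name per region (see [material()]).
#' @param labels region labels (defaults to `region_1..n`).
#' @return An object of class `sphere_stack`.
#' @export
sphere_stack <- function(radii_um, materials,
                         labels = paste0("region_", seq_along(radii_um))) {
  if (is.unsorted(radii_um, strictly = TRUE)) stop("radii must be strictly increasing")
  if (length(materials) != length(radii_um) || length(labels) != length(radii_um))
    stop("radii, materials and labels must align")
  structure(list(radii_um = radii_um, materials = materials, labels = labels),
            class = "sphere_stack")
}

# normalize cell_model / sphere_stack into kernel arrays
.transport_geometry <- function(geometry) {
  if (inherits(geometry, "cell_model")) {
    radii <- .cell_radii(geometry)
    labels <- .cell_labels(geometry)
    materials <- rep("water", length(radii))
    if (geometry$boron_material == "boron") materials[1] <- "boron"
  } else if (inherits(geometry, "sphere_stack")) {
    radii <- geometry$radii_um
    labels <- geometry$labels
    materials <- geometry$materials
  } else stop("geometry must be a cell_model or sphere_stack")
  uniq <- unique(materials)
  mats <- t(vapply(uniq, function(m) {
    mo <- material(m)
    c(mo$density, mo$za_eff, mo$mean_excitation_eV * 1e-6)
  }, numeric(3)))
  list(radii = radii, labels = labels,
       mat_id = match(materials, uniq) - 1L, mats = mats,
       densities = vapply(materials, function(m) material(m)$density, numeric(1)))
}

# masses (g) of the nested regions
.region_masses <- function(geo) {
  r_in <- c(0, geo$radii[-length(geo$radii)])
  vol <- 4 / 3 * pi * (geo$radii^3 - r_in^3)
  vol * 1e-12 * geo$densities
}

#' Single condensed-history step
#'
#' Advances one particle by the shorter of the distance to the next sphere
#' boundary and the distance giving `max_fractional_loss` of its energy by
#' CSDA; deposits the (midpoint-corrected) mean loss in the region the
#' segment lies in, and kills the particle below the 1 keV cutoff with local
#' deposition. Reference semantics for the compiled kernel.
#'
#' @param state a [particle_state()] (must be alive).
#' @param geometry a [cell_model()] or [sphere_stack()].
#' @param max_fractional_loss per-step energy-loss cap, in (0, 0.05].
#' @return list with `state` (advanced), `region` and `deposit_MeV`.
#' @export
transport_step <- function(state, geometry, max_fractional_loss = 0.01) {
  if (!state$alive) stop("state must be alive")
  if (max_fractional_loss <= 0 || max_fractional_loss > 0.05)
    stop("max_fractional_loss must be in (0, 0.05]")
  geo <- .transport_geometry(geometry)
  p <- state$position
  d <- state$direction
  E <- state$energy_MeV
  r2 <- sum(p^2)
  b <- sum(p * d)
  reg <- which(r2 <= geo$radii^2 + 1e-12)[1]
  eps <- 1e-7
  if (is.na(reg)) {   # exterior: vacuum flight to the stack, or escape
    Rmax <- geo$radii[length(geo$radii)]
    disc <- b^2 - (r2 - Rmax^2)
    t <- if (disc > 0) -b - sqrt(disc) else -1
    if (t <= 0) {
      state$alive <- FALSE
      return(list(state = state, region = "exterior", deposit_MeV = 0))
    }
    state$position <- p + d * (t + eps)
    return(list(state = state, region = "exterior", deposit_MeV = 0))
  }
  mat <- material(rownames(geo$mats)[geo$mat_id[reg] + 1L])
  t_out <- Inf
  disc <- b^2 - (r2 - geo$radii[reg]^2)
  if (disc > 0 && (-b + sqrt(disc)) > 0) t_out <- -b + sqrt(disc)
  if (reg > 1) {
    disc <- b^2 - (r2 - geo$radii[reg - 1]^2)
    if (disc > 0) {
      t_in <- -b - sqrt(disc)
      if (t_in > 1e-12 && t_in < t_out) t_out <- t_in
    }
  }
  S <- stopping_power(E, state$species, mat) * mat$density * 1e-4  # MeV/um
  ds_energy <- max_fractional_loss * E / S
  ds <- min(ds_energy, t_out)
  hit <- t_out <= ds_energy
  e_mid <- max(E - 0.5 * S * ds, .E_MIN / 2)
  dE <- stopping_power(max(e_mid, .E_MIN), state$species, mat) * mat$density * 1e-4 * ds
  dE <- min(dE, E)
  state$position <- p + d * (ds + if (hit) eps else 0)
  state$energy_MeV <- E - dE
  if (state$energy_MeV < .E_MIN) {
    dE <- dE + state$energy_MeV
    state$energy_MeV <- 0
    state$alive <- FALSE
  }
  list(state = state, region = geo$labels[reg], deposit_MeV = dE * state$weight)
}

#' Isotropic unit directions
#'
#' Uniform directions on the unit sphere (uniform cos-polar, uniform
#' azimuth).
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
sample_isotropic <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Energy-to-dose conversion
#'
#' @param energy_MeV deposited energy, MeV.
#' @param mass_g absorbing mass, g (> 0).
#' @return absorbed dose in Gy.
#' @export
dose_from_energy <- function(energy_MeV, mass_g) {
  if (any(mass_g <= 0)) stop("mass must be positive")
  energy_MeV * .MEV_TO_J / (mass_g * 1e-3)
}

# sample beam start positions/energies; returns pos, dir, energy, weight-per-history
.sample_beam <- function(beam, Rmax, n) {
  if (beam$field == "point") {
    xy <- matrix(0, n, 2)
    w <- beam$n_physical / n
  } else if (beam$field == "broad") {
    r <- Rmax * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    xy <- cbind(r * cos(a), r * sin(a))
    w <- beam$n_physical / n
  } else {  # square spot, importance-sampled over the cell disk
    if (beam$side_um < 2 * Rmax)
      stop("square field side must cover the cell (side >= 2 * cell radius)")
    r <- Rmax * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    xy <- cbind(r * cos(a), r * sin(a))
    w <- beam$n_physical * (pi * Rmax^2 / beam$side_um^2) / n
  }
  e <- rep(beam$energy_MeV, n)
  if (beam$energy_spread_keV > 0) {
    e <- stats::rnorm(n, beam$energy_MeV, beam$energy_spread_keV * 1e-3)
    e <- pmax(e, 2 * .E_MIN)
  }
  list(pos = cbind(xy, -Rmax - 1), dir = cbind(0, 0, rep(1, n)),
       energy = e, weight = rep(w, n))
}

# fluence (cm^-2) implied by the beam over its field
.beam_fluence <- function(beam, Rmax) {
  area_cm2 <- switch(beam$field,
    broad = pi * (Rmax * 1e-4)^2,
    square = (beam$side_um * 1e-4)^2,
    point = NA_real_)
  beam$n_physical / area_cm2
}

#' Run a batched Monte Carlo transport simulation
#'
#' Transports `n_histories` histories (split into `batches` independent
#' batches, batch `b` seeded with `seed + b`) through the geometry and
#' converts per-region energy deposits to absorbed dose at the physical
#' fluence implied by the beam. Each batch is a full-fluence estimate, so
#' the batch spread gives the relative standard error of each region dose.
#'
#' @param beam a [beam_spec()]; its energy is taken at the geometry entrance
#'   (apply [degrade_beam()]/[tune_degrader()] upstream for a degraded beam).
#' @param geometry a [cell_model()] or [sphere_stack()].
#' @param n_histories total histories (>= batches).
#' @param batches number of statistical batches (>= 2).
#' @param seed integer seed; runs are bit-reproducible for a fixed seed.
#' @param straggle sample Bohr energy straggling per step (default off
#'   inside the cell; the degrader applies its own straggling upstream).
#' @param species transported species.
#' @param source optional list overriding the beam's spatial sampling:
#'   function(n) returning list(pos, dir, energy, weight) — used by the
#'   two-step alpha stage.
#' @return A `tally_set`: data.frame with `region`, `mass_g`, `energy_MeV`,
#'   `dose_Gy`, `rel_err`, `dose_per_fluence_Gy_cm2`, with attributes
#'   `escaped_MeV`, `fluence_cm2`, `batches`, `n_histories`, `seed`,
#'   `batch_dose` (matrix).
#' @export
run_mc <- function(beam, geometry, n_histories = 1e4, batches = 10, seed = 1,
                   straggle = FALSE, species = "proton", source = NULL) {
  if (batches < 2 || n_histories < batches)
    stop("need n_histories >= batches >= 2")
  geo <- .transport_geometry(geometry)
  masses <- .region_masses(geo)
  Rmax <- geo$radii[length(geo$radii)]
  per_batch <- diff(floor(seq(0, n_histories, length.out = batches + 1)))
  nreg <- length(geo$radii)
  dep <- matrix(0, batches, nreg)
  escaped <- 0
  for (b in seq_len(batches)) {
    set.seed(as.integer(seed + b))
    nb <- per_batch[b]
    src <- if (is.null(source)) .sample_beam(beam, Rmax, nb) else source(nb)
    out <- .cd_transport(src$pos, src$dir, src$energy, src$weight, species,
                         geo$radii, geo$mat_id, geo$mats,
                         0.01, .E_MIN, straggle, FALSE)
    dep[b, ] <- out$deposit
    escaped <- escaped + out$escaped
  }
  mean_dep <- colMeans(dep)
  dose_b <- sweep(dep, 2, masses, function(e, m) dose_from_energy(e, m))
  dose <- colMeans(dose_b)
  se <- apply(dose_b, 2, stats::sd) / sqrt(batches)
  rel <- ifelse(dose > 0, se / dose, NA_real_)
  fl <- .beam_fluence(beam, Rmax)
  res <- data.frame(region = geo$labels, mass_g = masses,
                    energy_MeV = mean_dep, dose_Gy = dose, rel_err = rel,
                    dose_per_fluence_Gy_cm2 = dose / fl)
  class(res) <- c("tally_set", "data.frame")
  attr(res, "escaped_MeV") <- escaped / batches
  attr(res, "fluence_cm2") <- fl
  attr(res, "batches") <- batches
  attr(res, "n_histories") <- n_histories
  attr(res, "seed") <- seed
  attr(res, "batch_dose") <- dose_b
  res
}

#' @export
print.tally_set <- function(x, ...) {
  cat(sprintf("Monte Carlo tally: %d histories in %d batches (seed %s)\n",
              attr(x, "n_histories"), attr(x, "batches"),
              format(attr(x, "seed"))))
  print.data.frame(cbind(x[, c("region", "dose_Gy", "rel_err")]),
                   digits = 4, row.names = FALSE)
  invisible(x)
}
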