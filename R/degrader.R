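# Upstream degrader stack: air path plus Mylar foils used to slow the 2 MeV
# accelerator beam to the p+11B resonance (~675 keV) at the cell layer.
#
# Slabs are traversed in beam order under the CSDA (range subtraction);
# Bohr straggling accumulates a Gaussian energy spread.

#' Degrader stack
#'
#' @param materials character vector of slab materials (`"air"` or `"mylar"`).
#' @param thickness_um slab thicknesses in um (> 0), beam order.
#' @return An object of class `degrader_stack`.
#' @export
degrader_stack <- function(materials, thickness_um) {
  if (length(materials) != length(thickness_um))
    stop("materials and thicknesses must align")
  if (!all(materials %in% c("air", "mylar"))) stop("slabs must be air or mylar")
  if (any(thickness_um <= 0)) stop("thicknesses must be positive")
  structure(list(materials = materials, thickness_um = thickness_um),
            class = "degrader_stack")
}

#' Transport a proton beam through a degrader stack
#'
#' CSDA range-subtraction through each slab, with Bohr straggling variance
#' accumulated across the stack. Deterministic: returns the mean exit energy
#' and the Gaussian energy spread, not samples.
#'
#' @param energy_MeV entrance kinetic energy, MeV.
#' @param stack a [degrader_stack()].
#' @param species transported species (proton).
#' @return list with `mean_MeV` (0 if the beam ranges out) and `sigma_MeV`.
#' @export
degrade_beam <- function(energy_MeV, stack, species = "proton") {
  e <- energy_MeV
  var <- 0
  for (i in seq_along(stack$materials)) {
    if (e <= .E_MIN) return(list(mean_MeV = 0, sigma_MeV = sqrt(var)))
    m <- material(stack$materials[i])
    dx <- stack$thickness_um[i] * 1e-4 * m$density   # g/cm^2
    r0 <- csda_range(e, species, m)$range_g_cm2
    var <- var + .bohr_variance(e, species, m, min(dx, r0))
    e <- .energy_at_range(r0 - dx, species, m)
  }
  list(mean_MeV = if (e <= .E_MIN) 0 else e, sigma_MeV = sqrt(var))
}

#' Tune a degrader stack to a target mean energy
#'
#' Solves for the free air-path length (appended after any fixed Mylar
#' foils) that degrades the beam to the target mean energy at the cell
#' entrance, by bisection on the thickness (at most 60 iterations).
#'
#' @param beam_energy_MeV accelerator energy, MeV.
#' @param target_keV target mean entrance energy, keV.
#' @param mylar_foils_um thicknesses of fixed Mylar foils, um (may be empty).
#' @param tolerance_keV acceptance half-width on the mean energy (default 10).
#' @param max_air_cm bracketing upper limit for the air path, cm.
#' @return A [degrader_stack()] whose transported mean energy is within
#'   `tolerance_keV` of the target; the achieved mean and spread are attached
#'   as attributes `mean_MeV` and `sigma_MeV`.
#' @export
tune_degrader <- function(beam_energy_MeV, target_keV, mylar_foils_um = c(6, 6),
                          tolerance_keV = 10, max_air_cm = 400) {
  target <- target_keV * 1e-3
  if (target >= beam_energy_MeV) stop("target must be below the beam energy")
  make <- function(air_um) {
    if (length(mylar_foils_um))
      degrader_stack(c(rep("mylar", length(mylar_foils_um)), "air"),
                     c(mylar_foils_um, air_um))
    else degrader_stack("air", air_um)
  }
  e_at <- function(air_um) degrade_beam(beam_energy_MeV, make(air_um))$mean_MeV
  lo <- 1e-3
  hi <- max_air_cm * 1e4
  e_lo <- e_at(lo)
  e_hi <- e_at(hi)
  if (e_lo < target)
    stop(sprintf("target unreachable: fixed foils alone give %.0f keV < %.0f keV",
                 e_lo * 1e3, target * 1e3))
  if (e_hi > target)
    stop(sprintf("target unreachable: max air path still leaves %.0f keV > %.0f keV",
                 e_hi * 1e3, target * 1e3))
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    e_mid <- e_at(mid)
    if (abs(e_mid - target) <= tolerance_keV * 1e-3 / 2) break
    if (e_mid > target) lo <- mid else hi <- mid
  }
  stack <- make(mid)
  res <- degrade_beam(beam_energy_MeV, stack)
  if (abs(res$mean_MeV - target) > tolerance_keV * 1e-3)
    stop("bisection failed to reach the target mean energy")
  attr(stack, "mean_MeV") <- res$mean_MeV
  attr(stack, "sigma_MeV") <- res$sigma_MeV
  stack
}
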