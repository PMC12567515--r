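# Charged-particle stopping power and CSDA ranges.
#
# Model: first-order Bethe mass stopping power with a material-level mean
# excitation energy, Barkas effective charge for helium ions, and a power-law
# low-energy continuation matched in value and log-slope at the junction
# energy (0.5 MeV for protons; the velocity-equivalent energy for alphas).
# Units: energies MeV, mass stopping power MeV cm^2/g, densities g/cm^3.

# physical constants (MeV unless noted)
.ME_C2 <- 0.51099895
.K_BETHE <- 0.307075            # 4 pi N_A r_e^2 m_e c^2, MeV mol^-1 cm^2
.MP_C2 <- 938.27208816
.MALPHA_C2 <- 3727.3794066
.BOHR_COEF <- 0.1569            # Bohr straggling, MeV^2 cm^2/g per unit z^2 (Z/A)
.E_MIN <- 1e-3                  # 1 keV transport cutoff
.E_MAX <- 20

.species_params <- function(species) {
  switch(species,
    proton = list(mass = .MP_C2, z = 1, junction = 0.5),
    alpha  = list(mass = .MALPHA_C2, z = 2,
                  junction = 0.5 * .MALPHA_C2 / .MP_C2),
    stop("unknown species: ", species)
  )
}

#' Stopping-model material definition
#'
#' Builds the material description used by [stopping_power()], [csda_range()]
#' and the Monte Carlo transport kernel: elemental composition by mass
#' fraction, bulk density and a single mean excitation energy.
#'
#' @param name material label.
#' @param composition named numeric vector of element mass fractions
#'   (names are element symbols known to the internal table: H, C, N, O, Ar, B).
#' @param density bulk density in g/cm^3.
#' @param mean_excitation_eV mean excitation energy I in eV.
#' @return An object of class `stopping_model` with the effective Z/A.
#' @examples
#' water <- stopping_model("water", c(H = 0.1119, O = 0.8881), 1.0, 75)
#' @export
stopping_model <- function(name, composition, density, mean_excitation_eV) {
  elements <- data.frame(
    symbol = c("H", "C", "N", "O", "Ar", "B"),
    Z = c(1, 6, 7, 8, 18, 5),
    A = c(1.008, 12.011, 14.007, 15.999, 39.948, 10.811)
  )
  if (is.null(names(composition)) || !all(names(composition) %in% elements$symbol))
    stop("composition must be named with known element symbols")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("mass fractions must sum to 1 within 1e-9")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (mean_excitation_eV <= 0) stop("mean excitation energy must be positive")
  idx <- match(names(composition), elements$symbol)
  za_eff <- sum(composition * elements$Z[idx] / elements$A[idx])
  structure(
    list(name = name, composition = composition, density = density,
         mean_excitation_eV = mean_excitation_eV, za_eff = za_eff),
    class = "stopping_model"
  )
}

#' Built-in materials
#'
#' Water (I = 75 eV), Mylar (C10H8O4, 1.40 g/cm^3), dry sea-level air and
#' elemental boron (2.37 g/cm^3), the four media the cell and degrader
#' geometries use.
#'
#' @param name one of `"water"`, `"mylar"`, `"air"`, `"boron"`.
#' @return A `stopping_model`.
#' @export
material <- function(name = c("water", "mylar", "air", "boron")) {
  name <- match.arg(name)
  switch(name,
    water = stopping_model("water", c(H = 0.111894, O = 0.888106), 1.0, 75),
    mylar = stopping_model("mylar",
      c(H = 0.041959, C = 0.625016, O = 0.333025), 1.40, 78.7),
    air = stopping_model("air",
      c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012828),
      1.20479e-3, 85.7),
    boron = stopping_model("boron", c(B = 1), 2.37, 76)
  )
}

# squared velocity terms for kinetic energy E and rest mass m (exact relativistic)
.beta_gamma <- function(E, mass) {
  gamma <- 1 + E / mass
  b2g2 <- gamma^2 - 1
  list(beta2 = b2g2 / gamma^2, b2g2 = b2g2)
}

# Barkas effective charge (squared); ~z^2 above a few hundred keV/u
.zeff2 <- function(beta, z) {
  (z * (1 - exp(-125 * beta / z^(2 / 3))))^2
}

# Bethe evaluation without the low-energy continuation; vectorized in E
.bethe <- function(E, sp, model) {
  kin <- .beta_gamma(E, sp$mass)
  I_MeV <- model$mean_excitation_eV * 1e-6
  L <- log(2 * .ME_C2 * kin$b2g2 / I_MeV) - kin$beta2
  z2 <- .zeff2(sqrt(kin$beta2), sp$z)
  .K_BETHE * z2 / kin$beta2 * model$za_eff * L
}

# continuation exponent d log S / d log E at the junction (numeric, cached per call)
.junction_exponent <- function(sp, model) {
  h <- 1e-4 * sp$junction
  (log(.bethe(sp$junction + h, sp, model)) -
     log(.bethe(sp$junction - h, sp, model))) / (log(sp$junction + h) - log(sp$junction - h))
}

#' Mass stopping power
#'
#' Electronic mass stopping power for protons or alpha particles, in
#' MeV cm^2/g. Above the species' junction energy this is the Bethe formula
#' with Barkas effective charge; below it a power law matched in value and
#' log-slope at the junction, so the function is positive and continuous over
#' the whole supported range (1 keV to 20 MeV).
#'
#' @param E kinetic energy in MeV (vectorized).
#' @param species `"proton"` or `"alpha"`.
#' @param model a `stopping_model` (default water).
#' @return mass stopping power, MeV cm^2/g.
#' @seealso [let_keV_um()] for the linear energy transfer, [csda_range()].
#' @export
stopping_power <- function(E, species = c("proton", "alpha"), model = material("water")) {
  species <- match.arg(species)
  sp <- .species_params(species)
  if (any(!is.finite(E)) || any(E < .E_MIN) || any(E > .E_MAX))
    stop("energy out of supported range [1 keV, 20 MeV]")
  .mass_stopping(E, sp, model)
}

# unchecked evaluation (any E > 0), shared by stopping_power and quadrature
.mass_stopping <- function(E, sp, model) {
  out <- numeric(length(E))
  hi <- E >= sp$junction
  if (any(hi)) out[hi] <- .bethe(E[hi], sp, model)
  if (any(!hi)) {
    p <- .junction_exponent(sp, model)
    s0 <- .bethe(sp$junction, sp, model)
    out[!hi] <- s0 * (E[!hi] / sp$junction)^p
  }
  out
}

#' Linear energy transfer in keV/um
#'
#' `S(E) * density`, converted from MeV/cm to keV/um; the unrestricted LET
#' used throughout the cellular dosimetry.
#'
#' @inheritParams stopping_power
#' @return LET in keV/um.
#' @export
let_keV_um <- function(E, species = c("proton", "alpha"), model = material("water")) {
  stopping_power(E, species, model) * model$density * 0.1
}

#' CSDA range
#'
#' Continuous-slowing-down range `integral_0^E dE'/S(E')` by adaptive
#' quadrature (relative tolerance 1e-8). The integrand vanishes at zero
#' energy under the power-law continuation, so the integral is proper.
#'
#' @inheritParams stopping_power
#' @param E kinetic energy in MeV (vectorized).
#' @return A data.frame with columns `energy_MeV`, `range_g_cm2` and
#'   `range_um` (the latter using the model's density).
#' @export
csda_range <- function(E, species = c("proton", "alpha"), model = material("water")) {
  species <- match.arg(species)
  if (any(!is.finite(E)) || any(E < .E_MIN) || any(E > .E_MAX))
    stop("energy out of supported range [1 keV, 20 MeV]")
  sp <- .species_params(species)
  r <- vapply(E, function(e) {
    stats::integrate(function(x) 1 / .mass_stopping(x, sp, model),
                     lower = 0, upper = e,
                     rel.tol = 1e-8, subdivisions = 400L)$value
  }, numeric(1))
  data.frame(energy_MeV = E, range_g_cm2 = r,
             range_um = r / model$density * 1e4)
}

# inverse of csda_range in g/cm^2; returns 0 if the particle ranges out
.energy_at_range <- function(r_gcm2, species, model) {
  if (r_gcm2 <= 0) return(0)
  r_min <- csda_range(.E_MIN, species, model)$range_g_cm2
  if (r_gcm2 <= r_min) return(.E_MIN)
  f <- function(e) csda_range(e, species, model)$range_g_cm2 - r_gcm2
  if (f(.E_MAX) < 0) stop("range exceeds supported energy window")
  stats::uniroot(f, c(.E_MIN, .E_MAX), tol = 1e-9)$root
}

# Bohr energy-loss straggling variance (MeV^2) across thickness dx_gcm2
.bohr_variance <- function(E, species, model, dx_gcm2) {
  sp <- .species_params(species)
  kin <- .beta_gamma(E, sp$mass)
  .BOHR_COEF * .zeff2(sqrt(kin$beta2), sp$z) * model$za_eff * dx_gcm2
}
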