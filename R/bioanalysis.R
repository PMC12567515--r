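# Assay analysis: uptake ratios and fold changes, B:Fe stoichiometry,
# growth rate, clonogenic survival, ROS kinetics and IC50 estimation.

.ATOMIC_MASS_B <- 10.811
.ATOMIC_MASS_FE <- 55.845
.BORON_PER_ANION <- 18   # [3,3'-Fe(1,2-C2B9H11)2]-: 18 B, 1 Fe

# round to k significant figures, half away from zero (matches how fold
# changes are conventionally reported; signif() rounds half to even)
.signif_half_away <- function(x, k = 2) {
  if (x == 0) return(0)
  m <- floor(log10(abs(x)))
  scale <- 10^(k - 1 - m)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Fold change between treated and control means
#'
#' @param treated_mean,control_mean compartment means (same units;
#'   control > 0).
#' @return list with `raw` (the exact ratio) and `reported` (rounded
#'   half-away-from-zero to 2 significant figures).
#' @examples
#' fold_change(250, 150)$reported  # 1.7
#' fold_change(430, 200)$reported  # 2.2
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("control mean must be positive")
  r <- treated_mean / control_mean
  list(raw = r, reported = .signif_half_away(r, 2))
}

#' Stoichiometric B:Fe mass ratio of the ferrabis(dicarbollide) anion
#'
#' 18 boron atoms per iron atom: `18 * A(B) / A(Fe)` = 3.484 by mass.
#'
#' @return named vector with `mass` and `molar` theoretical ratios.
#' @export
b_fe_stoichiometry <- function() {
  c(mass = .BORON_PER_ANION * .ATOMIC_MASS_B / .ATOMIC_MASS_FE,
    molar = .BORON_PER_ANION)
}

#' Measured B-to-Fe ratio per cellular compartment
#'
#' @param records data.frame with columns `element` (`"B"`/`"Fe"`),
#'   `compartment`, `amount` (ng per 1e6 cells); replicates as extra rows.
#' @return data.frame with per-compartment mean mass ratio, the implied
#'   molar ratio, and the theoretical stoichiometric values for comparison.
#' @export
b_fe_ratio <- function(records) {
  need <- c("element", "compartment", "amount")
  if (!all(need %in% names(records))) stop("records need element/compartment/amount")
  comps <- unique(records$compartment)
  theo <- b_fe_stoichiometry()
  out <- lapply(comps, function(cc) {
    sub <- records[records$compartment == cc, ]
    b <- sub$amount[sub$element == "B"]
    fe <- sub$amount[sub$element == "Fe"]
    if (!length(b) || !length(fe))
      stop("missing element records in compartment: ", cc)
    r <- mean(b) / mean(fe)
    data.frame(compartment = cc, ratio_mass = r,
               ratio_molar = r * .ATOMIC_MASS_FE / .ATOMIC_MASS_B,
               theoretical_mass = theo[["mass"]],
               theoretical_molar = theo[["molar"]])
  })
  do.call(rbind, out)
}

#' Cell growth rate relative to the assay start
#'
#' `(N(ti) - N(t0)) / N(t0) * 100`, with N any quantity proportional to cell
#' number (total protein works); negative values indicate inhibition.
#'
#' @param curve data.frame with strictly increasing `time` and positive-start
#'   `n` columns.
#' @param ti time point at which to evaluate (must be sampled).
#' @return growth rate in percent.
#' @export
growth_rate <- function(curve, ti) {
  if (!all(c("time", "n") %in% names(curve))) stop("curve needs time and n columns")
  if (is.unsorted(curve$time, strictly = TRUE)) stop("times must be strictly increasing")
  n0 <- curve$n[1]
  if (n0 <= 0) stop("N(t0) must be positive")
  i <- match(ti, curve$time)
  if (is.na(i)) stop("time point not sampled: ", ti)
  (curve$n[i] - n0) / n0 * 100
}

#' Clonogenic survival fraction
#'
#' `colonies / (seeded * plating efficiency of controls)`, the standard
#' clonogenic definition.
#'
#' @param colonies colony count (vectorized over wells).
#' @param seeded cells seeded per well (> 0).
#' @param plating_efficiency_control control plating efficiency in (0, 1].
#' @return survival fraction(s); values above 1 are returned as-is with a
#'   `clipped` attribute flagging them.
#' @export
survival_fraction <- function(colonies, seeded, plating_efficiency_control) {
  if (any(seeded <= 0)) stop("seeded must be positive")
  if (plating_efficiency_control <= 0 || plating_efficiency_control > 1)
    stop("plating efficiency must lie in (0, 1]")
  sf <- colonies / (seeded * plating_efficiency_control)
  attr(sf, "clipped") <- any(sf > 1)
  sf
}

#' ROS fold-change kinetics
#'
#' Pointwise ratio of mean fluorescence between a treated+irradiated series
#' and the reference series (non-irradiated treated cells), with the
#' delta-method standard deviation.
#'
#' @param treated,reference data.frames with `time` and `value` columns;
#'   replicates as repeated rows per time. Time grids must match.
#' @return data.frame with `time`, `fold`, `sd`.
#' @export
ros_fold <- function(treated, reference) {
  agg <- function(d) {
    s <- stats::aggregate(value ~ time, d, function(v)
      c(m = mean(v), se2 = stats::var(v) / length(v)))
    data.frame(time = s$time, m = s$value[, "m"], se2 = s$value[, "se2"])
  }
  a <- agg(treated)
  b <- agg(reference)
  if (!isTRUE(all.equal(a$time, b$time)))
    stop("time grids are not aligned")
  fold <- a$m / b$m
  sdv <- fold * sqrt(ifelse(a$m > 0, a$se2 / a$m^2, 0) +
                       ifelse(b$m > 0, b$se2 / b$m^2, 0))
  sdv[is.na(sdv)] <- 0
  data.frame(time = a$time, fold = fold, sd = sdv)
}

#' Fit a four-parameter logistic dose-response and estimate the IC50
#'
#' `v(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill)` fitted by
#' Levenberg-Marquardt (weighted) least squares with the IC50 on the log
#' scale; the top is left free rather than pinned at 100%. The 95% CI is
#' Wald on log(IC50).
#'
#' @param data data.frame with `concentration` (> 0) and `viability`
#'   columns (viability as a fraction; values slightly above 1 tolerated).
#' @param weights optional per-point weights for the least squares.
#' @return An object of class `dose_response_fit`: list with `ic50`,
#'   `ic50_ci` (length-2), `bottom`, `top`, `hill`, `converged`, `fit` (the
#'   underlying nls object). A negative fitted hill (viability increasing
#'   with dose) raises a warning and sets `inverted = TRUE`.
#' @export
fit_ic50 <- function(data, weights = NULL) {
  if (!all(c("concentration", "viability") %in% names(data)))
    stop("data needs concentration and viability columns")
  d <- data[data$concentration > 0, ]
  if (length(unique(d$concentration)) < 5)
    stop("need at least 5 distinct positive concentrations spanning the transition")
  v_lo <- min(d$viability)
  v_hi <- max(d$viability)
  mid <- (v_lo + v_hi) / 2
  # crude start: concentration whose mean response is closest to the midpoint
  m <- stats::aggregate(viability ~ concentration, d, mean)
  c50 <- m$concentration[which.min(abs(m$viability - mid))]
  st <- list(bottom = v_lo, top = v_hi, log_ic50 = log(c50), hill = 1.5)
  form <- viability ~ bottom + (top - bottom) /
    (1 + (concentration / exp(log_ic50))^hill)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch(
    if (is.null(weights))
      minpack.lm::nlsLM(form, data = d, start = st, control = ctrl)
    else
      minpack.lm::nlsLM(form, data = d, start = st, weights = weights,
                        control = ctrl),
    error = function(e) stop("dose-response fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  # an increasing response fits either as hill < 0 or as swapped asymptotes
  inverted <- (co[["top"]] - co[["bottom"]]) * co[["hill"]] <= 0
  if (inverted)
    warning("fitted slope is non-negative in dose: response increases with concentration")
  se_log <- tryCatch(sqrt(stats::vcov(fit)["log_ic50", "log_ic50"]),
                     error = function(e) NA_real_)
  ic50 <- exp(co[["log_ic50"]])
  ci <- if (is.finite(se_log))
    exp(co[["log_ic50"]] + c(-1, 1) * stats::qnorm(0.975) * se_log)
  else c(NA_real_, NA_real_)
  structure(list(ic50 = ic50, ic50_ci = ci, bottom = co[["bottom"]],
                 top = co[["top"]], hill = co[["hill"]],
                 inverted = inverted,
                 converged = fit$convInfo$isConv, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit: IC50 = %.3g (95%% CI %.3g-%.3g)\n",
              x$ic50, x$ic50_ci[1], x$ic50_ci[2]))
  cat(sprintf("  top %.3g, bottom %.3g, hill %.3g\n", x$top, x$bottom, x$hill))
  invisible(x)
}
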