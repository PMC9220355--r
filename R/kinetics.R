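#' Assay conditions for photometric LPMO activity measurements
#'
#' Bundles the constants needed to turn an absorbance slope into a
#' specific activity: the molar absorption coefficient of the chromophore
#' (coerulignone: 53,200 M^-1 cm^-1 at 469 nm), cuvette path length,
#' reaction volume, enzyme mass and the substrate stoichiometry (2 umol
#' 2,6-DMP or 1 umol hydrocoerulignone per umol coerulignone formed).
#'
#' @param epsilon Molar absorption coefficient, M^-1 cm^-1.
#' @param path_length Optical path, cm.
#' @param reaction_volume Reaction volume, L.
#' @param enzyme_mass Enzyme mass in the reaction, g.
#' @param stoichiometry 1 or 2 (umol substrate per umol coerulignone).
#' @param wavelength Wavelength, nm (informational).
#' @return List of class `assay_conditions`.
#' @export
assay_conditions <- function(epsilon, path_length = 1, reaction_volume,
                             enzyme_mass, stoichiometry = 1,
                             wavelength = NA_real_) {
  if (!(epsilon > 0)) stop("epsilon must be > 0")
  if (!(path_length > 0)) stop("path_length must be > 0")
  if (!(reaction_volume > 0)) stop("reaction_volume must be > 0")
  if (!(stoichiometry %in% c(1, 2))) stop("stoichiometry must be 1 or 2")
  structure(list(epsilon = epsilon, path_length = path_length,
                 reaction_volume = reaction_volume,
                 enzyme_mass = enzyme_mass,
                 stoichiometry = stoichiometry, wavelength = wavelength),
            class = "assay_conditions")
}

#' Beer-Lambert concentration
#'
#' `c = A / (epsilon * l)`, e.g. hydrogen peroxide from its 240 nm
#' absorbance with epsilon = 43.6 M^-1 cm^-1.
#'
#' @param absorbance Absorbance (AU), >= 0.
#' @param epsilon Molar absorption coefficient, M^-1 cm^-1.
#' @param path Path length, cm.
#' @return Concentration in M.
#' @export
beer_lambert_conc <- function(absorbance, epsilon, path = 1) {
  if (!(is.numeric(epsilon) && all(epsilon > 0))) stop("epsilon must be > 0")
  if (!(is.numeric(path) && all(path > 0))) stop("path must be > 0")
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  absorbance / (epsilon * path)
}

#' Specific activity from an absorbance slope
#'
#' Blank-corrects the rate first, converts it to a molar product-formation
#' rate by Beer-Lambert, scales by the reaction volume to umol/min and
#' divides by the enzyme mass: one unit (U) is 1 umol coerulignone formed
#' per minute, so the result is in U per g enzyme. A slope below the blank
#' is clipped to zero with a warning.
#'
#' @param slope Absorbance slope with enzyme, AU/min.
#' @param blank_slope Absorbance slope of the enzyme-free blank, AU/min.
#' @param cond An [assay_conditions()] object.
#' @return Specific activity, U g^-1.
#' @export
specific_activity <- function(slope, blank_slope = 0, cond) {
  stopifnot(inherits(cond, "assay_conditions"))
  if (!(cond$enzyme_mass > 0)) stop("enzyme_mass must be > 0")
  net <- slope - blank_slope
  if (any(net < 0)) {
    warning("slope below blank; clipping activity at 0")
    net <- pmax(net, 0)
  }
  rate_M_min <- net / (cond$epsilon * cond$path_length)  # M/min of product
  umol_min <- rate_M_min * cond$reaction_volume * 1e6
  umol_min / cond$enzyme_mass
}

#' Residual activity relative to the uninhibited reference
#'
#' `100 * activity / reference`. Scale-invariant: multiplying both
#' activities by a common factor leaves the percentage unchanged.
#'
#' @param activity Activity with inhibitor (any consistent unit).
#' @param reference Uninhibited reference activity, > 0, same unit.
#' @return Residual activity in percent.
#' @export
residual_activity <- function(activity, reference) {
  if (!(is.numeric(reference) && all(reference > 0)))
    stop("reference activity must be > 0")
  100 * activity / reference
}

#' Rate of turbidity change from an assay trace
#'
#' Least-squares slope of light intensity versus time over a stated window
#' (e.g. 40-200 s after starting the reaction with peroxide), rescaled to
#' per-minute. The rate is reported as a magnitude with a direction flag,
#' since depolymerization assays read a *decrease* in optical density.
#'
#' @param time Time, s.
#' @param intensity Optical signal at each time point.
#' @param window Numeric `c(t_start, t_end)` in s.
#' @return List: `rate` (magnitude, min^-1), `direction` (-1, 0, or +1),
#'   `slope_per_min` (signed), `se_per_min` (standard error), `n_points`.
#' @export
turbidity_rate <- function(time, intensity, window = range(time)) {
  stopifnot(length(time) == length(intensity), length(window) == 2L)
  if (window[1] < min(time) || window[2] > max(time))
    stop("window [", window[1], ", ", window[2], "] outside trace span")
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 10L) stop("fewer than 10 trace points in window")
  fit <- stats::lm(intensity[keep] ~ time[keep])
  slope_s <- unname(stats::coef(fit)[2])
  se_s <- tryCatch(
    suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2])),
    error = function(e) NA_real_)
  list(rate = abs(slope_s) * 60,
       direction = sign(slope_s),
       slope_per_min = slope_s * 60,
       se_per_min = se_s * 60,
       n_points = sum(keep))
}

#' Cheng-Prusoff inhibition constant from an IC50
#'
#' For competitive inhibition under Michaelis-Menten kinetics,
#' `K_i = IC50 / (1 + S / K_M)`. `K_M` must be supplied by the user.
#'
#' @param ic50 IC50, mM (> 0).
#' @param S Substrate concentration, mM (>= 0).
#' @param K_M Michaelis constant, mM (> 0).
#' @return K_i in mM.
#' @export
cheng_prusoff_ki <- function(ic50, S, K_M) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  if (!(is.numeric(K_M) && all(K_M > 0))) stop("K_M must be > 0")
  ic50 / (1 + S / K_M)
}

#' Equilibrium constants from a binding free energy
#'
#' `K_D = exp(-dG_bind / (R T))` and the rough inverse relation
#' `K_i ~ 1/K_D = exp(dG_bind / (R T))`. With dG_bind in kJ/mol the
#' exponent uses R = 8.314462618 J mol^-1 K^-1. Note the convention here
#' follows the thermodynamic-cycle bookkeeping: a more negative dG_bind
#' gives a *larger* K_D (association-like behavior) and a smaller K_i.
#'
#' @param dG_bind Binding free energy, kJ/mol.
#' @param T Temperature, K (> 0); default 298.15.
#' @return List with `K_D` and `K_i_approx` (dimensionless).
#' @export
kd_from_dg <- function(dG_bind, T = 298.15) {
  if (!(T > 0)) stop("temperature must be > 0")
  x <- dG_bind * 1000 / (GAS_CONSTANT * T)
  list(K_D = exp(-x), K_i_approx = exp(x))
}
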