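#' Boltzmann sigmoid value
#'
#' `y(x) = a2 + (a1 - a2) / (1 + exp((x - x0)/dx))`: the survival curve of
#' the intact complex as a function of collision voltage difference. `a1`
#' and `a2` are the initial and final educt rates (percent), `x0` the
#' midpoint voltage (the CV50) and `dx` the transition width (volts).
#'
#' @param x Voltage (volts), vectorized.
#' @param a1,a2 Initial/final educt rate (percent).
#' @param x0 Midpoint voltage (volts).
#' @param dx Transition width (volts, > 0).
#' @return Curve values.
#' @export
boltzmann_curve <- function(x, a1, a2, x0, dx) {
  a2 + (a1 - a2) / (1 + exp((x - x0) / dx))
}

#' Construct a Boltzmann survival-curve fit object
#'
#' Usually produced by [fit_boltzmann()]; constructing one directly is
#' useful when curve parameters are already known (e.g. published course
#' parameters).
#'
#' @param a1,a2 Initial/final educt rate (percent), `a1 > a2` for a
#'   decaying educt.
#' @param x0 Midpoint voltage CV50 (volts).
#' @param dx Transition width (volts, > 0).
#' @param r_squared Goodness of fit (NA when constructed from parameters).
#' @param r2_threshold Acceptance gate on `r_squared`.
#' @return Object of class `boltzmann_fit`.
#' @export
boltzmann_fit <- function(a1, a2, x0, dx, r_squared = NA_real_, r2_threshold = 0.98) {
  if (dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (a1 < a2) stop("a1 must not be below a2 for a decaying educt", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, x0 = x0, dx = dx,
                 r_squared = r_squared, r2_threshold = r2_threshold,
                 accepted = is.na(r_squared) || r_squared >= r2_threshold),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> a1=%.2f a2=%.2f x0=%.2f dx=%.2f R2=%s%s\n",
              x$a1, x$a2, x$x0, x$dx,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (x$accepted) "" else " [below acceptance threshold]"))
  invisible(x)
}

#' Fit a Boltzmann sigmoid to an educt survival curve
#'
#' Least-squares fit of the normalized educt percentage versus collision
#' voltage difference. Fits are carried out in percent units (0-100).
#' A fit with `r_squared` below `r2_threshold` is returned with
#' `accepted = FALSE` (a quality gate, not an error).
#'
#' @param delta_cv Voltages (volts), >= 5 points spanning both plateaus.
#' @param norm_ed_pct Normalized educt signal in percent.
#' @param r2_threshold Acceptance gate on R-squared.
#' @return A [boltzmann_fit()] object.
#' @export
fit_boltzmann <- function(delta_cv, norm_ed_pct, r2_threshold = 0.98) {
  x <- as.numeric(delta_cv); y <- as.numeric(norm_ed_pct)
  if (length(x) != length(y) || length(x) < 5L)
    stop("need >= 5 (delta_cv, norm_ed) points", call. = FALSE)
  if (stats::sd(y) < sqrt(.Machine$double.eps) * max(1, abs(mean(y))))
    stop("degenerate survival data: no transition (constant signal)", call. = FALSE)
  if (stats::cor(x, y) > 0)
    stop("orientation error: educt signal increases with collision voltage",
         call. = FALSE)
  a1_0 <- max(y); a2_0 <- min(y)
  x0_0 <- x[which.min(abs(y - (a1_0 + a2_0) / 2))]
  dx_0 <- max(diff(range(x)) / 10, 1e-3)
  fit <- minpack.lm::nlsLM(
    y ~ a2 + (a1 - a2) / (1 + exp((x - x0) / dx)),
    start = list(a1 = a1_0, a2 = a2_0, x0 = x0_0, dx = dx_0),
    lower = c(a1 = 0, a2 = 0, x0 = min(x), dx = 1e-6),
    upper = c(a1 = Inf, a2 = Inf, x0 = max(x), dx = diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  if (cf["a1"] <= cf["a2"])
    stop("orientation error: fitted curve is not a decaying educt", call. = FALSE)
  boltzmann_fit(unname(cf["a1"]), unname(cf["a2"]), unname(cf["x0"]),
                unname(cf["dx"]), r_squared = r2, r2_threshold = r2_threshold)
}

#' Tangent slope of the survival curve at its midpoint
#'
#' Analytically `dy/dx` at `x = x0` equals `-(a1 - a2) / (4 dx)` (percent
#' per volt): the slope of the tangent line along the steep part of the
#' curve.
#'
#' @param fit A [boltzmann_fit()].
#' @return Midpoint slope in percent per volt.
#' @export
midpoint_slope <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  -(fit$a1 - fit$a2) / (4 * fit$dx)
}

#' Steep-region voltage window of a survival curve
#'
#' Voltages where the local slope magnitude is at least half the midpoint
#' slope: `x0 +/- log(3 + 2 sqrt(2)) * dx` (about `x0 +/- 1.76 dx`). Used to
#' select the points entering the Arrhenius and van't Hoff regressions.
#'
#' @param fit A [boltzmann_fit()].
#' @return Numeric vector `c(lower, upper)` in volts.
#' @export
steep_region <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  half <- log(3 + 2 * sqrt(2))
  c(fit$x0 - half * fit$dx, fit$x0 + half * fit$dx)
}

#' Collision temperature model
#'
#' Maps a collision-cell voltage difference to an effective ion temperature.
#' The default model adds to the ambient temperature the center-of-mass
#' collision energy per collision distributed over an effective heat
#' capacity: `T_coll = T_amb + dof_scale * z e dCV * m_gas/(m_gas + m_ion) / kB`.
#' At `dCV = 0` it returns `t_amb` exactly and grows strictly linearly.
#' The mapping is a pluggable strategy (`fun`): all closure identities among
#' the derived thermodynamic quantities are evaluated at ambient temperature
#' and hold for any strictly increasing mapping.
#'
#' @param t_amb Ambient temperature (K), default 298.
#' @param gas_mass Collision gas mass (Da); default argon.
#' @param ion_mass Ion mass (Da).
#' @param mean_charge Mean charge state of the ion.
#' @param dof_scale Dimensionless calibration constant (2 / effective
#'   degrees of freedom heated per collision).
#' @param fun Optional replacement mapping `function(model, delta_cv)`.
#' @return Object of class `temperature_model`.
#' @export
temperature_model <- function(t_amb = 298, gas_mass = 39.948, ion_mass = 13708.2,
                              mean_charge = 7, dof_scale = 0.02, fun = NULL) {
  if (gas_mass <= 0 || ion_mass <= 0)
    stop("gas_mass and ion_mass must be positive", call. = FALSE)
  structure(list(t_amb = t_amb, gas_mass = gas_mass, ion_mass = ion_mass,
                 mean_charge = mean_charge, dof_scale = dof_scale, fun = fun),
            class = "temperature_model")
}

#' Effective collision temperature at a voltage step
#'
#' @param model A [temperature_model()].
#' @param delta_cv Collision voltage difference (volts, >= 0), vectorized.
#' @return Temperature(s) in kelvin.
#' @export
collision_temperature <- function(model, delta_cv) {
  stopifnot(inherits(model, "temperature_model"))
  if (any(delta_cv < 0)) stop("delta_cv must be >= 0", call. = FALSE)
  if (!is.null(model$fun)) return(model$fun(model, delta_cv))
  com <- model$gas_mass / (model$gas_mass + model$ion_mass)
  model$t_amb + model$dof_scale * model$mean_charge * .const$e_over_kB *
    delta_cv * com
}

#' Pseudo-first-order survival rate constant
#'
#' Treats the surviving educt fraction as exponential decay over the ion's
#' residence time in the collision cell:
#' `k = -ln(norm_ed / norm_ed_initial) / residence_time`. Survival is
#' referenced to the educt fraction at the lowest voltage step, so that
#' in-solution pre-dissociation (initial educt rates below 100 percent)
#' does not masquerade as gas-phase kinetics. A fully dissociated point
#' (`norm_ed = 0`) returns `Inf` (flagged; excluded from regressions).
#'
#' @param norm_ed Surviving educt fraction (0..1].
#' @param norm_ed_initial Reference educt fraction at the lowest voltage.
#' @param residence_time Ion residence time in seconds (default 8.8e-5, the
#'   pusher period of a Q-ToF-class instrument).
#' @return Rate constant(s) in 1/s.
#' @export
survival_rate_constant <- function(norm_ed, norm_ed_initial, residence_time = 8.8e-5) {
  if (residence_time <= 0) stop("residence_time must be > 0", call. = FALSE)
  if (any(norm_ed < 0) || any(norm_ed > norm_ed_initial + 1e-12))
    stop("need 0 <= norm_ed <= norm_ed_initial", call. = FALSE)
  ifelse(norm_ed == 0, Inf, -log(norm_ed / norm_ed_initial) / residence_time)
}

#' Arrhenius regression of ln k against reciprocal collision temperature
#'
#' @param inv_t Reciprocal temperatures (1/K).
#' @param ln_k Log rate constants; non-finite values are dropped.
#' @return List `slope` (kelvin), `intercept`, `n`.
#' @export
arrhenius_line <- function(inv_t, ln_k) {
  ok <- is.finite(inv_t) & is.finite(ln_k)
  inv_t <- inv_t[ok]; ln_k <- ln_k[ok]
  if (length(inv_t) < 2L)
    stop("insufficient data: need >= 2 finite (1/T, ln k) points", call. = FALSE)
  cf <- stats::coef(stats::lm(ln_k ~ inv_t))
  list(slope = unname(cf[2]), intercept = unname(cf[1]), n = length(inv_t))
}

#' van't Hoff analysis of ln KD against reciprocal collision temperature
#'
#' Fits `ln KD = -(dH/R) * (1/T) + dS/R`. Because the line's slope is the
#' same everywhere, the slope at ambient temperature defines the apparent
#' zero-energy enthalpy: `dH = -R * slope`, and the entropy term at ambient
#' temperature is `T_amb * R * intercept`. Both are reported in kJ/mol.
#'
#' @param inv_t Reciprocal temperatures (1/K).
#' @param ln_kd Log equilibrium dissociation constants.
#' @param t_amb Ambient temperature (K).
#' @return List `dh_m0g`, `tds_m0g` (kJ/mol), `slope` (K), `intercept`, `n`.
#' @export
vant_hoff_thermo <- function(inv_t, ln_kd, t_amb = 298) {
  ok <- is.finite(inv_t) & is.finite(ln_kd)
  inv_t <- inv_t[ok]; ln_kd <- ln_kd[ok]
  if (length(inv_t) < 2L)
    stop("insufficient data: need >= 2 finite (1/T, ln KD) points", call. = FALSE)
  cf <- stats::coef(stats::lm(ln_kd ~ inv_t))
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  list(dh_m0g = -.const$R_gas * slope / 1000,
       tds_m0g = t_amb * .const$R_gas * intercept / 1000,
       slope = slope, intercept = intercept, n = length(inv_t))
}

#' Gibbs energy from an equilibrium dissociation constant
#'
#' `dG = -R T ln(KD) / 1000` in kJ/mol, with R = 8.314 J/(mol K).
#'
#' @param kd Dimensionless dissociation constant (> 0), vectorized.
#' @param t Temperature in kelvin (> 0).
#' @return Gibbs energy in kJ/mol.
#' @export
gibbs_from_kd <- function(kd, t = 298) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(t <= 0)) stop("temperature must be > 0", call. = FALSE)
  -.const$R_gas * t * log(kd) / 1000
}

#' Equilibrium dissociation constant from normalized intensities
#'
#' Default `mass-action-normalized` construction: one educt dissociates
#' into two products, each product fraction is `norm_prod / 2`, and on the
#' normalized (dimensionless) scale `KD = (norm_prod/2)^2 / norm_ed`. The
#' construction is a pluggable strategy (`fun`).
#'
#' @param norm_ed Educt fraction (> 0), vectorized.
#' @param norm_prod Product fraction.
#' @param mode Construction name.
#' @param fun Optional replacement `function(norm_ed, norm_prod)`.
#' @return Dimensionless KD.
#' @export
kd_from_intensities <- function(norm_ed, norm_prod,
                                mode = "mass-action-normalized", fun = NULL) {
  if (any(norm_ed <= 0)) stop("norm_ed must be > 0", call. = FALSE)
  if (!is.null(fun)) return(fun(norm_ed, norm_prod))
  if (!identical(mode, "mass-action-normalized"))
    stop("unknown kd mode: ", mode, call. = FALSE)
  (norm_prod / 2)^2 / norm_ed
}

#' Full kinetic/thermodynamic analysis of an aggregated survival series
#'
#' Chains the stages of the survival-yield analysis: Boltzmann fit of the
#' aggregated educt percentages, steep-region point selection, per-point
#' survival rate constants and normalized dissociation constants, collision
#' temperatures from the temperature model, Arrhenius and van't Hoff
#' regressions, and evaluation of both lines at ambient temperature. The
#' apparent quantities are reported at ambient temperature: `k_m0g` from
#' the Arrhenius line at `1/T_amb`, `kd_m0g` from the van't Hoff line at
#' `1/T_amb`, `dg_m0g = -R T_amb ln(kd_m0g)/1000`, `dh_m0g = -R * slope`,
#' `tds_m0g = T_amb R * intercept` — so `dg = dh - tds` holds by
#' construction (checked to 0.2 kJ/mol).
#'
#' @param aggregated Data frame from [aggregate_replicates()] (`delta_cv`,
#'   `mean_norm_ed` as a fraction in \[0,1\]).
#' @param model A [temperature_model()].
#' @param residence_time Ion residence time (s).
#' @param kd_mode KD construction passed to [kd_from_intensities()].
#' @param r2_threshold Boltzmann acceptance gate.
#' @return Object of class `thermo_result`: the apparent quantities, the
#'   regression lines, the Boltzmann fit and the points used.
#' @export
analyze_series <- function(aggregated, model = temperature_model(),
                           residence_time = 8.8e-5,
                           kd_mode = "mass-action-normalized",
                           r2_threshold = 0.98) {
  stopifnot(is.data.frame(aggregated),
            all(c("delta_cv", "mean_norm_ed") %in% names(aggregated)))
  agg <- aggregated[order(aggregated$delta_cv), , drop = FALSE]
  fit <- fit_boltzmann(agg$delta_cv, agg$mean_norm_ed * 100,
                       r2_threshold = r2_threshold)
  win <- steep_region(fit)
  sel <- agg$delta_cv >= win[1] & agg$delta_cv <= win[2] &
    agg$mean_norm_ed > 0 & agg$mean_norm_ed < 1
  pts <- agg[sel, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop("insufficient data: fewer than 2 aggregated points fall in the ",
         "steep region of the survival curve", call. = FALSE)
  s0 <- agg$mean_norm_ed[1]
  k <- survival_rate_constant(pts$mean_norm_ed, s0, residence_time)
  kd <- kd_from_intensities(pts$mean_norm_ed, 1 - pts$mean_norm_ed, mode = kd_mode)
  tc <- collision_temperature(model, pts$delta_cv)
  inv_t <- 1 / tc
  arr <- arrhenius_line(inv_t, log(k))
  vh_line <- vant_hoff_thermo(inv_t, log(kd), t_amb = model$t_amb)
  inv_amb <- 1 / model$t_amb
  k_m0g <- exp(arr$intercept + arr$slope * inv_amb)
  kd_m0g <- exp(vh_line$intercept + vh_line$slope * inv_amb)
  dg_m0g <- gibbs_from_kd(kd_m0g, model$t_amb)
  res <- structure(list(
    k_m0g = k_m0g, kd_m0g = kd_m0g, dg_m0g = dg_m0g,
    dh_m0g = vh_line$dh_m0g, tds_m0g = vh_line$tds_m0g,
    arrhenius_slope = arr$slope, arrhenius_intercept = arr$intercept,
    vant_hoff_slope = vh_line$slope, vant_hoff_intercept = vh_line$intercept,
    t_amb = model$t_amb, boltzmann = fit,
    points = data.frame(delta_cv = pts$delta_cv, norm_ed = pts$mean_norm_ed,
                        t_coll = tc, k = k, kd = kd)
  ), class = "thermo_result")
  if (abs(res$dg_m0g - (res$dh_m0g - res$tds_m0g)) > 0.2)
    stop("internal inconsistency: dG != dH - TdS beyond 0.2 kJ/mol", call. = FALSE)
  res
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(paste0("<thermo_result> at T_amb = %g K\n",
                     "  k_m0g#  = %.3e 1/s\n  KD_m0g# = %.3e\n",
                     "  dG_m0g# = %.2f kJ/mol\n  dH_m0g# = %.2f kJ/mol\n",
                     "  TdS_m0g# = %.2f kJ/mol\n"),
              x$t_amb, x$k_m0g, x$kd_m0g, x$dg_m0g, x$dh_m0g, x$tds_m0g))
  invisible(x)
}

#' Reference course parameters for the RNase S benchmark system
#'
#' Published Boltzmann course parameters (mean charge, initial/final educt
#' rate, CV50, width, midpoint slope) for gas-phase dissociation of the
#' RNase S complex at six solvent conditions, shipped as a plain-text table
#' for validation of the slope identity. Values are reference data, not
#' package constants.
#'
#' @return Data frame with columns `condition`, `mean_charge`,
#'   `mean_charge_sd`, `a1`, `a2`, `x0`, `dx`, `slope`.
#' @export
rnase_s_course_parameters <- function() {
  utils::read.csv(system.file("extdata", "rnase_s_course_parameters.csv",
                              package = "itemtwo"), stringsAsFactors = FALSE)
}

#' Reference apparent thermodynamic values for the RNase S benchmark system
#'
#' Published apparent gas-phase quantities (rate constant, dissociation
#' constant, Gibbs energy, enthalpy and entropy terms at 298 K) for the
#' RNase S complex at six solvent conditions, shipped as a plain-text table
#' for validation of the thermodynamic closure identities.
#'
#' @return Data frame with columns `condition`, `k_m0g`, `kd_m0g`,
#'   `dg_m0g`, `dh_m0g`, `tds_m0g`.
#' @export
rnase_s_thermo_values <- function() {
  utils::read.csv(system.file("extdata", "rnase_s_thermo_values.csv",
                              package = "itemtwo"), stringsAsFactors = FALSE)
}
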