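# One-set-of-sites ITC isotherm: simulation and least-squares fitting.

.R_GAS <- 8.314 # J/(mol K)

#' Thermodynamic conditions
#'
#' @param temperature Absolute temperature in kelvin; default 293.15 K
#'   (20 degrees C, the calorimetry condition).
#' @return List of class `thermo_conditions` with `temperature` and the
#'   gas constant `gas_constant` (8.314 J/(mol K)).
#' @export
thermo_conditions <- function(temperature = 293.15) {
  stopifnot(temperature > 0)
  structure(list(temperature = temperature, gas_constant = .R_GAS),
            class = "thermo_conditions")
}

#' One-site binding parameters
#'
#' @param n_sites Stoichiometry N, titrant binding sites per molecule of
#'   cell material (dimensionless, > 0).
#' @param kd Dissociation constant in molar (> 0).
#' @param delta_h Binding enthalpy in kJ/mol.
#' @return List of class `binding_params`.
#' @export
binding_params <- function(n_sites, kd, delta_h) {
  stopifnot(n_sites > 0, kd > 0, is.finite(delta_h))
  structure(list(n_sites = n_sites, kd = kd, delta_h = delta_h),
            class = "binding_params")
}

#' ITC titration series
#'
#' Injection schedule for a perfusion-cell titration. The default mirrors
#' the instrument setup used for the FBF-2/LST-1 titrations: a 200-uL cell
#' and 2-uL injections from a 40-uL syringe.
#'
#' @param cell_volume Cell volume in liters (default `200e-6`, i.e.
#'   200 uL).
#' @param cell_conc0 Starting macromolecule concentration in the cell
#'   (molar).
#' @param syringe_conc Titrant concentration in the syringe (molar).
#' @param injection_volumes Ordered injection volumes in liters.
#' @param heats Optional measured heats, one per injection.
#' @param heat_unit Dialect of `heats`: `"uJ"` (microjoules per injection)
#'   or `"kJ/mol"` (kJ per mole of injectant).
#' @return List of class `titration_series`.
#' @export
titration_series <- function(cell_conc0, syringe_conc,
                             injection_volumes = rep(2e-6, 19L),
                             cell_volume = 200e-6,
                             heats = NULL, heat_unit = c("uJ", "kJ/mol")) {
  heat_unit <- match.arg(heat_unit)
  stopifnot(cell_volume > 0, cell_conc0 > 0, syringe_conc > 0,
            all(injection_volumes > 0))
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    stop("heats and injection_volumes must have equal length")
  }
  structure(list(cell_volume = cell_volume, cell_conc0 = cell_conc0,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 heats = heats, heat_unit = heat_unit),
            class = "titration_series")
}

# Diluted totals after each injection, perfusion-cell convention:
# with v = cumulative injected volume / cell volume,
#   Mt = M0 (1 - v/2) / (1 + v/2),  Xt = Xs v / (1 + v/2).
.itc_totals <- function(series) {
  v <- cumsum(series$injection_volumes) / series$cell_volume
  list(v = v,
       Mt = series$cell_conc0 * (1 - v / 2) / (1 + v / 2),
       Xt = series$syringe_conc * v / (1 + v / 2))
}

#' Predicted per-injection heats under the one-set-of-sites model
#'
#' Computes the cumulative heat content of the cell after each injection,
#' \deqn{Q = \frac{N M_t \Delta H V_0}{2}\left[1 + \frac{X_t}{N M_t} +
#'   \frac{1}{N K M_t} - \sqrt{\left(1 + \frac{X_t}{N M_t} +
#'   \frac{1}{N K M_t}\right)^2 - \frac{4 X_t}{N M_t}}\right]}
#' with association constant \eqn{K = 1/K_d} and the perfusion-cell
#' dilution of both species, and differences successive Q values with the
#' half-displaced-volume correction to give the observed heat per
#' injection.
#'
#' @param params A [binding_params].
#' @param series A [titration_series] (its `heats`, if any, are ignored).
#' @param conditions A [thermo_conditions] (unused by the isotherm itself;
#'   kept for interface symmetry with the thermodynamic conversions).
#' @param unit Output dialect: `"uJ"` per injection (default) or
#'   `"kJ/mol"` of injectant.
#' @return Numeric vector of per-injection heats.
#' @export
one_site_heats <- function(params, series,
                           conditions = thermo_conditions(),
                           unit = c("uJ", "kJ/mol")) {
  unit <- match.arg(unit)
  stopifnot(inherits(params, "binding_params"),
            inherits(series, "titration_series"))
  tot <- .itc_totals(series)
  N <- params$n_sites
  K <- 1 / params$kd
  dH <- params$delta_h * 1000       # J/mol
  V0 <- series$cell_volume
  xr <- tot$Xt / (N * tot$Mt)
  r <- 1 / (N * K * tot$Mt)
  disc <- (1 + xr + r)^2 - 4 * xr
  if (any(disc < 0)) stop("negative discriminant in one-site isotherm")
  Q <- (N * tot$Mt * dH * V0 / 2) * (1 + xr + r - sqrt(disc))
  Qprev <- c(0, Q[-length(Q)])
  dV <- series$injection_volumes
  dQ <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2   # joules
  if (unit == "uJ") {
    dQ * 1e6
  } else {
    moles_injected <- dV * series$syringe_conc
    dQ / moles_injected / 1000
  }
}

#' Fit the one-set-of-sites model to a titration
#'
#' Levenberg-Marquardt least squares for (N, Kd, dH) on per-injection
#' heats, with N and Kd fitted on the log scale to keep them positive.
#' Default initialization: N = 1, dH from the first retained injection
#' converted to kJ per mole of injectant, and a small grid of Kd starting
#' values around the cell concentration; the best converged start wins.
#' The first injection is discarded by default (syringe-tip diffusion).
#'
#' @param series A [titration_series] carrying measured `heats`.
#' @param conditions A [thermo_conditions].
#' @param init Optional [binding_params] used as the single starting
#'   point.
#' @param discard_first Drop the first injection before fitting (default
#'   `TRUE`).
#' @return Object of class `itc_fit`: list with `params` (a
#'   [binding_params] of the estimates), `se` (standard errors from the
#'   least-squares covariance, named `n_sites`, `kd`, `delta_h`),
#'   `residual_norm`, `converged`, `fitted`, `n_used`.
#' @export
fit_itc <- function(series, conditions = thermo_conditions(), init = NULL,
                    discard_first = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$heats)) stop("titration series carries no heats")
  keep <- seq_along(series$heats)
  if (discard_first) keep <- keep[-1L]
  if (length(keep) < 6L) stop("need at least 6 usable injections")
  obs <- series$heats[keep]
  if (max(abs(obs)) == 0) {
    return(structure(list(params = NULL, se = NULL,
                          residual_norm = 0, converged = FALSE,
                          degenerate = "all-zero heats",
                          fitted = NULL, n_used = length(keep)),
                     class = "itc_fit"))
  }
  unit <- series$heat_unit

  predict_heats <- function(theta) {
    p <- binding_params(exp(theta[1L]), exp(theta[2L]), theta[3L])
    one_site_heats(p, series, conditions, unit = unit)[keep]
  }
  resid_fn <- function(theta) obs - predict_heats(theta)

  # dH guess: first retained injection per mole of injectant, in kJ/mol
  dh0 <- if (unit == "kJ/mol") obs[1L] else {
    obs[1L] * 1e-6 /
      (series$injection_volumes[keep[1L]] * series$syringe_conc) / 1000
  }
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -10
  starts <- if (!is.null(init)) {
    list(c(log(init$n_sites), log(init$kd), init$delta_h))
  } else {
    lapply(series$cell_conc0 * c(0.01, 0.1, 1, 10),
           function(kd0) c(log(1), log(kd0), dh0))
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, se = NULL, residual_norm = NA_real_,
                          converged = FALSE, fitted = NULL,
                          n_used = length(keep)), class = "itc_fit"))
  }
  fit <- best$fit
  theta <- fit$par
  est <- binding_params(exp(theta[1L]), exp(theta[2L]), theta[3L])
  # delta-method SEs on the natural scale from the log-scale covariance
  se <- rep(NA_real_, 3L)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv)))) {
    se_log <- sqrt(pmax(diag(cv), 0))
    se <- c(est$n_sites * se_log[1L], est$kd * se_log[2L], se_log[3L])
  }
  names(se) <- c("n_sites", "kd", "delta_h")
  converged <- fit$info %in% 1:4 && all(is.finite(theta))
  structure(list(params = if (converged) est else NULL,
                 se = if (converged) se else NULL,
                 residual_norm = sqrt(best$ssr),
                 converged = converged,
                 fitted = if (converged) predict_heats(theta) else NULL,
                 n_used = length(keep)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<itc_fit> not converged",
        if (!is.null(x$degenerate)) paste0(" (", x$degenerate, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("<itc_fit> N = %.3g, Kd = %.3g uM, dH = %.4g kJ/mol (n = %d injections)\n",
              x$params$n_sites, x$params$kd * 1e6, x$params$delta_h,
              x$n_used))
  invisible(x)
}

#' Gibbs free energy from a dissociation constant
#'
#' `delta_g = R T ln(Kd)` in kJ/mol; negative for sub-molar Kd.
#'
#' @param kd Dissociation constant in molar.
#' @param conditions A [thermo_conditions].
#' @return Free energy in kJ/mol.
#' @examples
#' delta_g(1.1e-6)  # about -33.4 kJ/mol at 293.15 K
#' @export
delta_g <- function(kd, conditions = thermo_conditions()) {
  stopifnot(all(kd > 0))
  conditions$gas_constant * conditions$temperature * log(kd) / 1000
}

#' Entropic term -T dS from dG and dH
#'
#' @param delta_g,delta_h Free energy and enthalpy in kJ/mol.
#' @return `-T dS = dG - dH` in kJ/mol.
#' @export
minus_t_delta_s <- function(delta_g, delta_h) {
  delta_g - delta_h
}
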