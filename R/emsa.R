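# EMSA fraction-bound quantitation, one-site specific binding fits,
# FRET efficiency and affinity fold changes.

#' Fraction of RNA bound from band intensities
#'
#' `bound / (bound + unbound)`.
#'
#' @param intensity_bound,intensity_unbound Nonnegative band intensities
#'   (arbitrary units); vectorized, but a pair that is both zero is an
#'   error.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_bound <- function(intensity_bound, intensity_unbound) {
  stopifnot(all(intensity_bound >= 0), all(intensity_unbound >= 0))
  tot <- intensity_bound + intensity_unbound
  if (any(tot == 0)) stop("bound and unbound intensities are both zero")
  intensity_bound / tot
}

#' One-site specific binding curve
#'
#' `bmax * x / (kd + x)`: the fraction bound at free ligand concentration
#' `x` under the trace-RNA approximation (free protein equals total
#' protein).
#'
#' @param bmax Saturating fraction bound.
#' @param kd Dissociation constant (molar).
#' @param x Protein concentration(s), molar.
#' @return Predicted fraction(s) bound.
#' @export
one_site_specific <- function(bmax, kd, x) {
  stopifnot(kd > 0, all(x >= 0))
  bmax * x / (kd + x)
}

# Exact fraction bound when the trace approximation is not wanted: solve
# the binding quadratic for the complex given total protein P, total RNA R.
.one_site_exact <- function(bmax, kd, p_tot, rna_conc) {
  s <- p_tot + rna_conc + kd
  complex <- (s - sqrt(s^2 - 4 * p_tot * rna_conc)) / 2
  bmax * complex / rna_conc
}

#' EMSA binding curve
#'
#' @param protein_conc Strictly increasing protein concentrations (molar).
#' @param fraction_bound Fractions bound in `[0, 1]`, one per
#'   concentration.
#' @param rna_conc Trace RNA concentration (molar); default 5 nM.
#' @return List of class `emsa_curve`.
#' @export
emsa_curve <- function(protein_conc, fraction_bound, rna_conc = 5e-9) {
  stopifnot(length(protein_conc) == length(fraction_bound),
            all(protein_conc >= 0), !is.unsorted(protein_conc, strictly = TRUE),
            all(fraction_bound >= 0), all(fraction_bound <= 1.5),
            rna_conc > 0)
  structure(list(protein_conc = protein_conc,
                 fraction_bound = fraction_bound, rna_conc = rna_conc),
            class = "emsa_curve")
}

#' Fit a one-site specific binding model to an EMSA curve
#'
#' Least-squares estimates of `bmax` and `kd` (`kd` fitted on the log
#' scale). By default free protein is approximated by total protein (the
#' RNA is trace, nM against uM protein); `exact = TRUE` instead solves the
#' binding quadratic for ligand depletion. A fitted `kd` above the highest
#' tested concentration is reported as a lower bound (`censored = TRUE`),
#' mirroring the ">" convention for out-of-range affinities.
#'
#' @param curve An [emsa_curve]. At least 4 concentration points.
#' @param exact Use the exact (depletion-corrected) model.
#' @return Object of class `emsa_fit`: `bmax`, `kd`, `se` (named standard
#'   errors), `residual_norm`, `converged`, `censored`, `kd_bound` (the
#'   highest tested concentration when censored), `fitted`.
#' @export
fit_emsa <- function(curve, exact = FALSE) {
  stopifnot(inherits(curve, "emsa_curve"))
  x <- curve$protein_conc
  y <- curve$fraction_bound
  pos <- x > 0
  if (sum(pos) < 4L) stop("need at least 4 nonzero concentration points")
  if (max(y) <= 0) {
    return(structure(list(bmax = NA_real_, kd = NA_real_, se = NULL,
                          residual_norm = NA_real_, converged = FALSE,
                          censored = FALSE, kd_bound = NA_real_,
                          fitted = NULL), class = "emsa_fit"))
  }
  predict_fb <- function(theta) {
    bmax <- theta[1L]; kd <- exp(theta[2L])
    if (exact) .one_site_exact(bmax, kd, x, curve$rna_conc)
    else one_site_specific(bmax, kd, x)
  }
  resid_fn <- function(theta) y - predict_fb(theta)
  bmax0 <- max(y)
  kd0 <- x[pos][which.min(abs(y[pos] - bmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(bmax0, log(kd0)), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4 &&
    all(is.finite(fit$par))
  if (!converged) {
    return(structure(list(bmax = NA_real_, kd = NA_real_, se = NULL,
                          residual_norm = NA_real_, converged = FALSE,
                          censored = FALSE, kd_bound = NA_real_,
                          fitted = NULL), class = "emsa_fit"))
  }
  bmax <- fit$par[1L]; kd <- exp(fit$par[2L])
  se <- rep(NA_real_, 2L)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv)))) {
    se_raw <- sqrt(pmax(diag(cv), 0))
    se <- c(se_raw[1L], kd * se_raw[2L])
  }
  names(se) <- c("bmax", "kd")
  censored <- kd > max(x)
  structure(list(bmax = bmax, kd = kd, se = se,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = TRUE, censored = censored,
                 kd_bound = if (censored) max(x) else NA_real_,
                 fitted = predict_fb(fit$par)),
            class = "emsa_fit")
}

#' @export
print.emsa_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<emsa_fit> not converged\n")
  } else if (x$censored) {
    cat(sprintf("<emsa_fit> Kd > %.0f nM (above titration range), Bmax = %.3g\n",
                x$kd_bound * 1e9, x$bmax))
  } else {
    cat(sprintf("<emsa_fit> Kd = %.3g nM, Bmax = %.3g\n",
                x$kd * 1e9, x$bmax))
  }
  invisible(x)
}

#' Mean and SEM of replicate Kd estimates
#'
#' @param kds Numeric vector of per-replicate dissociation constants.
#' @return List with `mean`, `sem` (sample SD over sqrt(n)) and `n`.
#' @examples
#' replicate_summary(c(100, 110, 120))
#' @export
replicate_summary <- function(kds) {
  stopifnot(length(kds) >= 2L)
  list(mean = mean(kds), sem = stats::sd(kds) / sqrt(length(kds)),
       n = length(kds))
}

#' Relative FRET efficiency
#'
#' Acceptor fraction of total emission: `I_668 / (I_668 + I_564)`, with
#' donor (Cy3) emission read at 564 nm and acceptor (Cy5) at 668 nm.
#'
#' @param i_564,i_668 Nonnegative donor and acceptor intensities;
#'   vectorized, but a pair that is both zero is an error.
#' @return Efficiency in `[0, 1]`.
#' @examples
#' fret_efficiency(i_564 = 300, i_668 = 100)  # 0.25
#' @export
fret_efficiency <- function(i_564, i_668) {
  stopifnot(all(i_564 >= 0), all(i_668 >= 0))
  tot <- i_564 + i_668
  if (any(tot == 0)) stop("donor and acceptor intensities are both zero")
  i_668 / tot
}

#' Affinity fold change between two Kd values
#'
#' `kd_reference / kd_test`: how many fold tighter the test condition
#' binds than the reference.
#'
#' @param kd_reference,kd_test Dissociation constants (> 0), any common
#'   unit.
#' @return Dimensionless fold change.
#' @examples
#' fold_change(435, 109)  # about 4
#' @export
fold_change <- function(kd_reference, kd_test) {
  stopifnot(all(kd_reference > 0), all(kd_test > 0))
  kd_reference / kd_test
}
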