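# Germline protein-intensity profiles along the distal-proximal axis.

.check_profiles <- function(profiles) {
  need <- c("gonad_id", "genotype", "position_um", "intensity")
  missing <- setdiff(need, names(profiles))
  if (length(missing) > 0L) {
    stop("profile table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(profiles$intensity < 0)) stop("intensities must be nonnegative")
  invisible(profiles)
}

# Linear interpolation of one gonad's profile onto the common grid;
# positions outside the measured range give NA and are dropped per point.
.interp_gonad <- function(position, intensity, grid) {
  if (is.unsorted(position, strictly = TRUE)) {
    o <- order(position)
    position <- position[o]; intensity <- intensity[o]
  }
  stats::approx(position, intensity, xout = grid, rule = 1)$y
}

#' Per-position mean profile with 95% confidence interval
#'
#' Resamples each gonad's intensity profile onto a common position grid by
#' linear interpolation, then takes the pointwise arithmetic mean with a
#' 95% t-interval (n - 1 degrees of freedom) across gonads. Grid points
#' outside a gonad's measured range receive no contribution from that
#' gonad.
#'
#' @param profiles Long-format data.frame with columns `gonad_id`,
#'   `genotype`, `position_um`, `intensity`; all rows should belong to one
#'   genotype.
#' @param grid Common position grid in micrometers from the distal end
#'   (default 0 to 100 um at 1-um steps).
#' @return data.frame of class `profile_summary` columns: `genotype`,
#'   `position_um`, `mean`, `ci95_low`, `ci95_high`, `n`.
#' @export
mean_profile <- function(profiles, grid = 0:100) {
  .check_profiles(profiles)
  if (length(unique(profiles$genotype)) > 1L) {
    stop("mean_profile expects a single genotype; see profile_summaries()")
  }
  gonads <- split(profiles, profiles$gonad_id)
  if (length(gonads) < 2L) stop("need at least 2 gonads per genotype")
  mat <- vapply(gonads, function(g) {
    .interp_gonad(g$position_um, g$intensity, grid)
  }, numeric(length(grid)))
  n <- rowSums(!is.na(mat))
  mu <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  half <- ifelse(n >= 2L, stats::qt(0.975, pmax(n - 1L, 1L)) * sdv / sqrt(n),
                 NA_real_)
  out <- data.frame(genotype = profiles$genotype[1L], position_um = grid,
                    mean = mu, ci95_low = mu - half, ci95_high = mu + half,
                    n = n, stringsAsFactors = FALSE)
  class(out) <- c("profile_summary", class(out))
  out
}

#' Mean profiles for every genotype in a table
#'
#' @inheritParams mean_profile
#' @return Named list of `profile_summary` data.frames, one per genotype.
#' @export
profile_summaries <- function(profiles, grid = 0:100) {
  .check_profiles(profiles)
  lapply(split(profiles, profiles$genotype), mean_profile, grid = grid)
}

#' Normalize profile summaries to the wild-type distal maximum
#'
#' Divides every genotype's mean and confidence bounds by the maximum of
#' the wild-type mean profile over the distal 0-100 um, so the wild-type
#' maximum becomes exactly 1. The operation is idempotent and invariant to
#' rescaling all raw intensities by a positive constant.
#'
#' @param summaries Named list of `profile_summary` data.frames (as from
#'   [profile_summaries]).
#' @param wt_label Name of the wild-type genotype in `summaries`.
#' @param distal_window Interval (um) over which the wild-type maximum is
#'   taken; default `c(0, 100)`.
#' @return The list with `mean`, `ci95_low`, `ci95_high` rescaled.
#' @export
normalize_to_wt_max <- function(summaries, wt_label,
                                distal_window = c(0, 100)) {
  if (!wt_label %in% names(summaries)) {
    stop("wild-type genotype '", wt_label, "' not found")
  }
  wt <- summaries[[wt_label]]
  sel <- wt$position_um >= distal_window[1L] &
    wt$position_um <= distal_window[2L]
  wt_max <- max(wt$mean[sel], na.rm = TRUE)
  if (!is.finite(wt_max) || wt_max <= 0) {
    stop("wild-type maximum over the distal window is not positive")
  }
  lapply(summaries, function(s) {
    s$mean <- s$mean / wt_max
    s$ci95_low <- s$ci95_low / wt_max
    s$ci95_high <- s$ci95_high / wt_max
    s
  })
}

#' Map a p-value to a significance label
#'
#' `*** p < 0.001, ** p < 0.01, * p < 0.05, ns` otherwise.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

# Average of a piecewise-linear profile over [a, b]: trapezoidal integral
# of the interpolant divided by the overlap width. Exactly invariant to
# resampling the profile onto any grid containing its knots.
.window_mean <- function(position, intensity, a, b) {
  if (is.unsorted(position, strictly = TRUE)) {
    o <- order(position)
    position <- position[o]; intensity <- intensity[o]
  }
  lo <- max(a, min(position)); hi <- min(b, max(position))
  if (lo > hi) return(NA_real_)
  if (lo == hi) {
    return(stats::approx(position, intensity, xout = lo)$y)
  }
  xs <- sort(unique(c(lo, hi, position[position > lo & position < hi])))
  ys <- stats::approx(position, intensity, xout = xs)$y
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2) /
    (hi - lo)
}

#' Compare two genotypes over a positional window
#'
#' For each gonad, averages the intensity over the window (trapezoidal
#' average of the gonad's piecewise-linear profile, so the result does not
#' depend on how finely the profile was sampled); the two groups of
#' per-gonad means are then compared with the unpaired equal-variance
#' two-sided t-test. This is the pooled-window comparison used for the
#' distal 0-10 um and proximal 70-80 / 90-100 um regions.
#'
#' @param profiles_a,profiles_b Long-format profile tables, one genotype
#'   each (same columns as [mean_profile]); intensities should already be
#'   on a common (e.g. wild-type-normalized) scale if that is the desired
#'   comparison.
#' @param window Length-2 numeric interval in um, e.g. `c(0, 10)`.
#' @return List with the `group_comparison` (`test`), per-gonad window
#'   means (`means_a`, `means_b`), `window` and `stars`.
#' @export
window_compare <- function(profiles_a, profiles_b, window) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  gonad_means <- function(profiles) {
    .check_profiles(profiles)
    out <- vapply(split(profiles, profiles$gonad_id), function(g) {
      .window_mean(g$position_um, g$intensity, window[1L], window[2L])
    }, numeric(1))
    if (all(is.na(out))) {
      stop("window [", window[1L], ", ", window[2L],
           "] lies outside every measured profile")
    }
    out[!is.na(out)]
  }
  a <- gonad_means(profiles_a)
  b <- gonad_means(profiles_b)
  test <- pooled_t_test(a, b,
                        label_a = profiles_a$genotype[1L],
                        label_b = profiles_b$genotype[1L])
  list(test = test, means_a = a, means_b = b, window = window,
       stars = significance_stars(test$p_value))
}
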