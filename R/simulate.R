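# Synthetic data with known ground truth for every pipeline stage.

.BASES <- c("A", "C", "G", "U")

#' Uniform and 3'UTR-like background base compositions
#'
#' `uniform_composition()` gives 0.25 per base; `utr3_composition()` is a
#' U-rich preset (A 0.30, U 0.40, C 0.15, G 0.15) emulating 3'UTR
#' composition.
#'
#' @return Named numeric probability vector over A, C, G, U.
#' @export
uniform_composition <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
}

#' @rdname uniform_composition
#' @export
utr3_composition <- function() {
  c(A = 0.30, C = 0.15, G = 0.15, U = 0.40)
}

.check_composition <- function(composition) {
  if (!identical(sort(names(composition)), .BASES) ||
      any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    stop("composition must be a named nonnegative vector over A,C,G,U summing to 1")
  }
  composition[.BASES]
}

#' Random i.i.d. background sequence
#'
#' @param length Sequence length in nt (>= 0).
#' @param composition Per-base probabilities (default uniform).
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return RNA string.
#' @export
gen_background <- function(length, composition = uniform_composition(),
                           seed = NULL) {
  stopifnot(length >= 0)
  composition <- .check_composition(composition)
  if (length == 0L) return("")
  draw <- function() paste(sample(.BASES, length, replace = TRUE,
                                  prob = composition), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Draw a concrete element from a consensus class
#'
#' Degenerate positions are drawn uniformly from their allowed bases; the
#' result always matches its own class pattern.
#'
#' @param class Pattern name (one of `names(fbe_patterns())`) or an
#'   [fbe_pattern].
#' @param seed Optional integer seed.
#' @return Element string.
#' @export
realize_element <- function(class, seed = NULL) {
  pat <- if (inherits(class, "fbe_pattern")) class else
    fbe_patterns(class)[[1L]]
  draw <- function() {
    paste(vapply(pat$symbols, function(s) {
      allowed <- .FBE_SYMBOL_SETS[[s]]
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }, character(1)), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plant a pair of elements into a background sequence
#'
#' Overwrites (never inserts) the two element strings at positions chosen
#' so that exactly `gap` background bases separate them, keeping the
#' total length fixed.
#'
#' @param background RNA string.
#' @param elem_5p,elem_3p Concrete element strings.
#' @param gap Bases between the elements (>= 0).
#' @param offset 1-based start of the 5' element.
#' @return List: `sequence`, plus 1-based `up_start`, `up_length`,
#'   `down_start`, `down_length`, `gap`.
#' @export
plant_pair <- function(background, elem_5p, elem_3p, gap, offset = 1L) {
  stopifnot(gap >= 0, offset >= 1L)
  len5 <- nchar(elem_5p); len3 <- nchar(elem_3p)
  L <- nchar(background)
  down_start <- offset + len5 + gap
  if (down_start + len3 - 1L > L) {
    stop("elements with gap ", gap, " at offset ", offset,
         " do not fit in a ", L, "-nt background")
  }
  seq <- background
  substr(seq, offset, offset + len5 - 1L) <- elem_5p
  substr(seq, down_start, down_start + len3 - 1L) <- elem_3p
  list(sequence = seq, up_start = as.integer(offset),
       up_length = len5, down_start = as.integer(down_start),
       down_length = len3, gap = as.integer(gap))
}

#' Analytic per-offset match probability of a pattern
#'
#' Probability that a pattern matches at a fixed offset of an i.i.d.
#' background: the product over pattern positions of the composition mass
#' of each symbol's allowed base set. The expected number of matches in a
#' sequence of length L is `(L - m + 1)` times this value.
#'
#' @param pattern An [fbe_pattern] or pattern name.
#' @param composition Background composition (default uniform).
#' @return Probability per offset.
#' @examples
#' expected_match_probability("FBE9")  # 2^-11 under uniform background
#' @export
expected_match_probability <- function(pattern,
                                       composition = uniform_composition()) {
  pat <- if (inherits(pattern, "fbe_pattern")) pattern else
    fbe_patterns(pattern)[[1L]]
  composition <- .check_composition(composition)
  prod(vapply(pat$symbols, function(s) {
    sum(composition[.FBE_SYMBOL_SETS[[s]]])
  }, numeric(1)))
}

#' Specification for a synthetic peak set
#'
#' @param n_planted Number of peaks that receive a planted adjacent pair.
#' @param n_background Number of background-only peaks.
#' @param peak_length Peak length in nt (constant).
#' @param composition Background composition.
#' @param planted_gaps Integer vector of gaps to draw from when planting
#'   (default 1:20).
#' @param second_classes Classes eligible as the second element (default
#'   all four; the first element is always canonical).
#' @param fpkm_logmean,fpkm_logsd Lognormal peak-height parameters on the
#'   log scale (defaults log(400) and 1, giving a long-tailed FPKM
#'   distribution with median 400).
#' @param adjacent_multiplier Multiplicative height effect for planted
#'   peaks (>= 1; default 4).
#' @param region_probs Region-label probabilities (default heavily 3'UTR,
#'   as CLIP peak sets are).
#' @return List of class `peak_sim_spec`.
#' @export
peak_sim_spec <- function(n_planted = 50L, n_background = 50L,
                          peak_length = 80L,
                          composition = uniform_composition(),
                          planted_gaps = 1:20,
                          second_classes = names(fbe_patterns()),
                          fpkm_logmean = log(400), fpkm_logsd = 1,
                          adjacent_multiplier = 4,
                          region_probs = c(three_prime_utr = 0.9,
                                           five_prime_utr = 0.05,
                                           cds = 0.05, other = 0)) {
  stopifnot(n_planted >= 0L, n_background >= 0L, peak_length > 0L,
            adjacent_multiplier >= 1, fpkm_logsd >= 0,
            abs(sum(region_probs) - 1) < 1e-9)
  structure(list(n_planted = n_planted, n_background = n_background,
                 peak_length = peak_length,
                 composition = .check_composition(composition),
                 planted_gaps = as.integer(planted_gaps),
                 second_classes = second_classes,
                 fpkm_logmean = fpkm_logmean, fpkm_logsd = fpkm_logsd,
                 adjacent_multiplier = adjacent_multiplier,
                 region_probs = region_probs),
            class = "peak_sim_spec")
}

#' Generate a synthetic peak set with ground truth
#'
#' Planted peaks carry one canonical FBE plus a second element at a known
#' gap, overwritten onto an i.i.d. background; their heights are drawn
#' lognormal with the log-mean shifted by `log(adjacent_multiplier)`.
#' Background-only peaks are pure i.i.d. sequence (accidental element
#' matches are possible and are left in, as in real sequence). A mutant
#' (partnership-defective) height track is included so categorization can
#' be exercised: planted peaks lose the multiplier in the mutant track.
#'
#' @param spec A [peak_sim_spec].
#' @param seed Integer seed (required; the generator is a pure function of
#'   spec and seed).
#' @return List: `sequences` (named character), `peaks` (annotation
#'   data.frame with `peak_id`, `gene_id`, `region`, `height_wt`,
#'   `height_mut`, `planted`), `truth` (per-peak planted coordinates and
#'   the generating parameters).
#' @export
gen_peakset <- function(spec, seed) {
  stopifnot(inherits(spec, "peak_sim_spec"), !missing(seed))
  with_seed(seed, {
    n_tot <- spec$n_planted + spec$n_background
    if (n_tot == 0L) {
      return(list(sequences = stats::setNames(character(0), character(0)),
                  peaks = data.frame(peak_id = character(),
                                     gene_id = character(),
                                     region = character(),
                                     height_wt = numeric(),
                                     height_mut = numeric(),
                                     planted = logical(),
                                     stringsAsFactors = FALSE),
                  truth = list(planted = NULL, spec = spec, seed = seed)))
    }
    ids <- sprintf("peak_%04d", seq_len(n_tot))
    planted_flag <- rep(c(TRUE, FALSE), c(spec$n_planted, spec$n_background))
    sequences <- character(n_tot)
    truth_rows <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      bg <- gen_background(spec$peak_length, spec$composition)
      if (planted_flag[i]) {
        first <- realize_element("FBE9")
        second <- realize_element(sample(spec$second_classes, 1L))
        gap <- if (length(spec$planted_gaps) == 1L) spec$planted_gaps else
          sample(spec$planted_gaps, 1L)
        # randomize which side the canonical element is on
        if (stats::runif(1) < 0.5) {
          e5 <- first; e3 <- second
        } else {
          e5 <- second; e3 <- first
        }
        span <- nchar(e5) + gap + nchar(e3)
        max_off <- spec$peak_length - span + 1L
        if (max_off < 1L) stop("peak_length too short for planted pair")
        off <- sample.int(max_off, 1L)
        pl <- plant_pair(bg, e5, e3, gap = gap, offset = off)
        sequences[i] <- pl$sequence
        truth_rows[[i]] <- data.frame(peak_id = ids[i],
                                      up_start = pl$up_start,
                                      up_length = pl$up_length,
                                      down_start = pl$down_start,
                                      down_length = pl$down_length,
                                      gap = pl$gap,
                                      stringsAsFactors = FALSE)
      } else {
        sequences[i] <- bg
      }
    }
    names(sequences) <- ids
    lm_wt <- spec$fpkm_logmean +
      ifelse(planted_flag, log(spec$adjacent_multiplier), 0)
    height_wt <- stats::rlnorm(n_tot, meanlog = lm_wt,
                               sdlog = spec$fpkm_logsd)
    height_mut <- stats::rlnorm(n_tot, meanlog = spec$fpkm_logmean,
                                sdlog = spec$fpkm_logsd)
    region <- sample(names(spec$region_probs), n_tot, replace = TRUE,
                     prob = spec$region_probs)
    peaks <- data.frame(
      peak_id = ids,
      gene_id = sprintf("gene_%04d", seq_len(n_tot)),
      region = region, height_wt = height_wt, height_mut = height_mut,
      planted = planted_flag, stringsAsFactors = FALSE)
    truth <- do.call(rbind, Filter(Negate(is.null), truth_rows))
    list(sequences = sequences, peaks = peaks,
         truth = list(planted = truth, spec = spec, seed = seed))
  })
}

#' Simulate an ITC titration with known parameters
#'
#' Forward model is [one_site_heats]; Gaussian noise of standard deviation
#' `noise_sd` (same unit as the heats) is added.
#'
#' @param params A [binding_params] (the ground truth).
#' @param series A [titration_series] giving the schedule.
#' @param conditions A [thermo_conditions].
#' @param noise_sd Noise SD (>= 0) in the chosen heat unit.
#' @param unit Heat dialect, `"uJ"` or `"kJ/mol"`.
#' @param seed Optional integer seed.
#' @return The [titration_series] with `heats` filled in, plus a `truth`
#'   attribute holding the generating parameters.
#' @export
gen_itc <- function(params, series, conditions = thermo_conditions(),
                    noise_sd = 0, unit = c("uJ", "kJ/mol"), seed = NULL) {
  unit <- match.arg(unit)
  stopifnot(noise_sd >= 0)
  mu <- one_site_heats(params, series, conditions, unit = unit)
  noise <- if (noise_sd == 0) 0 else {
    if (is.null(seed)) stats::rnorm(length(mu), 0, noise_sd) else
      with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  }
  series$heats <- mu + noise
  series$heat_unit <- unit
  attr(series, "truth") <- params
  series
}

#' Simulate an EMSA binding curve with known parameters
#'
#' @param bmax,kd Generating saturation and dissociation constant (molar).
#' @param protein_conc Protein concentration series (molar); default a
#'   12-point 2-fold dilution from 5 uM.
#' @param rna_conc Trace RNA concentration (molar).
#' @param noise_sd Gaussian noise SD on the fractions (>= 0).
#' @param seed Optional integer seed.
#' @return An [emsa_curve] with a `truth` attribute.
#' @export
gen_emsa <- function(bmax, kd, protein_conc = 5e-6 / 2^(11:0),
                     rna_conc = 5e-9, noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  mu <- one_site_specific(bmax, kd, protein_conc)
  noise <- if (noise_sd == 0) 0 else {
    if (is.null(seed)) stats::rnorm(length(mu), 0, noise_sd) else
      with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  }
  fb <- pmin(pmax(mu + noise, 0), 1.5)
  curve <- emsa_curve(protein_conc, fb, rna_conc = rna_conc)
  attr(curve, "truth") <- list(bmax = bmax, kd = kd)
  curve
}

#' Simulate FRET intensity pairs with known efficiency
#'
#' Draws donor/acceptor intensity pairs whose noiseless ratio gives the
#' stated relative FRET efficiency.
#'
#' @param efficiency True relative FRET efficiency in `(0, 1)`.
#' @param n Number of replicate measurements.
#' @param total_intensity Total emission per measurement (arbitrary
#'   units).
#' @param noise_sd Gaussian noise SD on each intensity (>= 0).
#' @param seed Optional integer seed.
#' @return data.frame with `i_564`, `i_668` and a `truth` attribute.
#' @export
gen_fret <- function(efficiency, n = 3L, total_intensity = 1000,
                     noise_sd = 0, seed = NULL) {
  stopifnot(efficiency > 0, efficiency < 1, noise_sd >= 0)
  draw <- function() {
    i668 <- efficiency * total_intensity +
      stats::rnorm(n, 0, noise_sd)
    i564 <- (1 - efficiency) * total_intensity +
      stats::rnorm(n, 0, noise_sd)
    data.frame(i_564 = pmax(i564, 0), i_668 = pmax(i668, 0))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  attr(out, "truth") <- efficiency
  out
}

# Smooth reference GLD-1-like shape: low in the distal-most (stem cell)
# region, rising to a peak near the meiotic entry position, in arbitrary
# intensity units on a 0-100 um axis.
.profile_shape <- function(x, rise_mid = 45, rise_rate = 0.12,
                           amplitude = 100, baseline = 5) {
  baseline + amplitude / (1 + exp(-rise_rate * (x - rise_mid)))
}

#' Simulate per-gonad intensity profiles
#'
#' Wild-type gonads follow a logistic rise from a low distal baseline;
#' mutant genotypes add a constant distal offset (`distal_shift`, as a
#' fraction of the wild-type amplitude over 0-40 um, decaying linearly to
#' zero at 60 um), emulating de-repression in the stem cell region.
#' Multiplicative per-gonad scale and additive Gaussian noise are applied.
#'
#' @param genotypes Character vector of genotype labels; the first is
#'   treated as wild type.
#' @param n_gonads Gonads per genotype.
#' @param distal_shift Fractional distal offset for every non-wild-type
#'   genotype (default 0.5).
#' @param positions Measurement positions in um (default 0:100).
#' @param noise_sd Additive noise SD as a fraction of the wild-type
#'   amplitude (default 0.1).
#' @param scale_sd SD of the per-gonad lognormal scale factor (default
#'   0.05).
#' @param seed Integer seed (required).
#' @return Long-format data.frame (`gonad_id`, `genotype`, `position_um`,
#'   `intensity`) with a `truth` attribute describing the generating
#'   shape.
#' @export
gen_profiles <- function(genotypes = c("wild_type", "fbe_mutant"),
                         n_gonads = 10L, distal_shift = 0.5,
                         positions = 0:100, noise_sd = 0.1,
                         scale_sd = 0.05, seed) {
  stopifnot(!missing(seed), n_gonads >= 2L, noise_sd >= 0, scale_sd >= 0)
  amplitude <- 100
  with_seed(seed, {
    rows <- list()
    for (g in seq_along(genotypes)) {
      shift <- if (g == 1L) 0 else distal_shift * amplitude
      for (k in seq_len(n_gonads)) {
        base <- .profile_shape(positions, amplitude = amplitude)
        taper <- pmax(pmin((60 - positions) / 20, 1), 0)
        mu <- base + shift * taper
        scale <- stats::rlnorm(1, 0, scale_sd)
        y <- pmax(scale * mu +
                    stats::rnorm(length(positions), 0,
                                 noise_sd * amplitude), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          gonad_id = sprintf("%s_g%02d", genotypes[g], k),
          genotype = genotypes[g], position_um = positions,
          intensity = y, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(amplitude = amplitude,
                               distal_shift = distal_shift,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}
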