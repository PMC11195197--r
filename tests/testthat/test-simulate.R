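test_that("background generation is compositional and reproducible", {
  expect_identical(gen_background(0), "")
  expect_identical(gen_background(25, seed = 4), gen_background(25, seed = 4))
  expect_false(gen_background(25, seed = 4) == gen_background(25, seed = 5))
  expect_error(gen_background(10, composition = c(A = 1, C = 0, G = 0)),
               "composition")

  seq <- gen_background(40000, seed = 9)
  counts <- table(strsplit(seq, "")[[1]])
  p <- 0.25; n <- 40000
  band <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < band))

  # U-rich preset shifts the composition as configured
  seq_u <- gen_background(40000, composition = utr3_composition(), seed = 9)
  freq_u <- mean(strsplit(seq_u, "")[[1]] == "U")
  expect_lt(abs(freq_u - 0.40), 0.01)
})

test_that("realized elements always match their own class", {
  pats <- fbe_patterns()
  set.seed(21)
  for (nm in names(pats)) {
    for (i in 1:25) {
      el <- realize_element(nm)
      expect_equal(match_positions(el, pats[[nm]])$start, 1L,
                   info = paste(nm, el))
      expect_equal(nchar(el), pats[[nm]]$length)
    }
  }
  # the gld-1 FBEa core is itself a valid canonical draw
  expect_equal(match_positions("UGUGCCAUA", pats$FBE9)$start, 1L)
  expect_identical(realize_element("FBE9", seed = 3),
                   realize_element("FBE9", seed = 3))
})

test_that("planted pairs reproduce the requested geometry exactly", {
  bg <- strrep("C", 60)
  pl <- plant_pair(bg, "UGUGCCAUA", "UGUUGCCAUU", gap = 5, offset = 5)
  expect_equal(nchar(pl$sequence), 60L)
  expect_equal(element_gap(pl$up_start, pl$up_length, pl$down_start), 5L)
  got <- scan_peak(pl$sequence)$pairs
  expect_equal(nrow(got), 1L)
  expect_equal(got$gap, 5L)
  expect_equal(got$up_start, pl$up_start)
  expect_equal(got$down_start, pl$down_start)

  # boundary gaps: 0 yields no qualifying pair, 20 does
  p0 <- plant_pair(bg, "UGUGCCAUA", "UGUGCCAUA", gap = 0, offset = 5)
  expect_equal(nrow(scan_peak(p0$sequence)$pairs), 0L)
  p20 <- plant_pair(bg, "UGUGCCAUA", "UGUGCCAUA", gap = 20, offset = 5)
  expect_equal(scan_peak(p20$sequence)$pairs$gap, 20L)

  expect_error(plant_pair(strrep("C", 20), "UGUGCCAUA", "UGUGCCAUA",
                          gap = 5, offset = 5), "do not fit")
})

test_that("analytic match probabilities are exact products of symbol masses", {
  expect_equal(expected_match_probability(fbe_pattern("anchor", "UGU")),
               0.25^3)
  expect_equal(expected_match_probability("FBE9"), 2^-11)
  expect_equal(expected_match_probability("ASTAR10"),
               0.25^3 * 1 * 0.5 * 1 * 1 * 0.25 * 0.25 * 1)
  # composition-weighted: A-free background can never host an FBE
  expect_equal(expected_match_probability(
    "FBE9", c(A = 0, C = 0.5, G = 0.25, U = 0.25)), 0)

  # Monte Carlo verification of the per-offset probability
  set.seed(17)
  n <- 2e5
  mers <- vapply(seq_len(n), function(i) random_rna(9), character(1))
  hit <- vapply(mers, function(s) {
    length(oracle_match_starts(s, "UGURnnAUn")) > 0
  }, logical(1))
  p <- 2^-11
  expect_lt(abs(mean(hit) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("false-positive rate on element-free peaks matches the analytic value", {
  set.seed(88)
  L <- 80L
  n_seq <- 1000L
  p_any <- sum(vapply(fbe_patterns(), function(pat) {
    (L - pat$length + 1) * expected_match_probability(pat)
  }, numeric(1)))
  # expected matches per sequence summed over classes; compare total count
  total <- 0L
  for (i in seq_len(n_seq)) total <- total + nrow(scan_all(random_rna(L)))
  # Poisson-style 99% band around the analytic mean count
  mu <- n_seq * p_any
  expect_gt(total, qpois(0.005, mu))
  expect_lt(total, qpois(0.995, mu))
})

test_that("generated peak sets are pure functions of spec and seed", {
  spec <- peak_sim_spec(n_planted = 15L, n_background = 15L)
  a <- gen_peakset(spec, seed = 7L)
  b <- gen_peakset(spec, seed = 7L)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$peaks, b$peaks)
  c <- gen_peakset(spec, seed = 8L)
  expect_false(identical(a$sequences, c$sequences))

  empty <- gen_peakset(peak_sim_spec(n_planted = 0L, n_background = 0L),
                       seed = 1L)
  expect_equal(length(empty$sequences), 0L)
  expect_equal(nrow(empty$peaks), 0L)
})

test_that("ground-truth coordinates are re-detected by the scanner", {
  spec <- peak_sim_spec(n_planted = 40L, n_background = 0L,
                        peak_length = 80L)
  sim <- gen_peakset(spec, seed = 55L)
  scan <- scan_peaks(sim$peaks, sim$sequences)
  expect_true(all(scan$peaks$has_pair))
  truth <- sim$truth$planted
  for (k in seq_len(nrow(truth))) {
    pk <- scan$pairs[scan$pairs$peak_id == truth$peak_id[k], ]
    found <- any(pk$up_start == truth$up_start[k] &
                   pk$down_start == truth$down_start[k] &
                   pk$gap == truth$gap[k])
    expect_true(found, info = truth$peak_id[k])
  }
})

test_that("height effect calibration: null is uniform, effect is detected", {
  # multiplier 1: planted and background heights indistinguishable
  null_p <- vapply(1:200, function(s) {
    sim <- gen_peakset(peak_sim_spec(n_planted = 40L, n_background = 40L,
                                     peak_length = 40L,
                                     adjacent_multiplier = 1),
                       seed = 30000L + s)
    pooled_t_test(sim$peaks$height_wt[sim$peaks$planted],
                  sim$peaks$height_wt[!sim$peaks$planted])$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)

  # multiplier 4 at n = 500/500: essentially always detected at 0.001
  hits <- vapply(1:100, function(s) {
    sim <- gen_peakset(peak_sim_spec(n_planted = 500L, n_background = 500L,
                                     peak_length = 40L, fpkm_logsd = 1,
                                     adjacent_multiplier = 4),
                       seed = 40000L + s)
    pooled_t_test(sim$peaks$height_wt[sim$peaks$planted],
                  sim$peaks$height_wt[!sim$peaks$planted])$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("measurement simulators are exact at zero noise and seeded", {
  ser <- titration_series(20e-6, 300e-6)
  truth <- binding_params(0.5, 1.1e-6, -61.9)
  sim0 <- gen_itc(truth, ser)
  expect_equal(sim0$heats, one_site_heats(truth, ser))
  expect_identical(gen_itc(truth, ser, noise_sd = 1, seed = 2)$heats,
                   gen_itc(truth, ser, noise_sd = 1, seed = 2)$heats)
  expect_error(gen_itc(truth, ser, noise_sd = -1))

  curve <- gen_emsa(0.9, 131e-9)
  expect_equal(curve$fraction_bound,
               one_site_specific(0.9, 131e-9, curve$protein_conc))
  fit <- fit_emsa(curve)
  expect_lt(abs(fit$kd / 131e-9 - 1), 0.01)

  fr <- gen_fret(0.25, n = 5L)
  expect_equal(fret_efficiency(fr$i_564, fr$i_668), rep(0.25, 5))

  prof <- gen_profiles(seed = 42L)
  expect_identical(prof, gen_profiles(seed = 42L))
  expect_setequal(unique(prof$genotype), c("wild_type", "fbe_mutant"))
})
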