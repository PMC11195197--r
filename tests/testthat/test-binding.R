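# Titration schedule used throughout: 19 x 2-uL injections of 300 uM
# titrant into a 200-uL cell of 20 uM macromolecule.
std_series <- function() {
  titration_series(cell_conc0 = 20e-6, syringe_conc = 300e-6)
}

test_that("one-site heats vanish without enthalpy or binding", {
  ser <- std_series()
  zero_dh <- one_site_heats(binding_params(0.5, 1e-6, 0), ser)
  expect_equal(zero_dh, rep(0, 19))
  weak <- one_site_heats(binding_params(0.5, 10, -60), ser)  # Kd 10 M
  expect_lt(max(abs(weak)), 1e-3 *
              max(abs(one_site_heats(binding_params(0.5, 1e-6, -60), ser))))
})

test_that("closed-form isotherm agrees with a numeric equilibrium solver", {
  # independent oracle: solve free-titrant mass action per injection with
  # uniroot, then accumulate cell heat content directly
  params <- binding_params(0.5, 1.1e-6, -61.9)
  ser <- std_series()
  v <- cumsum(ser$injection_volumes) / ser$cell_volume
  Mt <- ser$cell_conc0 * (1 - v / 2) / (1 + v / 2)
  Xt <- ser$syringe_conc * v / (1 + v / 2)
  Q_oracle <- vapply(seq_along(v), function(i) {
    free <- uniroot(function(x) {
      x + params$n_sites * Mt[i] * x / (params$kd + x) - Xt[i]
    }, c(0, Xt[i]), tol = 1e-15)$root
    bound <- Xt[i] - free
    bound * params$delta_h * 1000 * ser$cell_volume * 1e6  # uJ
  }, numeric(1))
  dQ <- one_site_heats(params, ser)
  Qprev <- c(0, Q_oracle[-length(Q_oracle)])
  dQ_oracle <- Q_oracle - Qprev +
    (ser$injection_volumes / ser$cell_volume) * (Q_oracle + Qprev) / 2
  expect_equal(dQ, dQ_oracle, tolerance = 1e-8)
})

test_that("bound titrant never exceeds the mass-conservation bound", {
  ser <- std_series()
  for (params in list(binding_params(0.5, 1.1e-6, -61.9),
                      binding_params(0.46, 0.48e-6, -139),
                      binding_params(2, 20e-6, -30))) {
    dQ <- one_site_heats(params, ser)             # uJ
    # exact inversion of the half-displaced-volume correction:
    # dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2
    Q <- numeric(length(dQ))
    qprev <- 0
    for (i in seq_along(dQ)) {
      w <- ser$injection_volumes[i] / (2 * ser$cell_volume)
      Q[i] <- (dQ[i] + qprev * (1 - w)) / (1 + w)
      qprev <- Q[i]
    }
    v <- cumsum(ser$injection_volumes) / ser$cell_volume
    Mt <- ser$cell_conc0 * (1 - v / 2) / (1 + v / 2)
    Xt <- ser$syringe_conc * v / (1 + v / 2)
    bound <- abs(Q * 1e-6 / (params$delta_h * 1000 * ser$cell_volume))
    cap <- pmin(Xt, params$n_sites * Mt)
    expect_true(all(bound <= cap * 1.02))
  }
})

test_that("noise-free titration fits recover generating parameters", {
  ser <- std_series()
  grid <- expand.grid(N = c(0.3, 0.5, 1, 2), kd = c(0.1, 1, 10, 50) * 1e-6)
  for (k in seq_len(nrow(grid))) {
    truth <- binding_params(grid$N[k], grid$kd[k], -60)
    fit <- fit_itc(gen_itc(truth, ser))
    expect_true(fit$converged, info = paste("grid row", k))
    expect_lt(abs(fit$params$n_sites / truth$n_sites - 1), 0.01)
    expect_lt(abs(fit$params$kd / truth$kd - 1), 0.01)
    expect_lt(abs(fit$params$delta_h / truth$delta_h - 1), 0.01)
  }
})

test_that("printed stoichiometries are recovered from synthetic titrations", {
  ser <- std_series()
  fit1 <- fit_itc(gen_itc(binding_params(0.50, 1.1e-6, -61.9), ser))
  expect_lt(abs(fit1$params$n_sites / 0.50 - 1), 0.01)
  fit5 <- fit_itc(gen_itc(binding_params(0.46, 0.48e-6, -139), ser))
  expect_lt(abs(fit5$params$n_sites / 0.46 - 1), 0.01)
})

test_that("titration fits tolerate measurement noise", {
  # schedule designed so equivalence falls mid-titration for N = 0.5:
  # 150 uM titrant into a 30 uM cell reaches 1.9x equivalence by the end
  ser <- titration_series(cell_conc0 = 30e-6, syringe_conc = 150e-6)
  truth <- binding_params(0.5, 1.1e-6, -61.9)
  scale <- max(abs(one_site_heats(truth, ser)))
  err <- vapply(1:200, function(s) {
    sim <- gen_itc(truth, ser, noise_sd = 0.02 * scale, seed = s)
    fit <- fit_itc(sim)
    if (!fit$converged) return(NA_real_)
    abs(fit$params$kd / truth$kd - 1)
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 0.10)
  expect_lt(mean(is.na(err)), 0.05)
})

test_that("degenerate titrations are flagged instead of fitted", {
  ser <- std_series()
  ser$heats <- rep(0, 19)
  fit <- fit_itc(ser)
  expect_false(fit$converged)
  expect_null(fit$params)
  expect_error(fit_itc(titration_series(20e-6, 300e-6,
                                        injection_volumes = rep(2e-6, 5),
                                        heats = rep(1, 5))),
               "at least 6")
})

test_that("free energy and entropy conversions reproduce the printed table", {
  expect_equal(round(delta_g(1.1e-6), 1), -33.4)
  expect_equal(delta_g(1), 0)
  # line 6: direct evaluation from the printed Kd (itself rounded to two
  # digits) gives -38.64; agreement is bounded by the propagated Kd
  # rounding (RT * 0.005/0.13 ~ 0.09) plus the dG print rounding
  expect_lt(abs(delta_g(0.13e-6) - (-38.7)), 0.15)
  # -TdS = dG - dH for every replicate, within the printed rounding of
  # the three columns involved
  tol <- half_ulp(TABLE1$mtds) + half_ulp(TABLE1$dg) + half_ulp(TABLE1$dh)
  expect_true(all(abs(minus_t_delta_s(TABLE1$dg, TABLE1$dh) -
                        TABLE1$mtds) <= tol))
  # and the printed dG column itself follows from the printed Kd at 20 C
  dg_from_kd <- delta_g(TABLE1$kd_um * 1e-6)
  expect_true(all(abs(dg_from_kd - TABLE1$dg) <= 0.1 + half_ulp(TABLE1$dg)))
  expect_equal(minus_t_delta_s(-33.4, -61.9), 28.5)
  expect_equal(minus_t_delta_s(-7, -7), 0)
})

test_that("fraction bound and the specific binding curve behave", {
  expect_equal(fraction_bound(0, 10), 0)
  expect_equal(fraction_bound(10, 0), 1)
  expect_equal(fraction_bound(30, 70), 0.3)
  expect_error(fraction_bound(0, 0), "both zero")
  expect_equal(one_site_specific(0.9, 1e-7, 0), 0)
  expect_equal(one_site_specific(0.9, 1e-7, 1e-7), 0.45)
  expect_lt(abs(one_site_specific(0.9, 1e-7, 1e-2) - 0.9), 1e-5)
})

test_that("noise-free EMSA fits recover the printed affinities", {
  for (kd_nm in c(435, 131, 80, 1190)) {
    curve <- gen_emsa(0.95, kd_nm * 1e-9)
    fit <- fit_emsa(curve)
    expect_true(fit$converged)
    expect_lt(abs(fit$kd / (kd_nm * 1e-9) - 1), 0.01)
    expect_lt(abs(fit$bmax / 0.95 - 1), 0.01)
  }
  # depletion-corrected variant agrees under trace-RNA conditions
  fit_exact <- fit_emsa(gen_emsa(0.95, 131e-9), exact = TRUE)
  expect_lt(abs(fit_exact$kd / 131e-9 - 1), 0.05)
})

test_that("EMSA fits tolerate noise and flag out-of-range affinities", {
  err <- vapply(1:200, function(s) {
    fit <- fit_emsa(gen_emsa(0.95, 435e-9, noise_sd = 0.05, seed = s))
    if (!fit$converged) return(NA_real_)
    abs(fit$kd / 435e-9 - 1)
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 0.10)

  # affinity above the highest tested concentration reported as a bound
  weak <- fit_emsa(gen_emsa(0.95, 8e-6))
  expect_true(weak$censored)
  expect_equal(weak$kd_bound, 5e-6)

  flat <- emsa_curve(5e-6 / 2^(11:0), rep(0, 12))
  expect_false(fit_emsa(flat)$converged)
})

test_that("replicate Kd summaries report mean and SEM", {
  rs <- replicate_summary(c(100, 110, 120))
  expect_equal(rs$mean, 110)
  expect_equal(rs$sem, 10 / sqrt(3))
  expect_equal(rs$n, 3L)
})

test_that("FRET efficiency is the acceptor fraction of total emission", {
  expect_equal(fret_efficiency(100, 100), 0.5)
  expect_equal(fret_efficiency(100, 0), 0)
  expect_equal(fret_efficiency(i_564 = 300, i_668 = 100), 0.25)
  expect_error(fret_efficiency(0, 0), "both zero")
})

test_that("affinity fold changes reproduce the printed comparisons", {
  # RBD+CT on the element pair: without vs with the partner peptide
  expect_equal(round(fold_change(435, 109)), 4)
  # RBD on the single noncanonical element vs the canonical one
  expect_equal(round(fold_change(427, 70), 1), 6.1)
  expect_equal(fold_change(3, 3), 1)
})
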