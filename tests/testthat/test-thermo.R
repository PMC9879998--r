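test_that("Gibbs-Helmholtz vanishes at the midpoint and matches hand arithmetic", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      st <- thermo_state("x", t_m = runif(1, 40, 110), dh_m = runif(1, 20, 90),
                        dcp = runif(1, 0, 1.5))
      expect_lt(abs(gibbs_helmholtz(kelvin_to_celsius(st$t_m_K), st)), 1e-9)
    }
  })
  # dCp = 0, dH_m = 50, T_m = 338.15 K, T = 298.15 K:
  # dG_unf = 50 * (1 - 298.15/338.15) = +5.9146 kcal/mol
  st <- thermo_state("x", t_m = 65, dh_m = 50, dcp = 0)
  expect_equal(-gibbs_helmholtz(25, st), 50 * (1 - 298.15 / 338.15),
               tolerance = 1e-12)
  # positive dCp bends the stability curve: a maximum below T_m
  st2 <- thermo_state("x", t_m = 65, dh_m = 50, dcp = 1)
  t_grid <- seq(-20, 64, by = 0.5)
  dg_unf <- -gibbs_helmholtz(t_grid, st2)
  peak <- t_grid[which.max(dg_unf)]
  expect_lt(peak, 65)
  expect_gt(dg_unf[which.max(dg_unf)], -gibbs_helmholtz(64.9, st2))
  expect_error(gibbs_helmholtz(-300, st), class = "foldswitch_domain_error")
})

test_that("switch free energy is the short-minus-long linkage difference", {
  expect_equal(switch_free_energy(-4.0, -5.3), 1.3)
  expect_equal(switch_free_energy(-1.2, -3.5), 2.3)
  withr::with_seed(4, {
    for (rep in 1:20) {
      a <- runif(1, -10, 2)
      b <- runif(1, -10, 2)
      expect_equal(switch_free_energy(a, b), -switch_free_energy(b, a))
      expect_equal(switch_free_energy(a, a), 0)
    }
  })
  expect_error(switch_free_energy(NA, -1), class = "foldswitch_domain_error")
})

test_that("three-state populations follow Boltzmann weights and sum to one", {
  # direct-weight oracle
  oracle_pops <- function(dg_long, dg_switch, t_c) {
    rt <- 1.9872e-3 * (t_c + 273.15)
    ks <- exp(-dg_long / rt)
    kg <- exp(-(dg_long + dg_switch) / rt)
    fu <- 1 / (1 + ks + kg)
    c(f_S = ks * fu, f_G = kg * fu, f_U = fu)
  }
  p <- three_state_populations(-5.3, 1.3, 25)
  o <- oracle_pops(-5.3, 1.3, 25)
  expect_equal(c(p$f_S, p$f_G, p$f_U), unname(o), tolerance = 1e-12)
  expect_equal(round(p$f_S, 3), 0.900)
  expect_equal(round(p$f_G, 3), 0.100)
  expect_lt(p$f_U, 2e-4)
  # dg_switch = 0 gives an equal folded mixture to machine precision
  p0 <- three_state_populations(-3.5, 0, 25)
  expect_identical(p0$f_S, p0$f_G)
  # fully degenerate case: thirds
  p3 <- three_state_populations(0, 0, 25)
  expect_equal(c(p3$f_S, p3$f_G, p3$f_U), rep(1 / 3, 3), tolerance = 1e-12)
  # log-sum-exp form agrees with the naive form wherever finite, sums to 1,
  # and extreme stabilities stay finite
  withr::with_seed(8, {
    for (rep in 1:25) {
      dgl <- runif(1, -12, 6)
      dgs <- runif(1, -8, 8)
      t_c <- runif(1, 1, 99)
      pp <- three_state_populations(dgl, dgs, t_c)
      expect_equal(pp$f_S + pp$f_G + pp$f_U, 1, tolerance = 1e-9)
      expect_true(all(c(pp$f_S, pp$f_G, pp$f_U) >= 0 &
                        c(pp$f_S, pp$f_G, pp$f_U) <= 1))
      expect_equal(unname(oracle_pops(dgl, dgs, t_c)),
                   c(pp$f_S, pp$f_G, pp$f_U), tolerance = 1e-9)
    }
  })
  pe <- three_state_populations(-400, 10, 25)
  expect_true(all(is.finite(c(pe$f_S, pe$f_G, pe$f_U))))
  # monotone: raising dg_switch at fixed dg_long depletes the embedded fold
  ratios <- vapply(seq(-3, 3, by = 0.5), function(s) {
    pp <- three_state_populations(-4, s, 25)
    pp$f_G / pp$f_S
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("population-inferred switch free energy inverts the forward map", {
  expect_equal(switch_from_populations(0.45, 0.45, 25), 0)
  p <- three_state_populations(-3.5, 1.7, 25)
  expect_equal(switch_from_populations(p$f_S, p$f_G, 25), 1.7,
               tolerance = 1e-9)
})

test_that("simulated melts obey the two-state closed form", {
  st <- thermo_state("x", t_m = 65, dh_m = 45, dcp = 0.014 * 56)
  bl <- melt_baselines()
  # at T_m the signal is the baseline midpoint (K_unf = 1)
  mid <- simulate_melt(st, bl, t_grid = c(20, 65, 100))
  th_n <- bl$folded_intercept + bl$folded_slope * 65
  th_u <- bl$unfolded_intercept + bl$unfolded_slope * 65
  expect_equal(mid$mre[2], (th_n + th_u) / 2, tolerance = 1e-9)
  # far above T_m the curve rides the unfolded baseline
  hot <- simulate_melt(st, bl, t_grid = c(99, 99.5, 100))
  expect_equal(hot$mre,
               bl$unfolded_intercept + bl$unfolded_slope * hot$temperature_C,
               tolerance = 1e-2)
  # determinism: same seed gives identical curves, noiseless is exact
  c1 <- simulate_melt(st, bl, noise_sd = 300, seed = 42)
  c2 <- simulate_melt(st, bl, noise_sd = 300, seed = 42)
  expect_identical(c1$mre, c2$mre)
  expect_error(simulate_melt(st, bl, t_grid = c(30, 20)),
               class = "foldswitch_domain_error")
})

test_that("melt fitting recovers simulation parameters exactly without noise", {
  curve <- simulate_melt_preset(t_m = 65, dh_m = 45, n_residues = 56,
                                noise_frac = 0)
  fit <- fit_melt(curve, dcp = 0.014 * 56, name = "roundtrip")
  expect_lt(abs(kelvin_to_celsius(fit$state$t_m_K) - 65), 0.01)
  expect_lt(abs(fit$state$dh_m - 45), 0.01)
  # derived free energy matches the generating state
  truth <- thermo_state("truth", 65, 45, 0.014 * 56)
  expect_equal(fit$state$dg_ref, truth$dg_ref, tolerance = 1e-3)
  # per-residue policy resolves to the same fixed value
  fit2 <- fit_melt(curve, dcp = "per_residue", n_residues = 56)
  expect_equal(fit2$state$dcp, 0.014 * 56)
  expect_match(fit2$dcp_policy, "per_residue")
  # borrowed unfolded baseline (low-stability reference construct strategy)
  bl <- melt_baselines()
  fit3 <- fit_melt(curve, dcp = 0.014 * 56,
                   fixed_unfolded_baseline = c(bl$unfolded_intercept,
                                               bl$unfolded_slope))
  expect_lt(abs(kelvin_to_celsius(fit3$state$t_m_K) - 65), 0.01)
})

test_that("fit bias shrinks as melt noise decreases", {
  errs <- vapply(c(0.04, 0.01, 0.0025), function(nf) {
    e <- vapply(1:8, function(s) {
      cv <- simulate_melt_preset(65, 45, 56, noise_frac = nf, seed = s)
      f <- suppressWarnings(fit_melt(cv, dcp = 0.014 * 56))
      abs(kelvin_to_celsius(f$state$t_m_K) - 65)
    }, numeric(1))
    median(e)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("degenerate melts are flagged instead of silently fitted", {
  # flat curve: no transition
  flat <- tibble::tibble(temperature_C = seq(20, 100, 2),
                         mre = rnorm(41, -5000, 5))
  expect_error(fit_melt(flat, dcp = 0.5), class = "foldswitch_fit_error")
  # transition far outside the scanned range: flagged by warning or fit error
  st_hot <- thermo_state("hot", t_m = 140, dh_m = 60, dcp = 0.5)
  hot <- simulate_melt(st_hot, t_grid = seq(20, 100, 0.5), noise_sd = 120,
                       seed = 2)
  flagged <- FALSE
  res <- tryCatch(
    withCallingHandlers(
      fit_melt(hot, dcp = 0.5),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    foldswitch_fit_error = function(e) "fit_error"
  )
  expect_true(flagged || identical(res, "fit_error"))
  # biphasic melt (two transitions) leaves systematic residuals
  s1 <- thermo_state("a", t_m = 10, dh_m = 40, dcp = 0)
  s2 <- thermo_state("b", t_m = 60, dh_m = 50, dcp = 0)
  grid <- seq(0, 100, 0.5)
  bl <- melt_baselines()
  mix <- simulate_melt(s1, bl, grid)$mre * 0.5 +
    simulate_melt(s2, bl, grid)$mre * 0.5
  biph <- tibble::tibble(temperature_C = grid, mre = mix)
  w <- capture_warnings(fit_melt(biph, dcp = 0.5))
  expect_true(any(grepl("autocorrelation|misfit|poorly resolved", w)))
})

test_that("melting-curve files and tidiers round-trip", {
  curve <- simulate_melt_preset(noise_frac = 0.02, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_melting_curve(curve, path)
  back <- read_melting_curve(path)
  expect_equal(back$temperature_C, curve$temperature_C)
  expect_equal(back$mre, curve$mre, tolerance = 1e-9)
  fit <- suppressWarnings(fit_melt(curve, dcp = 0.014 * 56))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("t_m_C" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(curve))
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$mre, tolerance = 1e-9)
})
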