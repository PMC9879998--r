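#' Two-state stability parameters of one construct
#'
#' Temperatures are given in degrees Celsius at every interface and stored in
#' Kelvin internally; free energies are kcal/mol with the folding sign
#' convention (negative = folded stable).
#'
#' @param name Construct name.
#' @param t_m Melting midpoint (deg C).
#' @param dh_m van 't Hoff enthalpy of unfolding at `t_m` (kcal/mol, > 0 for
#'   cooperative unfolding).
#' @param dcp Heat-capacity change of unfolding (kcal/mol/K, >= 0).
#' @param t_ref Reference temperature for `dg_ref` (deg C, default 25).
#' @return An object of class `thermo_state` with fields `t_m_K`, `dh_m`,
#'   `dcp`, `t_ref_K` and `dg_ref` (the folding free energy at `t_ref`,
#'   consistent with the Gibbs-Helmholtz relation).
#' @export
#' @examples
#' thermo_state("A1", t_m = 65, dh_m = 45, dcp = 0.014 * 56)
thermo_state <- function(name, t_m, dh_m, dcp = 0, t_ref = 25) {
  t_m_K <- celsius_to_kelvin(t_m)
  if (t_m_K <= 0) abort_domain("T_m must be above absolute zero")
  if (dh_m <= 0) abort_domain("dH_m must be positive for cooperative unfolding")
  state <- structure(
    list(name = name, t_m_K = t_m_K, dh_m = dh_m, dcp = dcp,
         t_ref_K = celsius_to_kelvin(t_ref), dg_ref = NA_real_),
    class = "thermo_state"
  )
  state$dg_ref <- gibbs_helmholtz(t_ref, state)
  state
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf(
    "<thermo_state> %s: T_m %.1f degC, dH_m %.1f kcal/mol, dCp %.3f kcal/mol/K, dG_folding(%.0f degC) %.2f kcal/mol\n",
    x$name, kelvin_to_celsius(x$t_m_K), x$dh_m, x$dcp,
    kelvin_to_celsius(x$t_ref_K), x$dg_ref
  ))
  invisible(x)
}

#' Gibbs-Helmholtz folding free energy
#'
#' `dG_unf(T) = dH_m (1 - T/T_m) - dCp [(T_m - T) + T log(T/T_m)]`; the
#' returned value is the folding free energy `-dG_unf(T)`, negative when the
#' fold is stable.  At `T = T_m` the result is exactly zero.
#'
#' @param t Temperature(s) in deg C (vectorised).
#' @param state A [thermo_state()].
#' @return Folding free energy in kcal/mol.
#' @export
#' @examples
#' s <- thermo_state("x", t_m = 65, dh_m = 50)
#' gibbs_helmholtz(65, s)  # 0 at the midpoint
gibbs_helmholtz <- function(t, state) {
  t_K <- celsius_to_kelvin(t)
  if (any(t_K <= 0)) abort_domain("temperature must be above absolute zero")
  dg_unf <- state$dh_m * (1 - t_K / state$t_m_K) -
    state$dcp * ((state$t_m_K - t_K) + t_K * log(t_K / state$t_m_K))
  -dg_unf
}

#' Fold-switch free energy from the linkage of short and long constructs
#'
#' Because the two folded states and the unfolded state are thermodynamically
#' linked, the free energy of switching the long construct from its own fold
#' to the embedded fold is approximated by the difference of folding free
#' energies of the short and long constructs:
#' `dG_switch = dG_short - dG_long` (positive = long fold favoured).
#'
#' @param dg_short,dg_long Folding free energies (kcal/mol) of the short and
#'   long constructs at a common temperature.
#' @return `dG_switch` in kcal/mol.
#' @export
#' @examples
#' switch_free_energy(-4.0, -5.3)  # +1.3
#' switch_free_energy(-1.2, -3.5)  # +2.3
switch_free_energy <- function(dg_short, dg_long) {
  if (!all(is.finite(c(dg_short, dg_long)))) {
    abort_domain("free energies must be finite")
  }
  dg_short - dg_long
}

#' Three-state populations of a switchable construct
#'
#' States: long fold (S), embedded fold (G) and unfolded (U).  With
#' `K_S = exp(-dG_long / RT)` and `K_G = exp(-(dG_long + dG_switch) / RT)`,
#' `f_U = 1 / (1 + K_S + K_G)`, `f_S = K_S f_U`, `f_G = K_G f_U`, computed in
#' log space so extreme stabilities cannot overflow.
#'
#' @param dg_long Folding free energy of the long construct (kcal/mol).
#' @param dg_switch Fold-switch free energy (kcal/mol).
#' @param t Temperature in deg C (default 25).
#' @return One-row tibble of class `switch_equilibrium`: `dg_long`,
#'   `dg_switch`, `temperature_C`, `f_S`, `f_G`, `f_U` (summing to 1).
#' @export
#' @examples
#' three_state_populations(-3.5, 0)      # f_S == f_G
#' three_state_populations(-5.3, 1.3)
three_state_populations <- function(dg_long, dg_switch, t = 25) {
  t_K <- celsius_to_kelvin(t)
  if (t_K <= 0) abort_domain("temperature must be above absolute zero")
  rt <- R_KCAL * t_K
  logw <- c(U = 0, S = -dg_long / rt, G = -(dg_long + dg_switch) / rt)
  lz <- logsumexp(logw)
  f <- exp(logw - lz)
  out <- tibble::tibble(
    dg_long = dg_long, dg_switch = dg_switch, temperature_C = t,
    f_S = unname(f["S"]), f_G = unname(f["G"]), f_U = unname(f["U"])
  )
  class(out) <- c("switch_equilibrium", class(out))
  out
}

#' Infer the switch free energy from observed state populations
#'
#' Inverse of the population relation: `dG_switch = -RT log(f_G / f_S)`.
#' Equal populations of the two folded states imply `dG_switch = 0`.
#'
#' @param f_S,f_G Populations of the long-fold and embedded-fold states.
#' @param t Temperature in deg C (default 25).
#' @return `dG_switch` in kcal/mol.
#' @export
#' @examples
#' switch_from_populations(0.45, 0.45)  # 0
switch_from_populations <- function(f_S, f_G, t = 25) {
  if (f_S <= 0 || f_G <= 0) abort_domain("populations must be positive")
  -R_KCAL * celsius_to_kelvin(t) * log(f_G / f_S)
}

#' Linear CD baselines for melt simulation
#'
#' Mean residue ellipticity baselines of the folded and unfolded states,
#' each linear in temperature (deg C).  Defaults are typical 222 nm values
#' for a small helical protein.
#'
#' @param folded_intercept,folded_slope Folded-state baseline
#'   (deg cm^2 dmol^-1 and per deg C).
#' @param unfolded_intercept,unfolded_slope Unfolded-state baseline.
#' @return A list of class `melt_baselines`.
#' @export
melt_baselines <- function(folded_intercept = -15000, folded_slope = 30,
                           unfolded_intercept = -4000, unfolded_slope = 10) {
  structure(
    list(folded_intercept = folded_intercept, folded_slope = folded_slope,
         unfolded_intercept = unfolded_intercept, unfolded_slope = unfolded_slope),
    class = "melt_baselines"
  )
}

melt_theta <- function(t_c, state, baselines) {
  t_K <- celsius_to_kelvin(t_c)
  dg_unf <- -gibbs_helmholtz(t_c, state)
  k_unf <- exp(-dg_unf / (R_KCAL * t_K))
  th_n <- baselines$folded_intercept + baselines$folded_slope * t_c
  th_u <- baselines$unfolded_intercept + baselines$unfolded_slope * t_c
  (th_n + th_u * k_unf) / (1 + k_unf)
}

#' Simulate a two-state CD melting curve
#'
#' `theta(T) = (theta_N(T) + theta_U(T) K_unf(T)) / (1 + K_unf(T))` with
#' `K_unf = exp(-dG_unf(T)/RT)` and linear baselines; optional additive
#' Gaussian noise.  With `noise_sd = 0` the curve is deterministic; with a
#' seed it is reproducible.
#'
#' @param state A [thermo_state()].
#' @param baselines A [melt_baselines()].
#' @param t_grid Temperature grid in deg C, strictly increasing (default
#'   20-100 in 0.5 deg steps, the usual scan range at 0.5 deg/min).
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   ellipticity).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble of class `melting_curve` with columns `temperature_C`
#'   and `mre` (mean residue ellipticity, deg cm^2 dmol^-1).
#' @export
#' @examples
#' simulate_melt(thermo_state("x", 65, 45), t_grid = seq(20, 100, 5))
simulate_melt <- function(state, baselines = melt_baselines(),
                          t_grid = seq(20, 100, by = 0.5),
                          noise_sd = 0, seed = NULL) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort_domain("temperature grid must be strictly increasing")
  }
  if (noise_sd < 0) abort_domain("noise_sd must be non-negative")
  theta <- melt_theta(t_grid, state, baselines)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(t_grid), 0, noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(t_grid), 0, noise_sd))
    }
    theta <- theta + noise
  }
  out <- tibble::tibble(temperature_C = t_grid, mre = theta)
  class(out) <- c("melting_curve", class(out))
  out
}

#' Read / write a melting curve as two-column delimited text
#'
#' Header required; columns `temperature_C`, `mre_deg_cm2_dmol` (tab- or
#' comma-separated, inferred from the file).
#'
#' @param path File path.
#' @return `read_melting_curve()` returns a `melting_curve` tibble.
#' @export
read_melting_curve <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE)
  if (ncol(df) < 2) abort_format("melting curve file needs two columns")
  out <- tibble::tibble(temperature_C = as.numeric(df[[1]]),
                        mre = as.numeric(df[[2]]))
  class(out) <- c("melting_curve", class(out))
  out
}

#' @rdname read_melting_curve
#' @param curve A `melting_curve` tibble.
#' @export
write_melting_curve <- function(curve, path) {
  utils::write.table(
    data.frame(temperature_C = curve$temperature_C,
               mre_deg_cm2_dmol = curve$mre),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

resolve_dcp <- function(dcp, n_residues, dcp_per_residue) {
  if (is.numeric(dcp)) {
    list(value = dcp, policy = sprintf("fixed:%g", dcp))
  } else if (identical(dcp, "per_residue")) {
    if (is.null(n_residues)) {
      abort_config("dcp = 'per_residue' requires n_residues")
    }
    list(value = dcp_per_residue * n_residues,
         policy = sprintf("per_residue:%d (%.3f kcal/mol/K per residue)",
                          n_residues, dcp_per_residue))
  } else {
    abort_config("dcp must be numeric or 'per_residue'")
  }
}

# Profiled SSE: given (t_m, dh_m) the four baseline parameters are linear and
# solved exactly by least squares.
melt_profile_sse <- function(par, t_c, theta, dcp, fixed_unfolded = NULL) {
  t_m <- par[1]
  dh_m <- exp(par[2])
  state <- list(t_m_K = celsius_to_kelvin(t_m), dh_m = dh_m, dcp = dcp)
  t_K <- celsius_to_kelvin(t_c)
  dg_unf <- dh_m * (1 - t_K / state$t_m_K) -
    dcp * ((state$t_m_K - t_K) + t_K * log(t_K / state$t_m_K))
  k <- exp(pmin(-dg_unf / (R_KCAL * t_K), 500))
  f_u <- k / (1 + k)
  f_n <- 1 - f_u
  y <- theta
  if (is.null(fixed_unfolded)) {
    x <- cbind(f_n, f_n * t_c, f_u, f_u * t_c)
  } else {
    y <- y - f_u * (fixed_unfolded[1] + fixed_unfolded[2] * t_c)
    x <- cbind(f_n, f_n * t_c)
  }
  fit <- stats::lm.fit(x, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  resid <- y - x %*% coefs
  list(sse = sum(resid^2), coefs = coefs, resid = as.numeric(resid),
       f_u = f_u)
}

#' Fit a two-state melting curve
#'
#' Nonlinear least squares for the melting midpoint, van 't Hoff enthalpy and
#' linear folded/unfolded baselines, with the heat-capacity change fixed by
#' policy (a user value, or the common per-residue empirical estimate
#' 0.014 kcal/mol/K per residue).  The fit is multi-started from five
#' midpoint seeds across the grid and is deterministic given the curve and
#' policy.  The folding free energy at the reference temperature is derived
#' from the fitted parameters via the Gibbs-Helmholtz relation.
#'
#' @param curve A `melting_curve` tibble (at least 20 points spanning the
#'   transition).
#' @param dcp Numeric heat-capacity change (kcal/mol/K) or `"per_residue"`.
#' @param n_residues Chain length, required for the per-residue policy.
#' @param dcp_per_residue Per-residue estimate (default 0.014 kcal/mol/K).
#' @param fixed_unfolded_baseline Optional `c(intercept, slope)` borrowed
#'   from a reference curve of a low-stability variant, fixing the
#'   unfolded-state baseline instead of fitting it.
#' @param t_ref Reference temperature for the derived free energy (deg C).
#' @param name Construct name recorded in the fitted state.
#' @return An object of class `melt_fit`: the fitted [thermo_state()],
#'   [melt_baselines()], standard errors, diagnostics (SSE, residual sigma,
#'   convergence, warnings raised) and the recorded dCp policy.  Raises a
#'   fit error for a curve with no resolvable transition; warns when the
#'   midpoint falls outside the grid or residuals are strongly
#'   autocorrelated (systematic misfit, e.g. a biphasic melt).
#' @export
fit_melt <- function(curve, dcp = "per_residue", n_residues = NULL,
                     dcp_per_residue = 0.014,
                     fixed_unfolded_baseline = NULL,
                     t_ref = 25, name = "fit") {
  t_c <- curve$temperature_C
  theta <- curve$mre
  if (length(t_c) < 20) abort_domain("need at least 20 points to fit a melt")
  pol <- resolve_dcp(dcp, n_residues, dcp_per_residue)
  dcp_val <- pol$value
  starts <- stats::quantile(t_c, c(0.15, 0.3, 0.5, 0.7, 0.85), names = FALSE)
  fits <- purrr::map(starts, function(tm0) {
    stats::optim(
      c(tm0, log(50)),
      function(p) melt_profile_sse(p, t_c, theta, dcp_val,
                                   fixed_unfolded_baseline)$sse,
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000)
    )
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  prof <- melt_profile_sse(best$par, t_c, theta, dcp_val,
                           fixed_unfolded_baseline)
  t_m <- best$par[1]
  dh_m <- exp(best$par[2])
  coefs <- prof$coefs
  if (is.null(fixed_unfolded_baseline)) {
    baselines <- melt_baselines(coefs[1], coefs[2], coefs[3], coefs[4])
  } else {
    baselines <- melt_baselines(coefs[1], coefs[2],
                                fixed_unfolded_baseline[1],
                                fixed_unfolded_baseline[2])
  }
  n <- length(t_c)
  n_par <- 2 + if (is.null(fixed_unfolded_baseline)) 4 else 2
  sigma <- sqrt(prof$sse / max(1, n - n_par))
  amplitude <- abs(
    (baselines$folded_intercept + baselines$folded_slope * t_m) -
      (baselines$unfolded_intercept + baselines$unfolded_slope * t_m)
  )
  warnings <- character(0)
  if (amplitude < 2 * sigma || amplitude < 1e-8 * (max(abs(theta)) + 1)) {
    abort_fit(
      "no resolvable unfolding transition (amplitude %.3g vs residual sigma %.3g)",
      amplitude, sigma
    )
  }
  if (amplitude < 5 * sigma) {
    warnings <- c(warnings,
                  "transition poorly resolved relative to residual scatter")
    rlang::warn(warnings[length(warnings)])
  }
  if (t_m < min(t_c) || t_m > max(t_c)) {
    warnings <- c(warnings, "transition midpoint outside temperature grid; T_m poorly determined")
    rlang::warn(warnings[length(warnings)])
  }
  r <- prof$resid
  # autocorrelation is only meaningful when residuals exceed numerical noise
  if (length(r) > 3 && sigma > 1e-6 * amplitude) {
    ac1 <- stats::cor(r[-1], r[-length(r)])
    if (is.finite(ac1) && ac1 > 0.6) {
      warnings <- c(warnings,
                    "strong residual autocorrelation: systematic misfit (biphasic melt or wrong model)")
      rlang::warn(warnings[length(warnings)])
    }
  }
  # asymptotic standard errors of (t_m, dh_m) from the profiled SSE curvature
  se <- tryCatch({
    h <- stats::optimHess(best$par, function(p) {
      melt_profile_sse(p, t_c, theta, dcp_val, fixed_unfolded_baseline)$sse
    })
    cov <- 2 * sigma^2 * solve(h)
    c(t_m = sqrt(abs(cov[1, 1])),
      dh_m = dh_m * sqrt(abs(cov[2, 2])))  # delta method for log-dH
  }, error = function(e) c(t_m = NA_real_, dh_m = NA_real_))
  state <- thermo_state(name, t_m = t_m, dh_m = dh_m, dcp = dcp_val,
                        t_ref = t_ref)
  structure(
    list(
      state = state,
      baselines = baselines,
      se = se,
      dcp_policy = pol$policy,
      curve = curve,
      fitted = theta - r,
      residuals = r,
      diagnostics = list(sse = prof$sse, sigma = sigma, n = n,
                         convergence = best$convergence,
                         warnings = warnings)
    ),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit> %s: T_m %.2f +/- %.2f degC, dH_m %.1f +/- %.1f kcal/mol, dG_folding(%.0f degC) %.2f kcal/mol [dCp %s]\n",
    x$state$name, kelvin_to_celsius(x$state$t_m_K), x$se["t_m"],
    x$state$dh_m, x$se["dh_m"], kelvin_to_celsius(x$state$t_ref_K),
    x$state$dg_ref, x$dcp_policy
  ))
  invisible(x)
}
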