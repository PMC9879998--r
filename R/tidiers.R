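#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted melting curve
#'
#' @param x A [fit_melt()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("t_m_C", "dh_m", "dcp", "dg_folding_ref",
             "folded_intercept", "folded_slope",
             "unfolded_intercept", "unfolded_slope"),
    estimate = c(kelvin_to_celsius(x$state$t_m_K), x$state$dh_m, x$state$dcp,
                 x$state$dg_ref,
                 x$baselines$folded_intercept, x$baselines$folded_slope,
                 x$baselines$unfolded_intercept, x$baselines$unfolded_slope),
    std.error = c(x$se["t_m"], x$se["dh_m"], NA, NA, NA, NA, NA, NA)
  )
}

#' @rdname tidy.melt_fit
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$diagnostics$sse, sigma = x$diagnostics$sigma,
    nobs = x$diagnostics$n, convergence = x$diagnostics$convergence,
    n_warnings = length(x$diagnostics$warnings),
    dcp_policy = x$dcp_policy
  )
}

#' @rdname tidy.melt_fit
#' @method augment melt_fit
#' @export
augment.melt_fit <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$curve),
                .fitted = x$fitted, .resid = x$residuals)
}

#' Tidy a fitted inhibition constant
#'
#' @param x A [fit_ki()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy ki_fit
#' @export
tidy.ki_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_i_nM", "k_i_two_stage_nM", "k_m_uM", "v_max"),
    estimate = c(x$ki, x$ki_two_stage, x$k_m, x$v_max),
    std.error = c(x$ki_se, NA, NA, NA)
  )
}

#' @rdname tidy.ki_fit
#' @method glance ki_fit
#' @export
glance.ki_fit <- function(x, ...) {
  tibble::tibble(
    no_inhibition = x$no_inhibition,
    n_inhibitor_levels = nrow(x$stage1),
    nobs = nrow(x$data)
  )
}
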