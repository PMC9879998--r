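# Gas constant in kcal mol^-1 K^-1, used wherever K = exp(-dG/RT) is formed.
R_KCAL <- 1.9872e-3

celsius_to_kelvin <- function(t_c) t_c + 273.15
kelvin_to_celsius <- function(t_k) t_k - 273.15

abort_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "foldswitch_domain_error")
}

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "foldswitch_format_error")
}

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "foldswitch_config_error")
}

abort_fit <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "foldswitch_fit_error")
}

abort_generation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "foldswitch_generation_error")
}

#' Split an amino acid (or other) string into single characters
#' @noRd
seq_chars <- function(x) {
  if (length(x) != 1L || is.na(x)) abort_domain("expected a single non-NA string")
  strsplit(x, "", fixed = TRUE)[[1]]
}

#' Validate a protein sequence over the 20 standard residues
#' @noRd
check_sequence <- function(sequence, what = "sequence") {
  chars <- seq_chars(sequence)
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort_domain(
      "%s contains nonstandard residue '%s' at position %d",
      what, chars[bad[1]], bad[1]
    )
  }
  invisible(chars)
}

# logsumexp over a numeric vector, overflow-safe
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
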