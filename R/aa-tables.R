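# Residue-level lookup tables used by conflict scoring and the coarse energy.
# All tables cover the 20 standard residues, one-letter code, alphabetical.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Mean residue volumes (A^3), Zamyatnin-style values; used for packing checks.
AA_VOLUME <- c(
  A = 88.6,  C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G = 60.1,  H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S = 89.0,  T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

# Kyte-Doolittle hydropathy; positive = hydrophobic.
AA_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Helix / strand propensities (Chou-Fasman style, dimensionless, >1 favours).
AA_HELIX_PROP <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)

AA_STRAND_PROP <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
  G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
  M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
  S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47
)

# Polar/charged residues that are catastrophic when fully buried.
BURIED_POLAR_SET <- c("D", "E", "K", "R", "N", "Q", "H")

# Default design alphabet: no Cys (disulfides), no Pro (breaker), no Trp/Met/His.
DESIGN_ALPHABET <- c(
  "A", "G", "S", "T", "V", "L", "I", "F", "Y",
  "D", "E", "K", "R", "N", "Q"
)

#' Coarse contact potential between residue types
#'
#' Builds the bundled symmetric 20 x 20 knowledge-based-style contact table
#' used by [coarse_energy()].  Attraction is the product of shifted
#' Kyte-Doolittle hydropathies (so hydrophobic pairs score most favourably,
#' i.e. most negative), with an electrostatic correction: like-charged pairs
#' are penalised and salt bridges rewarded.  Only orderings of these values
#' matter for design decisions; magnitudes are dimensionless.
#'
#' @return A symmetric 20 x 20 numeric matrix with residue one-letter
#'   dimnames; lower values are more favourable.
#' @export
#' @examples
#' p <- contact_potential()
#' p["I", "L"] < p["K", "E"]
contact_potential <- function() {
  h <- (AA_HYDROPATHY + 4.5) / 9  # in [0, 1], 1 = most hydrophobic
  pot <- -outer(h, h)
  positive <- c("K", "R")
  negative <- c("D", "E")
  pot[positive, positive] <- pot[positive, positive] + 0.3
  pot[negative, negative] <- pot[negative, negative] + 0.3
  pot[positive, negative] <- pot[positive, negative] - 0.3
  pot[negative, positive] <- pot[negative, positive] - 0.3
  dimnames(pot) <- list(AA_ALPHABET, AA_ALPHABET)
  pot
}

# Per-burial-class, per-residue term: burying polar residues and exposing
# hydrophobic ones is penalised; boundary positions are neutral.
burial_table <- function() {
  core <- (4.5 - AA_HYDROPATHY) / 3
  surface <- (AA_HYDROPATHY + 4.5) / 6
  boundary <- rep(0, length(AA_ALPHABET))
  names(boundary) <- AA_ALPHABET
  rbind(core = core, boundary = boundary, surface = surface)
}

# Per-element-kind, per-residue secondary structure term (-log propensity).
ss_table <- function() {
  rbind(helix = -log(AA_HELIX_PROP), strand = -log(AA_STRAND_PROP))
}

#' Coarse energy model for dual-fold design
#'
#' Bundles the contact potential, burial term, secondary-structure propensity
#' term and their weights into the scoring model used by [coarse_energy()],
#' [resolve_cluster()] and [optimize_nonoverlap()].  This is a deliberately
#' coarse, deterministic surrogate for an all-atom scorer; an external scorer
#' can be substituted wherever a function `(sequence, template) -> score` is
#' accepted (see [coarse_energy()]'s `scorer` argument in the design
#' functions).
#'
#' @param w_contact,w_burial,w_ss Non-negative weights of the three additive
#'   terms.  Defaults `(1, 1, 0.5)`.
#' @param contact 20 x 20 symmetric contact table (lower = more favourable).
#' @param burial 3 x 20 matrix with rows `core`, `boundary`, `surface`.
#' @param ss 2 x 20 matrix with rows `helix`, `strand`.
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' names(m$weights)
energy_model <- function(w_contact = 1, w_burial = 1, w_ss = 0.5,
                         contact = contact_potential(),
                         burial = burial_table(),
                         ss = ss_table()) {
  if (any(c(w_contact, w_burial, w_ss) < 0)) {
    abort_domain("energy model weights must be non-negative")
  }
  if (!isTRUE(all.equal(contact, t(contact)))) {
    abort_domain("contact potential must be symmetric")
  }
  stopifnot(
    identical(colnames(contact), AA_ALPHABET),
    identical(colnames(burial), AA_ALPHABET),
    identical(colnames(ss), AA_ALPHABET)
  )
  structure(
    list(
      contact = contact, burial = burial, ss = ss,
      weights = c(contact = w_contact, burial = w_burial, ss = w_ss)
    ),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> weights:",
      paste(names(x$weights), signif(x$weights, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
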