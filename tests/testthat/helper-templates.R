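# Small hand-built fold templates used across tests.

# A 12-residue template: strand 1-4, helix 6-12, a few long-range contacts.
tiny_template <- function(name = "tiny",
                          ref = "VKVAAEELLKKA",
                          contacts = data.frame(i = c(1, 2, 3, 1),
                                                j = c(8, 9, 10, 12)),
                          burial = NULL) {
  fold_template(
    name = name, length = 12,
    elements = secondary_elements(c("strand", "helix"), c(1, 6), c(4, 12)),
    contacts = contacts, ref_sequence = ref, burial = burial
  )
}

# Long/short pair mirroring the published S/A-like geometry: a 99-residue
# scaffold with its first helix at 16-32 and a 56-residue domain with its
# helix at 6-22, so the helix-aligned embedding sits at offset 10
# (positions 11-66).
sa_like_pair <- function() {
  long <- fold_template(
    name = "long99", length = 99,
    elements = secondary_elements(
      c("strand", "helix", "strand", "strand", "helix", "strand"),
      c(2, 16, 40, 59, 73, 86),
      c(10, 32, 44, 67, 81, 92)
    ),
    contacts = data.frame(i = c(5, 20, 25, 62, 75),
                          j = c(90, 62, 88, 88, 90)),
    ref_sequence = paste(rep("A", 99), collapse = "")
  )
  short <- fold_template(
    name = "short56", length = 56,
    elements = secondary_elements(
      c("helix", "helix", "helix"),
      c(6, 27, 40),
      c(22, 35, 53)
    ),
    contacts = data.frame(i = c(8, 10, 30), j = c(45, 50, 45)),
    ref_sequence = paste(rep("A", 56), collapse = "")
  )
  list(long = long, short = short)
}

# Deterministic random template for property tests: elements + random
# geometric contacts on a compressed random walk.
random_template <- function(n, seed, name = "rand") {
  withr::with_seed(seed, {
    # alternating elements
    kinds <- character(0)
    starts <- integer(0)
    ends <- integer(0)
    pos <- 2L
    kind <- sample(c("helix", "strand"), 1)
    while (pos + 5 <= n - 1) {
      len <- sample(5:9, 1)
      if (pos + len - 1 > n - 1) break
      kinds <- c(kinds, kind)
      starts <- c(starts, pos)
      ends <- c(ends, pos + len - 1L)
      pos <- pos + len + sample(2:3, 1)
      kind <- if (kind == "helix") "strand" else "helix"
    }
    xyz <- matrix(cumsum(rnorm(3 * n, sd = 2.2)), ncol = 3)
    xyz <- xyz * 0.9  # compress so some long-range pairs fall under 8 A
    contacts <- contacts_from_coordinates(xyz, cutoff = 8, min_seq_sep = 3)
    aa <- sample(DESIGN_ALPHABET_TEST, n, replace = TRUE)
    fold_template(
      name = name, length = n,
      elements = secondary_elements(kinds, starts, ends),
      contacts = contacts,
      ref_sequence = paste(aa, collapse = "")
    )
  })
}

DESIGN_ALPHABET_TEST <- c("A", "G", "S", "T", "V", "L", "I", "F", "Y",
                          "D", "E", "K", "R", "N", "Q")
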