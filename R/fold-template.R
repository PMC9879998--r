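#' Secondary-structure elements table
#'
#' Helper to build the ordered elements tibble of a [fold_template()].
#' Residue numbering is 1-based and inclusive; loops are the implicit gaps
#' between elements.
#'
#' @param kind Character vector, `"helix"` or `"strand"` per element.
#' @param start,end Integer vectors of first/last residue of each element.
#' @param label Optional element labels (e.g. `"α1"`, `"β2"`); default labels
#'   number helices and strands separately in chain order.
#' @return A tibble with columns `kind`, `start`, `end`, `label`.
#' @export
#' @examples
#' secondary_elements(c("strand", "helix"), c(2, 16), c(10, 32))
secondary_elements <- function(kind, start, end, label = NULL) {
  if (!all(kind %in% c("helix", "strand"))) {
    abort_domain("element kind must be 'helix' or 'strand'")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start > end)) abort_domain("element start must be <= end")
  if (is.unsorted(start, strictly = TRUE) ||
      any(utils::head(end, -1) >= utils::tail(start, -1))) {
    abort_domain("elements must be ordered and non-overlapping")
  }
  if (is.null(label)) {
    greek <- c(helix = "α", strand = "β")
    idx <- stats::ave(seq_along(kind), kind, FUN = seq_along)
    label <- paste0(greek[kind], idx)
  }
  tibble::tibble(kind = kind, start = start, end = end, label = label)
}

#' Burial classification policy
#'
#' Residues are classified from their contact number: `core` at or above
#' `contact_number_core`, `surface` at or below `contact_number_surface`,
#' `boundary` otherwise.
#'
#' @param contact_number_core Integer threshold for core (default 6).
#' @param contact_number_surface Integer threshold for surface (default 2);
#'   must be strictly below the core threshold.
#' @return An object of class `burial_policy`.
#' @export
burial_policy <- function(contact_number_core = 6L, contact_number_surface = 2L) {
  if (contact_number_surface >= contact_number_core) {
    abort_domain("contact_number_surface must be < contact_number_core")
  }
  structure(
    list(contact_number_core = as.integer(contact_number_core),
         contact_number_surface = as.integer(contact_number_surface)),
    class = "burial_policy"
  )
}

normalize_contacts <- function(contacts, length, min_seq_sep = 3L) {
  if (is.null(contacts) || (is.data.frame(contacts) && nrow(contacts) == 0)) {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  if (is.matrix(contacts)) {
    contacts <- tibble::tibble(i = as.integer(contacts[, 1]),
                               j = as.integer(contacts[, 2]))
  }
  contacts <- tibble::as_tibble(contacts)[, c("i", "j")]
  ii <- pmin(contacts$i, contacts$j)
  jj <- pmax(contacts$i, contacts$j)
  out <- dplyr::distinct(tibble::tibble(i = as.integer(ii), j = as.integer(jj)))
  if (any(out$i < 1 | out$j > length)) {
    abort_domain("contact indices must lie in 1..length")
  }
  if (any(out$j - out$i < min_seq_sep)) {
    abort_domain("every contact pair must satisfy |i - j| >= %d", min_seq_sep)
  }
  dplyr::arrange(out, .data$i, .data$j)
}

#' Coarse-grained fold template
#'
#' A fold template records everything the design engine needs to know about
#' one fold: its secondary-structure topology, a residue-residue contact map,
#' per-residue burial classes, and a reference amino acid sequence.
#'
#' @param name Template name.
#' @param length Residue count.
#' @param elements Elements tibble from [secondary_elements()].
#' @param contacts Two-column (`i`, `j`) data frame or matrix of unordered
#'   residue contact pairs with `|i - j| >= 3`.
#' @param ref_sequence Reference amino acid string of length `length`.
#' @param burial Optional per-residue class vector (`core` / `boundary` /
#'   `surface`).  When `NULL` it is computed from the contact map under
#'   `policy`.
#' @param policy A [burial_policy()].
#' @return An object of class `fold_template`.
#' @export
#' @examples
#' el <- secondary_elements(c("strand", "helix"), c(1, 6), c(4, 12))
#' fold_template("toy", 12, el,
#'   contacts = data.frame(i = c(1, 2), j = c(8, 9)),
#'   ref_sequence = "VKVAAEELLKKA"
#' )
fold_template <- function(name, length, elements, contacts, ref_sequence,
                          burial = NULL, policy = burial_policy()) {
  length <- as.integer(length)
  if (length < 1L) abort_domain("template length must be positive")
  elements <- tibble::as_tibble(elements)
  if (nrow(elements) > 0 && max(elements$end) > length) {
    abort_domain("elements extend beyond template length")
  }
  if (nchar(ref_sequence) != length) {
    abort_domain("ref_sequence length (%d) != template length (%d)",
                 nchar(ref_sequence), length)
  }
  check_sequence(ref_sequence, "ref_sequence")
  contacts <- normalize_contacts(contacts, length)
  tmpl <- structure(
    list(
      name = name,
      length = length,
      elements = elements,
      topology_string = format_topology(elements$kind),
      contacts = contacts,
      burial = NULL,
      ref_sequence = ref_sequence
    ),
    class = "fold_template"
  )
  if (is.null(burial)) {
    burial <- classify_burial(tmpl, policy)
  } else {
    if (base::length(burial) != length ||
        !all(burial %in% c("core", "boundary", "surface"))) {
      abort_domain("burial must classify every residue as core/boundary/surface")
    }
  }
  tmpl$burial <- burial
  tmpl
}

#' @export
print.fold_template <- function(x, ...) {
  cat(sprintf(
    "<fold_template> %s: %d residues, topology %s, %d contacts (%d core / %d boundary / %d surface)\n",
    x$name, x$length, x$topology_string, nrow(x$contacts),
    sum(x$burial == "core"), sum(x$burial == "boundary"),
    sum(x$burial == "surface")
  ))
  invisible(x)
}

contact_counts <- function(template) {
  tabulate(c(template$contacts$i, template$contacts$j), nbins = template$length)
}

#' Classify residue burial from contact numbers
#'
#' @param template A [fold_template()] with contacts populated.
#' @param policy A [burial_policy()].
#' @return Character vector of length `template$length` over
#'   `core` / `boundary` / `surface`; the classes partition the residues.
#' @export
#' @examples
#' # a residue with zero contacts is surface under any policy
classify_burial <- function(template, policy = burial_policy()) {
  counts <- contact_counts(template)
  dplyr::case_when(
    counts >= policy$contact_number_core ~ "core",
    counts <= policy$contact_number_surface ~ "surface",
    TRUE ~ "boundary"
  )
}

#' Build a contact map from representative-atom coordinates
#'
#' A pair `(i, j)` is a contact iff its Euclidean distance is at most
#' `cutoff` and the sequence separation `|i - j|` is at least `min_seq_sep`.
#' Residues whose representative atom is missing (an `NA` row) are excluded
#' with a warning.
#'
#' @param coords N x 3 numeric matrix of representative-atom positions
#'   (conventionally C-beta, C-alpha for glycine), row `i` = residue `i`.
#' @param cutoff Distance cutoff in Angstrom (default 8.0).
#' @param min_seq_sep Minimum sequence separation (default 3).
#' @return Tibble of contacts with columns `i < j`.
#' @export
#' @examples
#' xyz <- cbind(seq(0, 40, by = 10), 0, 0)
#' contacts_from_coordinates(xyz, cutoff = 12)
contacts_from_coordinates <- function(coords, cutoff = 8, min_seq_sep = 3L) {
  if (cutoff <= 0) abort_domain("cutoff must be positive")
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort_domain("coords must have 3 columns")
  n <- nrow(coords)
  missing <- which(apply(coords, 1, function(r) any(is.na(r))))
  if (length(missing) > 0) {
    rlang::warn(sprintf(
      "excluding %d residue(s) with missing coordinates: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
  }
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  keep <- d[pairs] <= cutoff &
    (pairs[, 2] - pairs[, 1]) >= min_seq_sep &
    !(pairs[, 1] %in% missing) & !(pairs[, 2] %in% missing)
  out <- tibble::tibble(i = as.integer(pairs[keep, 1]),
                        j = as.integer(pairs[keep, 2]))
  dplyr::arrange(out, .data$i, .data$j)
}

#' Serialize / read a fold template as JSON
#'
#' Contacts are written as a sorted list of `[i, j]` pairs with `i < j`.
#'
#' @param template A [fold_template()].
#' @param path File path.
#' @return `write_fold_template()` returns `path` invisibly;
#'   `read_fold_template()` returns the template.
#' @export
write_fold_template <- function(template, path) {
  obj <- list(
    name = template$name,
    length = template$length,
    elements = as.data.frame(template$elements),
    topology_string = template$topology_string,
    contacts = unname(as.matrix(template$contacts)),
    burial = template$burial,
    ref_sequence = template$ref_sequence
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_template
#' @export
read_fold_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  contacts <- obj$contacts
  if (length(contacts) == 0) contacts <- matrix(integer(0), ncol = 2)
  fold_template(
    name = obj$name,
    length = obj$length,
    elements = tibble::as_tibble(obj$elements),
    contacts = contacts,
    ref_sequence = obj$ref_sequence,
    burial = obj$burial
  )
}

#' Build a fold template from a PDB file
#'
#' Reads ATOM records of the first model (altloc blank or 'A'), takes the
#' C-beta atom per residue (C-alpha for glycine) as the representative atom,
#' and derives the contact map with [contacts_from_coordinates()].  Element
#' boundaries are supplied, not computed from the coordinates.
#'
#' @param path PDB-format file.
#' @param elements Elements tibble from [secondary_elements()], numbered on
#'   the extracted chain (1-based from the first residue read).
#' @param chain Chain identifier; default the first chain in the file.
#' @param name Template name; defaults to the file name.
#' @param cutoff,min_seq_sep Passed to [contacts_from_coordinates()].
#' @param policy A [burial_policy()].
#' @return A [fold_template()].
#' @export
template_from_pdb <- function(path, elements, chain = NULL, name = NULL,
                              cutoff = 8, min_seq_sep = 3L,
                              policy = burial_policy()) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort_config("template_from_pdb requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$alt %in% c("", "A", NA), ]
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, ]
  if (nrow(atoms) == 0) abort_domain("no ATOM records for chain '%s'", chain)
  resnos <- unique(atoms$resno)
  rep_xyz <- t(vapply(resnos, function(rn) {
    res <- atoms[atoms$resno == rn, ]
    pick <- if (res$resid[1] == "GLY") "CA" else "CB"
    row <- res[res$elety == pick, , drop = FALSE]
    if (nrow(row) == 0) row <- res[res$elety == "CA", , drop = FALSE]
    if (nrow(row) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(row$x[1], row$y[1], row$z[1])
  }, numeric(3)))
  aa1 <- vapply(resnos, function(rn) {
    bio3d::aa321(atoms$resid[atoms$resno == rn][1])
  }, character(1))
  keep <- aa1 %in% AA_ALPHABET
  if (!all(keep)) {
    rlang::warn(sprintf("dropping %d non-standard residue(s)", sum(!keep)))
    rep_xyz <- rep_xyz[keep, , drop = FALSE]
    aa1 <- aa1[keep]
  }
  fold_template(
    name = name %||% basename(path),
    length = length(aa1),
    elements = elements,
    contacts = contacts_from_coordinates(rep_xyz, cutoff, min_seq_sep),
    ref_sequence = paste(aa1, collapse = ""),
    policy = policy
  )
}

#' Read / write FASTA files
#'
#' Thin wrappers over Biostrings preserving description lines, returning and
#' accepting tidy tibbles.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a tibble with columns `name` (first word of
#'   the description line), `description` (full line) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_config("read_fasta requires the 'Biostrings' package")
  }
  set <- Biostrings::readAAStringSet(path)
  desc <- names(set)
  tibble::tibble(
    name = sub("\\s.*$", "", desc),
    description = desc,
    sequence = unname(as.character(set))
  )
}

#' @rdname read_fasta
#' @param records Tibble with `name`/`sequence` (optionally `description`),
#'   or a named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_config("write_fasta requires the 'Biostrings' package")
  }
  if (is.character(records)) {
    records <- tibble::tibble(name = names(records), sequence = unname(records))
  }
  desc <- if ("description" %in% names(records)) records$description else records$name
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- desc
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
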