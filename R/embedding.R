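overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

find_element <- function(template, label) {
  idx <- which(template$elements$label == label)
  if (length(idx) == 0) {
    abort_config("anchor element '%s' not found in template '%s'",
                 label, template$name)
  }
  template$elements[idx[1], ]
}

#' Construct a contiguous embedding of a short fold into a long fold
#'
#' Short-fold position `i` maps to long-fold position `i + offset`.  The
#' anchor element pair must overlap by at least `min_anchor_overlap` residues
#' under the offset, and the embedded window must lie fully inside the long
#' fold.
#'
#' @param long,short [fold_template()] objects; `short$length <= long$length`.
#' @param offset Integer embedding offset (0 means window starts at long
#'   position 1).
#' @param anchor Character vector of one or two element labels,
#'   `c(short_label, long_label)`; a single label is used for both.
#' @param min_anchor_overlap Minimum anchor overlap in residues (default 4,
#'   roughly one helical turn).
#' @return An object of class `embedding` with fields `offset`, `short_len`,
#'   `start`/`end` (long-frame window), `anchor`, `anchor_overlap` and a
#'   `correspondences` tibble (one row per short element: best-overlapping
#'   long element, overlap length, kind match).
#' @export
#' @examples
#' # see enumerate_embeddings() for a toy pair
embedding <- function(long, short, offset, anchor,
                      min_anchor_overlap = 4L) {
  offset <- as.integer(offset)
  if (short$length > long$length) {
    abort_domain("short template is longer than long template")
  }
  if (1L + offset < 1L || short$length + offset > long$length) {
    abort_domain("embedding at offset %d does not fit inside the long fold", offset)
  }
  anchor <- as.character(anchor)
  if (length(anchor) == 1L) anchor <- c(anchor, anchor)
  a_short <- find_element(short, anchor[1])
  a_long <- find_element(long, anchor[2])
  ov <- overlap_len(a_short$start + offset, a_short$end + offset,
                    a_long$start, a_long$end)
  if (ov < min_anchor_overlap) {
    abort_domain(
      "anchor elements overlap by %d residue(s) at offset %d (need >= %d)",
      ov, offset, min_anchor_overlap
    )
  }
  corr <- purrr::pmap_dfr(short$elements, function(kind, start, end, label) {
    s <- start + offset
    e <- end + offset
    ovs <- overlap_len(s, e, long$elements$start, long$elements$end)
    best <- which.max(ovs)
    if (length(best) == 0 || ovs[best] == 0) {
      tibble::tibble(short_element = label, long_element = NA_character_,
                     overlap = 0L, kind_match = FALSE)
    } else {
      tibble::tibble(
        short_element = label,
        long_element = long$elements$label[best],
        overlap = as.integer(ovs[best]),
        kind_match = long$elements$kind[best] == kind
      )
    }
  })
  structure(
    list(
      offset = offset,
      short_len = short$length,
      start = 1L + offset,
      end = short$length + offset,
      anchor = anchor,
      anchor_overlap = as.integer(ov),
      correspondences = corr
    ),
    class = "embedding"
  )
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf(
    "<embedding> offset %d: window %d-%d (%d residues), anchor %s:%s overlap %d\n",
    x$offset, x$start, x$end, x$short_len, x$anchor[1], x$anchor[2],
    x$anchor_overlap
  ))
  invisible(x)
}

#' Enumerate all valid contiguous embeddings
#'
#' Scans every offset at which the short fold fits inside the long fold and
#' keeps those where the anchor elements overlap by at least
#' `min_anchor_overlap` residues.
#'
#' @inheritParams embedding
#' @return A tibble with one row per valid embedding: `offset`, `start`,
#'   `end`, `anchor_overlap`, `kind_matches` (number of short elements whose
#'   best long counterpart has the same kind) and a list-column `embedding`
#'   of [embedding()] objects.
#' @export
enumerate_embeddings <- function(long, short, anchor,
                                 min_anchor_overlap = 4L) {
  if (short$length > long$length) {
    abort_domain("short template is longer than long template")
  }
  anchor <- as.character(anchor)
  if (length(anchor) == 1L) anchor <- c(anchor, anchor)
  find_element(short, anchor[1])
  find_element(long, anchor[2])
  offsets <- 0:(long$length - short$length)
  embs <- purrr::map(offsets, function(off) {
    tryCatch(
      embedding(long, short, off, anchor, min_anchor_overlap),
      foldswitch_domain_error = function(e) NULL
    )
  })
  embs <- purrr::compact(embs)
  purrr::map_dfr(embs, function(e) {
    tibble::tibble(
      offset = e$offset, start = e$start, end = e$end,
      anchor_overlap = e$anchor_overlap,
      kind_matches = sum(e$correspondences$kind_match &
                           e$correspondences$overlap > 0),
      embedding = list(e)
    )
  })
}

#' Parameters of catastrophic-interaction scoring
#'
#' @param severity Named severities for the five conflict kinds.  Ordinal
#'   only: ranking sorts by conflict count before severity.
#' @param overpack_factor A contacting core pair is overpacked when its
#'   side-chain volume sum exceeds `overpack_factor` times the
#'   reference-sequence sum for that pair (default 1.25).
#' @param underpack_factor A core G/A is underpacked when its volume falls
#'   below `underpack_factor` times the reference volume at that position
#'   (default 0.5).
#' @param helix_nterm_exempt Prolines within this many residues of a helix
#'   N-terminus are tolerated (first turn, default 3).
#' @return A list of class `conflict_params`.
#' @export
conflict_params <- function(severity = c(buried_polar = 2, helix_breaker = 3,
                                         strand_breaker = 3, overpacked_pair = 1,
                                         underpacked_core = 0.5),
                            overpack_factor = 1.25,
                            underpack_factor = 0.5,
                            helix_nterm_exempt = 3L) {
  structure(
    list(severity = severity, overpack_factor = overpack_factor,
         underpack_factor = underpack_factor,
         helix_nterm_exempt = as.integer(helix_nterm_exempt)),
    class = "conflict_params"
  )
}

# Per-context residue annotations on the template's own frame.
context_annotation <- function(template, params) {
  n <- template$length
  in_helix_interior <- rep(FALSE, n)
  in_strand <- rep(FALSE, n)
  in_helix <- rep(FALSE, n)
  for (k in seq_len(nrow(template$elements))) {
    el <- template$elements[k, ]
    span <- el$start:el$end
    if (el$kind == "helix") {
      in_helix[span] <- TRUE
      interior <- span[span - el$start >= params$helix_nterm_exempt + 1L]
      in_helix_interior[interior] <- TRUE
    } else {
      in_strand[span] <- TRUE
    }
  }
  list(
    core = template$burial == "core",
    in_helix_interior = in_helix_interior,
    in_strand = in_strand,
    ref = seq_chars(template$ref_sequence)
  )
}

# Conflicts of one fold context evaluated on a candidate sequence given in
# that context's own frame; positions reported in the context frame.
context_conflicts <- function(chars, template, params, context_name) {
  ann <- context_annotation(template, params)
  vol <- AA_VOLUME[chars]
  ref_vol <- AA_VOLUME[ann$ref]
  out <- list()

  bp <- which(ann$core & chars %in% BURIED_POLAR_SET)
  if (length(bp) > 0) {
    out$bp <- tibble::tibble(
      position = bp, kind = "buried_polar", context = context_name,
      partner = NA_integer_,
      detail = sprintf("%s buried at core position %d", chars[bp], bp)
    )
  }
  hb <- which(ann$in_helix_interior & chars == "P")
  if (length(hb) > 0) {
    out$hb <- tibble::tibble(
      position = hb, kind = "helix_breaker", context = context_name,
      partner = NA_integer_,
      detail = sprintf("P inside helix at %d", hb)
    )
  }
  sb <- which(ann$in_strand & chars == "P")
  if (length(sb) > 0) {
    out$sb <- tibble::tibble(
      position = sb, kind = "strand_breaker", context = context_name,
      partner = NA_integer_,
      detail = sprintf("P inside strand at %d", sb)
    )
  }
  cc <- template$contacts
  if (nrow(cc) > 0) {
    both_core <- ann$core[cc$i] & ann$core[cc$j]
    over <- both_core &
      (vol[cc$i] + vol[cc$j] >
         params$overpack_factor * (ref_vol[cc$i] + ref_vol[cc$j]))
    if (any(over)) {
      out$op <- tibble::tibble(
        position = cc$i[over], kind = "overpacked_pair", context = context_name,
        partner = cc$j[over],
        detail = sprintf("pair %d-%d exceeds volume budget", cc$i[over], cc$j[over])
      )
    }
  }
  up <- which(ann$core & chars %in% c("G", "A") &
                vol < params$underpack_factor * ref_vol)
  if (length(up) > 0) {
    out$up <- tibble::tibble(
      position = up, kind = "underpacked_core", context = context_name,
      partner = NA_integer_,
      detail = sprintf("%s underfills core position %d", chars[up], up)
    )
  }
  dplyr::bind_rows(out)
}

#' Score catastrophic interactions of a sequence in both fold contexts
#'
#' Every long-frame position is evaluated in the long fold context; positions
#' inside the embedded window are additionally evaluated in the short fold
#' context (mapped through the offset).  Conflict kinds: `buried_polar`
#' (D/E/K/R/N/Q/H at a core position), `helix_breaker` / `strand_breaker`
#' (proline inside a helix beyond the first turn, or inside a strand),
#' `overpacked_pair` (contacting core pair exceeding the reference volume
#' budget) and `underpacked_core` (G/A starving a core position).  A residue
#' incompatible with both contexts yields one conflict per context.
#'
#' @param emb An [embedding()].
#' @param long,short The fold templates.
#' @param sequence Candidate amino acid string on the long frame.
#' @param params A [conflict_params()].
#' @return An object of class `conflict_report`: list with the embedding, a
#'   `conflicts` tibble (long-frame `position`, `kind`, `context`,
#'   `severity`, `partner`, `detail`), `total_count`, `total_severity` and
#'   `kind_matches`.
#' @export
score_conflicts <- function(emb, long, short, sequence,
                            params = conflict_params()) {
  if (nchar(sequence) != long$length) {
    abort_domain("sequence length (%d) != long template length (%d)",
                 nchar(sequence), long$length)
  }
  chars <- check_sequence(sequence)
  long_conf <- context_conflicts(chars, long, params, "long")
  window_chars <- chars[emb$start:emb$end]
  short_conf <- context_conflicts(window_chars, short, params, "short")
  if (nrow(short_conf) > 0) {
    short_conf$position <- short_conf$position + emb$offset
    short_conf$partner <- short_conf$partner + emb$offset
  }
  conflicts <- dplyr::bind_rows(long_conf, short_conf)
  if (nrow(conflicts) > 0) {
    conflicts$severity <- unname(params$severity[conflicts$kind])
    conflicts <- dplyr::arrange(conflicts, .data$position, .data$kind,
                                .data$context)
  } else {
    conflicts <- tibble::tibble(
      position = integer(0), kind = character(0), context = character(0),
      partner = integer(0), detail = character(0), severity = numeric(0)
    )
  }
  structure(
    list(
      embedding = emb,
      conflicts = conflicts,
      total_count = nrow(conflicts),
      total_severity = sum(conflicts$severity),
      kind_matches = sum(emb$correspondences$kind_match &
                           emb$correspondences$overlap > 0)
    ),
    class = "conflict_report"
  )
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf(
    "<conflict_report> offset %d: %d conflict(s), severity %.1f, %d kind-matched element(s)\n",
    x$embedding$offset, x$total_count, x$total_severity, x$kind_matches
  ))
  invisible(x)
}

#' Rank embeddings by catastrophic-interaction load
#'
#' Sorts ascending by conflict count, then total severity, then descending by
#' the number of kind-matched element correspondences, then ascending offset.
#' The ordering is total and deterministic.
#'
#' @param reports A non-empty list of [score_conflicts()] reports.
#' @return A tibble sorted best-first with columns `rank`, `offset`,
#'   `total_count`, `total_severity`, `kind_matches` and a list-column
#'   `report`.
#' @export
rank_embeddings <- function(reports) {
  if (inherits(reports, "conflict_report")) reports <- list(reports)
  if (length(reports) == 0) abort_domain("no conflict reports to rank")
  tab <- purrr::map_dfr(reports, function(r) {
    tibble::tibble(
      offset = r$embedding$offset,
      total_count = r$total_count,
      total_severity = r$total_severity,
      kind_matches = r$kind_matches
    )
  })
  tab$report <- reports
  tab <- dplyr::arrange(tab, .data$total_count, .data$total_severity,
                        dplyr::desc(.data$kind_matches), .data$offset)
  dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1)
}

#' Enumerate, score and rank embeddings of a fold pair in one call
#'
#' Convenience wrapper: for every valid embedding the merged initial sequence
#' (short reference inside the window, long reference outside) is scored and
#' the reports are ranked.
#'
#' @inheritParams enumerate_embeddings
#' @param params A [conflict_params()].
#' @return The ranked tibble from [rank_embeddings()].
#' @export
rank_fold_pair <- function(long, short, anchor, min_anchor_overlap = 4L,
                           params = conflict_params()) {
  cand <- enumerate_embeddings(long, short, anchor, min_anchor_overlap)
  if (nrow(cand) == 0) abort_domain("no valid embeddings for this fold pair")
  reports <- purrr::map(cand$embedding, function(e) {
    merged <- merged_sequence(e, long, short)
    score_conflicts(e, long, short, merged, params)
  })
  rank_embeddings(reports)
}
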