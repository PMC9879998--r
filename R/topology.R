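#' Parse a secondary-structure topology string
#'
#' Topology strings name only helices and strands, in chain order; loops are
#' implicit gaps.  Both the Greek alphabet (`"α"` = helix, `"β"` =
#' strand) and the H/E alphabet are accepted, and may be mixed.
#'
#' @param topology A single string, e.g. `"βαββαβ"`
#'   or `"HEEH"`.  The empty string parses to an empty vector.
#' @return A character vector of element kinds, each `"helix"` or `"strand"`.
#' @seealso [format_topology()] for the inverse.
#' @export
#' @examples
#' parse_topology("HEEH")
#' parse_topology("βαββαβ")
parse_topology <- function(topology) {
  if (length(topology) != 1L || is.na(topology)) {
    abort_format("topology must be a single string")
  }
  if (nchar(topology) == 0L) return(character(0))
  chars <- seq_chars(topology)
  map <- c(
    "α" = "helix", "H" = "helix", "h" = "helix",
    "β" = "strand", "E" = "strand", "e" = "strand"
  )
  kinds <- unname(map[chars])
  bad <- which(is.na(kinds))
  if (length(bad) > 0) {
    abort_format(
      "unknown topology character '%s' at position %d", chars[bad[1]], bad[1]
    )
  }
  kinds
}

#' Format a list of element kinds as a topology string
#'
#' @param kinds Character vector of `"helix"` / `"strand"` (loops omitted).
#' @param alphabet `"greek"` (default) for α/β or `"he"` for H/E.
#' @return A single topology string; `parse_topology()` round-trips it.
#' @export
#' @examples
#' format_topology(c("strand", "helix"), alphabet = "he")
format_topology <- function(kinds, alphabet = c("greek", "he")) {
  alphabet <- match.arg(alphabet)
  if (length(kinds) == 0L) return("")
  bad <- which(!kinds %in% c("helix", "strand"))
  if (length(bad) > 0) {
    abort_format("unknown element kind '%s' at position %d", kinds[bad[1]], bad[1])
  }
  map <- if (alphabet == "greek") {
    c(helix = "α", strand = "β")
  } else {
    c(helix = "H", strand = "E")
  }
  paste(map[kinds], collapse = "")
}
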