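# Independent brute-force oracles.  These deliberately avoid the package's
# internal fast paths: plain loops and direct arithmetic only.

# all-pairs contact oracle
oracle_contacts <- function(coords, cutoff, min_seq_sep) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < min_seq_sep) next
      if (any(is.na(coords[i, ])) || any(is.na(coords[j, ]))) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= cutoff) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(tibble::tibble(i = integer(0), j = integer(0)))
  m <- do.call(rbind, out)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

# per-residue contact-count recount
oracle_contact_counts <- function(template) {
  counts <- integer(template$length)
  for (k in seq_len(nrow(template$contacts))) {
    counts[template$contacts$i[k]] <- counts[template$contacts$i[k]] + 1L
    counts[template$contacts$j[k]] <- counts[template$contacts$j[k]] + 1L
  }
  counts
}

# exhaustive offset scan for valid embeddings (anchor overlap rule)
oracle_offsets <- function(long, short, anchor_label, min_overlap = 4) {
  a_s <- short$elements[short$elements$label == anchor_label, ]
  a_l <- long$elements[long$elements$label == anchor_label, ]
  keep <- integer(0)
  for (off in 0:(long$length - short$length)) {
    ov <- min(a_s$end + off, a_l$end) - max(a_s$start + off, a_l$start) + 1
    if (ov >= min_overlap) keep <- c(keep, off)
  }
  keep
}

# term-by-term energy summation
oracle_energy <- function(sequence, template, model) {
  chars <- strsplit(sequence, "")[[1]]
  e <- 0
  for (k in seq_len(nrow(template$contacts))) {
    e <- e + model$weights["contact"] *
      model$contact[chars[template$contacts$i[k]], chars[template$contacts$j[k]]]
  }
  for (i in seq_len(template$length)) {
    e <- e + model$weights["burial"] * model$burial[template$burial[i], chars[i]]
  }
  for (k in seq_len(nrow(template$elements))) {
    el <- template$elements[k, ]
    for (i in el$start:el$end) {
      e <- e + model$weights["ss"] * model$ss[el$kind, chars[i]]
    }
  }
  unname(e)
}

# conflicts involving a cluster, recomputed with the full scorer on an
# explicitly substituted sequence (independent of the cluster fast path)
oracle_cluster_conflicts <- function(design, cluster, letters) {
  chars <- strsplit(design$long_sequence, "")[[1]]
  chars[cluster] <- letters
  rep <- score_conflicts(design$embedding, design$long, design$short,
                         paste(chars, collapse = ""))
  cf <- rep$conflicts
  sum(cf$position %in% cluster |
        (!is.na(cf$partner) & cf$partner %in% cluster))
}

oracle_dual_energy <- function(design, cluster, letters, model) {
  chars <- strsplit(design$long_sequence, "")[[1]]
  chars[cluster] <- letters
  long_seq <- paste(chars, collapse = "")
  short_seq <- substr(long_seq, design$embedding$start, design$embedding$end)
  coarse_energy(long_seq, design$long, model) +
    coarse_energy(short_seq, design$short, model)
}

# exhaustive assignment search replicating the documented tie-break chain
oracle_resolve <- function(design, cluster, alphabet, model) {
  k <- length(cluster)
  cur <- strsplit(design$long_sequence, "")[[1]][cluster]
  cand <- lapply(seq_len(k), function(i) sort(unique(c(cur[i], alphabet))))
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    letters <- as.character(unlist(grid[r, ]))
    key <- list(
      conf = oracle_cluster_conflicts(design, cluster, letters),
      nmut = sum(letters != cur),
      ener = oracle_dual_energy(design, cluster, letters, model),
      str = paste(letters, collapse = "")
    )
    if (is.null(best)) { best <- key; next }
    better <- if (key$conf != best$conf) key$conf < best$conf
      else if (key$nmut != best$nmut) key$nmut < best$nmut
      else if (abs(key$ener - best$ener) > 1e-9) key$ener < best$ener
      else key$str < best$str
    if (better) best <- key
  }
  best
}

# independent re-sort of a ranked table by the documented key tuple
oracle_rank_order <- function(tab) {
  tab[order(tab$total_count, tab$total_severity, -tab$kind_matches,
            tab$offset), ]$offset
}
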