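#' Merged initial sequence of an embedding
#'
#' The embedded window takes the short fold's reference sequence; all other
#' positions take the long fold's reference sequence.
#'
#' @param emb An [embedding()].
#' @param long,short Fold templates carrying reference sequences.
#' @return Amino acid string on the long frame.
#' @export
merged_sequence <- function(emb, long, short) {
  chars <- seq_chars(long$ref_sequence)
  chars[emb$start:emb$end] <- seq_chars(short$ref_sequence)
  paste(chars, collapse = "")
}

#' Create a joint design from an embedding
#'
#' Threads the short fold's reference sequence into the long fold at the
#' embedding offset ([merged_sequence()]) and wraps the result, together
#' with both templates, as a `joint_design` whose embedded window IS the
#' short construct at all times.  The mutation log starts empty and replays
#' from this initial merged sequence.
#'
#' @inheritParams merged_sequence
#' @param name Design name.
#' @return An object of class `joint_design`.
#' @export
merge_initial <- function(emb, long, short, name = "design") {
  seq0 <- merged_sequence(emb, long, short)
  structure(
    list(
      name = name,
      long = long,
      short = short,
      embedding = emb,
      initial_sequence = seq0,
      long_sequence = seq0,
      mutation_log = empty_mutation_log(),
      optimization = NULL
    ),
    class = "joint_design"
  )
}

empty_mutation_log <- function() {
  tibble::tibble(
    position = integer(0), from = character(0), to = character(0),
    stage = character(0), in_window = logical(0)
  )
}

#' @export
print.joint_design <- function(x, ...) {
  cat(sprintf(
    "<joint_design> %s: %d residues, window %d-%d, %d logged mutation(s)\n",
    x$name, nchar(x$long_sequence), x$embedding$start, x$embedding$end,
    nrow(x$mutation_log)
  ))
  invisible(x)
}

#' Extract the embedded short-construct sequence
#'
#' Returns exactly the embedded window of the long sequence; by the
#' embedded-identity invariant this is the short construct.
#'
#' @param design A [merge_initial()] design.
#' @return Amino acid string of length `short_len`.
#' @export
truncate_to_short <- function(design) {
  substr(design$long_sequence, design$embedding$start, design$embedding$end)
}

#' @rdname truncate_to_short
#' @export
short_sequence <- truncate_to_short

#' Replay a design's mutation log
#'
#' Applies the log to the initial merged sequence; the result must equal the
#' design's current long sequence byte-for-byte.
#'
#' @param design A `joint_design`.
#' @return The replayed amino acid string.
#' @export
replay_mutations <- function(design) {
  s <- design$initial_sequence
  log <- design$mutation_log
  for (k in seq_len(nrow(log))) {
    if (log$stage[k] == "tail_graft") {
      s <- paste0(substr(s, 1, log$position[k] - 1L), log$to[k])
    } else {
      if (substr(s, log$position[k], log$position[k]) != log$from[k]) {
        abort_domain("mutation log does not replay: position %d holds '%s', log expects '%s'",
                     log$position[k], substr(s, log$position[k], log$position[k]),
                     log$from[k])
      }
      substr(s, log$position[k], log$position[k]) <- log$to[k]
    }
  }
  s
}

log_mutations <- function(design, positions, to, stage) {
  chars <- seq_chars(design$long_sequence)
  from <- chars[positions]
  changed <- from != to
  positions <- positions[changed]
  to <- to[changed]
  from <- from[changed]
  if (length(positions) == 0) return(design)
  chars[positions] <- to
  design$long_sequence <- paste(chars, collapse = "")
  design$mutation_log <- dplyr::bind_rows(
    design$mutation_log,
    tibble::tibble(
      position = as.integer(positions), from = from, to = to, stage = stage,
      in_window = positions >= design$embedding$start &
        positions <= design$embedding$end
    )
  )
  design
}

#' Coarse additive sequence-structure energy
#'
#' `score = w_contact * sum over contacts of P[s_i, s_j] +
#' w_burial * sum over residues of B[burial_i, s_i] +
#' w_ss * sum over element residues of S[kind_i, s_i]`.  Deterministic,
#' additive over terms; lower is more favourable.  This is a coarse stand-in
#' for an all-atom scorer: any function `(sequence, template) -> score` can
#' replace it in the design loop.
#'
#' @param sequence Amino acid string of the template's length.
#' @param template A [fold_template()].
#' @param model An [energy_model()].
#' @return A single numeric score (dimensionless).
#' @export
coarse_energy <- function(sequence, template, model = energy_model()) {
  if (nchar(sequence) != template$length) {
    abort_domain("sequence length (%d) != template length (%d)",
                 nchar(sequence), template$length)
  }
  chars <- check_sequence(sequence)
  w <- model$weights
  e_contact <- if (nrow(template$contacts) > 0) {
    sum(model$contact[cbind(chars[template$contacts$i], chars[template$contacts$j])])
  } else 0
  e_burial <- sum(model$burial[cbind(template$burial, chars)])
  e_ss <- 0
  for (k in seq_len(nrow(template$elements))) {
    el <- template$elements[k, ]
    e_ss <- e_ss + sum(model$ss[el$kind, chars[el$start:el$end]])
  }
  unname(w["contact"] * e_contact + w["burial"] * e_burial + w["ss"] * e_ss)
}

# ---- internal context machinery for local (delta) scoring -------------------

# Describes one fold context on the long frame: which long-frame positions it
# covers and how they map to the template frame.
design_contexts <- function(design, params) {
  emb <- design$embedding
  list(
    long = list(
      template = design$long,
      covers = function(p) p >= 1L & p <= design$long$length,
      to_frame = function(p) p,
      to_long = function(q) q,
      ann = context_annotation(design$long, params)
    ),
    short = list(
      template = design$short,
      covers = function(p) p >= emb$start & p <= emb$end,
      to_frame = function(p) p - emb$offset,
      to_long = function(q) q + emb$offset,
      ann = context_annotation(design$short, params)
    )
  )
}

# Count conflicts involving long-frame position p if it held `letter`
# (everything else fixed at `chars`); returns keys "kind|context|partner".
local_conflict_keys <- function(p, letter, chars, contexts, params) {
  keys <- character(0)
  vols <- AA_VOLUME
  for (nm in names(contexts)) {
    ctx <- contexts[[nm]]
    if (!ctx$covers(p)) next
    q <- ctx$to_frame(p)
    ann <- ctx$ann
    if (ann$core[q] && letter %in% BURIED_POLAR_SET) {
      keys <- c(keys, paste("buried_polar", nm, p, sep = "|"))
    }
    if (ann$in_helix_interior[q] && letter == "P") {
      keys <- c(keys, paste("helix_breaker", nm, p, sep = "|"))
    }
    if (ann$in_strand[q] && letter == "P") {
      keys <- c(keys, paste("strand_breaker", nm, p, sep = "|"))
    }
    if (ann$core[q] && letter %in% c("G", "A") &&
        vols[letter] < params$underpack_factor * vols[ann$ref[q]]) {
      keys <- c(keys, paste("underpacked_core", nm, p, sep = "|"))
    }
    cc <- ctx$template$contacts
    inc <- which(cc$i == q | cc$j == q)
    for (e in inc) {
      r <- if (cc$i[e] == q) cc$j[e] else cc$i[e]
      if (!(ann$core[q] && ann$core[r])) next
      r_long <- ctx$to_long(r)
      if (vols[letter] + vols[chars[r_long]] >
          params$overpack_factor * (vols[ann$ref[q]] + vols[ann$ref[r]])) {
        keys <- c(keys, paste("overpacked_pair", nm, min(p, r_long),
                              max(p, r_long), sep = "|"))
      }
    }
  }
  keys
}

# Per-position, per-letter singleton conflict counts and energies for a
# cluster search; pairs wholly inside the cluster handled separately.
cluster_precompute <- function(design, cluster, model, params, contexts,
                               dual = TRUE) {
  chars <- seq_chars(design$long_sequence)
  k <- length(cluster)
  naa <- length(AA_ALPHABET)
  conf <- matrix(0, nrow = k, ncol = naa, dimnames = list(NULL, AA_ALPHABET))
  ener <- matrix(0, nrow = k, ncol = naa, dimnames = list(NULL, AA_ALPHABET))
  pair_conf <- list()
  pair_ener <- list()
  w <- model$weights
  ctx_names <- if (dual) names(contexts) else "long"
  for (ci in seq_len(k)) {
    p <- cluster[ci]
    for (nm in ctx_names) {
      ctx <- contexts[[nm]]
      if (!ctx$covers(p)) next
      q <- ctx$to_frame(p)
      ann <- ctx$ann
      tpl <- ctx$template
      # singleton conflict indicators over the 20 letters
      v <- rep(0, naa)
      if (ann$core[q]) {
        v <- v + as.numeric(AA_ALPHABET %in% BURIED_POLAR_SET)
        v <- v + as.numeric(AA_ALPHABET %in% c("G", "A") &
                              AA_VOLUME < params$underpack_factor * AA_VOLUME[ann$ref[q]])
      }
      if (ann$in_helix_interior[q]) v <- v + as.numeric(AA_ALPHABET == "P")
      if (ann$in_strand[q]) v <- v + as.numeric(AA_ALPHABET == "P")
      conf[ci, ] <- conf[ci, ] + v
      # singleton energy: burial + ss
      e <- w["burial"] * model$burial[tpl$burial[q], ]
      el_idx <- which(tpl$elements$start <= q & tpl$elements$end >= q)
      if (length(el_idx) == 1) {
        e <- e + w["ss"] * model$ss[tpl$elements$kind[el_idx], ]
      }
      ener[ci, ] <- ener[ci, ] + e
      # contacts incident to q
      cc <- tpl$contacts
      inc <- which(cc$i == q | cc$j == q)
      for (eidx in inc) {
        r <- if (cc$i[eidx] == q) cc$j[eidx] else cc$i[eidx]
        r_long <- ctx$to_long(r)
        cj <- match(r_long, cluster)
        if (!is.na(cj)) {
          if (cj < ci) next  # handled when ci was cj's partner? no: handle once, ci<cj
          if (cj == ci) next
          # intra-cluster pair (ci, cj)
          key <- paste(nm, ci, cj, sep = "_")
          pe <- w["contact"] * model$contact
          pair_ener[[key]] <- (pair_ener[[key]] %||% matrix(0, naa, naa,
            dimnames = list(AA_ALPHABET, AA_ALPHABET))) + pe
          pc <- matrix(0, naa, naa, dimnames = list(AA_ALPHABET, AA_ALPHABET))
          if (ann$core[q] && ann$core[r]) {
            budget <- params$overpack_factor * (AA_VOLUME[ann$ref[q]] + AA_VOLUME[ann$ref[r]])
            pc <- pc + (outer(AA_VOLUME, AA_VOLUME, "+") > budget) * 1
          }
          pair_conf[[key]] <- (pair_conf[[key]] %||% matrix(0, naa, naa,
            dimnames = list(AA_ALPHABET, AA_ALPHABET))) + pc
          attr(pair_conf[[key]], "pair") <- c(ci, cj)
          attr(pair_ener[[key]], "pair") <- c(ci, cj)
        } else {
          # partner fixed outside the cluster
          s_r <- chars[r_long]
          ener[ci, ] <- ener[ci, ] + w["contact"] * model$contact[, s_r]
          if (ann$core[q] && ann$core[r]) {
            budget <- params$overpack_factor * (AA_VOLUME[ann$ref[q]] + AA_VOLUME[ann$ref[r]])
            conf[ci, ] <- conf[ci, ] + as.numeric(AA_VOLUME + AA_VOLUME[s_r] > budget)
          }
        }
      }
    }
  }
  list(conf = conf, ener = ener, pair_conf = pair_conf, pair_ener = pair_ener,
       current = chars[cluster])
}

evaluate_assignments <- function(pre, assign) {
  # assign: integer matrix (rows = assignments, cols = cluster positions),
  # values index AA_ALPHABET
  n <- nrow(assign)
  k <- ncol(assign)
  conf <- numeric(n)
  ener <- numeric(n)
  nmut <- integer(n)
  cur_idx <- match(pre$current, AA_ALPHABET)
  for (ci in seq_len(k)) {
    conf <- conf + pre$conf[ci, ][assign[, ci]]
    ener <- ener + pre$ener[ci, ][assign[, ci]]
    nmut <- nmut + as.integer(assign[, ci] != cur_idx[ci])
  }
  for (key in names(pre$pair_conf)) {
    pr <- attr(pre$pair_conf[[key]], "pair")
    idx <- cbind(assign[, pr[1]], assign[, pr[2]])
    conf <- conf + pre$pair_conf[[key]][idx]
    ener <- ener + pre$pair_ener[[key]][idx]
  }
  list(conf = conf, ener = ener, nmut = nmut)
}

assignment_grid <- function(cand_idx) {
  # cand_idx: list of integer vectors (candidate AA indices per position)
  g <- expand.grid(cand_idx, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Group conflict positions into mutation clusters
#'
#' Conflict positions plus their contact partners form a graph (union of the
#' long-fold contacts and the short-fold contacts mapped through the offset);
#' its connected components are the clusters.  Components larger than
#' `max_size` are split greedily by sequence position; singleton components
#' are padded with their highest-contact-count neighbour when possible.
#'
#' @param report A [score_conflicts()] report on the design's current
#'   sequence.
#' @param design The `joint_design` the report was computed on.
#' @param max_size Maximum cluster size (default 6).
#' @return A list of sorted integer vectors of long-frame positions; empty
#'   when the report has no conflicts.
#' @export
find_conflict_clusters <- function(report, design, max_size = 6L) {
  if (report$total_count == 0) return(list())
  emb <- design$embedding
  long_cc <- design$long$contacts
  short_cc <- design$short$contacts
  union_cc <- dplyr::distinct(dplyr::bind_rows(
    long_cc,
    tibble::tibble(i = short_cc$i + emb$offset, j = short_cc$j + emb$offset)
  ))
  conf_pos <- unique(c(report$conflicts$position,
                       report$conflicts$partner[!is.na(report$conflicts$partner)]))
  partners <- unique(c(
    union_cc$j[union_cc$i %in% conf_pos],
    union_cc$i[union_cc$j %in% conf_pos]
  ))
  nodes <- sort(unique(c(conf_pos, partners)))
  # adjacency restricted to nodes
  keep <- union_cc$i %in% nodes & union_cc$j %in% nodes
  ed <- union_cc[keep, ]
  adj <- split(c(ed$j, ed$i), c(ed$i, ed$j))
  comp_of <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  comp <- 0L
  for (v in nodes) {
    if (!is.na(comp_of[as.character(v)])) next
    comp <- comp + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp_of[as.character(u)])) next
      comp_of[as.character(u)] <- comp
      nb <- adj[[as.character(u)]]
      queue <- c(queue, nb[is.na(comp_of[as.character(nb)])])
    }
  }
  comps <- split(as.integer(names(comp_of)), comp_of)
  counts <- tabulate(c(union_cc$i, union_cc$j), nbins = nchar(design$long_sequence))
  out <- list()
  for (cmp in comps) {
    cmp <- sort(cmp)
    if (length(cmp) > max_size) {
      splits <- split(cmp, ceiling(seq_along(cmp) / max_size))
      out <- c(out, unname(splits))
    } else if (length(cmp) == 1L) {
      nb <- unique(c(union_cc$j[union_cc$i == cmp], union_cc$i[union_cc$j == cmp]))
      if (length(nb) > 0) {
        best <- nb[which.max(counts[nb])]
        out <- c(out, list(sort(c(cmp, best))))
      } else {
        out <- c(out, list(cmp))
      }
    } else {
      out <- c(out, list(cmp))
    }
  }
  out
}

#' Resolve a conflict cluster by exhaustive substitution search
#'
#' Searches candidate residue assignments for the cluster positions, scoring
#' each assignment in BOTH fold contexts simultaneously (positions inside the
#' embedding carry a single shared sequence).  An assignment is feasible when
#' it leaves zero conflicts involving the cluster.  Among feasible
#' assignments the choice is lexicographic: fewest mutations from the current
#' sequence first (conserve original residues whenever possible), then lowest
#' summed dual coarse energy (long + short), then alphabetical.  When no
#' feasible assignment exists the minimal-conflict assignment under the same
#' tie-break chain is applied and a warning is raised.
#'
#' @param design A `joint_design`.
#' @param cluster Integer vector of long-frame positions, length at most 6
#'   (split larger components upstream with [find_conflict_clusters()]).
#' @param model An [energy_model()].
#' @param alphabet Candidate alphabet; the current residue at each position is
#'   always included.
#' @param params A [conflict_params()].
#' @param max_assignments Enumeration budget.  Clusters whose full grid
#'   exceeds it are searched in stages of increasing mutation count (the
#'   first objective), stopping at the first feasible stage or when the
#'   budget is exhausted.
#' @return The updated `joint_design` (mutations logged with stage
#'   `"cluster"`).
#' @export
resolve_cluster <- function(design, cluster, model = energy_model(),
                            alphabet = DESIGN_ALPHABET,
                            params = conflict_params(),
                            max_assignments = 60000) {
  cluster <- sort(as.integer(cluster))
  if (length(cluster) > 6L) {
    abort_domain("cluster size %d exceeds 6; split it upstream", length(cluster))
  }
  contexts <- design_contexts(design, params)
  pre <- cluster_precompute(design, cluster, model, params, contexts)
  cand <- purrr::map2(pre$current, seq_along(cluster), function(cur, i) {
    sort(match(unique(c(cur, alphabet)), AA_ALPHABET))
  })
  total <- prod(purrr::map_int(cand, length))
  cur_idx <- match(pre$current, AA_ALPHABET)
  if (total <= max_assignments) {
    assign <- assignment_grid(cand)
    ev <- evaluate_assignments(pre, assign)
  } else {
    # staged by mutation count; early exit at first feasible stage
    assign <- matrix(cur_idx, nrow = 1)
    ev <- evaluate_assignments(pre, assign)
    budget <- max_assignments
    k <- length(cluster)
    for (m in seq_len(k)) {
      stage_rows <- list()
      for (posset in utils::combn(k, m, simplify = FALSE)) {
        per <- purrr::map(seq_len(k), function(i) {
          if (i %in% posset) setdiff(cand[[i]], cur_idx[i]) else cur_idx[i]
        })
        stage_rows[[length(stage_rows) + 1L]] <- assignment_grid(per)
      }
      stage <- do.call(rbind, stage_rows)
      if (nrow(stage) > budget) {
        rlang::warn(sprintf(
          "cluster search budget exhausted at %d mutation(s); result may be suboptimal", m - 1L))
        break
      }
      budget <- budget - nrow(stage)
      sev <- evaluate_assignments(pre, stage)
      assign <- rbind(assign, stage)
      ev <- list(conf = c(ev$conf, sev$conf), ener = c(ev$ener, sev$ener),
                 nmut = c(ev$nmut, sev$nmut))
      if (any(sev$conf == 0)) break
    }
  }
  feasible <- ev$conf == 0
  idx <- if (any(feasible)) which(feasible) else seq_along(ev$conf)
  if (!any(feasible)) {
    rlang::warn(sprintf(
      "cluster %s infeasible: best assignment leaves %d conflict(s)",
      paste(cluster, collapse = ","), min(ev$conf)
    ))
    idx <- idx[ev$conf[idx] == min(ev$conf[idx])]
  }
  idx <- idx[ev$nmut[idx] == min(ev$nmut[idx])]
  idx <- idx[ev$ener[idx] <= min(ev$ener[idx]) + 1e-9]
  if (length(idx) > 1) {
    strings <- apply(assign[idx, , drop = FALSE], 1,
                     function(r) paste(AA_ALPHABET[r], collapse = ""))
    idx <- idx[order(strings)][1]
  }
  chosen <- AA_ALPHABET[assign[idx[1], ]]
  log_mutations(design, cluster, chosen, stage = "cluster")
}

#' Resolve every conflict cluster of a design
#'
#' Scores the current sequence, groups conflicts into clusters and resolves
#' each in turn, repeating until no resolvable conflicts remain or
#' `max_rounds` is reached.
#'
#' @inheritParams resolve_cluster
#' @param max_rounds Maximum score-cluster-resolve rounds (default 5).
#' @return The updated design; `design$conflict_history` records the conflict
#'   count after each round.
#' @export
resolve_all_conflicts <- function(design, model = energy_model(),
                                  alphabet = DESIGN_ALPHABET,
                                  params = conflict_params(),
                                  max_rounds = 5L,
                                  max_assignments = 60000) {
  history <- integer(0)
  for (round in seq_len(max_rounds)) {
    rep <- score_conflicts(design$embedding, design$long, design$short,
                           design$long_sequence, params)
    history <- c(history, rep$total_count)
    if (rep$total_count == 0) break
    clusters <- find_conflict_clusters(rep, design)
    before <- design$long_sequence
    for (cl in clusters) {
      design <- resolve_cluster(design, cl, model, alphabet, params,
                                max_assignments)
    }
    if (identical(design$long_sequence, before)) break
  }
  design$conflict_history <- history
  design
}

#' Optimise non-overlapping positions for long-fold stability
#'
#' Greedy single-position sweeps restricted to positions OUTSIDE the embedded
#' window.  A substitution is accepted iff it strictly lowers the long-fold
#' coarse energy and introduces no new conflict; sweeps repeat until a full
#' sweep accepts nothing or `max_sweeps` is reached.  The embedded window is
#' bit-identical before and after.
#'
#' @inheritParams resolve_cluster
#' @param max_sweeps Maximum sweeps (default 20).
#' @return Updated design; `design$optimization` records sweeps used,
#'   convergence and the energy trajectory.
#' @export
optimize_nonoverlap <- function(design, model = energy_model(),
                                alphabet = DESIGN_ALPHABET,
                                params = conflict_params(),
                                max_sweeps = 20L) {
  emb <- design$embedding
  outside <- setdiff(seq_len(design$long$length), emb$start:emb$end)
  contexts <- design_contexts(design, params)
  energies <- coarse_energy(design$long_sequence, design$long, model)
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    accepted_any <- FALSE
    for (p in outside) {
      chars <- seq_chars(design$long_sequence)
      cur <- chars[p]
      pre <- cluster_precompute(design, p, model, params, contexts, dual = FALSE)
      cand_letters <- setdiff(unique(alphabet), cur)
      cand_i <- match(cand_letters, AA_ALPHABET)
      delta <- pre$ener[1, cand_i] - pre$ener[1, match(cur, AA_ALPHABET)]
      ord <- order(delta)
      before_keys <- local_conflict_keys(p, cur, chars, contexts, params)
      for (oi in ord) {
        if (delta[oi] >= -1e-9) break
        letter <- cand_letters[oi]
        after_keys <- local_conflict_keys(p, letter, chars, contexts, params)
        if (length(setdiff(after_keys, before_keys)) > 0) next
        design <- log_mutations(design, p, letter, stage = "nonoverlap")
        energies <- c(energies, utils::tail(energies, 1) + delta[oi])
        accepted_any <- TRUE
        break
      }
    }
    if (!accepted_any) {
      converged <- TRUE
      break
    }
  }
  design$optimization <- list(sweeps = sweeps, converged = converged,
                              energy_trajectory = energies)
  design
}

parse_mutation <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))[[1]]
  if (length(m) != 4) abort_domain("cannot parse mutation '%s' (expected e.g. 'Y5L')", x)
  tibble::tibble(position = as.integer(m[3]), from = m[2], to = m[4])
}

#' Apply named point mutations to a design
#'
#' Each mutation's `from` residue must match the current sequence (guards
#' against stale coordinates).  Mutations inside the embedded window change
#' the derived short construct too; the log records this via `in_window`.
#'
#' @param design A `joint_design`.
#' @param mutations A tibble with columns `position`, `from`, `to`; or a
#'   character vector of compact mutation names such as `"Y5L"`.  May be
#'   empty.
#' @param name New design name; default appends the mutation names.
#' @return The renamed, mutated design (stage `"variant"` in the log).
#' @export
apply_variant <- function(design, mutations, name = NULL) {
  if (is.character(mutations)) {
    mutations <- purrr::map_dfr(mutations, parse_mutation)
  }
  mutations <- tibble::as_tibble(mutations)
  if (nrow(mutations) > 0) {
    chars <- seq_chars(design$long_sequence)
    bad <- which(chars[mutations$position] != mutations$from)
    if (length(bad) > 0) {
      abort_domain(
        "variant '%s%d%s' does not match current residue '%s' at position %d",
        mutations$from[bad[1]], mutations$position[bad[1]], mutations$to[bad[1]],
        chars[mutations$position[bad[1]]], mutations$position[bad[1]]
      )
    }
    design <- log_mutations(design, mutations$position, mutations$to,
                            stage = "variant")
  }
  design$name <- name %||%
    paste0(design$name,
           if (nrow(mutations) > 0) {
             paste0("_", paste0(mutations$from, mutations$position, mutations$to,
                                collapse = "_"))
           } else "_variant")
  design
}

#' Replace C-terminal residues with a functional tail
#'
#' `result = sequence[1 .. len - n_replace] + tail`; used e.g. to graft a
#' protease-binding tail (such as `DKLYRAL`) onto a designed scaffold.  For a
#' `joint_design` the graft must not reach into the embedded window, so the
#' short construct is unchanged.
#'
#' @param x An amino acid string or a `joint_design`.
#' @param n_replace Number of C-terminal residues to replace (0 = append).
#' @param tail Non-empty tail sequence.
#' @param ... Unused.
#' @return Same type as `x`.
#' @export
#' @examples
#' graft_cterminal_tail("AKLVAAD", 3, "DKLYRAL")
graft_cterminal_tail <- function(x, n_replace, tail, ...) {
  UseMethod("graft_cterminal_tail")
}

#' @export
graft_cterminal_tail.character <- function(x, n_replace, tail, ...) {
  if (nchar(tail) == 0) abort_domain("tail must be non-empty")
  check_sequence(tail, "tail")
  n <- nchar(x)
  if (n_replace > n) abort_domain("n_replace (%d) exceeds sequence length (%d)",
                                  n_replace, n)
  paste0(substr(x, 1, n - n_replace), tail)
}

#' @export
graft_cterminal_tail.joint_design <- function(x, n_replace, tail, ...) {
  n <- nchar(x$long_sequence)
  if (n - n_replace < x$embedding$end) {
    abort_domain("tail graft would cut into the embedded window (ends at %d)",
                 x$embedding$end)
  }
  new_seq <- graft_cterminal_tail(x$long_sequence, n_replace, tail)
  pos <- n - n_replace + 1L
  x$mutation_log <- dplyr::bind_rows(
    x$mutation_log,
    tibble::tibble(position = as.integer(pos),
                   from = substr(x$long_sequence, pos, n),
                   to = tail, stage = "tail_graft", in_window = FALSE)
  )
  x$long_sequence <- new_seq
  x
}

#' Percent sequence identity over a gap-free alignment
#'
#' Positional identity over an embedding-defined alignment (no gaps); both
#' the raw percentage and its nearest-integer rounding are reported.
#'
#' @param a,b Amino acid strings of equal length.
#' @return One-row tibble: `matches`, `length`, `identity` (0-100, raw) and
#'   `identity_rounded`.
#' @export
#' @examples
#' percent_identity("AKLV", "AKIV")
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort_domain("sequences differ in length (%d vs %d)", nchar(a), nchar(b))
  }
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  matches <- sum(ca == cb)
  pct <- 100 * matches / length(ca)
  tibble::tibble(
    matches = matches, length = length(ca),
    identity = pct, identity_rounded = round(pct)
  )
}
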