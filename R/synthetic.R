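#' Specification of a synthetic fold pair with a planted embedding
#'
#' The generator guarantees that the merged sequence at `planted_offset`
#' scores exactly `n_planted_conflicts` catastrophic interactions while every
#' other valid offset scores at least `decoy_conflict_floor`, so the planted
#' alignment is recoverable at rank 1 by construction.
#'
#' @param long_length,short_length Residue counts (short fits inside long;
#'   the default pair mimics a ~56-residue domain embedded in a ~90-residue
#'   scaffold).
#' @param anchor_kind,anchor_length Kind (`"helix"`/`"strand"`) and length of
#'   the shared anchor element present in both folds.
#' @param planted_offset The embedding offset the generator makes optimal.
#' @param n_planted_conflicts Conflicts present at the planted offset.
#' @param decoy_conflict_floor Minimum conflicts at every other valid offset;
#'   must exceed `n_planted_conflicts`.
#' @param seed Integer RNG seed; the generator is a pure function of the
#'   spec.
#' @return A list of class `toy_fold_spec`.
#' @export
toy_fold_spec <- function(long_length = 90L, short_length = 56L,
                          anchor_kind = "helix", anchor_length = 16L,
                          planted_offset = 10L, n_planted_conflicts = 3L,
                          decoy_conflict_floor = 6L, seed = 1L) {
  if (short_length > long_length) abort_domain("short fold longer than long fold")
  if (decoy_conflict_floor <= n_planted_conflicts) {
    abort_domain("decoy_conflict_floor must exceed n_planted_conflicts")
  }
  if (!anchor_kind %in% c("helix", "strand")) {
    abort_domain("anchor_kind must be 'helix' or 'strand'")
  }
  if (planted_offset < 0 || short_length + planted_offset > long_length) {
    abort_domain("planted embedding does not fit inside the long fold")
  }
  structure(
    list(long_length = as.integer(long_length),
         short_length = as.integer(short_length),
         anchor_kind = anchor_kind, anchor_length = as.integer(anchor_length),
         planted_offset = as.integer(planted_offset),
         n_planted_conflicts = as.integer(n_planted_conflicts),
         decoy_conflict_floor = as.integer(decoy_conflict_floor),
         seed = as.integer(seed)),
    class = "toy_fold_spec"
  )
}

# Build an ordered element table around a fixed anchor element, filling the
# flanks with alternating helices/strands separated by short loops.
build_toy_topology <- function(total, anchor_kind, anchor_len, anchor_start) {
  anchor_end <- anchor_start + anchor_len - 1L
  if (anchor_start < 1 || anchor_end > total) {
    abort_generation("anchor does not fit in a %d-residue fold", total)
  }
  other <- function(k) if (k == "helix") "strand" else "helix"
  elen <- function(kind) {
    if (kind == "helix") sample(8:11, 1) else sample(5:8, 1)
  }
  fill <- function(lo, hi, first_kind) {
    # fills [lo, hi] leaving loops; returns tibble(kind, start, end)
    out <- list()
    kind <- first_kind
    pos <- lo
    while (hi - pos + 1 >= 5) {
      len <- min(elen(kind), hi - pos + 1)
      out[[length(out) + 1L]] <- tibble::tibble(kind = kind, start = pos,
                                                end = pos + len - 1L)
      pos <- pos + len + sample(2:4, 1)
      kind <- other(kind)
    }
    dplyr::bind_rows(out)
  }
  pre <- fill(2L, anchor_start - 3L, other(anchor_kind))
  post <- fill(anchor_end + 3L, total - 1L, other(anchor_kind))
  anchor <- tibble::tibble(kind = anchor_kind, start = anchor_start,
                           end = anchor_end)
  els <- dplyr::bind_rows(pre, anchor, post)
  els <- dplyr::arrange(els, .data$start)
  els$anchor <- els$start == anchor_start & els$kind == anchor_kind
  els
}

# Idealized 3D layout: strands form a pleated sheet (z near 0, 5.3 A apart),
# helices sit in a layer above on a spiral of radius 2.3 A; chain direction
# alternates within each layer; loops interpolate linearly.  Spacings are
# tuned so that an 8 A C-beta cutoff yields protein-like contact numbers
# (packed faces high, outward faces low).
layout_toy_coords <- function(els, total) {
  coords <- matrix(NA_real_, nrow = total, ncol = 3)
  strands <- which(els$kind == "strand")
  helices <- which(els$kind == "helix")
  strand_dx <- 5.6
  helix_dx <- 11.0
  sheet_width <- max(1, length(strands) - 1) * strand_dx
  hx0 <- sheet_width / 2 - (max(1, length(helices) - 1) * helix_dx) / 2
  for (k in seq_len(nrow(els))) {
    el <- els[k, ]
    idx <- el$start:el$end
    n <- length(idx)
    mid <- (n + 1) / 2
    y0 <- 4.0 * (k %% 3 - 1)  # stagger midpoints so elements overlap partially
    if (el$kind == "strand") {
      s <- match(k, strands)
      dir <- if (s %% 2 == 1) 1 else -1
      x <- strand_dx * (s - 1)
      y <- y0 + (seq_len(n) - mid) * 3.3 * dir
      pleat <- 1.4 * rep_len(c(1, -1), n)  # side chains alternate sheet faces
      coords[idx, ] <- cbind(x, y, pleat)
    } else {
      h <- match(k, helices)
      dir <- if (h %% 2 == 1) 1 else -1
      x0 <- hx0 + helix_dx * (h - 1)
      theta <- (seq_len(n) - 1) * 100 * pi / 180
      y <- y0 + (seq_len(n) - mid) * 1.5 * dir
      coords[idx, ] <- cbind(x0 + 2.3 * cos(theta), y, 6.8 + 2.3 * sin(theta))
    }
  }
  # loops between consecutive elements: interpolate, then bulge outwards
  # (away from the element centroid in the x-z plane) as real loops point
  # into solvent rather than cutting through the core
  element_idx <- unlist(purrr::map2(els$start, els$end, seq))
  centroid_xz <- c(mean(coords[element_idx, 1]), mean(coords[element_idx, 3]))
  for (k in seq_len(nrow(els) - 1)) {
    a <- els$end[k]
    b <- els$start[k + 1]
    if (b - a <= 1) next
    gap <- (a + 1):(b - 1)
    for (m in seq_along(gap)) {
      t <- m / (length(gap) + 1)
      p <- coords[a, ] * (1 - t) + coords[b, ] * t
      d <- c(p[1] - centroid_xz[1], 0, p[3] - centroid_xz[2])
      nd <- sqrt(sum(d^2))
      d <- if (nd < 1e-6) c(0, 0, -1) else d / nd
      coords[gap[m], ] <- p + d * 6.0 * sin(pi * t)
    }
  }
  # termini extended outwards
  first <- els$start[1]
  if (first > 1) {
    d <- coords[first, ] - coords[first + 1, ]
    d <- d / sqrt(sum(d^2))
    for (m in seq_len(first - 1)) {
      coords[first - m, ] <- coords[first, ] + d * 3.3 * m
    }
  }
  last <- els$end[nrow(els)]
  if (last < total) {
    d <- coords[last, ] - coords[last - 1, ]
    d <- d / sqrt(sum(d^2))
    for (m in seq_len(total - last)) {
      coords[last + m, ] <- coords[last, ] + d * 3.3 * m
    }
  }
  coords
}

sample_residues_by_burial <- function(burial) {
  vapply(burial, function(b) {
    switch(b,
      core = sample(c("L", "I", "V", "F"), 1, prob = c(0.35, 0.3, 0.2, 0.15)),
      boundary = sample(c("A", "T", "S", "V", "L"), 1),
      surface = sample(c("E", "K", "D", "R", "N", "Q", "S", "T"), 1,
                       prob = c(0.22, 0.22, 0.12, 0.08, 0.09, 0.09, 0.09, 0.09))
    )
  }, character(1))
}

build_toy_template <- function(name, total, anchor_kind, anchor_len,
                               anchor_start, policy = burial_policy()) {
  els <- build_toy_topology(total, anchor_kind, anchor_len, anchor_start)
  coords <- layout_toy_coords(els, total)
  contacts <- contacts_from_coordinates(coords, cutoff = 8, min_seq_sep = 3L)
  greek <- c(helix = "α", strand = "β")
  idx <- stats::ave(seq_len(nrow(els)), els$kind, FUN = seq_along)
  labels <- paste0(greek[els$kind], idx)
  # the anchor element is always labelled α1 / β1 in both folds
  anchor_row <- which(els$anchor)
  anchor_label <- paste0(greek[anchor_kind], 1)
  labels[labels == anchor_label & seq_along(labels) != anchor_row] <-
    paste0(greek[anchor_kind], "x")
  labels[anchor_row] <- anchor_label
  elements <- secondary_elements(els$kind, els$start, els$end, labels)
  tmpl <- fold_template(
    name = name, length = total, elements = elements, contacts = contacts,
    ref_sequence = paste(rep("A", total), collapse = ""), policy = policy
  )
  tmpl$ref_sequence <- paste(sample_residues_by_burial(tmpl$burial),
                             collapse = "")
  tmpl
}

#' Generate a toy fold pair with a planted embedding
#'
#' Both templates carry geometrically coherent topologies, contact maps
#' (derived from an idealized 3D layout of the elements), burial classes and
#' reference sequences.  The short fold's reference sequence is constructed
#' to be conflict-free against both contexts at the planted offset, after
#' which exactly `n_planted_conflicts` buried-polar conflicts are introduced
#' at positions that are core in exactly one fold.  Layouts are retried (up
#' to `max_attempts`) until every other valid offset scores at least
#' `decoy_conflict_floor` conflicts.  Deterministic per seed.
#'
#' @param spec A [toy_fold_spec()].
#' @param max_attempts Layout retries before giving up (default 100).
#' @return A list with elements `long`, `short` (fold templates), `truth`
#'   (the planted [embedding()]), `anchor` (its label) and `attempts`.
#' @export
#' @examples
#' pair <- make_fold_pair(toy_fold_spec(seed = 7))
#' pair$truth$offset
make_fold_pair <- function(spec, max_attempts = 100L) {
  stopifnot(inherits(spec, "toy_fold_spec"))
  withr::with_seed(spec$seed, {
    greek <- c(helix = "α", strand = "β")
    anchor_label <- paste0(greek[spec$anchor_kind], 1)
    for (attempt in seq_len(max_attempts)) {
      res <- tryCatch(
        make_fold_pair_attempt(spec, anchor_label),
        foldswitch_generation_error = function(e) NULL
      )
      if (!is.null(res)) {
        res$attempts <- attempt
        return(res)
      }
    }
    abort_generation(
      "could not satisfy the fold-pair spec in %d attempts; loosen decoy_conflict_floor or lengths",
      max_attempts
    )
  })
}

make_fold_pair_attempt <- function(spec, anchor_label) {
  # anchor placement: inside the short fold with room on both sides, and at
  # the planted offset inside the long fold
  a_short_min <- 5L
  a_short_max <- spec$short_length - spec$anchor_length - 7L
  if (a_short_max < a_short_min) {
    abort_generation("anchor too long for the short fold")
  }
  a_short <- if (a_short_min == a_short_max) a_short_min else
    sample(seq(a_short_min, a_short_max), 1)
  a_long <- a_short + spec$planted_offset
  if (a_long + spec$anchor_length + 7L > spec$long_length) {
    abort_generation("anchor does not fit the long fold at the planted offset")
  }
  long <- build_toy_template("toy_long", spec$long_length, spec$anchor_kind,
                             spec$anchor_length, a_long)
  short <- build_toy_template("toy_short", spec$short_length, spec$anchor_kind,
                              spec$anchor_length, a_short)
  # short reference sequence compatible with BOTH contexts at the plant
  off <- spec$planted_offset
  q <- seq_len(spec$short_length)
  core_long <- long$burial[q + off] == "core"
  core_short <- short$burial == "core"
  sref <- character(spec$short_length)
  for (k in q) {
    sref[k] <- if (core_long[k] || core_short[k]) {
      sample(c("L", "I", "V"), 1)
    } else {
      # not core in either context: polar-rich exterior (boundary positions
      # tolerate polar residues; only core positions reject them)
      sample(c("E", "K", "D", "N", "Q", "S", "T", "A"), 1,
             prob = c(0.22, 0.22, 0.12, 0.1, 0.1, 0.08, 0.08, 0.08))
    }
  }
  # plant conflicts at positions core in exactly ONE fold context
  eligible <- which(xor(core_long, core_short))
  if (length(eligible) < spec$n_planted_conflicts) {
    abort_generation("not enough single-context core positions to plant conflicts")
  }
  if (spec$n_planted_conflicts > 0) {
    planted <- sort(sample(eligible, spec$n_planted_conflicts))
    sref[planted] <- "K"
  }
  short$ref_sequence <- paste(sref, collapse = "")
  # verify the plant and the decoy floor
  ranks <- tryCatch(
    rank_fold_pair(long, short, anchor_label),
    foldswitch_domain_error = function(e) abort_generation("no valid embeddings")
  )
  if (nrow(ranks) < 3) abort_generation("fewer than 3 candidate offsets")
  at_plant <- ranks$total_count[ranks$offset == off]
  if (length(at_plant) != 1 || at_plant != spec$n_planted_conflicts) {
    abort_generation("planted offset does not score exactly the planted conflicts")
  }
  decoys <- ranks$total_count[ranks$offset != off]
  if (any(decoys < spec$decoy_conflict_floor)) {
    abort_generation("a decoy offset undercuts the conflict floor")
  }
  truth <- embedding(long, short, off, anchor_label)
  list(long = long, short = short, truth = truth, anchor = anchor_label)
}

#' Script a ladder of stabilizing/destabilizing mutations on the linkage node
#'
#' Starting from `(dG_long, dG_switch)`, each effect adds its
#' `(ddG_long, ddG_switch)` increments and the three-state populations are
#' evaluated after every step.  Effects are additive by construction: the
#' total change along a ladder is the sum of its steps.  This emulates a
#' mutation series that first equalizes the two folded states and then tips
#' the construct into the embedded fold.
#'
#' @param dg_long,dg_switch Starting free energies (kcal/mol).
#' @param effects Tibble with columns `name`, `ddg_long`, `ddg_switch` (one
#'   row per mutation), or `NULL` for just the starting state.
#' @param t Temperature in deg C (default 25).
#' @return Tibble with one row per state (`step` = "start" then the effect
#'   names): cumulative `dg_long`, `dg_switch` and populations `f_S`, `f_G`,
#'   `f_U`.
#' @export
#' @examples
#' make_switch_scenario(-3.5, 2.3,
#'   tibble::tibble(name = c("stabilize_G", "destabilize_S"),
#'                  ddg_long = c(0, 2), ddg_switch = c(-2.3, -5)))
make_switch_scenario <- function(dg_long, dg_switch, effects = NULL, t = 25) {
  steps <- tibble::tibble(name = "start", ddg_long = 0, ddg_switch = 0)
  if (!is.null(effects) && nrow(tibble::as_tibble(effects)) > 0) {
    effects <- tibble::as_tibble(effects)
    steps <- dplyr::bind_rows(steps, effects)
  }
  cum_long <- dg_long + cumsum(steps$ddg_long)
  cum_switch <- dg_switch + cumsum(steps$ddg_switch)
  pops <- purrr::map2_dfr(cum_long, cum_switch,
                          ~ three_state_populations(.x, .y, t))
  dplyr::bind_cols(tibble::tibble(step = steps$name), pops)
}

#' Simulate a competitive-inhibition rate table
#'
#' Rates follow the Michaelis-Menten model with the apparent Michaelis
#' constant per inhibitor level, multiplied by lognormal noise of the given
#' coefficient of variation (mean-one, so expected rates stay on-model).
#' The default grids are the standard assay design: substrate 0.1-10 uM,
#' inhibitor 0/50/100 nM.
#'
#' @param v_max Maximal rate.
#' @param k_m Michaelis constant, uM.
#' @param k_i Inhibition constant, nM.
#' @param s_grid Substrate grid, uM.
#' @param i_grid Inhibitor grid, nM.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact rates).
#' @param seed Optional integer seed (RNG state restored).
#' @return A tibble of class `inhibition_data` with columns `inhibitor_nM`,
#'   `substrate_uM`, `rate`; generating parameters are attached as the
#'   `params` attribute.
#' @export
#' @examples
#' simulate_inhibition(noise_cv = 0)
simulate_inhibition <- function(v_max = 100, k_m = 1, k_i = 50,
                                s_grid = c(0.1, 0.5, 1, 2, 5, 10),
                                i_grid = c(0, 50, 100),
                                noise_cv = 0, seed = NULL) {
  if (any(c(v_max, k_m, k_i) <= 0)) abort_domain("parameters must be positive")
  grid <- tidyr::expand_grid(inhibitor_nM = i_grid, substrate_uM = s_grid)
  km_app <- km_apparent(k_m, grid$inhibitor_nM, k_i)
  rate <- v_max * grid$substrate_uM / (km_app + grid$substrate_uM)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    draw <- function() stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog)
    mult <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    rate <- rate * mult
  }
  out <- dplyr::mutate(grid, rate = rate)
  attr(out, "params") <- list(v_max = v_max, k_m = k_m, k_i = k_i,
                              noise_cv = noise_cv)
  class(out) <- c("inhibition_data", class(out))
  out
}

#' Simulate a CD melt with assay-like presets
#'
#' Wraps [simulate_melt()] with the standard scan (20-100 deg C in 0.5 deg
#' steps, matching a 0.5 deg/min continuous scan sampled twice a minute) and
#' noise expressed as a fraction of the transition amplitude.
#'
#' @param t_m,dh_m Midpoint (deg C) and van 't Hoff enthalpy (kcal/mol).
#' @param n_residues Chain length; sets the per-residue heat-capacity change
#'   (0.014 kcal/mol/K per residue).
#' @param noise_frac Gaussian noise as a fraction of the folded-unfolded
#'   amplitude at the midpoint (e.g. 0.02 = 2 percent).
#' @param seed Optional seed.
#' @param baselines A [melt_baselines()].
#' @param t_grid Temperature grid, deg C.
#' @return A `melting_curve` tibble; the generating [thermo_state()] is
#'   attached as the `state` attribute.
#' @export
simulate_melt_preset <- function(t_m = 65, dh_m = 45, n_residues = 56,
                                 noise_frac = 0.02, seed = NULL,
                                 baselines = melt_baselines(),
                                 t_grid = seq(20, 100, by = 0.5)) {
  state <- thermo_state("preset", t_m = t_m, dh_m = dh_m,
                        dcp = 0.014 * n_residues)
  amp <- abs(
    (baselines$folded_intercept + baselines$folded_slope * t_m) -
      (baselines$unfolded_intercept + baselines$unfolded_slope * t_m)
  )
  curve <- simulate_melt(state, baselines, t_grid,
                         noise_sd = noise_frac * amp, seed = seed)
  attr(curve, "state") <- state
  curve
}
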