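pipeline_schema <- function() {
  list(
    name = NULL,
    output_dir = NULL,
    seed = NULL,
    fold_pair = names(formals(toy_fold_spec)),
    embed = c("min_anchor_overlap"),
    design = c("max_sweeps", "max_rounds", "max_assignments"),
    thermo = c("dg_short", "dg_long", "temperature_C"),
    log_level = NULL
  )
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    abort_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (key in names(config)) {
    allowed <- schema[[key]]
    if (is.null(allowed)) next
    if (!is.list(config[[key]]) && !is.null(config[[key]])) {
      abort_config("config key '%s' must be a mapping", key)
    }
    bad <- setdiff(names(config[[key]]), allowed)
    if (length(bad) > 0) {
      abort_config("unknown config key(s) under '%s': %s", key,
                   paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$output_dir)) abort_config("config requires output_dir")
  config
}

pipeline_log <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

#' Run the embed-design-thermo pipeline on a synthetic fold pair
#'
#' Executes the full workflow: generate a toy fold pair with a planted
#' embedding, enumerate and rank embeddings, build and refine a joint design
#' (cluster resolution then non-overlap optimization), and evaluate the
#' thermodynamic linkage/populations.  Each stage's outputs are written
#' before the next starts; a rerun with the same config is byte-identical.
#' A manifest echoing the fully resolved config and package version is
#' written last, so any run can be repeated from its manifest alone.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Top-level keys: `name`, `output_dir` (required), `seed`, and the stage
#'   mappings `fold_pair` (any [toy_fold_spec()] argument), `embed`
#'   (`min_anchor_overlap`), `design` (`max_sweeps`, `max_rounds`,
#'   `max_assignments`), `thermo` (`dg_short`, `dg_long`, `temperature_C`).
#'   Unknown keys are rejected before any stage runs.
#' @param overrides Optional named list merged over the file config (deeper
#'   mappings are replaced key-wise), mirroring command-line overrides.
#' @return Invisibly, a list with the resolved config, the stage results and
#'   the written file paths.
#' @export
run_pipeline <- function(config, overrides = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      if (is.list(overrides[[key]]) && is.list(config[[key]])) {
        config[[key]] <- utils::modifyList(config[[key]], overrides[[key]])
      } else {
        config[[key]] <- overrides[[key]]
      }
    }
  }
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  paths <- list()

  # stage 1: synthetic fold pair
  pipeline_log("fold_pair", "generating templates")
  spec_args <- config$fold_pair %||% list()
  spec_args$seed <- spec_args$seed %||% seed
  spec <- do.call(toy_fold_spec, spec_args)
  pair <- make_fold_pair(spec)
  paths$long <- file.path(out_dir, "long.json")
  paths$short <- file.path(out_dir, "short.json")
  write_fold_template(pair$long, paths$long)
  write_fold_template(pair$short, paths$short)

  # stage 2: embedding enumeration + ranking
  pipeline_log("embed", "ranking embeddings")
  min_ov <- (config$embed %||% list())$min_anchor_overlap %||% 4L
  ranks <- rank_fold_pair(pair$long, pair$short, pair$anchor, min_ov)
  ranks_out <- dplyr::mutate(
    dplyr::select(ranks, "rank", "offset", "total_count", "total_severity",
                  "kind_matches"),
    conflicts = purrr::map_chr(ranks$report, function(r) {
      paste(sprintf("%d:%s", r$conflicts$position, r$conflicts$kind),
            collapse = ";")
    })
  )
  paths$ranks <- file.path(out_dir, "ranks.tsv")
  utils::write.table(ranks_out, paths$ranks, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  # stage 3: joint design on the top-ranked embedding
  pipeline_log("design", "resolving conflicts and optimizing")
  dcfg <- config$design %||% list()
  emb <- ranks$report[[1]]$embedding
  design <- merge_initial(emb, pair$long, pair$short,
                          name = config$name %||% "pipeline_design")
  conflicts_initial <- ranks$total_count[1]
  design <- resolve_all_conflicts(
    design, max_rounds = dcfg$max_rounds %||% 5L,
    max_assignments = dcfg$max_assignments %||% 60000
  )
  design <- optimize_nonoverlap(design, max_sweeps = dcfg$max_sweeps %||% 20L)
  final_rep <- score_conflicts(design$embedding, design$long, design$short,
                               design$long_sequence)
  model <- energy_model()
  design_out <- list(
    name = design$name,
    long_sequence = design$long_sequence,
    short_sequence = truncate_to_short(design),
    offset = emb$offset,
    mutation_log = as.data.frame(design$mutation_log),
    conflicts = list(initial = conflicts_initial,
                     history = design$conflict_history,
                     final = final_rep$total_count),
    energies = list(
      long = coarse_energy(design$long_sequence, design$long, model),
      short = coarse_energy(truncate_to_short(design), design$short, model)
    ),
    optimization = design$optimization[c("sweeps", "converged")]
  )
  paths$design <- file.path(out_dir, "design.json")
  jsonlite::write_json(design_out, paths$design, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$fasta <- file.path(out_dir, "design.fasta")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    write_fasta(tibble::tibble(
      name = c(paste0(design$name, "_long"), paste0(design$name, "_short")),
      sequence = c(design$long_sequence, truncate_to_short(design))
    ), paths$fasta)
  } else {
    writeLines(c(paste0(">", design$name, "_long"), design$long_sequence,
                 paste0(">", design$name, "_short"), truncate_to_short(design)),
               paths$fasta)
  }

  # stage 4: thermodynamic linkage
  pipeline_log("thermo", "computing switch free energy and populations")
  tcfg <- config$thermo %||% list(dg_short = -1.2, dg_long = -3.5,
                                  temperature_C = 25)
  dg_switch <- switch_free_energy(tcfg$dg_short, tcfg$dg_long)
  pops <- three_state_populations(tcfg$dg_long, dg_switch,
                                  tcfg$temperature_C %||% 25)
  paths$populations <- file.path(out_dir, "populations.json")
  jsonlite::write_json(as.list(pops), paths$populations, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # manifest: resolved config + version; enough to repeat the run exactly
  resolved <- config
  resolved$seed <- seed
  resolved$fold_pair <- unclass(spec)
  resolved$embed <- list(min_anchor_overlap = min_ov)
  resolved$design <- list(max_rounds = dcfg$max_rounds %||% 5L,
                          max_sweeps = dcfg$max_sweeps %||% 20L,
                          max_assignments = dcfg$max_assignments %||% 60000)
  resolved$thermo <- tcfg
  manifest <- list(
    package = "foldswitch",
    version = as.character(utils::packageVersion("foldswitch")),
    config = resolved,
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(config = resolved, pair = pair, ranks = ranks,
                 design = design, populations = pops, paths = paths))
}
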