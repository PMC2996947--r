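#' Read a declarative pipeline configuration
#'
#' YAML with top-level keys: `kam` (path), `output_dir`, `depth`,
#' `significant_cutoff`, `marginal_cutoff`, `tier_floor`,
#' `require_same_direction`, `perturbation` (`entity`/`aspect`),
#' `min_mapping_rate`, `seed`, and `experiments` — a list of entries with
#' `name`, `expression`, `design`, optional `phospho`, and optional
#' `criteria` (`p_mode`, `p_cutoff`, `min_abs_fold_change`; use `~`/null for
#' no fold criterion). Paths are resolved relative to the config file.
#'
#' @param path YAML file path.
#' @return list of class `rca_config` with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    if (grepl("^/", p)) p else file.path(base, p)
  cfg$kam <- rel(cfg$kam)
  if (is.null(cfg$output_dir)) cfg$output_dir <- file.path(base, "out")
  else cfg$output_dir <- rel(cfg$output_dir)
  if (is.null(cfg$depth)) cfg$depth <- 2
  if (is.null(cfg$significant_cutoff)) cfg$significant_cutoff <- 0.05
  if (is.null(cfg$marginal_cutoff)) cfg$marginal_cutoff <- 0.1
  if (cfg$significant_cutoff > cfg$marginal_cutoff)
    stop("cutoffs must be ordered: significant <= marginal")
  if (is.null(cfg$tier_floor)) cfg$tier_floor <- "significant"
  if (is.null(cfg$require_same_direction)) cfg$require_same_direction <- TRUE
  if (is.null(cfg$min_mapping_rate)) cfg$min_mapping_rate <- 0.25
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$experiments <- lapply(cfg$experiments, function(e) {
    e$expression <- rel(e$expression)
    e$design <- rel(e$design)
    e$phospho <- rel(e$phospho)
    if (is.null(e$criteria)) e$criteria <- list()
    e
  })
  class(cfg) <- "rca_config"
  cfg
}

.criteria_from_list <- function(cl) {
  if (inherits(cl, "change_criteria")) return(cl)
  p_mode <- if (!is.null(cl$p_mode)) cl$p_mode else "adjusted_bh"
  p_cutoff <- if (!is.null(cl$p_cutoff)) cl$p_cutoff else 0.05
  fc <- if ("min_abs_fold_change" %in% names(cl)) cl$min_abs_fold_change else 1.3
  change_criteria(p_mode, p_cutoff, fc)
}

.log <- function(...) message(sprintf(...))

#' Quantify: expression + phospho inputs to state-change tables
#'
#' Runs the state-quantification stage for every experiment in the config:
#' per-gene differential test under the experiment's criteria, phospho ratio
#' thresholding when a phospho table is given, merge, and one state-change
#' TSV per experiment in `output_dir`. Counts (measured, changed,
#' increase/decrease split) are logged.
#'
#' @param config an `rca_config` from [read_pipeline_config()].
#' @return named character vector of written state-change paths, invisibly.
#' @export
cmd_quantify <- function(config) {
  stopifnot(inherits(config, "rca_config"), length(config$experiments) >= 1)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (e in config$experiments) {
    exp <- read_expression_experiment(e$expression, e$design, name = e$name)
    crit <- .criteria_from_list(e$criteria)
    rna <- call_rna_state_changes(exp, crit)
    ph <- NULL
    if (!is.null(e$phospho))
      ph <- call_phospho_state_changes(read_phospho_table(e$phospho))
    merged <- merge_state_changes(rna, ph)
    path <- file.path(config$output_dir, paste0(e$name, "_state_changes.tsv"))
    write_state_changes(merged, path)
    chg <- merged$direction != "no_change"
    .log("[quantify] %s: %d measured, %d changed (%d increase / %d decrease)",
         e$name, nrow(merged), sum(chg),
         sum(merged$direction == "increase"),
         sum(merged$direction == "decrease"))
    out[e$name] <- path
  }
  invisible(out)
}

.load_experiment_changes <- function(config, name) {
  path <- file.path(config$output_dir, paste0(name, "_state_changes.tsv"))
  if (!file.exists(path))
    stop("no state-change table for experiment '", name,
         "' — run cmd_quantify first (expected ", path, ")")
  read_state_changes(path)
}

#' Reverse causal analysis: rank every graph node as a hypothesis
#'
#' For each experiment, evaluates all graph nodes against its state changes
#' and writes a ranked hypothesis report TSV plus prediction-detail tables
#' for the significant roots. Warns (does not fail) when the fraction of
#' measured entities mapping into the graph falls below
#' `config$min_mapping_rate`.
#'
#' @param config an `rca_config`.
#' @param sort_by ranking key for the written report: `"rank"` (the
#'   deterministic default ranking), `"concordance"`, `"richness"`, or `"Q"`.
#' @return invisible list of `rca_experiment` objects.
#' @export
cmd_rca <- function(config, sort_by = c("rank", "concordance", "richness", "Q")) {
  stopifnot(inherits(config, "rca_config"))
  sort_by <- match.arg(sort_by)
  g <- load_kam(config$kam)
  if (nrow(g$nodes) == 0L) warning("empty knowledge graph: empty reports")
  kam_keys <- node_key(g$nodes$entity, g$nodes$aspect)
  exps <- list()
  for (e in config$experiments) {
    changes <- .load_experiment_changes(config, e$name)
    universe <- universe_from_changes(changes)
    mapped <- mean(node_key(universe$entity, universe$aspect) %in% kam_keys)
    if (mapped < config$min_mapping_rate)
      warning(sprintf("experiment %s: only %.1f%% of measured nodes map into the graph",
                      e$name, 100 * mapped))
    hyps <- evaluate_all(g, universe, changes, depth = config$depth,
                         significant_cutoff = config$significant_cutoff,
                         marginal_cutoff = config$marginal_cutoff)
    rep <- hyps
    if (sort_by == "concordance") rep <- rep[order(rep$concordance_p), ]
    if (sort_by == "richness") rep <- rep[order(rep$richness_p), ]
    if (sort_by == "Q") rep <- rep[order(-rep$Q), ]
    path <- file.path(config$output_dir, paste0(e$name, "_hypotheses.tsv"))
    write_hypothesis_report(rep, path)
    sig <- hyps[hyps$tier == "significant", , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      det <- prediction_detail(g, sig$root_entity[i], sig$root_aspect[i],
                               universe, changes, config$depth)
      dpath <- file.path(config$output_dir,
                         sprintf("%s_detail_%s_%s.tsv", e$name,
                                 sig$root_entity[i], sig$root_aspect[i]))
      utils::write.table(det, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .log("[rca] %s: %d hypotheses (%d significant, %d marginal)", e$name,
         nrow(hyps), sum(hyps$tier == "significant"),
         sum(hyps$tier == "marginal"))
    exps[[e$name]] <- rca_experiment(e$name, universe, changes, hyps)
  }
  invisible(exps)
}

#' Assemble the cross-experiment Causal Network Model
#'
#' Intersects significant hypotheses across all experiments, computes the
#' change-overlap table and per-experiment coverage, assembles the merged
#' network, and writes the kamtsv subgraph, JSON annotation sidecar,
#' coverage TSV and overlap report to `output_dir`.
#'
#' @param config an `rca_config`.
#' @param experiments optional list of `rca_experiment` objects (as returned
#'   by [cmd_rca()]); recomputed from the written reports when omitted.
#' @return the `rca_cnm`, invisibly.
#' @export
cmd_cnm <- function(config, experiments = NULL) {
  stopifnot(inherits(config, "rca_config"))
  if (is.null(experiments)) experiments <- cmd_rca(config)
  if (length(experiments) < 1L) stop("need at least one experiment")
  g <- load_kam(config$kam)
  selected <- common_hypotheses(experiments, tier_floor = config$tier_floor,
                                require_same_direction = config$require_same_direction)
  .log("[cnm] %d common root(s) at tier floor '%s'", nrow(selected),
       config$tier_floor)
  cnm <- assemble_cnm(selected, g, experiments, depth = config$depth,
                      perturbation = config$perturbation)
  write_cnm(cnm, config$output_dir)
  if (length(experiments) >= 2L) {
    ov <- change_overlap(experiments)
    write_overlap_report(ov, file.path(config$output_dir, "overlap.tsv"))
    .log("[cnm] full change intersection: %d", ov$full_intersection)
  }
  invisible(cnm)
}

#' Simulate: write a synthetic benchmark fixture
#'
#' Generates the multi-experiment planted-mechanism fixture from the config
#' seed and writes it (graph, matrices, designs, ground-truth manifest) under
#' `output_dir/fixture`, together with a pipeline config YAML pointing at the
#' written files, so `cmd_quantify`/`cmd_rca`/`cmd_cnm` can run on it
#' directly.
#'
#' @param config an `rca_config` (only `output_dir` and `seed` are used) or a
#'   list with those fields.
#' @param n_experiments,shared_change_core fixture shape (defaults 3 and 17).
#' @return path of the written fixture config YAML, invisibly.
#' @export
cmd_simulate <- function(config, n_experiments = 3, shared_change_core = 17) {
  dir <- file.path(config$output_dir, "fixture")
  fx <- make_multi_experiment_fixture(
    n_experiments = n_experiments, shared_change_core = shared_change_core,
    config = sim_config(seed = config$seed))
  paths <- write_fixture(fx, dir)
  ycfg <- list(
    kam = "kam.tsv", output_dir = "out", depth = 2,
    tier_floor = "significant", require_same_direction = TRUE,
    perturbation = fx$truth$perturbation, seed = config$seed,
    experiments = lapply(fx$experiments, function(e) list(
      name = e$name,
      expression = paste0(e$name, "_matrix.tsv"),
      design = paste0(e$name, "_design.tsv"))))
  ypath <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(ycfg, ypath)
  .log("[simulate] fixture written under %s", dir)
  invisible(ypath)
}
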