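## Run code under a local, seeded RNG without touching global RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## Deterministic sub-stream seeds so graph topology, expression noise and
## phospho draws are independent but all derive from one user seed.
.sub_seed <- function(seed, k) ((as.numeric(seed) %% 1000003) * 7919 + k) %% 2147483647

#' Configuration for the synthetic planted-perturbation benchmark
#'
#' Defines a layered signed causal graph (regulator activities feeding RNA
#' abundance leaves), the planted perturbed roots, and the noise model for
#' simulated replicate expression data. The defaults emulate a drug-response
#' comparison: a 2-fold planted effect over log2-normal replicate noise of
#' sd 0.25 with 4 replicates per group.
#'
#' @param n_entities total nodes in the graph excluding phospho substrates
#'   (default 200).
#' @param n_rna_leaves how many of these are RNA-abundance leaves
#'   (default 120); the remainder are protein-activity regulators split into
#'   two layers so a depth-2 search spans regulator-to-leaf chains.
#' @param out_degree causal out-degree of each regulator (default 6).
#' @param inverting_fraction probability an edge is inverting (default 0.3).
#' @param contradiction_rate probability an edge gains an opposite-sign
#'   duplicate, creating ambiguous polarity (default 0.02).
#' @param planted_roots `NULL` (one increased top-layer regulator), a
#'   data.frame with columns `entity`, `direction`, or a zero-row data.frame
#'   for a null (no-signal) simulation.
#' @param effect_fold planted linear fold change (default 2.0).
#' @param noise_sd log2-scale replicate noise standard deviation
#'   (default 0.25).
#' @param n_replicates replicates per group (default 4).
#' @param background_change_rate probability an off-target leaf shifts anyway
#'   (default 0.01).
#' @param n_phospho_per_activity phospho substrate children attached to each
#'   top-layer regulator (default 2).
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `rca_sim_config`.
#' @export
sim_config <- function(n_entities = 200, n_rna_leaves = 120, out_degree = 6,
                       inverting_fraction = 0.3, contradiction_rate = 0.02,
                       planted_roots = NULL, effect_fold = 2.0,
                       noise_sd = 0.25, n_replicates = 4,
                       background_change_rate = 0.01,
                       n_phospho_per_activity = 2, seed = 1) {
  stopifnot(n_entities >= 4, n_rna_leaves >= 1, n_rna_leaves <= n_entities - 2,
            out_degree >= 1, effect_fold > 1, noise_sd >= 0, n_replicates >= 2,
            n_phospho_per_activity >= 0)
  for (pr in c(inverting_fraction, contradiction_rate, background_change_rate))
    stopifnot(pr >= 0, pr <= 1)
  structure(list(n_entities = n_entities, n_rna_leaves = n_rna_leaves,
                 out_degree = out_degree,
                 inverting_fraction = inverting_fraction,
                 contradiction_rate = contradiction_rate,
                 planted_roots = planted_roots, effect_fold = effect_fold,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 background_change_rate = background_change_rate,
                 n_phospho_per_activity = n_phospho_per_activity,
                 seed = as.integer(seed)),
            class = "rca_sim_config")
}

.rand_sign <- function(n, inverting_fraction)
  ifelse(stats::runif(n) < inverting_fraction, -1L, 1L)

## Expected leaf polarities implied by the generator's own layered wiring,
## computed by direct edge-table lookup (independent of the search engine):
## paths from an activity root to a leaf have at most 2 steps by construction.
.planted_leaf_signs <- function(edges, roots) {
  acc <- list()
  add <- function(leaf, s) acc[[leaf]] <<- union(acc[[leaf]], s)
  for (i in seq_len(nrow(roots))) {
    dr <- if (roots$direction[i] == "increase") 1L else -1L
    e1 <- edges[edges$source_entity == roots$entity[i] &
                  edges$source_aspect == "protein_activity", , drop = FALSE]
    for (r in seq_len(nrow(e1))) {
      if (e1$target_aspect[r] == "rna_abundance") {
        add(e1$target_entity[r], dr * e1$sign[r])
      } else if (e1$target_aspect[r] == "protein_activity") {
        e2 <- edges[edges$source_entity == e1$target_entity[r] &
                      edges$source_aspect == "protein_activity" &
                      edges$target_aspect == "rna_abundance", , drop = FALSE]
        for (r2 in seq_len(nrow(e2)))
          add(e2$target_entity[r2], dr * e1$sign[r] * e2$sign[r2])
      }
    }
  }
  acc
}

.signs_to_truth <- function(acc) {
  if (!length(acc)) {
    return(list(leaf_truth = data.frame(entity = character(),
                                        expected_direction = character(),
                                        stringsAsFactors = FALSE),
                conflicted = character()))
  }
  n_signs <- vapply(acc, length, integer(1))
  conflicted <- sort(names(acc)[n_signs == 2L])
  un <- names(acc)[n_signs == 1L]
  lt <- data.frame(entity = un,
                   expected_direction = ifelse(unlist(acc[un]) > 0,
                                               "increase", "decrease"),
                   stringsAsFactors = FALSE)
  lt <- lt[order(lt$entity), , drop = FALSE]
  rownames(lt) <- NULL
  list(leaf_truth = lt, conflicted = conflicted)
}

#' Generate a layered signed causal graph with planted ground truth
#'
#' Builds a directed acyclic graph of two protein-activity regulator layers
#' over RNA-abundance leaves (top layer wires into the second layer and
#' leaves; second layer wires into leaves), with inverting edges at the
#' requested fraction and deliberate contradictory edge pairs at the
#' contradiction rate. Phospho substrate children hang off top-layer
#' regulators. The ground truth records, for every leaf downstream of a
#' planted root, the expected state-change direction implied by the path-sign
#' products — computed from the layer wiring itself, independently of the
#' search engine — and which leaves are reachable with both polarities
#' (conflicted, hence expected unshifted).
#'
#' @param config an [sim_config] object.
#' @return list of class `rca_sim`: `kam`, `truth` (list: `planted_roots`,
#'   `leaf_truth`, `conflicted_leaves`, `phospho_truth`), `config`.
#' @export
generate_kam <- function(config) {
  stopifnot(inherits(config, "rca_sim_config"))
  n_upper <- config$n_entities - config$n_rna_leaves
  n_l1 <- ceiling(n_upper / 2)
  n_l2 <- n_upper - n_l1
  l1 <- sprintf("REG%03d", seq_len(n_l1))
  l2 <- if (n_l2) sprintf("MED%03d", seq_len(n_l2)) else character()
  leaves <- sprintf("G%04d", seq_len(config$n_rna_leaves))
  if (config$out_degree > n_l2 + config$n_rna_leaves ||
      config$out_degree > config$n_rna_leaves)
    stop("infeasible configuration: out_degree exceeds available targets")

  edges <- .with_seed(.sub_seed(config$seed, 1L), {
    rows <- list()
    l1_targets <- c(l2, leaves)
    l1_aspects <- c(rep("protein_activity", n_l2),
                    rep("rna_abundance", config$n_rna_leaves))
    for (i in seq_len(n_l1)) {
      pick <- sample.int(length(l1_targets), config$out_degree)
      rows[[length(rows) + 1L]] <- data.frame(
        source_entity = l1[i], source_aspect = "protein_activity",
        sign = .rand_sign(config$out_degree, config$inverting_fraction),
        target_entity = l1_targets[pick], target_aspect = l1_aspects[pick],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_l2)) {
      pick <- sample.int(config$n_rna_leaves, config$out_degree)
      rows[[length(rows) + 1L]] <- data.frame(
        source_entity = l2[i], source_aspect = "protein_activity",
        sign = .rand_sign(config$out_degree, config$inverting_fraction),
        target_entity = leaves[pick], target_aspect = "rna_abundance",
        stringsAsFactors = FALSE)
    }
    e <- do.call(rbind, rows)
    flip <- stats::runif(nrow(e)) < config$contradiction_rate
    if (any(flip)) {
      dup <- e[flip, , drop = FALSE]
      dup$sign <- -dup$sign
      e <- rbind(e, dup)
    }
    if (config$n_phospho_per_activity > 0) {
      subs <- list()
      for (i in seq_len(n_l1)) {
        ent <- sprintf("PS%03d_%d", i, seq_len(config$n_phospho_per_activity))
        subs[[i]] <- data.frame(
          source_entity = l1[i], source_aspect = "protein_activity",
          sign = 1L, target_entity = ent,
          target_aspect = "protein_modification", stringsAsFactors = FALSE)
      }
      e <- rbind(e, do.call(rbind, subs))
    }
    e
  })

  nodes <- data.frame(
    entity = c(l1, l2, leaves, edges$target_entity),
    aspect = c(rep("protein_activity", n_upper),
               rep("rna_abundance", config$n_rna_leaves),
               edges$target_aspect),
    stringsAsFactors = FALSE)
  g <- kam(nodes, edges, name = sprintf("sim_seed%d", config$seed))

  roots <- config$planted_roots
  if (is.null(roots))
    roots <- data.frame(entity = l1[1], direction = "increase",
                        stringsAsFactors = FALSE)
  roots <- as.data.frame(roots, stringsAsFactors = FALSE)
  if (nrow(roots)) {
    stopifnot(all(c("entity", "direction") %in% names(roots)),
              all(roots$direction %in% c("increase", "decrease")),
              all(roots$entity %in% c(l1, l2)))
  }
  acc <- .planted_leaf_signs(g$edges, roots)
  tr <- .signs_to_truth(acc)
  ## phospho substrates of inhibited planted roots are expected to dephosphorylate
  ph <- g$edges[g$edges$target_aspect == "protein_modification" &
                  g$edges$source_entity %in% roots$entity[roots$direction == "decrease"],
                , drop = FALSE]
  phospho_truth <- data.frame(entity = ph$target_entity,
                              expected_direction = rep("decrease", nrow(ph)),
                              stringsAsFactors = FALSE)
  truth <- list(planted_roots = data.frame(entity = roots$entity,
                                           aspect = rep("protein_activity", nrow(roots)),
                                           direction = roots$direction,
                                           stringsAsFactors = FALSE),
                leaf_truth = tr$leaf_truth,
                conflicted_leaves = tr$conflicted,
                phospho_truth = phospho_truth)
  structure(list(kam = g, truth = truth, config = config), class = "rca_sim")
}

.leaf_shifts <- function(sim, leaves) {
  shift <- stats::setNames(numeric(length(leaves)), leaves)
  lt <- sim$truth$leaf_truth
  d <- log2(sim$config$effect_fold)
  shift[lt$entity] <- ifelse(lt$expected_direction == "increase", d, -d)
  shift
}

#' Simulate a replicate expression experiment from planted ground truth
#'
#' Control replicates are baseline plus log2-normal noise; treated replicates
#' of leaves downstream of the planted roots are shifted by
#' `±log2(effect_fold)` per their expected direction. Conflicted leaves
#' (ambiguous polarity) stay unshifted. Off-target leaves shift in a random
#' direction with probability `background_change_rate`. Fully reproducible
#' from the config seed.
#'
#' @param sim an `rca_sim` object from [generate_kam()].
#' @param name experiment name (default derived from the seed).
#' @return an [expression_experiment]; attribute `"background_changes"`
#'   records the off-target shifted leaves and their directions.
#' @export
simulate_expression <- function(sim, name = NULL) {
  stopifnot(inherits(sim, "rca_sim"))
  cfg <- sim$config
  leaves <- sim$kam$nodes$entity[sim$kam$nodes$aspect == "rna_abundance"]
  leaves <- sort(leaves)
  if (is.null(name)) name <- sprintf("sim_expr_seed%d", cfg$seed)
  .with_seed(.sub_seed(cfg$seed, 2L), {
    nl <- length(leaves)
    nr <- cfg$n_replicates
    baseline <- stats::rnorm(nl, mean = 8, sd = 1.5)
    shift <- .leaf_shifts(sim, leaves)
    off <- setdiff(leaves, c(sim$truth$leaf_truth$entity,
                             sim$truth$conflicted_leaves))
    bg <- off[stats::runif(length(off)) < cfg$background_change_rate]
    bg_dir <- character()
    if (length(bg)) {
      s <- ifelse(stats::runif(length(bg)) < 0.5, 1, -1)
      shift[bg] <- s * log2(cfg$effect_fold)
      bg_dir <- stats::setNames(ifelse(s > 0, "increase", "decrease"), bg)
    }
    m <- matrix(0, nl, 2 * nr,
                dimnames = list(leaves, c(sprintf("C%d", seq_len(nr)),
                                          sprintf("T%d", seq_len(nr)))))
    m[, seq_len(nr)] <- baseline + stats::rnorm(nl * nr, 0, cfg$noise_sd)
    m[, nr + seq_len(nr)] <- baseline + shift +
      stats::rnorm(nl * nr, 0, cfg$noise_sd)
    design <- data.frame(sample = colnames(m),
                         group = rep(c("control", "treated"), each = nr),
                         stringsAsFactors = FALSE)
    out <- expression_experiment(m, design, name = name)
    attr(out, "background_changes") <- bg_dir
    out
  })
}

#' Simulate a phosphoprotein ratio table from planted ground truth
#'
#' Modification substrates of inhibited (decreased) planted roots get
#' treated/vehicle ratios drawn below the 20-percent-decrease threshold
#' (uniform on 0.40–0.78); every other substrate gets a ratio near 1
#' (uniform on 0.85–1.40, inside the no-change band). Seeded and
#' reproducible.
#'
#' @param sim an `rca_sim` object.
#' @param timepoint label attached to every row (default `"24h"`).
#' @return data.frame `entity`, `modification`, `timepoint`, `ratio`.
#' @export
simulate_phospho <- function(sim, timepoint = "24h") {
  stopifnot(inherits(sim, "rca_sim"))
  mods <- sort(sim$kam$nodes$entity[sim$kam$nodes$aspect == "protein_modification"])
  .with_seed(.sub_seed(sim$config$seed, 3L), {
    down <- mods %in% sim$truth$phospho_truth$entity
    ratio <- ifelse(down, stats::runif(length(mods), 0.40, 0.78),
                    stats::runif(length(mods), 0.85, 1.40))
    data.frame(entity = mods, modification = "phospho",
               timepoint = timepoint, ratio = ratio, stringsAsFactors = FALSE)
  })
}

#' Multi-experiment fixture with a planted common mechanism
#'
#' Builds one shared knowledge graph and `n_experiments` simulated expression
#' experiments that echo the cross-experiment structure the method targets:
#' a small chain of common-mechanism regulators drives an exactly shared core
#' of `shared_change_core` (entity, direction) pairs — roughly one third of
#' each experiment's changes — while private regulators and private
#' background changes, drawn from per-experiment disjoint leaf pools, make
#' the overall change sets largely non-overlapping. A distinguished compound
#' perturbation node (`CMPD`) feeds the common regulators. The generator
#' guarantees the core: replicate noise for a core gene is re-drawn (bounded
#' retries) if the default calling criteria would miss it.
#'
#' @param n_experiments number of experiments (default 3).
#' @param shared_mechanism_size number of common regulators (default 3).
#' @param private_mechanism_size private regulators per experiment
#'   (default 2).
#' @param shared_change_core size of the exactly shared changed core
#'   (default 17).
#' @param config an [sim_config]; `n_rna_leaves`, noise and replicate
#'   settings, `inverting_fraction`, `background_change_rate` and `seed` are
#'   used.
#' @return list of class `rca_multi_fixture`: `kam`, `experiments` (each a
#'   list `name`, `expression`), `truth` (`common_roots`, `private_roots`,
#'   `core_pairs`, `backbone_edges`, `perturbation`, per-experiment
#'   `leaf_truth`), `config`.
#' @export
make_multi_experiment_fixture <- function(n_experiments = 3,
                                          shared_mechanism_size = 3,
                                          private_mechanism_size = 2,
                                          shared_change_core = 17,
                                          config = sim_config()) {
  stopifnot(inherits(config, "rca_sim_config"), n_experiments >= 1,
            shared_mechanism_size >= 1, private_mechanism_size >= 0,
            shared_change_core >= 1)
  L <- config$n_rna_leaves
  leaves <- sprintf("G%04d", seq_len(L))
  if (shared_change_core >= L) stop("infeasible counts: core exceeds leaf count")
  pool_size <- (L - shared_change_core) %/% n_experiments
  leaves_per_private <- if (private_mechanism_size > 0)
    max(1L, (2L * shared_change_core - 2L) %/% private_mechanism_size) else 0L
  if (private_mechanism_size * leaves_per_private > pool_size)
    stop("infeasible counts: private mechanisms exceed per-experiment leaf pool")

  cmn <- sprintf("CMN%02d", seq_len(shared_mechanism_size))
  cmn_dir <- ifelse(seq_len(shared_mechanism_size) %% 2L == 1L,
                    "increase", "decrease")
  cmn_sign <- ifelse(cmn_dir == "increase", 1L, -1L)

  built <- .with_seed(.sub_seed(config$seed, 10L), {
    core <- sort(sample(leaves, shared_change_core))
    rest <- setdiff(leaves, core)
    pools <- split(rest[seq_len(pool_size * n_experiments)],
                   rep(seq_len(n_experiments), each = pool_size))
    ## common roots: round-robin partition of the core, signed edges
    assign_root <- rep_len(seq_len(shared_mechanism_size), shared_change_core)
    esign <- .rand_sign(shared_change_core, config$inverting_fraction)
    edges <- data.frame(
      source_entity = cmn[assign_root], source_aspect = "protein_activity",
      sign = esign, target_entity = core, target_aspect = "rna_abundance",
      stringsAsFactors = FALSE)
    ## cycle the common roots with direction-consistent signs (feedback loop):
    ## each root then also predicts its successor's targets at depth 2, so
    ## every common mechanism carries comparable directional evidence
    if (shared_mechanism_size > 1L) {
      i <- seq_len(shared_mechanism_size)
      nxt <- c(i[-1L], 1L)
      edges <- rbind(edges, data.frame(
        source_entity = cmn[i], source_aspect = "protein_activity",
        sign = cmn_sign[i] * cmn_sign[nxt],
        target_entity = cmn[nxt], target_aspect = "protein_activity",
        stringsAsFactors = FALSE))
    }
    ## perturbation compound feeding each common root
    edges <- rbind(edges, data.frame(
      source_entity = "CMPD", source_aspect = "compound",
      sign = cmn_sign, target_entity = cmn, target_aspect = "protein_activity",
      stringsAsFactors = FALSE))
    core_expected <- stats::setNames(
      ifelse(cmn_sign[assign_root] * esign > 0, "increase", "decrease"), core)
    ## private roots per experiment over disjoint pools
    private <- list()
    private_truth <- list()
    for (e in seq_len(n_experiments)) {
      pr <- if (private_mechanism_size > 0)
        sprintf("PRV%d_%02d", e, seq_len(private_mechanism_size)) else character()
      pdir <- ifelse(stats::runif(length(pr)) < 0.5, "increase", "decrease")
      pool <- pools[[e]]
      taken <- 0L
      et <- list()
      for (k in seq_along(pr)) {
        tg <- pool[taken + seq_len(leaves_per_private)]
        taken <- taken + leaves_per_private
        s <- .rand_sign(leaves_per_private, config$inverting_fraction)
        et[[k]] <- data.frame(
          source_entity = pr[k], source_aspect = "protein_activity",
          sign = s, target_entity = tg, target_aspect = "rna_abundance",
          stringsAsFactors = FALSE)
      }
      pe <- if (length(et)) do.call(rbind, et) else NULL
      if (!is.null(pe)) edges <- rbind(edges, pe)
      private[[e]] <- data.frame(entity = pr,
                                 aspect = rep("protein_activity", length(pr)),
                                 direction = pdir, stringsAsFactors = FALSE)
      expd <- character()
      if (!is.null(pe)) {
        ps <- ifelse(pdir == "increase", 1L, -1L)[match(pe$source_entity, pr)]
        expd <- stats::setNames(ifelse(ps * pe$sign > 0, "increase", "decrease"),
                                pe$target_entity)
      }
      private_truth[[e]] <- list(expected = expd,
                                 bg_pool = setdiff(pool, pool[seq_len(taken)]))
    }
    list(core = core, pools = pools, edges = edges,
         core_expected = core_expected, private = private,
         private_truth = private_truth)
  })

  nodes <- data.frame(
    entity = c("CMPD", cmn,
               unlist(lapply(built$private, `[[`, "entity")), leaves),
    aspect = c("compound", rep("protein_activity", length(cmn)),
               rep("protein_activity",
                   sum(vapply(built$private, nrow, integer(1)))),
               rep("rna_abundance", L)),
    stringsAsFactors = FALSE)
  g <- kam(nodes, built$edges, name = sprintf("multi_fixture_seed%d", config$seed))
  backbone <- built$edges[built$edges$source_entity %in% cmn, , drop = FALSE]

  default_crit <- change_criteria()
  experiments <- vector("list", n_experiments)
  leaf_truths <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    expected <- c(built$core_expected, built$private_truth[[e]]$expected)
    experiments[[e]] <- .with_seed(.sub_seed(config$seed, 20L + e), {
      nr <- config$n_replicates
      baseline <- stats::rnorm(L, 8, 1.5)
      names(baseline) <- leaves
      shift <- stats::setNames(numeric(L), leaves)
      shift[names(expected)] <- ifelse(expected == "increase", 1, -1) *
        log2(config$effect_fold)
      bg_pool <- built$private_truth[[e]]$bg_pool
      bg <- bg_pool[stats::runif(length(bg_pool)) < config$background_change_rate]
      if (length(bg)) {
        s <- ifelse(stats::runif(length(bg)) < 0.5, 1, -1)
        shift[bg] <- s * log2(config$effect_fold)
      }
      draw <- function(rows) {
        m <- matrix(0, length(rows), 2 * nr)
        m[, seq_len(nr)] <- baseline[rows] + stats::rnorm(length(rows) * nr, 0, config$noise_sd)
        m[, nr + seq_len(nr)] <- baseline[rows] + shift[rows] +
          stats::rnorm(length(rows) * nr, 0, config$noise_sd)
        m
      }
      m <- draw(leaves)
      dimnames(m) <- list(leaves, c(sprintf("C%d", seq_len(nr)),
                                    sprintf("T%d", seq_len(nr))))
      design <- data.frame(sample = colnames(m),
                           group = rep(c("control", "treated"), each = nr),
                           stringsAsFactors = FALSE)
      ## guarantee the shared core survives default calling criteria
      for (try in seq_len(30L)) {
        ee <- expression_experiment(m, design, name = sprintf("EXP%d", e))
        calls <- call_rna_state_changes(ee, default_crit)
        got <- stats::setNames(calls$direction, calls$entity)[built$core]
        miss <- built$core[got != built$core_expected[built$core]]
        if (!length(miss)) break
        m[miss, ] <- draw(miss)
      }
      expression_experiment(m, design, name = sprintf("EXP%d", e))
    })
    leaf_truths[[e]] <- expected
  }

  truth <- list(
    common_roots = data.frame(entity = cmn, aspect = "protein_activity",
                              direction = cmn_dir, stringsAsFactors = FALSE),
    private_roots = built$private,
    core_pairs = data.frame(entity = built$core,
                            direction = unname(built$core_expected[built$core]),
                            stringsAsFactors = FALSE),
    backbone_edges = backbone[order(backbone$source_entity,
                                    backbone$target_entity, backbone$sign), ],
    perturbation = list(entity = "CMPD", aspect = "compound"),
    leaf_truth = leaf_truths)
  rownames(truth$backbone_edges) <- NULL
  structure(list(kam = g,
                 experiments = lapply(seq_len(n_experiments), function(e)
                   list(name = sprintf("EXP%d", e),
                        expression = experiments[[e]])),
                 truth = truth, config = config),
            class = "rca_multi_fixture")
}

#' Write a synthetic fixture to disk in pipeline formats
#'
#' Writes the graph (kamtsv), one expression matrix + design TSV pair per
#' experiment, and a JSON manifest recording the ground truth.
#'
#' @param fixture an `rca_multi_fixture` or `rca_sim` (with simulated
#'   expression passed via `experiments`).
#' @param dir output directory.
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "rca_multi_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(kam = file.path(dir, "kam.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_kam(fixture$kam, paths$kam)
  for (ex in fixture$experiments) {
    mp <- file.path(dir, paste0(ex$name, "_matrix.tsv"))
    dp <- file.path(dir, paste0(ex$name, "_design.tsv"))
    m <- ex$expression$matrix
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                       mp, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ex$expression$design, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0(ex$name, "_matrix")]] <- mp
    paths[[paste0(ex$name, "_design")]] <- dp
  }
  jsonlite::write_json(
    list(common_roots = fixture$truth$common_roots,
         core_pairs = fixture$truth$core_pairs,
         private_roots = fixture$truth$private_roots,
         perturbation = fixture$truth$perturbation,
         seed = fixture$config$seed),
    paths$manifest, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
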