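#' Bundle one experiment's evidence and hypothesis ranking
#'
#' @param name experiment name (e.g. cell line + context + timepoint).
#' @param universe data.frame of measured nodes (`entity`, `aspect`).
#' @param changes `state_change_set` for the experiment.
#' @param hypotheses ranked `rca_hypotheses` from [evaluate_all()], derived
#'   from this experiment's universe and changes.
#' @return object of class `rca_experiment`.
#' @export
rca_experiment <- function(name, universe, changes, hypotheses) {
  stopifnot(is.character(name), length(name) == 1L,
            is.data.frame(universe), is.data.frame(changes),
            inherits(hypotheses, "rca_hypotheses"))
  structure(list(name = name, universe = universe, changes = changes,
                 hypotheses = hypotheses), class = "rca_experiment")
}

#' @export
print.rca_experiment <- function(x, ...) {
  cat(sprintf("<experiment> %s: %d measured, %d changed, %d hypotheses\n",
              x$name, nrow(unique(x$universe)),
              sum(x$changes$direction != "no_change"), nrow(x$hypotheses)))
  invisible(x)
}

.tier_ok <- function(tier, floor) {
  if (floor == "significant") tier == "significant"
  else tier %in% c("significant", "marginal")
}

#' Hypothesis roots shared by every experiment
#'
#' Intersects the per-experiment hypothesis rankings: a (root, direction) is
#' selected iff the root meets the tier floor in every experiment and — when
#' `require_same_direction` is set — its selected direction is identical
#' across all of them. This is the computable core of restricting a causal
#' model to mechanisms supported in all sensitive systems.
#'
#' @param experiments list of [rca_experiment] objects.
#' @param tier_floor `"significant"` (default) or `"marginal"`.
#' @param require_same_direction require a consistent direction (default
#'   `TRUE`; direction-inconsistent roots are excluded).
#' @return data.frame `root_entity`, `root_aspect`, `direction`, ordered by
#'   root id.
#' @export
common_hypotheses <- function(experiments, tier_floor = c("significant", "marginal"),
                              require_same_direction = TRUE) {
  tier_floor <- match.arg(tier_floor)
  stopifnot(length(experiments) >= 1L)
  sets <- lapply(experiments, function(e) {
    h <- e$hypotheses
    h <- h[.tier_ok(h$tier, tier_floor), , drop = FALSE]
    h[, c("root_entity", "root_aspect", "direction")]
  })
  keys <- lapply(sets, function(s) node_key(s$root_entity, s$root_aspect))
  common <- Reduce(intersect, keys)
  out <- sets[[1]][keys[[1]] %in% common, , drop = FALSE]
  if (require_same_direction && length(common) && length(sets) > 1L) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      k <- node_key(out$root_entity[i], out$root_aspect[i])
      dirs <- vapply(seq_along(sets), function(j)
        sets[[j]]$direction[match(k, keys[[j]])], character(1))
      length(unique(dirs)) == 1L
    }, logical(1))
    out <- out[ok, , drop = FALSE]
  }
  out <- out[order(out$root_entity, out$root_aspect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.changed_pairs <- function(e) {
  chg <- e$changes[e$changes$direction != "no_change", , drop = FALSE]
  unique(paste(chg$entity, chg$direction, sep = "|"))
}

#' Overlap of observed state changes across experiments
#'
#' Counts shared changed (entity, direction) pairs: per experiment, for every
#' pair of experiments, and over the full intersection. Symmetric under
#' experiment reordering.
#'
#' @param experiments list of at least two [rca_experiment] objects.
#' @return list of class `rca_change_overlap`: `per_experiment` (named counts),
#'   `pairwise` (symmetric matrix of pair intersection sizes),
#'   `full_intersection` (count), `full_intersection_pairs` (data.frame
#'   `entity`, `direction`).
#' @export
change_overlap <- function(experiments) {
  stopifnot(length(experiments) >= 2L)
  pairs <- lapply(experiments, .changed_pairs)
  nms <- vapply(experiments, `[[`, character(1), "name")
  names(pairs) <- nms
  n <- length(pairs)
  pw <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(pairs[[i]], pairs[[j]]))
  full <- sort(Reduce(intersect, pairs))
  sp <- strsplit(full, "|", fixed = TRUE)
  structure(list(
    per_experiment = vapply(pairs, length, integer(1)),
    pairwise = pw,
    full_intersection = length(full),
    full_intersection_pairs = data.frame(
      entity = vapply(sp, `[`, character(1), 1),
      direction = vapply(sp, `[`, character(1), 2),
      stringsAsFactors = FALSE)
  ), class = "rca_change_overlap")
}

#' @export
print.rca_change_overlap <- function(x, ...) {
  cat("<change overlap>\n  per experiment:",
      paste(sprintf("%s=%d", names(x$per_experiment), x$per_experiment),
            collapse = ", "),
      sprintf("\n  full intersection: %d\n", x$full_intersection))
  invisible(x)
}

## Per-root prediction map under its selected direction: named polarity
## vector (key -> "increase"/"decrease"/"ambiguous") over measured nodes.
.root_predictions <- function(kam, root_entity, root_aspect, direction, depth) {
  dn <- downstream_neighborhood(kam, root_entity, root_aspect, depth)
  if (!nrow(dn)) return(stats::setNames(character(), character()))
  pol <- ifelse(dn$plus & dn$minus, "ambiguous",
                ifelse(dn$plus, "increase", "decrease"))
  if (direction == "decrease") {
    pol <- ifelse(pol == "increase", "decrease",
                  ifelse(pol == "decrease", "increase", "ambiguous"))
  }
  stats::setNames(pol, node_key(dn$entity, dn$aspect))
}

#' Explanatory coverage of selected hypotheses per experiment
#'
#' For each experiment, each observed changed node is classified against the
#' selected (root, direction) set: `explained` when at least one root
#' unambiguously predicts the observed direction and none predicts the
#' opposite; `contradicted` when the reverse holds; `conflicted` when
#' selected roots predict both ways. The coverage fraction is
#' explained / total observed changes.
#'
#' @param selected data.frame `root_entity`, `root_aspect`, `direction` (as
#'   from [common_hypotheses()]).
#' @param experiments list of [rca_experiment] objects.
#' @param kam a [kam] object containing all selected roots.
#' @param depth causal search depth (default 2).
#' @return data.frame, one row per experiment: `experiment`, `explained`,
#'   `contradicted`, `conflicted`, `total_changes`, `fraction`.
#' @export
coverage <- function(selected, experiments, kam, depth = 2) {
  stopifnot(is.data.frame(selected), inherits(kam, "kam"))
  kk <- node_key(kam$nodes$entity, kam$nodes$aspect)
  miss <- setdiff(node_key(selected$root_entity, selected$root_aspect), kk)
  if (length(miss)) stop("selected root(s) absent from graph: ",
                         paste(miss, collapse = ", "))
  preds <- lapply(seq_len(nrow(selected)), function(i)
    .root_predictions(kam, selected$root_entity[i], selected$root_aspect[i],
                      selected$direction[i], depth))
  out <- lapply(experiments, function(e) {
    chg <- e$changes[e$changes$direction != "no_change", , drop = FALSE]
    ck <- node_key(chg$entity, chg$aspect)
    supp <- opp <- logical(length(ck))
    for (pm in preds) {
      pv <- unname(pm[ck])
      unamb <- !is.na(pv) & pv != "ambiguous"
      supp <- supp | (unamb & pv == chg$direction)
      opp <- opp | (unamb & pv != chg$direction)
    }
    data.frame(experiment = e$name,
               explained = sum(supp & !opp),
               contradicted = sum(opp & !supp),
               conflicted = sum(supp & opp),
               total_changes = length(ck),
               fraction = if (length(ck)) sum(supp & !opp) / length(ck) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Edges lying on simple directed paths of length <= depth from root id to any
## of the target ids. Returns integer row indices into kam$edges.
.path_edge_rows <- function(kam, index, root_id, target_ids, depth) {
  e <- kam$edges
  si <- unname(index$id[node_key(e$source_entity, e$source_aspect)])
  ti <- unname(index$id[node_key(e$target_entity, e$target_aspect)])
  out_rows <- split(seq_len(nrow(e)), si)
  targets <- rep(FALSE, index$n)
  targets[target_ids] <- TRUE
  hit <- logical(nrow(e))
  onpath <- logical(index$n)
  stack_rows <- integer(depth)
  visit <- function(v, rem, used) {
    rows <- out_rows[[as.character(v)]]
    if (is.null(rows)) return(invisible())
    for (r in rows) {
      t <- ti[r]
      if (onpath[t]) next
      if (targets[t]) hit[c(used, r)] <<- TRUE
      if (rem > 1L) {
        onpath[t] <<- TRUE
        visit(t, rem - 1L, c(used, r))
        onpath[t] <<- FALSE
      }
    }
  }
  onpath[root_id] <- TRUE
  visit(root_id, as.integer(depth), integer())
  which(hit)
}

#' Assemble a Causal Network Model from selected hypotheses
#'
#' Merges the selected (root, direction) hypotheses into one network: the
#' subgraph holds every edge on a simple directed path of at most `depth`
#' steps between selected roots, plus the path edges from each root to the
#' changed nodes it explains. Each root is annotated with the computable
#' vetting criteria: whether it lies causally downstream of the designated
#' perturbation node, whether it is causally connected to another selected
#' root, and whether the root entity is itself an observed state change.
#' Scientist-driven selection beyond these flags is out of scope; the flags
#' and coverage table are the inputs to that judgment.
#'
#' @inheritParams coverage
#' @param perturbation optional list/vector with `entity` and `aspect` naming
#'   the perturbation (e.g. drug compound) node in the graph.
#' @return object of class `rca_cnm`: `selected`, `subgraph` (a [kam]),
#'   `annotations` (per-root flags), `coverage` (from [coverage()]).
#' @export
assemble_cnm <- function(selected, kam, experiments, depth = 2,
                         perturbation = NULL) {
  stopifnot(is.data.frame(selected), inherits(kam, "kam"))
  index <- .kam_index(kam)
  root_keys <- node_key(selected$root_entity, selected$root_aspect)
  root_ids <- unname(index$id[root_keys])
  if (anyNA(root_ids)) stop("selected root(s) absent from graph: ",
                            paste(root_keys[is.na(root_ids)], collapse = ", "))
  cov <- coverage(selected, experiments, kam, depth)

  ## explained nodes per root: measured changed nodes the root unambiguously
  ## predicts in the observed direction in >= 1 experiment, not contradicted
  ## there by another selected root
  preds <- lapply(seq_len(nrow(selected)), function(i)
    .root_predictions(kam, selected$root_entity[i], selected$root_aspect[i],
                      selected$direction[i], depth))
  explained_keys <- lapply(seq_len(nrow(selected)), function(i) character())
  for (e in experiments) {
    chg <- e$changes[e$changes$direction != "no_change", , drop = FALSE]
    ck <- node_key(chg$entity, chg$aspect)
    pv <- lapply(preds, function(pm) unname(pm[ck]))
    supp_any <- Reduce(`|`, lapply(pv, function(v)
      !is.na(v) & v != "ambiguous" & v == chg$direction), rep(FALSE, length(ck)))
    opp_any <- Reduce(`|`, lapply(pv, function(v)
      !is.na(v) & v != "ambiguous" & v != chg$direction), rep(FALSE, length(ck)))
    expl <- supp_any & !opp_any
    for (i in seq_along(preds)) {
      mine <- !is.na(pv[[i]]) & pv[[i]] != "ambiguous" & pv[[i]] == chg$direction
      explained_keys[[i]] <- union(explained_keys[[i]], ck[expl & mine])
    }
  }

  edge_rows <- integer()
  inter_root <- logical(nrow(selected))
  for (i in seq_len(nrow(selected))) {
    other_ids <- root_ids[-i]
    rr <- .path_edge_rows(kam, index, root_ids[i], other_ids, depth)
    if (length(rr)) inter_root[i] <- TRUE
    ek <- unname(index$id[explained_keys[[i]]])
    ek <- ek[!is.na(ek)]
    rr2 <- .path_edge_rows(kam, index, root_ids[i], ek, depth)
    edge_rows <- union(edge_rows, union(rr, rr2))
  }
  ## a root reached by another root's path is also inter-root connected
  for (i in seq_len(nrow(selected))) {
    if (inter_root[i]) next
    ej <- kam$edges[edge_rows, , drop = FALSE]
    tk <- c(node_key(ej$source_entity, ej$source_aspect),
            node_key(ej$target_entity, ej$target_aspect))
    inter_root[i] <- root_keys[i] %in% tk &&
      any(vapply(seq_len(nrow(selected))[-i], function(j) {
        rr <- .path_edge_rows(kam, index, root_ids[j], root_ids[i], depth)
        length(rr) > 0L
      }, logical(1)))
  }

  sub_edges <- kam$edges[sort(edge_rows), , drop = FALSE]
  sub_node_keys <- unique(c(root_keys,
                            node_key(sub_edges$source_entity, sub_edges$source_aspect),
                            node_key(sub_edges$target_entity, sub_edges$target_aspect),
                            unlist(explained_keys)))
  keep <- node_key(kam$nodes$entity, kam$nodes$aspect) %in% sub_node_keys
  subgraph <- kam(kam$nodes[keep, , drop = FALSE], sub_edges,
                  name = paste0(kam$name, "_cnm"))

  downstream_pert <- rep(NA, nrow(selected))
  if (!is.null(perturbation)) {
    pk <- node_key(perturbation[["entity"]], perturbation[["aspect"]])
    pid <- index$id[pk]
    if (is.na(pid)) stop("perturbation node absent from graph: ", pk)
    reach <- .reachable_ids(index, unname(pid))
    downstream_pert <- root_ids %in% reach
  }
  changed_entities <- unique(unlist(lapply(experiments, function(e)
    e$changes$entity[e$changes$direction != "no_change"])))
  annotations <- data.frame(
    root_entity = selected$root_entity, root_aspect = selected$root_aspect,
    direction = selected$direction,
    downstream_of_perturbation = downstream_pert,
    inter_root_connected = inter_root,
    is_state_change = selected$root_entity %in% changed_entities,
    n_explained = vapply(explained_keys, length, integer(1)),
    stringsAsFactors = FALSE)

  structure(list(selected = selected, subgraph = subgraph,
                 annotations = annotations, coverage = cov),
            class = "rca_cnm")
}

#' @export
print.rca_cnm <- function(x, ...) {
  cat(sprintf("<causal network model> %d roots, %d nodes, %d edges\n",
              nrow(x$selected), nrow(x$subgraph$nodes), nrow(x$subgraph$edges)))
  print(x$coverage)
  invisible(x)
}

#' Export a Causal Network Model
#'
#' Writes the merged subgraph in kamtsv format, a JSON sidecar with the
#' selected roots, their annotation flags and per-experiment coverage, and a
#' coverage TSV.
#'
#' @param cnm an `rca_cnm` object.
#' @param dir output directory (created if missing).
#' @param stem file name stem (default `"cnm"`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cnm <- function(cnm, dir, stem = "cnm") {
  stopifnot(inherits(cnm, "rca_cnm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(graph = file.path(dir, paste0(stem, "_graph.tsv")),
             sidecar = file.path(dir, paste0(stem, ".json")),
             coverage = file.path(dir, paste0(stem, "_coverage.tsv")))
  write_kam(cnm$subgraph, paths[["graph"]])
  jsonlite::write_json(list(selected = cnm$selected,
                            annotations = cnm$annotations,
                            coverage = cnm$coverage),
                       paths[["sidecar"]], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(cnm$coverage, paths[["coverage"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a change-overlap report as TSV
#'
#' @param overlap an `rca_change_overlap` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(overlap, path) {
  stopifnot(inherits(overlap, "rca_change_overlap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# per_experiment\t",
                    paste(names(overlap$per_experiment),
                          overlap$per_experiment, sep = "=", collapse = "\t")), con)
  writeLines(paste0("# full_intersection\t", overlap$full_intersection), con)
  utils::write.table(overlap$full_intersection_pairs, con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
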